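channel,x,y,z
F3,-0.545,0.673,0.5
F4,0.545,0.673,0.5
C3,-0.707,0,0.707
C4,0.707,0,0.707
T7,-1,0,0
T8,1,0,0
P3,-0.545,-0.673,0.5
P4,0.545,-0.673,0.5
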