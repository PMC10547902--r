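Package: cryscope
Title: Multimodal Analysis of Newborn Cry Acoustics, EEG, NIRS and Behavioural Distress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking newborn cry acoustics to neurophysiological and
    behavioural signals across arousal conditions (resting, cry, distress).
    Provides a synthetic multimodal session generator with known ground truth;
    cry-unit segmentation and acoustic feature extraction (fundamental
    frequency statistics, formants, jitter, shimmer, harmonics-to-noise ratio,
    mel-frequency cepstral coefficients, mel spectrograms); EEG preprocessing,
    spherical-spline channel interpolation, Welch relative band power and
    percent change versus resting; an oximetry/heart-rate (NIRS) artifact
    filter cascade; COMFORT behavioural scoring; a non-parametric statistical
    battery (Mann-Whitney, Kruskal-Wallis with Dunn post hoc, bootstrap
    Tukey-Kramer, Holm correction, Spearman matrices, tie-corrected Kendall
    concordance); and a cry-versus-distress classifier (random forest on MFCC
    summaries and a small convolutional network on mel spectrograms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    readr,
    randomForest,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
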