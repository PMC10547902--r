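---
title: "Multimodal analysis of newborn cry distress: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal analysis of newborn cry distress: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cryscope)
```

## The scientific problem

A newborn's cry carries graded information about distress. The same arousal
state that raises the fundamental frequency of phonation also shows up in
brain rhythms, heart rate, peripheral and cerebral oxygenation, and in the
behaviours clinicians score at the bedside. cryscope implements a complete
analysis chain for studies that record these modalities simultaneously
across three conditions — *resting*, *cry* (ordinary crying), and
*distress* (acoustically intense, high-spectral-content crying):

1. cry audio is segmented into cry episodes (CEs) and cry units (CUs) and a
   per-unit acoustic descriptor set is extracted;
2. EEG is cleaned, epoched by the audio annotations, and summarized as
   relative band power with percent change versus resting;
3. the oximetry/heart-rate (NIRS) stream passes an artifact filter cascade
   and is segmented by the same annotations;
4. behavioural distress is scored on the six-item COMFORT scale;
5. a non-parametric statistical battery links the modalities; and
6. a classifier (random forest on MFCC summaries; a small convolutional
   network on mel spectrograms) discriminates cry from distress units.

Because multimodal neonatal recordings are rarely shareable, the package is
organised around a *synthetic session generator* with fully known ground
truth: every downstream stage can be exercised, and its estimators
validated, without any external data.

## The synthetic generator

### Cry audio

A cry unit is synthesized by a source–filter model, built
pitch-synchronously: each glottal cycle is an independently scaled copy of
the impulse response of a glottal source (one-pole spectral tilt, −6
dB/oct, so the fundamental carries a realistic share of the energy)
followed by three second-order resonators at the formant frequencies,
truncated at the next glottal instant. Cycle periods are perturbed
multiplicatively (local **jitter**) and cycle gains are perturbed (local
**shimmer**), each scaled by $\sqrt{\pi}/2$ so that the *expected* value of
the printed perturbation formulas equals the programmed fraction.
Aspiration noise is white noise shaped by the same resonators with 3×
broadened bandwidths (a distributed turbulence source sees heavier
damping), scaled analytically so that the harmonic-to-noise power ratio
equals the programmed **HNR** — the analytic ratio is the oracle of every
HNR round-trip test.

Because cycles are exact copies up to gain, noise, and truncation, the
programmed jitter, shimmer and HNR are recoverable *in principle* to the
sample-grid floor (pulses are placed at integer samples of the 48 kHz
grid, a jitter floor of roughly 1/3 sample per period, i.e. ~0.003–0.005
relative).

Default condition profiles are calibrated to the published per-unit feature
table: cry units at F0 478 Hz, HNR 11.9 dB, jitter 0.016, shimmer 0.113,
formants 1429/3558/5897 Hz; distress units at F0 413 Hz, HNR 6.7 dB,
jitter 0.022, shimmer 0.143, formants 1631/3740/6095 Hz, with the
published between-unit SDs. Two generator choices are free parameters the
source tables do not constrain, and were fixed a priori on domain grounds:

* **Intensity.** Distress episodes are *defined* as the acoustically more
  intense class, so distress units are drawn 6 dB louder than cry units
  (3 dB within-class SD).
* **Contour shape.** Cry units favour rise–fall F0 arcs (70%), distress
  units favour falling contours (65%), following the pain-cry literature.

Episode structure follows the published time-domain table: a mean of 37
(cry) / 23 (distress) units per episode with negative-binomial dispersion
matched to the published spread of per-episode vocalized time (`cryCE`),
alternating with expiratory gaps.

### EEG

Eight channels (F3, F4, C3, C4, T7, T8, P3, P4) at 512 Hz are sums of
band-limited Gaussian oscillators (delta, theta, alpha, plus a 12–45 Hz
residual) whose variances are proportional to per-condition relative-power
targets. The resting mix is delta-dominant (0.75/0.08/0.03 relative power
for delta/theta/alpha); cry and distress targets are the resting mix scaled
by the published percent changes (−3.15/+66.54/+166.55% for cry,
−6.27/+93.67/+215.69% for distress). These specific resting values are a
design choice: the published percent changes jointly constrain the resting
profile (the scaled relative powers must still sum below one), and a
delta-heavy mix is also what newborn wakeful EEG looks like. The
oscillators sit *inside* their bands (e.g. delta noise at 1–3 Hz), away
from the half-open band edges, because Welch-window smearing across band
boundaries otherwise dilutes the programmed contrasts; even so, some
leakage survives, so the generator reproduces the *orderings and signs*
exactly and the magnitudes only approximately — which is why the
acceptance checks assert the sign pattern, not the printed percentages. A
source shared across channels (mixing fraction 0.35) reproduces the
inter-channel correlation of volume conduction; fully independent channels
would (correctly) trip the low-correlation bad-channel rule.

### NIRS, COMFORT, and effort coupling

The oximetry stream is sampled once per 2 s with timestamps at bin centres
(1, 3, 5, … s); Gaussian noise surrounds condition means chosen with the
published directions (pulse rate 120/140/155 bpm and SpO2 97/95/93% for
resting/cry/distress; rSO2 77/74/71%). On top of the condition means, an
*effort coupling* shifts each episode's levels in proportion to its
standardized vocalized time (+6 bpm, −2% rSO2, −1% SpO2 per SD), and
COMFORT item means shift by +0.4 items per SD. This coupling is what makes
the published cross-modal structure (crying time positively correlated
with heart rate, negatively with cerebral oxygenation, COMFORT rising with
vocalization) recoverable from the synthetic sessions rather than merely
asserted. COMFORT items are drawn around condition means 1.5/3.2/4.5
(SD 0.6) and clipped to the 1–5 integer scale.

## The analysis chain

### Segmentation and time features

`detect_voiced_regions()` marks a frame voiced when its short-time energy
clears −40 dBFS *and* its normalized autocorrelation peak in the 200–1200
Hz band reaches 0.45. Voiced runs shorter than 200 ms are discarded as
segmentation noise; silences longer than 5 s split episodes (the source
protocol never defines the episode boundary rule, so this is the package's
own convention). `cryCE`/`unvoicedCE` are the summed voiced/unvoiced
durations; their percentages sum to one by construction.

### Pitch, jitter, shimmer, HNR

F0 is tracked framewise (40 ms frames, 10 ms hop) by normalized
autocorrelation restricted to 200–1200 Hz, with a shortest-near-best-lag
rule against octave errors and parabolic lag refinement.

Perturbation measures need cycle markers. `pick_cycles()` marches an
argmax search over the band-passed fundamental, guided by the *local*
expected period from the F0 contour; markers are then re-anchored on the
pre-emphasized (impulsive) signal — with a locally tracked offset, since
the fundamental peak sits a period-dependent fraction into the cycle — and
finally refined against an averaged cycle template, whose noise is
$\sqrt{N}$-suppressed.

Even refined markers carry noise that would inflate jitter and shimmer at
low HNR, so two measurement-error corrections are applied, both standard
moment-separation arguments:

* **Jitter.** True jitter makes cycle positions a random walk whose
  increment variance grows linearly with lag; independent marker errors
  add a constant. A regression of increment variance on lag (after
  removing the slow contour trend) separates the two, and the period
  deviations are rescaled to the implied true scale (a shrinkage, never an
  amplification). `jitter_local()` itself stays the plain printed formula
  `mean(|T[i+1]-T[i]|)/mean(T)`.
* **Shimmer.** Cycle amplitudes are window energies (noise energy
  subtracted); the per-cycle measurement variance is estimated from two
  interleaved-block replicates of the same window. Blocks are sized near
  the shaped-noise correlation length, so the replicate difference cancels
  the noise the blocks share — about half the total, a factor validated
  against synthetic ground truth across HNR 5–20 dB — and the amplitude
  deviations are shrunk accordingly.

HNR is measured from consecutive-cycle normalized cross-correlations at
per-pair alignments (a fixed-lag autocorrelation would conflate jitter
with noise), converted to a per-sample noise power from
maximization-free skip-pair correlations, and referenced against the
whole-unit signal power. The closed form `10*log10(r/(1-r))` is exposed as
`hnr_from_correlation()`. Values are clipped to [−10, 40] dB.

**Known limitation.** Under the distress profile's harshest draws — HNR
near 0 dB combined with two-octave F0 sweeps inside a single unit —
marker noise still inflates measured jitter/shimmer by roughly a quarter
to a third. The estimators are accurate across the calibration grid (F0
350–700 Hz, jitter 0–0.03, HNR 5–25 dB: F0 within 1%, jitter within
max(0.005, 25%), HNR within 2 dB), and the generator's *realized*
perturbations match the published targets within a few percent; the
residual estimator bias at the extreme corner is reported honestly rather
than recalibrated away.

### Formants, MFCCs, spectrograms

Formants: low-pass at 10 kHz, decimate to 16 kHz (an integer factor of
the 48 kHz acquisition rate), pre-emphasize (0.97, which exactly inverts
the source tilt), and run framewise linear prediction of order 10 —
three formant pole pairs plus source/noise poles. Higher orders (e.g. the
common `2 + fs/1000` rule) start modelling individual harmonics of these
high-pitched signals and displace the envelope estimates, which is why the
lower order is used. Poles count as formants when their bandwidth is under
800 Hz (the mixed voiced/turbulence excitation makes fitted bandwidths
broader than the voiced-only 600 Hz rule of thumb) and the per-formant
median over frames is reported; units that are not voiced return a missing
triple.

MFCCs use a 26-filter mel bank to 10 kHz and an orthonormal DCT-II; 13
coefficients, summarized per unit as framewise mean and SD (26 values).
With this normalization an overall gain change moves only the 0th
coefficient. Spectrogram images are 64 mel bands × 48 frames on a fixed
1.5 s canvas (pad/crop), in log10 power, *without* per-image level
normalization — absolute intensity is a class cue by construction.

### EEG pipeline

Order of operations: bad-channel detection → (at most one) spherical-spline
interpolation → band-pass and average reference → epoching → Welch power.
Channels are bad when flat (variance < 0.1 µV²), extreme (> 10× median
variance), or uncorrelated with every other channel; if more than one
channel is bad the recording is rejected rather than interpolated.
Spherical-spline interpolation uses the Legendre-series g-function of
order m = 4, truncated at 7 terms, ridge 1e-5, on idealized unit-sphere
10–20 coordinates shipped as a package fixture.

The 1–45 Hz band-pass is a zero-phase Butterworth high-pass plus
Chebyshev-II low-pass; the steep stopband is needed because 50 Hz line
noise sits only one-ninth of an octave above the 45 Hz edge. Epochs are
non-overlapping 4 s windows tiled inside each condition interval (never
crossing a boundary); an epoch is rejected when the channel-mean of its
peak absolute amplitude reaches 200 µV — "average amplitude" is read as
this statistic because it is both common practice and directly testable.
Welch uses 1 s Hamming segments at 50% overlap (1 Hz resolution aligned
with the band edges); band sums are half-open `[lo, hi)` so the 4 and 8 Hz
bins belong to the upper band exactly once, and relative power is
normalized by total 1–45 Hz power. Percent change versus resting treats
the resting mean as the 100% baseline.

### NIRS cascade

Per variable: a centred 60 s sliding-window SD check removes dropout runs
(SD < 0.5 in native units — window length and units are the package's
choices, the source protocol states neither), then Tukey fences at
1.5×IQR over the whole cleaned recording remove outliers. The cascade is
iterated to a fixed point, which makes it idempotent by construction.
Samples strictly inside `(start+15 s, end−15 s)` of an annotated interval
form its segment (intervals of ≤ 30 s are empty); a segment's variable is
excluded when its mean is strictly below the floor (SpO2 80%, rSO2 50%,
PR 70 bpm) — equality survives.

### Statistical battery

`mann_whitney()` (exact for small untied samples), `kruskal_dunn()`
(tie-corrected H; Dunn z statistics with Holm adjustment within the
pairwise family), `anova_tukey_bootstrap()` (Tukey–Kramer statistics whose
familywise null is a within-group resampling bootstrap, 10,000 repetitions
by default), `holm_bonferroni()`, `spearman_matrix()`
(pairwise-complete), and tie-corrected `kendall_w()`.

Concordance between audio features and the other modalities is
operationalized *pairwise*: each (audio feature, partner feature) pair is
treated as two rankers of a condition's segments, giving one W per pair
per condition, starred at W ≥ 0.5 and framed above 0.7. One caveat is
intrinsic to this reading: with exactly two rankers,
W = (ρ<sub>Spearman</sub>+1)/2, so independent features centre W at
exactly the 0.5 star threshold — the star marks direction-consistent
agreement, not significance. The null Monte-Carlo property tests therefore
check that noise pairs centre at 0.5 and stay below the framed threshold.

### Classifier

The 80/20 split sends the ceiling to training (1,964 units → 1,572/392)
and is plain random by default; a group-wise option exists for
subject-level splits. The random forest (500 trees) consumes the 26 MFCC
summaries. The convolutional network — three blocks of 3×3 convolution,
batch normalization, ReLU and 2×2 max pooling with 16/32/64 filters, a
64-unit dense layer and a 2-way softmax — is implemented directly on BLAS
matrix operations (shifted-matrix convolutions with precomputed index
maps); all gradients are verified against finite differences in the test
suite. Training uses Adam (1e-3), batches of 32, at most 8 epochs with
early stopping on validation loss (patience 3, best weights kept), inputs
standardized by the training set's global mean/SD. Reports use distress as
the positive class, so sensitivity measures distress detection.

## Problem sizes and reproducibility

All stochastic stages take integer seeds and are bit-reproducible at fixed
dependency versions. The shipped checks run at desk scale: the acoustic
round trip uses a 27-point grid of 1.2 s units; EEG condition contrasts
use 295 balanced 4 s epochs per condition; the end-to-end pipeline
exercise uses sessions of 5–9 episodes (≈ 10–13 simulated minutes); the
classifier analogue trains on 1,000 units and validates on 250, with a
label-shuffled control at chance. Cross-modal correlations pool two
sessions (18 episodes) — small by epidemiological standards, and the
reported coefficients are correspondingly noisy, but the coupling built
into the generator makes their signs stable.

## What passing these checks does and does not show

The generator produces stationary Gaussian EEG, ideal-electrode
geometry, stationary oximetry noise, and cries whose cycles are exact
copies up to gain and noise. Real recordings add movement artifacts with
structure, non-stationary backgrounds, imperfect synchronization, and
cry acoustics richer than a three-resonator source–filter model.
Passing the suite therefore demonstrates that the *implementations* are
correct against controllable ground truth and analytic oracles — not that
the pipeline's numbers on real bedside data would match a clinical study.
The quantities that depend only on arithmetic or closed forms (time
bookkeeping, COMFORT totals, band-power normalization, the statistical
oracles) transfer exactly; everything estimated from signals transfers
only as far as the generator's assumptions hold.
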