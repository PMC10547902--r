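## Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

## internal reproducibility helpers used throughout the tests
with_seed <- cryscope:::with_seed
cs_subseed <- cryscope:::cs_subseed

fixture <- function(name, expr) {
  if (!exists(name, .fixtures)) assign(name, force(expr), .fixtures)
  get(name, .fixtures)
}

## a clean flat 500 Hz unit (no perturbation, almost no noise)
clean_unit <- function() fixture("clean_unit", synth_cry_unit(
  cry_params(f0_mean = 500, f0_sd = 0, f0_contour_shape = "flat",
             jitter_frac = 0, shimmer_frac = 0, hnr_db = 40),
  dur = 0.5, seed = 101))

## a Table-1-like cry unit with moderate perturbations
cry_unit <- function() fixture("cry_unit", synth_cry_unit(
  cry_params(f0_mean = 478, f0_sd = 0, f0_contour_shape = "flat",
             jitter_frac = 0.016, shimmer_frac = 0.113, hnr_db = 11.9,
             formants = c(1429, 3558, 5897)),
  dur = 0.8, seed = 102))

audio_fs <- function() cs_default("audio_fs")

## tiny annotated EEG timeline shared by several EEG tests
eeg_fixture <- function() fixture("eeg_fixture", {
  ann <- tibble::tibble(start = c(0, 60, 120), end = c(60, 120, 180),
                        condition = c("resting", "cry", "distress"))
  rec <- synth_eeg(ann, default_condition_profiles(), seed = 301)
  list(ann = ann, rec = rec)
})
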