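#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Single source of truth for every tunable constant used across the
## pipeline. `run_config()` exposes these; individual functions default to
## them via `cs_default()` so a value is never hard-coded twice.
.cryscope_defaults <- list(
  ## -- audio acquisition / synthesis --------------------------------------
  audio_fs          = 48000L,   # Hz, acquisition sampling rate
  audio_bits        = 24L,      # PCM resolution for WAV output
  f0_search_range   = c(200, 1200),   # Hz, band-pass + F0 search interval
  formant_lowpass   = 10000,    # Hz, low-pass before spectral analysis
  high_pitch_hz     = 800,      # F0 threshold for "high pitch" fraction
  hyperphonation_hz = 1000,     # F0 threshold for hyper-phonation fraction
  hnr_limits_db     = c(-10, 40),

  ## -- acoustic analysis ---------------------------------------------------
  frame_ms          = 40,       # F0 analysis frame
  hop_ms            = 10,       # analysis hop
  voicing_threshold = 0.45,     # normalized autocorrelation floor
  min_unit_s        = 0.2,      # discard shorter voiced runs
  episode_break_s   = 5,        # silence longer than this splits episodes
  energy_thresh_db  = -40,      # short-time energy floor (rel. to peak)
  lpc_analysis_fs   = 16000,    # Hz after decimation for formant analysis
  lpc_bw_cutoff     = 800,      # Hz, max pole bandwidth accepted as formant
  preemphasis       = 0.97,
  n_mfcc            = 13L,
  n_mel_mfcc        = 26L,      # mel filters behind the cepstrum
  mel_fmax          = 10000,    # Hz, cepstral/spectrogram upper edge
  spec_canvas_s     = 1.5,      # pad/crop length for spectrogram images
  spec_mel_bands    = 64L,
  spec_frames       = 48L,

  ## -- EEG -----------------------------------------------------------------
  eeg_fs            = 512L,
  eeg_channels      = c("F3", "F4", "C3", "C4", "T7", "T8", "P3", "P4"),
  eeg_bandpass      = c(1, 45),   # Hz
  eeg_epoch_s       = 4,
  eeg_reject_uv     = 200,        # channel-mean peak amplitude ceiling
  eeg_bands         = list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12)),
  eeg_total_band    = c(1, 45),
  welch_window_s    = 1,
  welch_overlap     = 0.5,
  flat_var_uv2      = 0.1,        # variance floor marking a flat channel
  spline_m          = 4L,         # spherical-spline order
  spline_terms      = 7L,         # Legendre series truncation
  spline_lambda     = 1e-5,       # regularization

  ## -- NIRS ----------------------------------------------------------------
  nirs_step_s       = 2,
  nirs_sd_window_s  = 60,
  nirs_sd_floor     = 0.5,
  nirs_iqr_k        = 1.5,
  nirs_trim_s       = 15,
  nirs_floors       = c(SpO2 = 80, rSO2 = 50, PR = 70),

  ## -- COMFORT -------------------------------------------------------------
  comfort_items     = c("alertness", "agitation", "crying",
                        "body_movements", "muscular_tone", "facial_tension"),
  comfort_range     = c(1L, 5L),

  ## -- statistics ----------------------------------------------------------
  boot_reps         = 10000L,
  kendall_strong    = 0.5,
  kendall_framed    = 0.7,

  ## -- classifier ----------------------------------------------------------
  train_frac        = 0.8,
  rf_trees          = 500L,
  cnn_filters       = c(16L, 32L, 64L),
  cnn_dense         = 64L,
  cnn_epochs        = 8L,
  cnn_batch         = 32L,
  cnn_lr            = 1e-3,
  cnn_patience      = 3L
)

#' Look up a package default
#'
#' All paper-derived constants (200--1200 Hz pitch band, 800/1000 Hz pitch
#' thresholds, 1--45 Hz EEG band, 4-s epochs, 200 uV rejection, 0.5 SD floor,
#' 1.5*IQR fences, 15 s trimming, 80/50/70 floors, 10,000 bootstrap reps,
#' 0.8 training fraction) live in one internal table; this accessor reads it.
#'
#' @param name name of the constant.
#' @return the default value.
#' @export
cs_default <- function(name) {
  if (!name %in% names(.cryscope_defaults)) {
    stop("unknown default: ", name, call. = FALSE)
  }
  .cryscope_defaults[[name]]
}
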