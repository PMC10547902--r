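#' Ground-truth parameters of one synthetic cry unit generator
#'
#' Bundles the source-filter parameters that drive [synth_cry_unit()]:
#' fundamental frequency level and within-unit excursion, contour shape,
#' cycle-to-cycle perturbations (jitter/shimmer), harmonics-to-noise ratio
#' and the three vocal-tract resonances.
#'
#' @param f0_mean mean fundamental frequency, Hz (must lie in 200--1200 Hz,
#'   the phonation band of newborn cries).
#' @param f0_sd within-unit F0 excursion (standard deviation of the contour), Hz.
#' @param f0_contour_shape one of `"flat"`, `"rise-fall"`, `"falling"`.
#' @param jitter_frac target local jitter (mean relative cycle-to-cycle period
#'   deviation), in `[0, 0.2]`.
#' @param shimmer_frac target local shimmer (mean relative cycle-to-cycle
#'   amplitude deviation), in `[0, 0.2]`.
#' @param hnr_db target harmonics-to-noise ratio, dB, in `[-10, 40]`.
#' @param formants numeric triple `(F1, F2, F3)` in Hz, strictly increasing.
#' @param formant_bw resonator bandwidths in Hz (one per formant).
#' @param unit_dur_range range (s) cry-unit durations are drawn from.
#' @param gap_dur_range range (s) inter-unit (expiration) gaps are drawn from.
#' @param n_units mean number of cry units per episode.
#' @param n_units_cv coefficient of variation of the per-episode unit count
#'   (0 = fixed count; episode sizes are drawn negative-binomially so the
#'   total vocalized time per episode has a realistic spread).
#' @param level_db overall unit level, dB relative to full scale.
#' @return an object of class `cry_params`.
#' @examples
#' cry_params(f0_mean = 500, jitter_frac = 0.02)
#' @export
cry_params <- function(f0_mean = 480,
                       f0_sd = 95,
                       f0_contour_shape = c("rise-fall", "flat", "falling"),
                       jitter_frac = 0.016,
                       shimmer_frac = 0.113,
                       hnr_db = 12,
                       formants = c(1430, 3560, 5900),
                       formant_bw = c(250, 350, 450),
                       unit_dur_range = c(0.5, 1.2),
                       gap_dur_range = c(0.3, 0.8),
                       n_units = 8L,
                       n_units_cv = 0,
                       level_db = -20) {
  f0_contour_shape <- match.arg(f0_contour_shape)
  cs_assert(f0_mean >= 200 && f0_mean <= 1200, "f0_mean must lie in [200, 1200] Hz")
  cs_assert(f0_sd >= 0, "f0_sd must be non-negative")
  cs_assert(jitter_frac >= 0 && jitter_frac <= 0.2, "jitter_frac must lie in [0, 0.2]")
  cs_assert(shimmer_frac >= 0 && shimmer_frac <= 0.2, "shimmer_frac must lie in [0, 0.2]")
  lim <- cs_default("hnr_limits_db")
  cs_assert(hnr_db >= lim[1] && hnr_db <= lim[2],
            sprintf("hnr_db must lie in [%g, %g] dB", lim[1], lim[2]))
  cs_assert(length(formants) == 3 && all(diff(formants) > 0),
            "formants must be a strictly increasing triple")
  cs_assert(all(unit_dur_range > 0) && all(gap_dur_range > 0),
            "durations must be positive")
  cs_assert(n_units >= 1, "n_units must be at least 1")
  structure(list(
    f0_mean = f0_mean, f0_sd = f0_sd, f0_contour_shape = f0_contour_shape,
    jitter_frac = jitter_frac, shimmer_frac = shimmer_frac, hnr_db = hnr_db,
    formants = as.numeric(formants), formant_bw = as.numeric(formant_bw),
    unit_dur_range = as.numeric(unit_dur_range),
    gap_dur_range = as.numeric(gap_dur_range),
    n_units = as.integer(n_units), n_units_cv = n_units_cv,
    level_db = level_db
  ), class = "cry_params")
}

#' @export
print.cry_params <- function(x, ...) {
  cat("<cry_params>\n")
  cat(sprintf("  F0 %g Hz (sd %g, %s contour), jitter %.3f, shimmer %.3f, HNR %g dB\n",
              x$f0_mean, x$f0_sd, x$f0_contour_shape,
              x$jitter_frac, x$shimmer_frac, x$hnr_db))
  cat(sprintf("  formants %s Hz, %d units of %.2g-%.2g s, gaps %.2g-%.2g s\n",
              paste(round(x$formants), collapse = "/"), x$n_units,
              x$unit_dur_range[1], x$unit_dur_range[2],
              x$gap_dur_range[1], x$gap_dur_range[2]))
  invisible(x)
}

#' Per-condition generative profile for a synthetic session
#'
#' Describes one arousal condition (resting, cry or distress): the acoustic
#' generator parameters and their between-unit spread, the EEG relative-power
#' targets, the oximetry/heart-rate levels, and the COMFORT item means.
#'
#' @param condition `"resting"`, `"cry"` or `"distress"`.
#' @param cry_params a [cry_params()] object (`NULL` for resting).
#' @param cry_param_sd named list of between-unit standard deviations used when
#'   drawing per-unit parameters around `cry_params` (names among `f0_mean`,
#'   `jitter_frac`, `shimmer_frac`, `hnr_db`, `f1`, `f2`, `f3`, `level_db`).
#' @param contour_probs named probabilities over contour shapes for per-unit draws.
#' @param eeg_band_gains named numeric `(delta, theta, alpha)` relative-power
#'   targets (each positive, summing to < 1; the remainder goes to the
#'   12--45 Hz residual band).
#' @param nirs_levels named numeric `(rSO2, SpO2, PR)` condition means
#'   (percent, percent, beats/min).
#' @param nirs_sd named numeric noise SDs for the three series.
#' @param comfort_item_means six values in `[1, 5]`.
#' @param comfort_sd SD of the per-item score draw before integer clipping.
#' @return an object of class `condition_profile`.
#' @seealso [default_condition_profiles()]
#' @export
condition_profile <- function(condition = c("resting", "cry", "distress"),
                              cry_params = NULL,
                              cry_param_sd = list(),
                              contour_probs = NULL,
                              eeg_band_gains = c(delta = 0.75, theta = 0.08, alpha = 0.03),
                              nirs_levels = c(rSO2 = 77, SpO2 = 97, PR = 120),
                              nirs_sd = c(rSO2 = 3, SpO2 = 1.5, PR = 8),
                              comfort_item_means = rep(1.5, 6),
                              comfort_sd = 0.6) {
  condition <- match.arg(condition)
  cs_assert(all(eeg_band_gains > 0), "eeg_band_gains must be positive")
  cs_assert(sum(eeg_band_gains) < 1, "eeg_band_gains must sum to < 1")
  cs_assert(nirs_levels[["SpO2"]] >= 0 && nirs_levels[["SpO2"]] <= 100,
            "SpO2 must lie in [0, 100]")
  cs_assert(length(comfort_item_means) == 6 &&
              all(comfort_item_means >= 1 & comfort_item_means <= 5),
            "comfort_item_means must be six values in [1, 5]")
  if (condition != "resting") {
    cs_assert(inherits(cry_params, "cry_params"),
              "non-resting profiles need cry_params")
  }
  structure(list(
    condition = condition, cry_params = cry_params,
    cry_param_sd = cry_param_sd, contour_probs = contour_probs,
    eeg_band_gains = eeg_band_gains,
    nirs_levels = nirs_levels, nirs_sd = nirs_sd,
    comfort_item_means = as.numeric(comfort_item_means), comfort_sd = comfort_sd
  ), class = "condition_profile")
}

#' @export
print.condition_profile <- function(x, ...) {
  cat(sprintf("<condition_profile: %s>\n", x$condition))
  cat(sprintf("  EEG rel-power targets d/t/a: %s\n",
              paste(signif(x$eeg_band_gains, 3), collapse = "/")))
  cat(sprintf("  NIRS rSO2/SpO2/PR: %s\n",
              paste(signif(x$nirs_levels, 4), collapse = "/")))
  cat(sprintf("  COMFORT item means: %s\n",
              paste(signif(x$comfort_item_means, 2), collapse = ", ")))
  if (!is.null(x$cry_params)) print(x$cry_params)
  invisible(x)
}

#' Default condition profiles of the synthetic study
#'
#' The generator's study conditions. Acoustic means and between-unit SDs
#' follow the published per-unit feature table for the cry and distress
#' classes (F0 478/413 Hz, HNR 11.9/6.7 dB, jitter 0.016/0.022, shimmer
#' 0.113/0.143, formants 1429/3558/5897 vs 1631/3740/6095 Hz). Distress units
#' are on average 6 dB more intense than cry units (distress episodes are
#' defined as the acoustically more intense class) and favour falling F0
#' contours. EEG targets encode the relative-power percent changes versus
#' resting (delta -3.15/-6.27%, theta +66.54/+93.67%, alpha +166.55/+215.69%
#' for cry/distress) on a delta-dominant resting mix. NIRS levels encode the
#' observed directions: oxygenation falls and pulse rate rises with distress.
#' COMFORT item means increase from resting to distress.
#'
#' @return named list of three [condition_profile()] objects
#'   (`resting`, `cry`, `distress`).
#' @examples
#' prof <- default_condition_profiles()
#' prof$distress$cry_params$hnr_db
#' @export
default_condition_profiles <- function() {
  sd_cry <- list(f0_mean = 109.4, jitter_frac = 0.011, shimmer_frac = 0.044,
                 hnr_db = 4.38, f1 = 406, f2 = 449, f3 = 488, level_db = 3)
  sd_dis <- list(f0_mean = 109.1, jitter_frac = 0.013, shimmer_frac = 0.041,
                 hnr_db = 3.30, f1 = 470, f2 = 453, f3 = 459, level_db = 3)
  pc_cry <- c(delta = -3.15, theta = 66.54, alpha = 166.55)
  pc_dis <- c(delta = -6.27, theta = 93.67, alpha = 215.69)
  rest_gain <- c(delta = 0.75, theta = 0.08, alpha = 0.03)
  list(
    resting = condition_profile(
      "resting",
      eeg_band_gains = rest_gain,
      nirs_levels = c(rSO2 = 77, SpO2 = 97, PR = 120),
      comfort_item_means = rep(1.5, 6)
    ),
    cry = condition_profile(
      "cry",
      cry_params = cry_params(
        f0_mean = 477.563, f0_sd = 94.23, f0_contour_shape = "rise-fall",
        jitter_frac = 0.016, shimmer_frac = 0.113, hnr_db = 11.88,
        formants = c(1428.963, 3557.709, 5897.238),
        unit_dur_range = c(0.5, 1.2), gap_dur_range = c(0.3, 0.8),
        n_units = 37L, n_units_cv = 1.0, level_db = -20
      ),
      cry_param_sd = sd_cry,
      contour_probs = c("rise-fall" = 0.7, flat = 0.2, falling = 0.1),
      eeg_band_gains = rest_gain * (1 + pc_cry / 100),
      nirs_levels = c(rSO2 = 74, SpO2 = 95, PR = 140),
      comfort_item_means = rep(3.2, 6)
    ),
    distress = condition_profile(
      "distress",
      cry_params = cry_params(
        f0_mean = 412.587, f0_sd = 141.05, f0_contour_shape = "falling",
        jitter_frac = 0.022, shimmer_frac = 0.143, hnr_db = 6.662,
        formants = c(1630.672, 3739.816, 6094.533),
        unit_dur_range = c(0.9, 1.7), gap_dur_range = c(0.4, 0.9),
        n_units = 23L, n_units_cv = 0.55, level_db = -14
      ),
      cry_param_sd = sd_dis,
      contour_probs = c("rise-fall" = 0.25, flat = 0.1, falling = 0.65),
      eeg_band_gains = rest_gain * (1 + pc_dis / 100),
      nirs_levels = c(rSO2 = 71, SpO2 = 93, PR = 155),
      comfort_item_means = rep(4.5, 6)
    )
  )
}
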