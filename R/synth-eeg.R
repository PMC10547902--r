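## Synthetic 8-channel neonatal EEG with condition-dependent band structure.

## band-limited Gaussian noise scaled to an exact target variance
band_noise <- function(n, fs, lo, hi, target_var) {
  x <- stats::rnorm(n)
  ny <- fs / 2
  bf <- signal::butter(4, c(max(lo, 0.2) / ny, min(hi, 0.98 * ny) / ny), type = "pass")
  y <- as.numeric(signal::filtfilt(bf, x))
  y * sqrt(target_var) / stats::sd(y)
}

#' Synthesize a multichannel EEG recording over an annotated timeline
#'
#' Per channel and condition interval, the signal is a sum of band-limited
#' Gaussian processes (delta 1--4, theta 4--8, alpha 8--12, and a 12--45 Hz
#' residual) whose variances are proportional to the profile's
#' relative-power targets, so the expected Welch relative powers reproduce
#' the programmed condition ordering (delta falling, theta/alpha rising from
#' resting to distress). Optionally injects high-amplitude artifact bursts
#' (> 200 uV) and/or one flat channel for rejection testing.
#'
#' @param annotations tibble with `start`, `end` (s) and `condition`; must
#'   tile `[0, max(end)]` without gaps.
#' @param profiles named list of [condition_profile()]s (one per condition
#'   appearing in `annotations`).
#' @param seed integer seed.
#' @param fs sampling rate, Hz.
#' @param total_rms total signal scale in uV (RMS per channel).
#' @param artifact_rate expected artifact bursts per minute per channel.
#' @param flat_channel optional channel name to zero out (plus tiny jitter).
#' @return an [eeg_recording()] with attribute `truth` (the per-condition
#'   relative-power targets).
#' @export
synth_eeg <- function(annotations, profiles, seed = 1L,
                      fs = cs_default("eeg_fs"),
                      total_rms = 30,
                      artifact_rate = 0,
                      flat_channel = NULL) {
  annotations <- tibble::as_tibble(annotations)
  cs_assert(all(c("start", "end", "condition") %in% names(annotations)),
            "annotations need start, end, condition")
  o <- order(annotations$start)
  annotations <- annotations[o, ]
  gaps <- annotations$start[-1] - annotations$end[-nrow(annotations)]
  cs_assert(nrow(annotations) == 1 || all(abs(gaps) < 1e-6),
            "timeline must cover [0, T] without gaps")
  channels <- cs_default("eeg_channels")
  bands <- cs_default("eeg_bands")
  n_total <- round(max(annotations$end) * fs)

  with_seed(seed, {
    X <- matrix(0, n_total, length(channels), dimnames = list(NULL, channels))
    for (i in seq_len(nrow(annotations))) {
      cond <- annotations$condition[i]
      prof <- profiles[[cond]]
      cs_assert(!is.null(prof), paste("no profile for condition", cond))
      g <- prof$eeg_band_gains
      resid <- 1 - sum(g)
      i0 <- round(annotations$start[i] * fs) + 1L
      i1 <- min(n_total, round(annotations$end[i] * fs))
      n_seg <- i1 - i0 + 1L
      if (n_seg < fs) next
      ## oscillators sit inside their bands, away from the edges, so that
      ## filter skirts and Welch-window smearing leak little across the
      ## half-open band boundaries; a shared source mixed into every
      ## channel reproduces the inter-channel correlation of volume
      ## conduction (independent channels would trip the low-correlation
      ## bad-channel rule)
      rho_sh <- 0.35
      gen_seg <- function() {
        band_noise(n_seg, fs, bands$delta[1], bands$delta[2] - 1,
                   g[["delta"]] * total_rms^2) +
        band_noise(n_seg, fs, bands$theta[1] + 0.5, bands$theta[2] - 0.5,
                   g[["theta"]] * total_rms^2) +
        band_noise(n_seg, fs, bands$alpha[1] + 0.5, bands$alpha[2] - 0.5,
                   g[["alpha"]] * total_rms^2) +
        band_noise(n_seg, fs, 13, 45, resid * total_rms^2)
      }
      shared <- gen_seg()
      for (ch in seq_along(channels)) {
        X[i0:i1, ch] <- sqrt(1 - rho_sh) * gen_seg() + sqrt(rho_sh) * shared
      }
    }
    ## artifact bursts: 300 ms half-sine excursions well above the 200 uV rule
    art <- tibble::tibble(time = numeric(0), channel = character(0))
    if (artifact_rate > 0) {
      n_art <- stats::rpois(1, artifact_rate * (n_total / fs / 60) * length(channels))
      if (n_art > 0) {
        t_art <- sort(stats::runif(n_art, 0.5, n_total / fs - 0.5))
        ch_art <- sample(channels, n_art, replace = TRUE)
        for (k in seq_len(n_art)) {
          i0 <- round(t_art[k] * fs)
          len <- round(0.3 * fs)
          idx <- i0:min(n_total, i0 + len - 1L)
          X[idx, ch_art[k]] <- X[idx, ch_art[k]] +
            500 * sin(pi * seq_along(idx) / length(idx))
        }
        art <- tibble::tibble(time = t_art, channel = ch_art)
      }
    }
    if (!is.null(flat_channel)) {
      cs_assert(flat_channel %in% channels, "unknown flat_channel")
      X[, flat_channel] <- stats::rnorm(n_total, sd = 0.01)
    }
    rec <- eeg_recording(X, fs = fs)
    attr(rec, "truth") <- list(
      band_targets = lapply(profiles, function(p) p$eeg_band_gains),
      artifacts = art, flat_channel = flat_channel
    )
    rec
  })
}
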