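## Spectral-envelope analysis: formants, MFCCs, mel spectrograms.

## autocorrelation-method LPC coefficients of one windowed frame
lpc_coefs <- function(frame, order) {
  n <- length(frame)
  nfft <- cs_npow2(2L * n)
  sp <- stats::fft(c(frame, numeric(nfft - n)))
  ac <- Re(stats::fft(sp * Conj(sp), inverse = TRUE))[1:(order + 1L)] / nfft
  if (ac[1] <= 0) return(NULL)
  R <- stats::toeplitz(ac[1:order])
  a <- tryCatch(solve(R, -ac[2:(order + 1L)]), error = function(e) NULL)
  if (is.null(a) || anyNA(a)) return(NULL)
  c(1, a)
}

## resonance candidates (Hz, bandwidth Hz) from LPC polynomial roots
lpc_resonances <- function(a, fs) {
  rt <- polyroot(rev(a))
  ang <- Arg(rt); mod <- Mod(rt)
  keep <- ang > 0.01 & ang < pi - 0.01 & mod < 1
  f <- ang[keep] * fs / (2 * pi)
  bw <- -fs / pi * log(mod[keep])
  o <- order(f)
  cbind(freq = f[o], bw = bw[o])
}

#' Estimate the first three formants of a voiced cry unit
#'
#' Low-passes at 10 kHz, decimates to 16 kHz, pre-emphasizes, and runs
#' framewise linear-prediction analysis. The model order (10 at 16 kHz)
#' budgets three formant pole pairs plus poles for the source spectrum and
#' noise floor; higher orders start fitting individual harmonics of the
#' high-pitched cry and displace the envelope resonances. Resonances are the
#' complex-pole angles with bandwidth below the cutoff; the unit value is
#' the per-formant median over frames that yield at least three qualifying
#' poles. Units that are not voiced (e.g. noise), or where fewer than a
#' quarter of frames qualify, return a missing triple.
#'
#' @param wave mono waveform.
#' @param fs sampling rate, Hz.
#' @param lowpass anti-noise low-pass corner, Hz.
#' @param analysis_fs decimated analysis rate, Hz (divisor of `fs`).
#' @param order linear-prediction order at `analysis_fs`.
#' @param bw_cutoff maximum accepted pole bandwidth, Hz.
#' @param voicing_gate if `TRUE`, require at least 20% voiced frames first.
#' @return named numeric `(f1, f2, f3)` in Hz, or all-`NA` when missing.
#' @export
formants <- function(wave, fs,
                     lowpass = cs_default("formant_lowpass"),
                     analysis_fs = 16000,
                     order = 10L,
                     bw_cutoff = cs_default("lpc_bw_cutoff"),
                     voicing_gate = TRUE) {
  wave <- as.numeric(wave)
  missing3 <- c(f1 = NA_real_, f2 = NA_real_, f3 = NA_real_)
  if (voicing_gate) {
    ctr <- tryCatch(f0_contour(wave, fs), error = function(e) NULL)
    if (is.null(ctr) || mean(ctr$voiced) < 0.2) return(missing3)
  }
  x <- cs_lowpass(wave, fs, min(lowpass, 0.45 * fs))
  x <- cs_decimate(x, fs, analysis_fs)
  x <- c(x[1], x[-1] - cs_default("preemphasis") * x[-length(x)])
  flen <- round(0.030 * analysis_fs)
  hop <- round(0.015 * analysis_fs)
  fr <- cs_frames(x, flen, hop)
  if (ncol(fr) == 0) return(missing3)
  win <- cs_hamming(flen)
  picks <- matrix(NA_real_, 3, ncol(fr))
  for (j in seq_len(ncol(fr))) {
    a <- lpc_coefs(fr[, j] * win, order)
    if (is.null(a)) next
    res <- lpc_resonances(a, analysis_fs)
    res <- res[res[, "bw"] < bw_cutoff & res[, "freq"] > 400 &
                 res[, "freq"] < 0.47 * analysis_fs, , drop = FALSE]
    if (nrow(res) >= 3) picks[, j] <- res[1:3, "freq"]
  }
  ok <- colSums(is.na(picks)) == 0
  if (mean(ok) <= 0.25) return(missing3)
  out <- apply(picks[, ok, drop = FALSE], 1, stats::median)
  c(f1 = out[1], f2 = out[2], f3 = out[3])
}

## triangular mel filterbank matrix (n_mels x n_bins)
mel_filterbank <- function(n_mels, nfft, fs, fmin = 0, fmax = fs / 2) {
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  n_bins <- nfft %/% 2L + 1L
  freqs <- (seq_len(n_bins) - 1L) * fs / nfft
  edges <- mel2hz(seq(hz2mel(fmin), hz2mel(fmax), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (freqs - lo) / (ce - lo)
    dn <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

## orthonormal DCT-II matrix (n_out x n_in)
dct_matrix <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1L
  n <- seq_len(n_in) - 1L
  M <- sqrt(2 / n_in) * cos(outer(k, n, function(k, n) pi * k * (2 * n + 1) / (2 * n_in)))
  M[1, ] <- M[1, ] / sqrt(2)
  M
}

#' Mel-frequency cepstral coefficients of a cry unit
#'
#' Framewise mel filterbank log energies followed by an orthonormal DCT-II;
#' the first `n_mfcc` coefficients are kept. The unit summary is the
#' framewise mean and SD of each coefficient (`2 * n_mfcc` values).
#'
#' @param wave mono waveform.
#' @param fs sampling rate, Hz.
#' @param n_mfcc number of cepstral coefficients.
#' @param n_mels mel filters behind the cepstrum.
#' @param fmax upper filterbank edge, Hz.
#' @param frame_ms,hop_ms cepstral frame and hop, ms.
#' @return list: `frames` (n_mfcc x n_frames matrix) and `summary` (named
#'   numeric of per-coefficient means `mfcc*_mean` then SDs `mfcc*_sd`).
#' @export
mfcc <- function(wave, fs,
                 n_mfcc = cs_default("n_mfcc"),
                 n_mels = cs_default("n_mel_mfcc"),
                 fmax = cs_default("mel_fmax"),
                 frame_ms = 25, hop_ms = 10) {
  wave <- as.numeric(wave)
  flen <- round(frame_ms / 1000 * fs)
  hop <- round(hop_ms / 1000 * fs)
  fr <- cs_frames(wave, flen, hop)
  cs_assert(ncol(fr) > 0, "unit too short for cepstral analysis")
  win <- cs_hamming(flen)
  nfft <- cs_npow2(flen)
  sp <- stats::mvfft(rbind(fr * win, matrix(0, nfft - flen, ncol(fr))))
  pow <- abs(sp[1:(nfft %/% 2L + 1L), , drop = FALSE])^2
  fb <- mel_filterbank(n_mels, nfft, fs, fmax = fmax)
  loge <- log(pmax(fb %*% pow, 1e-12))
  cc <- dct_matrix(n_mfcc, n_mels) %*% loge
  mu <- rowMeans(cc)
  sdv <- apply(cc, 1, stats::sd)
  names(mu) <- paste0("mfcc", seq_len(n_mfcc) - 1L, "_mean")
  names(sdv) <- paste0("mfcc", seq_len(n_mfcc) - 1L, "_sd")
  list(frames = cc, summary = c(mu, sdv))
}

#' Fixed-size log-mel spectrogram image of a cry unit
#'
#' Pads or crops the unit to a fixed canvas, then computes a log-magnitude
#' mel spectrogram at a fixed shape so every unit maps to the same image
#' size (the convolutional classifier input).
#'
#' @param wave mono waveform.
#' @param fs sampling rate, Hz.
#' @param canvas_s canvas duration, s (pad with zeros / crop beyond).
#' @param n_mels mel bands (image rows).
#' @param n_frames time frames (image columns).
#' @param fmax upper mel edge, Hz.
#' @return `n_mels x n_frames` numeric matrix of log10 mel power.
#' @export
mel_spectrogram <- function(wave, fs,
                            canvas_s = cs_default("spec_canvas_s"),
                            n_mels = cs_default("spec_mel_bands"),
                            n_frames = cs_default("spec_frames"),
                            fmax = cs_default("mel_fmax")) {
  wave <- as.numeric(wave)
  n_canvas <- round(canvas_s * fs)
  if (length(wave) >= n_canvas) {
    wave <- wave[seq_len(n_canvas)]
  } else {
    wave <- c(wave, numeric(n_canvas - length(wave)))
  }
  hop <- n_canvas %/% n_frames
  flen <- min(2048L, 2L * hop)
  wave <- c(wave, numeric(flen))
  starts <- (seq_len(n_frames) - 1L) * hop + 1L
  fr <- vapply(starts, function(s) wave[s:(s + flen - 1L)], numeric(flen))
  win <- cs_hamming(flen)
  nfft <- cs_npow2(flen)
  sp <- stats::mvfft(rbind(fr * win, matrix(0, nfft - flen, n_frames)))
  pow <- abs(sp[1:(nfft %/% 2L + 1L), , drop = FALSE])^2
  fb <- mel_filterbank(n_mels, nfft, fs, fmax = fmax)
  log10(pmax(fb %*% pow, 1e-10))
}

#' Full acoustic feature vector of one cry unit
#'
#' Computes the per-unit frequency-domain descriptor set: F0 statistics over
#' voiced frames, high-pitch and hyper-phonation fractions, local jitter and
#' shimmer from picked cycles, HNR, and the three formants. Units whose
#' contour is entirely unvoiced are marked invalid (`valid = FALSE`, all
#' features `NA`) and are meant to be excluded downstream.
#'
#' @param wave mono waveform of one cry unit.
#' @param fs sampling rate, Hz.
#' @return one-row tibble with the feature columns plus `valid`.
#' @export
unit_features <- function(wave, fs) {
  ctr <- f0_contour(wave, fs)
  st <- f0_statistics(ctr)
  if (st$n_voiced == 0 || st$prop_voiced < 0.2) {
    return(tibble::tibble(
      f0_mean = NA_real_, f0_min = NA_real_, f0_max = NA_real_, f0_sd = NA_real_,
      high_pitch_pct = NA_real_, hyperphonation_pct = NA_real_,
      jitter_local = NA_real_, shimmer_local = NA_real_, hnr = NA_real_,
      f1 = NA_real_, f2 = NA_real_, f3 = NA_real_, valid = FALSE))
  }
  cyc <- pick_cycles(wave, fs, contour = ctr)
  fmt <- formants(wave, fs)
  tibble::tibble(
    f0_mean = st$f0_mean, f0_min = st$f0_min, f0_max = st$f0_max, f0_sd = st$f0_sd,
    high_pitch_pct = st$high_pitch_pct, hyperphonation_pct = st$hyperphonation_pct,
    jitter_local = jitter_local(cyc$periods),
    shimmer_local = shimmer_local(cyc$amplitudes),
    hnr = hnr(wave, fs, cycles = cyc),
    f1 = fmt[["f1"]], f2 = fmt[["f2"]], f3 = fmt[["f3"]],
    valid = TRUE)
}

#' Acoustic feature tables for a set of episodes over one waveform
#'
#' Applies [unit_features()] to every cry unit and [time_features()] to every
#' episode.
#'
#' @param episodes list of [cry_episode()] objects (e.g. from
#'   [detect_voiced_regions()] or built from annotation ground truth).
#' @param wave the underlying waveform.
#' @param fs sampling rate, Hz.
#' @return list of tibbles: `units` (one row per cry unit, with `episode`,
#'   `unit`, `condition`, `start`, `end` and the feature columns) and
#'   `episodes` (one row per episode with the time features).
#' @export
acoustic_feature_table <- function(episodes, wave, fs) {
  wave <- as.numeric(wave)
  unit_rows <- list(); ep_rows <- list()
  for (e in seq_along(episodes)) {
    ep <- episodes[[e]]
    ep_rows[[e]] <- dplyr::bind_cols(
      tibble::tibble(episode = e, condition = ep$condition,
                     start = ep$start, end = ep$end),
      time_features(ep))
    for (u in seq_len(nrow(ep$units))) {
      i0 <- max(1L, round(ep$units$start[u] * fs) + 1L)
      i1 <- min(length(wave), round(ep$units$end[u] * fs))
      feat <- unit_features(wave[i0:i1], fs)
      unit_rows[[length(unit_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(episode = e, unit = u, condition = ep$condition,
                       start = ep$units$start[u], end = ep$units$end[u]),
        feat)
    }
  }
  list(units = dplyr::bind_rows(unit_rows), episodes = dplyr::bind_rows(ep_rows))
}
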