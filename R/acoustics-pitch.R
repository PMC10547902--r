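## Pitch, perturbation and noise analysis of cry units.

## framewise normalized autocorrelation over frames starting at `starts`;
## FFTs are batched in blocks to bound memory on long recordings
frame_autocorr_f0 <- function(x, starts, flen, fs, f0_range) {
  lag_min <- max(2L, floor(fs / f0_range[2]))
  lag_max <- ceiling(fs / f0_range[1])
  nfft <- cs_npow2(2L * flen)
  out <- matrix(NA_real_, length(starts), 2,
                dimnames = list(NULL, c("f0", "r")))
  lags <- lag_min:min(lag_max, flen - 1L)
  block <- 512L
  for (b0 in seq(1L, length(starts), by = block)) {
    cols <- b0:min(length(starts), b0 + block - 1L)
    M <- vapply(starts[cols], function(s) x[s:(s + flen - 1L)], numeric(flen))
    M <- sweep(M, 2, colMeans(M))
    SP <- stats::mvfft(rbind(M, matrix(0, nfft - flen, ncol(M))))
    AC <- Re(stats::mvfft(SP * Conj(SP), inverse = TRUE))[1:(lag_max + 2L), ,
                                                          drop = FALSE]
    for (jj in seq_along(cols)) {
      ac <- AC[, jj]
      if (ac[1] <= 0) { out[cols[jj], ] <- c(NA, 0); next }
      r <- ac / ac[1]
      rl <- r[lags + 1L]
      ## local maxima; prefer the shortest lag among near-best peaks to
      ## avoid octave (period-doubling) errors of a plain global argmax
      iloc <- which(diff(sign(diff(rl))) == -2) + 1L
      if (!length(iloc)) iloc <- which.max(rl)
      best <- max(rl[iloc])
      cand <- iloc[rl[iloc] >= 0.87 * best]
      k <- cand[which.min(lags[cand])]
      lag <- lags[k]
      ## parabolic refinement around the integer lag
      if (lag > lag_min && lag < lag_max && lag + 2L <= length(r)) {
        y1 <- r[lag]; y2 <- r[lag + 1L]; y3 <- r[lag + 2L]
        den <- y1 - 2 * y2 + y3
        if (abs(den) > 1e-12) lag <- lag + max(-0.5, min(0.5, 0.5 * (y1 - y3) / den))
      }
      out[cols[jj], ] <- c(fs / lag, rl[k])
    }
  }
  out
}

#' Frame-wise fundamental frequency contour of a cry unit
#'
#' Band-passes the unit to the phonation band (200--1200 Hz by default),
#' then estimates per-frame F0 by normalized autocorrelation with the search
#' restricted to the same band. Frames whose autocorrelation peak falls below
#' the voicing threshold are flagged unvoiced and carry `NA` F0.
#'
#' @param wave numeric waveform (mono).
#' @param fs sampling rate, Hz.
#' @param frame_ms,hop_ms analysis frame and hop, ms.
#' @param f0_range numeric `(lo, hi)` Hz; both the band-pass corner
#'   frequencies and the F0 search interval.
#' @param voicing_threshold minimum normalized autocorrelation for a frame to
#'   count as voiced.
#' @return tibble with columns `time` (frame centre, s), `f0` (Hz, `NA` when
#'   unvoiced), `voiced`, `r` (autocorrelation peak).
#' @examples
#' w <- synth_cry_unit(cry_params(f0_mean = 440, f0_sd = 0, jitter_frac = 0,
#'                                shimmer_frac = 0, hnr_db = 40,
#'                                f0_contour_shape = "flat"), 0.4, seed = 2)
#' median(f0_contour(w, attr(w, "fs"))$f0, na.rm = TRUE)
#' @export
f0_contour <- function(wave, fs,
                       frame_ms = cs_default("frame_ms"),
                       hop_ms = cs_default("hop_ms"),
                       f0_range = cs_default("f0_search_range"),
                       voicing_threshold = cs_default("voicing_threshold")) {
  wave <- as.numeric(wave)
  cs_assert(length(wave) >= 3 * fs / f0_range[1] / 1,
            "unit shorter than three pitch periods")
  xb <- cs_bandpass(wave, fs, f0_range[1], f0_range[2], order = 2)
  flen <- round(frame_ms / 1000 * fs)
  hop <- round(hop_ms / 1000 * fs)
  starts <- seq(1L, length(wave) - flen + 1L, by = hop)
  if (!length(starts)) {
    return(tibble::tibble(time = numeric(0), f0 = numeric(0),
                          voiced = logical(0), r = numeric(0)))
  }
  est <- frame_autocorr_f0(xb, starts, flen, fs, f0_range)
  centers <- (starts - 1L) / fs + flen / 2 / fs
  voiced <- !is.na(est[, "f0"]) & est[, "r"] >= voicing_threshold
  tibble::tibble(
    time = centers,
    f0 = ifelse(voiced, est[, "f0"], NA_real_),
    voiced = voiced,
    r = est[, "r"]
  )
}

#' Descriptive statistics of an F0 contour
#'
#' Statistics are taken over voiced frames only. `high_pitch_pct` is the
#' fraction of voiced frames at or above 800 Hz, `hyperphonation_pct` the
#' fraction at or above 1000 Hz.
#'
#' @param contour tibble from [f0_contour()].
#' @param high_pitch_hz,hyperphonation_hz thresholds, Hz.
#' @return one-row tibble: `f0_mean`, `f0_min`, `f0_max`, `f0_sd`,
#'   `high_pitch_pct`, `hyperphonation_pct`, `n_voiced`, `prop_voiced`.
#' @export
f0_statistics <- function(contour,
                          high_pitch_hz = cs_default("high_pitch_hz"),
                          hyperphonation_hz = cs_default("hyperphonation_hz")) {
  f0 <- contour$f0[contour$voiced]
  n <- length(f0)
  if (n == 0) {
    return(tibble::tibble(f0_mean = NA_real_, f0_min = NA_real_,
                          f0_max = NA_real_, f0_sd = NA_real_,
                          high_pitch_pct = NA_real_, hyperphonation_pct = NA_real_,
                          n_voiced = 0L, prop_voiced = 0))
  }
  tibble::tibble(
    f0_mean = mean(f0), f0_min = min(f0), f0_max = max(f0),
    f0_sd = if (n > 1) stats::sd(f0) else 0,
    high_pitch_pct = mean(f0 >= high_pitch_hz),
    hyperphonation_pct = mean(f0 >= hyperphonation_hz),
    n_voiced = n,
    prop_voiced = mean(contour$voiced)
  )
}

#' Pick glottal cycle peaks of a voiced unit
#'
#' Cycle instants are located by marching an argmax search over a lightly
#' band-passed copy of the unit (150--2000 Hz, zero-phase), window-guided by
#' the running period estimate. Peak-picking (rather than zero crossings)
#' keeps the markers anchored to the glottal pulses under formant ripple and
#' additive noise. Periods and cycle amplitudes feed [jitter_local()],
#' [shimmer_local()] and [hnr()].
#'
#' @param wave numeric waveform.
#' @param fs sampling rate, Hz.
#' @param f0_hint optional F0 (Hz) to seed the search; estimated from the
#'   median of [f0_contour()] when missing.
#' @param contour optional precomputed [f0_contour()]: the local expected
#'   period guides the cycle search, which keeps the march on track through
#'   wide pitch sweeps and heavy noise.
#' @return list: `peaks` (refined sample indices), `periods` (s, from
#'   pair-aligned cycle distances), `amplitudes` (noise-corrected cycle RMS
#'   amplitudes), `r_mean` (mean normalized correlation between consecutive
#'   cycles, the harmonic fraction behind [hnr()]).
#' @export
pick_cycles <- function(wave, fs, f0_hint = NULL, contour = NULL) {
  wave <- as.numeric(wave)
  empty <- list(peaks = integer(0), periods = numeric(0),
                amplitudes = numeric(0), r_mean = NA_real_)
  if (is.null(contour) && is.null(f0_hint)) {
    contour <- tryCatch(f0_contour(wave, fs), error = function(e) NULL)
  }
  f0_fun <- NULL
  if (!is.null(contour) && any(contour$voiced)) {
    v <- contour[contour$voiced, ]
    if (is.null(f0_hint)) f0_hint <- stats::median(v$f0)
    f0_fun <- if (nrow(v) >= 2) {
      stats::approxfun(v$time, v$f0, rule = 2)
    } else {
      function(t) rep(v$f0[1], length(t))
    }
  }
  if (is.null(f0_hint) || !is.finite(f0_hint)) return(empty)
  if (is.null(f0_fun)) f0_fun <- function(t) rep(f0_hint, length(t))
  t_exp <- function(p) fs / f0_fun(p / fs)     # local expected period, samples

  ## isolate the fundamental: one clean peak per glottal cycle (a wider band
  ## would pass first-formant ripple and de-anchor the argmax march)
  xb <- cs_bandpass(wave, fs, 150, 950, order = 2)
  sgn <- sign(xb[which.max(abs(xb))])
  y <- xb * sgn
  t0 <- fs / f0_hint
  p0 <- which.max(y)
  march <- function(start, dir) {
    peaks <- integer(0); p <- start
    repeat {
      tr <- t_exp(p)
      lo <- round(p + dir * 1.30 * tr); hi <- round(p + dir * 0.70 * tr)
      win <- sort(c(lo, hi)); win[1] <- max(1L, win[1]); win[2] <- min(length(y), win[2])
      if (win[1] >= win[2]) break
      q <- win[1] - 1L + which.max(y[win[1]:win[2]])
      peaks <- c(peaks, q); p <- q
      if (length(peaks) > 10000) break
    }
    peaks
  }
  peaks <- sort(c(rev(march(p0, -1L)), p0, march(p0, +1L)))
  ## the input is an already-segmented voiced unit, so the march covers the
  ## whole span; cycles that fell into a quiet edge are filtered afterwards
  ## (a hard in-loop break would end the march on any single noise dip)
  peaks <- peaks[y[peaks] >= 0.1 * stats::median(y[peaks])]
  if (length(peaks) < 3) return(empty)

  ## re-anchor each cycle marker at the glottal pulse: the band-passed
  ## fundamental peaks a variable fraction into the cycle, while the
  ## pre-emphasized signal is impulsive at the excitation instant; anchoring
  ## there keeps the analysis windows inside their own glottal cycle
  n <- length(wave)
  wp_all <- c(wave[1], wave[-1] - 0.97 * wave[-n])
  sgn2 <- sign(wp_all[which.max(abs(wp_all))])
  yp <- wp_all * sgn2
  ## two passes: a wide search estimates the (constant within a unit)
  ## offset between the fundamental peak and the excitation instant; a tight
  ## search around the expected pulse then avoids locking onto first-formant
  ## ripple peaks one ripple period away
  anchor <- function(p, half) {
    lo <- min(max(1L, p - half), n)
    hi <- max(min(n, p + half), lo)
    as.integer(lo - 1L + which.max(yp[lo:hi]))
  }
  wide <- vapply(peaks, function(p)
    anchor(p, round(0.4 * t_exp(p))), integer(1))
  ## the fundamental-peak-to-pulse offset varies slowly with the period, so
  ## it is tracked locally (running median) rather than fixed per unit
  offs <- wide - peaks
  delta <- if (length(offs) >= 15) {
    as.integer(round(stats::runmed(offs, 15)))
  } else rep(as.integer(round(stats::median(offs))), length(offs))
  peaks <- vapply(seq_along(peaks), function(i)
    anchor(peaks[i] + delta[i], max(4L, round(0.12 * t_exp(peaks[i])))),
    integer(1))
  peaks <- sort(unique(peaks))
  if (length(peaks) < 3) return(empty)

  ## alignment runs on the pre-emphasized copy: impulsive timing, and
  ## (being a time-invariant FIR) aligned cycles remain exact copies
  wp <- wp_all

  ## template refinement: averaging aligned cycles suppresses the additive
  ## noise by sqrt(#cycles), and re-aligning every cycle against the clean
  ## template makes the per-cycle timing errors small and independent
  ## (pairwise alignment noise would add directly to the jitter estimate);
  ## the anchors are absolute positions, so errors do not accumulate
  L <- floor(0.85 * stats::quantile(diff(peaks), 0.1, names = FALSE))
  if (L < 16) return(empty)
  mk_template <- function(sig, positions) {
    ok <- positions >= 1 & positions + L - 1L <= n
    if (sum(ok) < 2) return(NULL)
    M <- vapply(positions[ok], function(p) sig[p:(p + L - 1L)], numeric(L))
    rowMeans(M)
  }
  refine <- function(sig, tmpl, p) {
    best <- -Inf; bs <- 0L
    for (s in -8L:8L) {
      q0 <- p + s
      if (q0 < 1L || q0 + L - 1L > n) next
      seg <- sig[q0:(q0 + L - 1L)]
      e <- sum(seg^2)
      r <- if (e > 0) sum(seg * tmpl) / sqrt(e) else -Inf
      if (r > best) { best <- r; bs <- s }
    }
    p + bs
  }
  tmpl <- mk_template(wp, peaks)
  if (is.null(tmpl)) return(empty)
  q <- vapply(peaks, function(p) refine(wp, tmpl, p), numeric(1))
  tmpl <- mk_template(wp, q)
  q <- vapply(q, function(p) refine(wp, tmpl, p), numeric(1))
  q <- as.integer(q)
  dq <- diff(q)
  med_q <- stats::median(dq)
  ## pairs judged against the local expected period (contour-aware)
  exp_q <- vapply((q[-length(q)] + q[-1]) / 2, t_exp, numeric(1))
  good_pair <- dq > 0.65 * exp_q & dq < 1.45 * exp_q

  ## separate true period perturbation from marker noise by their lag
  ## structure: true jitter makes the pulse positions a random walk whose
  ## increment variance grows linearly with lag, while independent marker
  ## errors add a constant; the regression intercept estimates the marker
  ## noise, and the period deviations are shrunk to the implied true scale
  ## the regression runs on the longest run of clean consecutive cycles so
  ## that occasional missed/doubled markers cannot corrupt the variances
  runs <- rle(good_pair)
  shrink_j <- 1
  marker_noise <- NA_real_
  if (any(runs$values & runs$lengths >= 20)) {
    ri <- which.max(ifelse(runs$values, runs$lengths, 0L))
    i1 <- sum(runs$lengths[seq_len(ri)])
    i0 <- i1 - runs$lengths[ri] + 1L
    qr <- q[i0:(i1 + 1L)]
    m_q <- length(qr)
    ## remove the slow F0 contour (running-mean position trend) before the
    ## lag regression: a contour would otherwise make the increment
    ## variance grow quadratically with lag and masquerade as jitter
    w_tr <- min(31L, m_q - (m_q + 1L) %% 2L)
    trend <- stats::filter(qr, rep(1 / w_tr, w_tr), sides = 2)
    e_q <- (qr - as.numeric(trend))[!is.na(trend)]
    m_e <- length(e_q)
    ks <- 1:6
    vk <- vapply(ks, function(k)
      if (m_e > k + 4) stats::var(e_q[(1 + k):m_e] - e_q[1:(m_e - k)]) else NA_real_,
      numeric(1))
    ok_k <- is.finite(vk)
    if (sum(ok_k) >= 3) {
      fit <- stats::lm.fit(cbind(1, ks[ok_k]), vk[ok_k])
      sT2 <- max(fit$coefficients[2], 0)
      se2 <- max(fit$coefficients[1] / 2, 0)
      ## slope-implied true jitter: E|T[i+1]-T[i]| = 2 sigma_T / sqrt(pi)
      ## for Gaussian iid period perturbations
      t0_run <- stats::median(diff(qr))
      marker_noise <- sqrt(se2) / t0_run
      j_slope <- 2 * sqrt(sT2 / pi) / t0_run
      raw_j <- mean(abs(diff(dq[good_pair]))) / mean(dq[good_pair])
      ## a shrinkage, never an amplification
      if (is.finite(j_slope) && raw_j > 0) shrink_j <- min(j_slope / raw_j, 1)
    }
  }
  ## periods are detrended with a robust running median so that the slow F0
  ## contour contributes to the contour statistics, not to cycle-to-cycle
  ## jitter; deviations are then rescaled to the marker-noise-corrected scale
  t0_hat <- mean(dq[good_pair])
  dq_trend <- stats::runmed(dq, k = min(15L, length(dq) - (length(dq) + 1L) %% 2L))
  periods_out <- (t0_hat + shrink_j * (dq - dq_trend))[good_pair] / fs

  ## noise power from distant cycle pairs (three cycles apart) at the
  ## template alignments: no shift maximization is performed on these
  ## correlations, so the implied uncorrelated (noise) share carries no
  ## selection bias; windows are bounded by each member's own cycle length
  ## so neither window crosses a grain boundary under jitter
  skip <- 3L
  n_skip <- max(0L, length(dq) - skip + 1L)
  pn_skip <- rep(NA_real_, n_skip)
  for (i in seq_len(n_skip)) {
    j <- i + skip
    own_j <- if (j <= length(dq)) dq[j] else dq[length(dq)]
    len <- floor(0.85 * min(dq[i], own_j))
    j0 <- q[i + skip]
    if (len < 16 || j0 < 1L || j0 + len - 1L > n || q[i] + len - 1L > n) next
    s1 <- wave[q[i]:(q[i] + len - 1L)]
    s3 <- wave[j0:(j0 + len - 1L)]
    den <- sqrt(sum(s1^2) * sum(s3^2))
    if (den > 0) {
      r13 <- sum(s1 * s3) / den
      pn_skip[i] <- (1 - min(r13, 1)) * den / len
    }
  }

  ## whole-unit HNR: the skip-pair-implied per-sample noise power against
  ## the total signal power over the spanned cycles (a correlation alone
  ## would report a cycle-onset-weighted, i.e. local, harmonic fraction)
  ## adjacent-cycle harmonic correlation at the template alignments (no
  ## shift search on these either)
  r_adj <- rep(NA_real_, max(0L, length(dq)))
  for (i in seq_along(dq)) {
    len <- floor(0.85 * min(dq[i], if (i < length(dq)) dq[i + 1] else dq[i]))
    j0 <- q[i + 1L]
    if (len < 16 || j0 + len - 1L > n || q[i] + len - 1L > n) next
    s1 <- wave[q[i]:(q[i] + len - 1L)]
    s2 <- wave[j0:(j0 + len - 1L)]
    den <- sqrt(sum(s1^2) * sum(s2^2))
    if (den > 0) r_adj[i] <- sum(s1 * s2) / den
  }
  r_mean <- if (any(is.finite(r_adj))) mean(r_adj, na.rm = TRUE) else NA_real_
  pn_hat <- if (any(is.finite(pn_skip))) mean(pn_skip, na.rm = TRUE) else NA_real_
  span <- wave[max(1L, q[1]):min(n, q[length(q)] + round(med_q))]
  p_tot <- mean(span^2)
  hnr_db <- if (is.finite(pn_hat) && pn_hat > 0) {
    lim <- cs_default("hnr_limits_db")
    ph_hat <- max(p_tot - pn_hat, p_tot * 1e-4)
    min(max(10 * log10(ph_hat / pn_hat), lim[1]), lim[2])
  } else NA_real_

  ## cycle amplitudes: RMS of a window opening a few samples before the
  ## excitation instant (residual alignment error then falls in the quiet
  ## pre-pulse region instead of clipping the energetic onset), with the
  ## estimated additive-noise energy subtracted. Two disjoint half-window
  ## replicates per cycle estimate the per-cycle measurement noise, and the
  ## amplitude deviations are shrunk to the implied true shimmer scale.
  pre <- 8L
  pnL <- if (is.finite(pn_hat)) pn_hat * L else 0
  idx_amp <- function(idx, frac) {
    vapply(q, function(p) {
      p0a <- p - pre
      if (p0a < 1L || p0a + L - 1L > n) return(NA_real_)
      en <- sum(wave[p0a + idx]^2)
      sqrt(max(en - pnL * frac, 0.1 * en))
    }, numeric(1))
  }
  amps <- idx_amp(0:(L - 1L), 1)
  ## per-cycle measurement variance from two interleaved-block replicates
  ## (blocks sized near the shaped-noise correlation length): the replicate
  ## difference cancels the noise component the blocks share, which is of
  ## the same size as the independent component, hence the factor two
  bl <- max(4L, L %/% 8L)
  b0 <- seq(0L, L - bl, by = bl)
  iA <- unlist(lapply(b0[seq(1, length(b0), by = 2)], function(s) s:(s + bl - 1L)))
  iB <- unlist(lapply(b0[seq(2, length(b0), by = 2)], function(s) s:(s + bl - 1L)))
  aA <- idx_amp(iA, length(iA) / L)
  aB <- idx_amp(iB, length(iB) / L)
  aA <- aA / mean(aA, na.rm = TRUE)
  aB <- aB / mean(aB, na.rm = TRUE)
  ok_a <- is.finite(amps) & is.finite(aA) & is.finite(aB)
  if (sum(ok_a) >= 10) {
    var_u <- stats::var(aA[ok_a] - aB[ok_a]) / 2
    mu_a <- mean(amps[ok_a])
    var_a <- stats::var(amps[ok_a] / mu_a)
    s_a <- sqrt(max(var_a - var_u, 0) / max(var_a, 1e-300))
    amps <- mu_a + s_a * (amps - mu_a)
  }
  list(peaks = q, periods = periods_out,
       amplitudes = amps,
       r_mean = r_mean, hnr_db = hnr_db,
       marker_noise = marker_noise,
       good_frac = mean(good_pair))
}

#' Local jitter of a pitch-period sequence
#'
#' `mean(|T[i+1] - T[i]|) / mean(T)`: the mean relative cycle-to-cycle
#' deviation of the pitch period.
#'
#' @param periods numeric vector of pitch periods (s); needs at least two.
#' @return dimensionless fraction, `NA` when fewer than two periods.
#' @examples
#' jitter_local(c(2.0, 2.2, 2.0) / 1000)  # 0.0968
#' @export
jitter_local <- function(periods) {
  periods <- periods[is.finite(periods)]
  if (length(periods) < 2) return(NA_real_)
  mean(abs(diff(periods))) / mean(periods)
}

#' Local shimmer of a cycle-amplitude sequence
#'
#' `mean(|A[i+1] - A[i]|) / mean(A)`: the mean relative cycle-to-cycle
#' deviation of the cycle peak amplitude.
#'
#' @param amplitudes numeric vector of per-cycle amplitudes; needs at least two.
#' @return dimensionless fraction, `NA` when fewer than two cycles.
#' @export
shimmer_local <- function(amplitudes) {
  amplitudes <- amplitudes[is.finite(amplitudes)]
  if (length(amplitudes) < 2) return(NA_real_)
  mean(abs(diff(amplitudes))) / mean(amplitudes)
}

#' Convert a harmonic-correlation value to HNR in dB
#'
#' `HNR = 10 log10(r / (1 - r))`, clipped to the supported range; `r` is the
#' harmonic fraction of the signal power (normalized correlation between
#' consecutive pitch cycles).
#'
#' @param r correlation in (0, 1).
#' @param limits clip range, dB.
#' @return HNR in dB.
#' @examples
#' hnr_from_correlation(0.5)  # 0 dB
#' @export
hnr_from_correlation <- function(r, limits = cs_default("hnr_limits_db")) {
  r <- pmin(pmax(r, 1e-4), 1 - 1e-4)
  pmin(pmax(10 * log10(r / (1 - r)), limits[1]), limits[2])
}

#' Harmonics-to-noise ratio of a cry unit
#'
#' The normalized cross-correlation between consecutive pitch cycles — each
#' pair aligned at its own picked cycle peaks and compared over the shorter
#' of the two cycle lengths — splits each cycle window's power into a
#' correlated (harmonic) and an uncorrelated (additive-noise) part. Aligning
#' per pair keeps the split unbiased under jitter: a fixed-lag
#' autocorrelation decorrelates as pulse timing drifts across a long
#' analysis window, conflating jitter with additive noise. The implied noise
#' power is then referenced against the whole-unit signal power, and the
#' ratio is reported in dB, clipped to `[-10, 40]`.
#'
#' @inheritParams pick_cycles
#' @param cycles optional precomputed [pick_cycles()] result.
#' @return HNR in dB (`NA` if fewer than three cycles are found).
#' @export
hnr <- function(wave, fs, f0_hint = NULL, cycles = NULL) {
  wave <- as.numeric(wave)
  if (is.null(cycles)) cycles <- pick_cycles(wave, fs, f0_hint)
  if (is.null(cycles$hnr_db)) return(NA_real_)
  cycles$hnr_db
}
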