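## EEG preprocessing, epoching, Welch relative band power, percent change.

#' Construct an 8-channel EEG recording
#'
#' @param data numeric matrix (samples x 8) in uV; column names must be the
#'   extended 10--20 channels F3, F4, C3, C4, T7, T8, P3, P4 (set if absent).
#' @param fs sampling rate, Hz.
#' @param bad_channels character vector of channel names flagged bad.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs = cs_default("eeg_fs"), bad_channels = character(0)) {
  channels <- cs_default("eeg_channels")
  data <- as.matrix(data)
  cs_assert(ncol(data) == length(channels),
            sprintf("expected %d channels", length(channels)))
  if (is.null(colnames(data))) colnames(data) <- channels
  cs_assert(identical(sort(colnames(data)), sort(channels)),
            "channel names must be the 8 extended 10-20 names")
  data <- data[, channels, drop = FALSE]
  cs_assert(all(bad_channels %in% channels), "unknown bad channel name")
  structure(list(data = data, fs = fs, bad_channels = bad_channels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: 8 ch x %.1f s @ %d Hz%s>\n",
              nrow(x$data) / x$fs, x$fs,
              if (length(x$bad_channels))
                paste0(", bad: ", paste(x$bad_channels, collapse = ",")) else ""))
  invisible(x)
}

#' Band-pass filter and average-reference an EEG recording
#'
#' Applies a zero-phase Butterworth band-pass (1--45 Hz by default, removing
#' line noise and slow drifts), then re-references every channel to the
#' average of the good channels.
#'
#' @param rec an [eeg_recording()].
#' @param band numeric `(lo, hi)` Hz.
#' @param average_reference re-reference to the good-channel mean?
#' @return filtered [eeg_recording()].
#' @export
preprocess_eeg <- function(rec, band = cs_default("eeg_bandpass"),
                           average_reference = TRUE) {
  cs_assert(inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  ny <- rec$fs / 2
  ## high-pass: drifts/DC; low-pass: a steep Chebyshev-II stopband so that
  ## 50 Hz line noise sits >= 40 dB down despite the nearby 45 Hz edge
  hp <- signal::butter(2, band[1] / ny, type = "high")
  lp <- signal::cheby2(6, 40, (band[2] + 4) / ny, type = "low")
  X <- apply(rec$data, 2, function(ch) {
    ch <- ch - mean(ch)          # demean first: filtfilt edge transients
    as.numeric(signal::filtfilt(lp, signal::filtfilt(hp, ch)))
  })
  if (average_reference) {
    good <- setdiff(colnames(X), rec$bad_channels)
    ref <- rowMeans(X[, good, drop = FALSE])
    X <- X - ref
  }
  eeg_recording(X, fs = rec$fs, bad_channels = rec$bad_channels)
}

#' Flag noisy or flat EEG channels
#'
#' A channel is flagged when it is flat (variance below `flat_var`), has
#' extreme variance (more than `var_ratio` times the median channel
#' variance), or correlates poorly with every other channel.
#'
#' @param rec an [eeg_recording()].
#' @param flat_var variance floor, uV^2.
#' @param var_ratio extreme-variance multiplier.
#' @param min_cor minimum best absolute correlation with any other channel.
#' @return character vector of flagged channel names.
#' @export
detect_bad_channels <- function(rec, flat_var = cs_default("flat_var_uv2"),
                                var_ratio = 10, min_cor = 0.05) {
  X <- rec$data
  v <- apply(X, 2, stats::var)
  flat <- v < flat_var
  extreme <- v > var_ratio * stats::median(v)
  lowcor <- rep(FALSE, ncol(X))
  if (ncol(X) > 2) {
    cm <- abs(stats::cor(X))
    diag(cm) <- 0
    lowcor <- apply(cm, 2, max) < min_cor
  }
  colnames(X)[flat | extreme | (lowcor & !flat)]
}

#' Idealized unit-sphere 10--20 electrode positions
#'
#' @return tibble with `channel`, `x`, `y`, `z` (unit-norm coordinates;
#'   +x right, +y anterior, +z vertex).
#' @export
electrode_positions <- function() {
  path <- system.file("extdata", "electrodes_1020.csv", package = "cryscope")
  if (nzchar(path)) {
    readr::read_csv(path, show_col_types = FALSE)
  } else {
    ## fallback used before installation
    tibble::tibble(
      channel = c("F3", "F4", "C3", "C4", "T7", "T8", "P3", "P4"),
      x = c(-0.545, 0.545, -0.707, 0.707, -1, 1, -0.545, 0.545),
      y = c(0.673, 0.673, 0, 0, 0, 0, -0.673, -0.673),
      z = c(0.5, 0.5, 0.707, 0.707, 0, 0, 0.5, 0.5)
    )
  }
}

## Legendre-series g-function of spherical-spline interpolation
spline_gfun <- function(cosang, m = cs_default("spline_m"),
                        n_terms = cs_default("spline_terms")) {
  out <- matrix(0, nrow(cosang), ncol(cosang))
  for (n in seq_len(n_terms)) {
    Pn <- legendre_pn(n, cosang)
    out <- out + (2 * n + 1) / (n^m * (n + 1)^m) * Pn
  }
  out / (4 * pi)
}

## Legendre polynomial P_n evaluated elementwise (Bonnet recursion)
legendre_pn <- function(n, x) {
  p0 <- matrix(1, nrow(x), ncol(x))
  if (n == 0) return(p0)
  p1 <- x
  if (n == 1) return(p1)
  for (k in 2:n) {
    p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
    p0 <- p1; p1 <- p2
  }
  p1
}

#' Spherical-spline interpolation of one bad EEG channel
#'
#' Reconstructs the potential at one electrode from the seven good
#' electrodes with the spherical-spline method (Legendre-series g-function
#' of order `m = 4`, series truncated at 7 terms, ridge regularization
#' `1e-5`). At most one channel may be interpolated: recordings with more
#' bad channels must be rejected instead, so more than one is an error.
#'
#' @param rec an [eeg_recording()] whose `bad_channels` has length one (or
#'   pass `bad` explicitly).
#' @param bad name of the channel to rebuild.
#' @param positions electrode table from [electrode_positions()].
#' @return an [eeg_recording()] with the channel replaced and no bad channels.
#' @export
interpolate_spherical_spline <- function(rec, bad = rec$bad_channels,
                                         positions = electrode_positions()) {
  cs_assert(inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  cs_assert(length(bad) == 1,
            "exactly one channel can be interpolated; reject the trial otherwise")
  channels <- colnames(rec$data)
  good <- setdiff(channels, bad)
  P <- as.matrix(positions[match(channels, positions$channel), c("x", "y", "z")])
  rownames(P) <- channels
  cosang <- P %*% t(P)
  cosang <- pmin(pmax(cosang, -1), 1)

  G <- spline_gfun(cosang[good, good, drop = FALSE])
  G <- G + diag(cs_default("spline_lambda"), length(good))
  gx <- spline_gfun(cosang[bad, good, drop = FALSE])

  ## solve [G 1; 1' 0] [c; c0] = [v; 0] for every sample at once
  A <- rbind(cbind(G, 1), c(rep(1, length(good)), 0))
  V <- rbind(t(rec$data[, good, drop = FALSE]), 0)
  C <- solve(A, V)
  interp <- as.numeric(cbind(gx, 1) %*% C)

  X <- rec$data
  X[, bad] <- interp
  eeg_recording(X, fs = rec$fs, bad_channels = character(0))
}

#' Cut condition-labelled 4-second epochs and reject high-amplitude ones
#'
#' Non-overlapping epochs are tiled within each annotated condition
#' interval (never crossing a boundary). An epoch is good when the mean
#' over channels of its peak absolute amplitude stays below the rejection
#' ceiling (200 uV).
#'
#' @param rec a preprocessed [eeg_recording()].
#' @param annotations tibble with `start`, `end`, `condition` (s).
#' @param epoch_s epoch length, s.
#' @param reject_uv amplitude ceiling, uV.
#' @return list of epochs; each has `data` (samples x channels), `condition`,
#'   `start`, `quality` (`"good"` or `"rejected"`). The attribute `counts`
#'   tabulates good/rejected per condition.
#' @export
epoch_and_reject <- function(rec, annotations,
                             epoch_s = cs_default("eeg_epoch_s"),
                             reject_uv = cs_default("eeg_reject_uv")) {
  cs_assert(inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  n_ep <- round(epoch_s * rec$fs)
  epochs <- list()
  for (i in seq_len(nrow(annotations))) {
    i0 <- round(annotations$start[i] * rec$fs) + 1L
    i1 <- round(annotations$end[i] * rec$fs)
    n_fit <- (i1 - i0 + 1L) %/% n_ep
    for (k in seq_len(n_fit)) {
      a <- i0 + (k - 1L) * n_ep
      seg <- rec$data[a:(a + n_ep - 1L), , drop = FALSE]
      peak <- mean(apply(abs(seg), 2, max))
      epochs[[length(epochs) + 1L]] <- list(
        data = seg, condition = annotations$condition[i],
        start = (a - 1L) / rec$fs,
        quality = if (peak < reject_uv) "good" else "rejected")
    }
  }
  counts <- table(
    condition = vapply(epochs, `[[`, character(1), "condition"),
    quality = vapply(epochs, `[[`, character(1), "quality"))
  structure(epochs, counts = counts, fs = rec$fs)
}

#' Welch power spectral density of one epoch
#'
#' Hamming-windowed segments (1 s, 50% overlap by default), periodograms
#' averaged per channel.
#'
#' @param epoch_data samples x channels matrix.
#' @param fs sampling rate, Hz.
#' @param window_s segment length, s.
#' @param overlap fractional overlap between segments.
#' @return list: `freq` (Hz) and `psd` (freq x channels, power per Hz bin).
#' @export
welch_psd <- function(epoch_data, fs,
                      window_s = cs_default("welch_window_s"),
                      overlap = cs_default("welch_overlap")) {
  epoch_data <- as.matrix(epoch_data)
  nwin <- round(window_s * fs)
  hop <- max(1L, round(nwin * (1 - overlap)))
  win <- cs_hamming(nwin)
  u <- sum(win^2)
  starts <- seq(1L, nrow(epoch_data) - nwin + 1L, by = hop)
  n_bins <- nwin %/% 2L + 1L
  psd <- matrix(0, n_bins, ncol(epoch_data),
                dimnames = list(NULL, colnames(epoch_data)))
  for (s in starts) {
    seg <- epoch_data[s:(s + nwin - 1L), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    sp <- stats::mvfft(seg * win)
    pw <- abs(sp[1:n_bins, , drop = FALSE])^2 / (u * fs)
    pw[2:(n_bins - 1L), ] <- 2 * pw[2:(n_bins - 1L), ]
    psd <- psd + pw
  }
  list(freq = (seq_len(n_bins) - 1L) * fs / nwin, psd = psd / length(starts))
}

#' Relative band power from a PSD
#'
#' Band power summed over half-open bins `[lo, hi)` divided by total power
#' over the half-open total range (1--45 Hz). With this convention the 4 Hz
#' and 8 Hz bins belong to the upper band exactly once, and the relative
#' powers of all bins in the total range sum to one.
#'
#' @param psd freq x channels matrix (or vector).
#' @param freq bin frequencies, Hz.
#' @param bands named list of `(lo, hi)` pairs.
#' @param total `(lo, hi)` of the normalization range.
#' @return bands x channels matrix of relative power.
#' @examples
#' freq <- 0:256
#' flat <- matrix(1, length(freq), 1)
#' relative_band_power(flat, freq)["delta", ]  # 3/44
#' @export
relative_band_power <- function(psd, freq,
                                bands = cs_default("eeg_bands"),
                                total = cs_default("eeg_total_band")) {
  psd <- as.matrix(psd)
  in_total <- freq >= total[1] & freq < total[2]
  tot <- colSums(psd[in_total, , drop = FALSE])
  out <- matrix(NA_real_, length(bands), ncol(psd),
                dimnames = list(names(bands), colnames(psd)))
  for (b in names(bands)) {
    sel <- freq >= bands[[b]][1] & freq < bands[[b]][2]
    out[b, ] <- colSums(psd[sel, , drop = FALSE]) / tot
  }
  out
}

#' Per-epoch relative band power table
#'
#' Runs [welch_psd()] + [relative_band_power()] over a list of good epochs.
#'
#' @param epochs output of [epoch_and_reject()] (rejected epochs skipped).
#' @param fs sampling rate, Hz (taken from the epochs attribute if absent).
#' @return tibble: `epoch`, `condition`, `channel`, `band`, `rel_power`.
#' @export
band_power_table <- function(epochs, fs = attr(epochs, "fs")) {
  rows <- list()
  for (i in seq_along(epochs)) {
    ep <- epochs[[i]]
    if (ep$quality != "good") next
    w <- welch_psd(ep$data, fs)
    rp <- relative_band_power(w$psd, w$freq)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      epoch = i, condition = ep$condition,
      channel = rep(colnames(rp), each = nrow(rp)),
      band = rep(rownames(rp), times = ncol(rp)),
      rel_power = as.numeric(rp))
  }
  dplyr::bind_rows(rows)
}

#' Percent change of relative band power versus resting
#'
#' For every channel and band: `100 * (mean condition - mean resting) /
#' mean resting`, i.e. resting is the 100% baseline.
#'
#' @param power_table tibble from [band_power_table()] containing a
#'   `"resting"` condition.
#' @param baseline baseline condition name.
#' @return tibble: `condition`, `channel`, `band`, `pct_change`.
#' @export
percent_change <- function(power_table, baseline = "resting") {
  cs_assert(baseline %in% power_table$condition,
            "baseline condition absent from table")
  means <- power_table |>
    dplyr::group_by(.data$condition, .data$channel, .data$band) |>
    dplyr::summarise(mean_rp = mean(.data$rel_power), .groups = "drop")
  base <- means |>
    dplyr::filter(.data$condition == baseline) |>
    dplyr::select("channel", "band", base_rp = "mean_rp")
  means |>
    dplyr::filter(.data$condition != baseline) |>
    dplyr::left_join(base, by = c("channel", "band")) |>
    dplyr::mutate(pct_change = 100 * (.data$mean_rp - .data$base_rp) / .data$base_rp) |>
    dplyr::select("condition", "channel", "band", "pct_change")
}
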