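## Internal helpers shared across modules.

#' Derive a child RNG seed from a master seed and a salt string
#'
#' Deterministic, keeps results below 2^31 so they remain valid R integers.
#' @keywords internal
#' @noRd
cs_subseed <- function(seed, salt) {
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((as.numeric(seed) * 69069 + h * 2654435 + 12345) %% 2147483647)
}

#' Evaluate an expression under a local, restored RNG state
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

cs_assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

## zero-phase Butterworth band-pass, applied forward-backward
cs_bandpass <- function(x, fs, lo, hi, order = 4) {
  ny <- fs / 2
  bf <- signal::butter(order, c(lo, hi) / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

cs_lowpass <- function(x, fs, hi, order = 6) {
  ny <- fs / 2
  bf <- signal::butter(order, hi / ny, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

## linear interpolation-free decimation by integer factor with prior low-pass
cs_decimate <- function(x, fs, target_fs) {
  fac <- fs / target_fs
  cs_assert(abs(fac - round(fac)) < 1e-9, "fs must be an integer multiple of target_fs")
  fac <- as.integer(round(fac))
  if (fac == 1L) return(x)
  y <- cs_lowpass(x, fs, 0.45 * target_fs)
  y[seq(1L, length(x), by = fac)]
}

## next power of two
cs_npow2 <- function(n) 2^ceiling(log2(n))

## frame a signal into a matrix (frame_len x n_frames), zero-padded tail drop
cs_frames <- function(x, frame_len, hop) {
  n <- length(x)
  if (n < frame_len) return(matrix(numeric(0), nrow = frame_len, ncol = 0))
  starts <- seq(1L, n - frame_len + 1L, by = hop)
  vapply(starts, function(s) x[s:(s + frame_len - 1L)], numeric(frame_len))
}

## Hamming window (periodic form not needed; symmetric as in spectral practice)
cs_hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
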