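## NIRS filter cascade and condition segmentation.

#' Construct an oximetry/heart-rate series
#'
#' @param t_s timestamps in seconds (strictly increasing, nominally one
#'   sample per 2 s).
#' @param rSO2,SpO2,PR numeric vectors (% / % / beats per minute); `NA`
#'   marks missing/removed values.
#' @return tibble of class `nirs_series`.
#' @export
nirs_series <- function(t_s, rSO2, SpO2, PR) {
  cs_assert(!is.unsorted(t_s, strictly = TRUE), "timestamps must be strictly increasing")
  out <- tibble::tibble(t_s = t_s, rSO2 = rSO2, SpO2 = SpO2, PR = PR)
  class(out) <- c("nirs_series", class(out))
  out
}

## one pass of the cascade; returns the series with new NAs
nirs_clean_pass <- function(series, sd_window_s, sd_floor, iqr_k) {
  vars <- c("rSO2", "SpO2", "PR")
  t_s <- series$t_s
  half <- sd_window_s / 2
  for (v in vars) {
    x <- series[[v]]
    ## flat-line rule: centred sliding-window SD below the floor
    bad_sd <- vapply(seq_along(t_s), function(i) {
      sel <- which(t_s >= t_s[i] - half & t_s <= t_s[i] + half & !is.na(x))
      if (length(sel) < 3) return(FALSE)
      stats::sd(x[sel]) < sd_floor
    }, logical(1))
    x[bad_sd] <- NA
    ## Tukey fences on the whole cleaned recording
    q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[2] - q[1]
    out_lo <- q[1] - iqr_k * iqr
    out_hi <- q[2] + iqr_k * iqr
    x[!is.na(x) & (x < out_lo | x > out_hi)] <- NA
    series[[v]] <- x
  }
  series
}

#' Clean an oximetry series: flat-line removal then IQR outlier removal
#'
#' A centred 60-s sliding-window standard-deviation check removes
#' acquisition dropouts (SD below 0.5 in native units), then the 1.5*IQR
#' rule removes outliers per variable over the whole recording. Removed
#' values become `NA`. The cascade is iterated to a fixed point, which makes
#' it idempotent: `nirs_clean(nirs_clean(x))` equals `nirs_clean(x)`.
#'
#' @param series a [nirs_series()].
#' @param sd_window_s sliding window length, s.
#' @param sd_floor SD floor in native units.
#' @param iqr_k Tukey fence multiplier.
#' @param max_iter iteration cap for the fixed point.
#' @return cleaned [nirs_series()].
#' @export
nirs_clean <- function(series,
                       sd_window_s = cs_default("nirs_sd_window_s"),
                       sd_floor = cs_default("nirs_sd_floor"),
                       iqr_k = cs_default("nirs_iqr_k"),
                       max_iter = 20L) {
  for (i in seq_len(max_iter)) {
    nxt <- nirs_clean_pass(series, sd_window_s, sd_floor, iqr_k)
    same <- all(vapply(c("rSO2", "SpO2", "PR"), function(v)
      identical(is.na(nxt[[v]]), is.na(series[[v]])), logical(1)))
    series <- nxt
    if (same) break
  }
  series
}

#' Assign cleaned samples to annotated condition segments
#'
#' Samples whose timestamps fall strictly inside `(start + trim, end - trim)`
#' of an annotated interval belong to its segment; the 15 s bordering each
#' interval are discarded, so intervals of 30 s or less yield empty
#' segments. Samples outside every annotation are dropped.
#'
#' @param series a cleaned [nirs_series()].
#' @param annotations tibble with `start`, `end`, `condition`.
#' @param trim_s discarded border, s.
#' @return tibble: `segment`, `condition`, `start`, `end`, `variable`, `n`,
#'   `mean` (per-variable sample count and mean over retained samples).
#' @export
nirs_segment <- function(series, annotations, trim_s = cs_default("nirs_trim_s")) {
  rows <- list()
  for (i in seq_len(nrow(annotations))) {
    lo <- annotations$start[i] + trim_s
    hi <- annotations$end[i] - trim_s
    sel <- series$t_s > lo & series$t_s < hi
    for (v in c("rSO2", "SpO2", "PR")) {
      x <- series[[v]][sel]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        segment = i, condition = annotations$condition[i],
        start = annotations$start[i], end = annotations$end[i],
        variable = v, n = length(x),
        mean = if (length(x)) mean(x) else NA_real_)
    }
  }
  dplyr::bind_rows(rows)
}

#' Physiological floor filter on segment means
#'
#' A segment's variable is excluded when its mean violates the variable's
#' floor: SpO2 below 80%, rSO2 below 50%, or pulse rate below 70 bpm
#' (strict inequalities: means exactly at the floor are retained). Flags
#' are independent per variable.
#'
#' @param segments tibble from [nirs_segment()].
#' @param floors named floors for `SpO2`, `rSO2`, `PR`.
#' @return the tibble with a logical `keep` column.
#' @export
nirs_threshold_filter <- function(segments, floors = cs_default("nirs_floors")) {
  ## strict comparison: exclusion only when strictly below the floor
  segments$keep <- segments$n > 0 & !is.na(segments$mean) &
    !(segments$mean < floors[segments$variable])
  segments
}
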