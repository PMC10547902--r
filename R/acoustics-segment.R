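## Segmentation of audio into cry episodes (CEs) and cry units (CUs).

#' Construct a cry episode
#'
#' A cry episode is a continuous crying bout: cry units (expiratory
#' vocalizations) interleaved with unvoiced intervals (inspirations and
#' pauses). Units and unvoiced intervals must tile the episode without
#' overlap.
#'
#' @param units tibble/data.frame with columns `start`, `end` (s).
#' @param unvoiced tibble with columns `start`, `end` (s); may be empty.
#' @param condition `"cry"`, `"distress"` or `NA`.
#' @return object of class `cry_episode`.
#' @export
cry_episode <- function(units, unvoiced = NULL, condition = NA_character_) {
  units <- tibble::as_tibble(units)
  cs_assert(all(units$end > units$start), "every unit needs end > start")
  cs_assert(!is.unsorted(units$start), "units must be sorted by start")
  if (is.null(unvoiced) || nrow(tibble::as_tibble(unvoiced)) == 0) {
    unvoiced <- tibble::tibble(start = numeric(0), end = numeric(0))
  } else {
    unvoiced <- tibble::as_tibble(unvoiced)
  }
  iv <- dplyr::arrange(dplyr::bind_rows(units[c("start", "end")],
                                        unvoiced[c("start", "end")]), .data$start)
  if (nrow(iv) > 1) {
    cs_assert(all(iv$start[-1] >= iv$end[-nrow(iv)] - 1e-9),
              "units and unvoiced intervals must not overlap")
  }
  structure(list(units = units, unvoiced = unvoiced, condition = condition,
                 start = min(iv$start), end = max(iv$end)),
            class = "cry_episode")
}

#' @export
print.cry_episode <- function(x, ...) {
  cat(sprintf("<cry_episode %s: %.2f-%.2f s, %d units, %d unvoiced intervals>\n",
              x$condition, x$start, x$end, nrow(x$units), nrow(x$unvoiced)))
  invisible(x)
}

#' Detect cry episodes and units in an audio waveform
#'
#' Automated stand-in for manual spectrographic segmentation: frames are
#' voiced when their short-time energy exceeds `energy_thresh_db` (dB re
#' full scale) *and* their normalized autocorrelation peak in the phonation
#' band clears the voicing threshold. Contiguous voiced runs become cry
#' units; runs shorter than `min_unit_s` are discarded as segmentation noise.
#' Gaps up to `min_gap_s` stay inside the episode as unvoiced intervals;
#' longer silences split episodes.
#'
#' @param wave mono waveform.
#' @param fs sampling rate, Hz (>= 16 kHz).
#' @param frame_ms,hop_ms analysis frame and hop, ms.
#' @param energy_thresh_db energy floor in dB re full scale.
#' @param min_gap_s silences longer than this end the episode (s).
#' @param min_unit_s shortest voiced run kept as a cry unit (s).
#' @param voicing_threshold autocorrelation floor for voicing.
#' @return list of [cry_episode()] objects sorted by start (empty for
#'   silence or DC-only input).
#' @export
detect_voiced_regions <- function(wave, fs,
                                  frame_ms = cs_default("frame_ms"),
                                  hop_ms = cs_default("hop_ms"),
                                  energy_thresh_db = cs_default("energy_thresh_db"),
                                  min_gap_s = cs_default("episode_break_s"),
                                  min_unit_s = cs_default("min_unit_s"),
                                  voicing_threshold = cs_default("voicing_threshold")) {
  wave <- as.numeric(wave)
  cs_assert(fs >= 16000, "fs must be at least 16 kHz")
  if (length(wave) < round(frame_ms / 1000 * fs) || max(abs(wave - mean(wave))) == 0) {
    return(list())
  }
  flen <- round(frame_ms / 1000 * fs)
  hop <- round(hop_ms / 1000 * fs)
  f0_range <- cs_default("f0_search_range")

  ## short-time energy from a running sum (no frame matrix: recordings can
  ## be tens of minutes long)
  starts <- seq(1L, length(wave) - flen + 1L, by = hop)
  csum <- cumsum(c(0, wave^2))
  frame_en <- (csum[starts + flen] - csum[starts]) / flen
  energy_db <- 10 * log10(pmax(frame_en, 1e-12))
  energetic <- energy_db > energy_thresh_db

  ## voicing check on the energetic frames, band-passing the signal in
  ## bounded chunks (padded to absorb zero-phase filter edges)
  voiced <- energetic
  if (any(energetic)) {
    chunk_n <- as.integer(60 * fs)
    pad <- as.integer(fs)
    for (c0 in seq(1L, length(wave), by = chunk_n)) {
      c1 <- min(length(wave), c0 + chunk_n - 1L)
      sel <- which(energetic & starts >= c0 & starts + flen - 1L <= c1 + pad &
                     starts + flen - 1L <= length(wave))
      sel <- sel[starts[sel] < c0 + chunk_n]
      if (!length(sel)) next
      a <- max(1L, c0 - pad)
      b <- min(length(wave), c1 + pad + flen)
      xb <- cs_bandpass(wave[a:b], fs, f0_range[1], f0_range[2], order = 2)
      est <- frame_autocorr_f0(xb, starts[sel] - a + 1L, flen, fs, f0_range)
      voiced[sel] <- !is.na(est[, "f0"]) & est[, "r"] >= voicing_threshold
    }
  }
  ## close single-frame holes
  if (length(voiced) > 2) {
    holes <- which(!voiced[-c(1, length(voiced))] &
                     voiced[-c(length(voiced) - 1, length(voiced))] &
                     voiced[-c(1, 2)]) + 1L
    voiced[holes] <- TRUE
  }
  r <- rle(voiced)
  if (!any(r$values)) return(list())
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  ## frame-centre based boundaries: overlapping analysis windows would
  ## otherwise make adjacent voiced runs overlap in time
  centre <- flen / 2 / fs
  runs <- tibble::tibble(
    start = pmax(0, (starts_i[r$values] - 1L) * hop / fs + centre - hop / 2 / fs),
    end = (ends_i[r$values] - 1L) * hop / fs + centre + hop / 2 / fs
  )
  runs <- runs[runs$end - runs$start >= min_unit_s, , drop = FALSE]
  if (nrow(runs) == 0) return(list())

  ## group units into episodes on gaps > min_gap_s
  gap_before <- c(Inf, runs$start[-1] - runs$end[-nrow(runs)])
  grp <- cumsum(gap_before > min_gap_s)
  lapply(split(runs, grp), function(u) {
    unv <- if (nrow(u) > 1) {
      tibble::tibble(start = u$end[-nrow(u)], end = u$start[-1])
    } else NULL
    cry_episode(u, unv)
  }) |> unname()
}

#' Time-domain bookkeeping of a cry episode
#'
#' `cryCE` is the summed duration of cry units, `unvoicedCE` the summed
#' duration of unvoiced intervals; the percentages are each over the episode
#' duration and sum to one.
#'
#' @param episode a [cry_episode()].
#' @return one-row tibble: `cryCE`, `unvoicedCE` (s), `cryCE_pct`,
#'   `unvoicedCE_pct` (fractions).
#' @examples
#' ep <- cry_episode(tibble::tibble(start = c(0, 3), end = c(2, 5)),
#'                   tibble::tibble(start = 2, end = 3))
#' time_features(ep)  # cryCE 4 s, unvoicedCE 1 s, 0.8 / 0.2
#' @export
time_features <- function(episode) {
  cs_assert(inherits(episode, "cry_episode"), "episode must be a cry_episode")
  cry_s <- sum(episode$units$end - episode$units$start)
  unv_s <- sum(episode$unvoiced$end - episode$unvoiced$start)
  tot <- cry_s + unv_s
  cs_assert(tot > 0, "episode has zero duration")
  tibble::tibble(cryCE = cry_s, unvoicedCE = unv_s,
                 cryCE_pct = cry_s / tot, unvoicedCE_pct = unv_s / tot)
}
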