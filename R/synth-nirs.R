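## Synthetic NIRS / pulse-oximetry series and COMFORT scores.

#' Synthesize an oximetry/heart-rate (NIRS) series over a timeline
#'
#' Samples every 2 s (timestamps at the centres of the 2-s acquisition
#' bins: 1, 3, 5, ... s). Each variable is Gaussian noise around its
#' condition mean. During cry/distress intervals an optional effort
#' coupling shifts the levels in proportion to the episode's standardized
#' vocalization amount (pulse rate up, oxygenation down), reproducing the
#' observed association between crying time and heart rate / regional
#' oxygenation. Optional injected anomalies exercise the filter cascade:
#' flat dropout runs (SD below the 0.5 floor) and sub-threshold excursions.
#'
#' @param annotations tibble with `start`, `end`, `condition` (s).
#' @param profiles named list of [condition_profile()]s.
#' @param seed integer seed.
#' @param step_s sampling step, s.
#' @param effort named vector of per-SD effort coupling slopes for
#'   `PR` (bpm), `rSO2`, `SpO2` (percentage points).
#' @param episode_effort optional tibble (`start`, `end`, `effort_z`) of
#'   standardized per-episode vocalization amounts driving the coupling.
#' @param flat_runs optional tibble (`start`, `end`) of dropout intervals
#'   (all variables frozen).
#' @param low_excursions optional tibble (`start`, `end`, `variable`,
#'   `level`) of injected sub-threshold episodes.
#' @return tibble of class `nirs_series`: `t_s`, `rSO2`, `SpO2`, `PR`.
#' @export
synth_nirs <- function(annotations, profiles, seed = 1L,
                       step_s = cs_default("nirs_step_s"),
                       effort = c(PR = 6, rSO2 = -2, SpO2 = -1),
                       episode_effort = NULL,
                       flat_runs = NULL,
                       low_excursions = NULL) {
  annotations <- tibble::as_tibble(annotations)
  t_end <- max(annotations$end)
  t_s <- seq(step_s / 2, t_end, by = step_s)
  with_seed(seed, {
    out <- tibble::tibble(t_s = t_s, rSO2 = NA_real_, SpO2 = NA_real_, PR = NA_real_)
    for (i in seq_len(nrow(annotations))) {
      sel <- t_s > annotations$start[i] & t_s <= annotations$end[i]
      if (!any(sel)) next
      prof <- profiles[[annotations$condition[i]]]
      cs_assert(!is.null(prof), paste("no profile for", annotations$condition[i]))
      z <- 0
      if (!is.null(episode_effort)) {
        hit <- which(episode_effort$start <= annotations$start[i] + 1e-9 &
                       episode_effort$end >= annotations$end[i] - 1e-9)
        if (length(hit)) z <- episode_effort$effort_z[hit[1]]
      }
      n_sel <- sum(sel)
      out$rSO2[sel] <- stats::rnorm(n_sel, prof$nirs_levels[["rSO2"]] +
                                      z * effort[["rSO2"]], prof$nirs_sd[["rSO2"]])
      out$SpO2[sel] <- pmin(100, stats::rnorm(n_sel, prof$nirs_levels[["SpO2"]] +
                                      z * effort[["SpO2"]], prof$nirs_sd[["SpO2"]]))
      out$PR[sel] <- stats::rnorm(n_sel, prof$nirs_levels[["PR"]] +
                                    z * effort[["PR"]], prof$nirs_sd[["PR"]])
    }
    if (!is.null(flat_runs)) {
      for (i in seq_len(nrow(flat_runs))) {
        sel <- which(t_s >= flat_runs$start[i] & t_s <= flat_runs$end[i])
        if (length(sel) > 1) {
          for (v in c("rSO2", "SpO2", "PR")) out[[v]][sel] <- out[[v]][sel[1]]
        }
      }
    }
    if (!is.null(low_excursions)) {
      for (i in seq_len(nrow(low_excursions))) {
        sel <- t_s >= low_excursions$start[i] & t_s <= low_excursions$end[i]
        v <- low_excursions$variable[i]
        out[[v]][sel] <- stats::rnorm(sum(sel), low_excursions$level[i], 1)
      }
    }
    class(out) <- c("nirs_series", class(out))
    out
  })
}

#' Draw COMFORT item scores for one episode
#'
#' Six behavioural items (alertness, agitation, crying, body movements,
#' muscular tone, facial tension) drawn around the profile's item means,
#' rounded and clipped to the 1--5 integer scale.
#'
#' @param profile a [condition_profile()].
#' @param seed integer seed.
#' @return named integer vector of the six items.
#' @export
synth_comfort <- function(profile, seed = 1L) {
  items <- cs_default("comfort_items")
  with_seed(seed, {
    x <- stats::rnorm(6, profile$comfort_item_means, profile$comfort_sd)
    x <- pmin(5L, pmax(1L, as.integer(round(x))))
    stats::setNames(x, items)
  })
}
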