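## COMFORT behavioural distress scale.

#' Validate COMFORT items and compute the total score
#'
#' The COMFORT scale rates six behavioural sections (alertness, agitation,
#' crying, body movements, muscular tone, facial tension) from 1 (calm) to
#' 5 (stressed); the total distress score therefore ranges 6--30.
#'
#' @param items six integers in 1--5 (named or in the canonical order).
#' @return one-row tibble of class `comfort_score`: the six items plus
#'   `total`.
#' @examples
#' validate_and_total(c(1, 2, 3, 4, 5, 5))$total  # 20
#' @export
validate_and_total <- function(items) {
  nm <- cs_default("comfort_items")
  rng <- cs_default("comfort_range")
  cs_assert(length(items) == 6, "COMFORT needs exactly six items")
  cs_assert(all(!is.na(items)), "COMFORT items must not be missing")
  cs_assert(all(items == round(items)), "COMFORT items must be integers")
  bad <- items < rng[1] | items > rng[2]
  if (any(bad)) {
    stop(sprintf("COMFORT item%s out of the 1-5 range: %s",
                 if (sum(bad) > 1) "s" else "",
                 paste0(nm[bad], "=", items[bad], collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(names(items))) {
    cs_assert(all(nm %in% names(items)), "unknown COMFORT item names")
    items <- items[nm]
  }
  out <- tibble::as_tibble(as.list(stats::setNames(as.integer(items), nm)))
  out$total <- sum(as.integer(items))
  class(out) <- c("comfort_score", class(out))
  out
}

#' Build a COMFORT table for a set of episodes
#'
#' @param scores list of six-item vectors (one per episode).
#' @param conditions character vector of episode conditions.
#' @return tibble with `episode`, `condition`, the six items and `total`.
#' @export
comfort_table <- function(scores, conditions) {
  cs_assert(length(scores) == length(conditions), "lengths differ")
  dplyr::bind_rows(lapply(seq_along(scores), function(i) {
    dplyr::bind_cols(tibble::tibble(episode = i, condition = conditions[i]),
                     validate_and_total(scores[[i]]))
  }))
}
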