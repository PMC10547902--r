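## One synthetic newborn session: audio, EEG, NIRS, COMFORT and annotations
## tied to a shared timeline with full ground truth.

#' Synthesize a complete multimodal session
#'
#' Lays out a timeline of resting blocks interleaved with cry and distress
#' episodes, synthesizes the audio episode by episode, then generates EEG,
#' NIRS and COMFORT streams over the same timeline. Heart rate and
#' oxygenation are coupled to each episode's standardized vocalized time
#' (effort): more crying raises pulse rate and lowers oxygenation, which is
#' what makes cross-modal correlations with `cryCE` recoverable downstream.
#'
#' @param profiles named list of `resting`/`cry`/`distress`
#'   [condition_profile()]s.
#' @param seed integer seed; the whole bundle is reproducible bit for bit.
#' @param n_cry,n_distress episode counts.
#' @param resting_dur_range range (s) of the resting blocks between episodes.
#' @param fs audio sampling rate, Hz.
#' @param eeg_artifact_rate artifact bursts per minute per channel.
#' @param comfort_effort_slope COMFORT item-mean shift per effort SD.
#' @return object of class `session_bundle`: `audio` (+`fs`),
#'   `annotations`, `eeg`, `nirs`, `comfort`, `truth`.
#' @export
synth_session <- function(profiles = default_condition_profiles(), seed = 1L,
                          n_cry = 4L, n_distress = 3L,
                          resting_dur_range = c(45, 70),
                          fs = cs_default("audio_fs"),
                          eeg_artifact_rate = 0,
                          comfort_effort_slope = 0.4) {
  conds <- with_seed(cs_subseed(seed, "layout"),
                     sample(rep(c("cry", "distress"), c(n_cry, n_distress))))
  n_ep <- length(conds)
  rest_durs <- with_seed(cs_subseed(seed, "rest"),
                         stats::runif(n_ep + 1L, resting_dur_range[1],
                                      resting_dur_range[2]))

  ## synthesize episodes first to know their realized durations
  episodes <- lapply(seq_len(n_ep), function(i)
    synth_episode(profiles[[conds[i]]], seed = cs_subseed(seed, paste0("ep", i)),
                  fs = fs))

  pieces <- list(); ann_rows <- list(); t_cur <- 0
  ep_meta <- list()
  for (i in seq_len(n_ep + 1L)) {
    r_dur <- rest_durs[i]
    pieces[[length(pieces) + 1L]] <- as.numeric(
      synth_resting_audio(r_dur, seed = cs_subseed(seed, paste0("restwav", i)), fs = fs))
    ann_rows[[length(ann_rows) + 1L]] <- tibble::tibble(
      start = t_cur, end = t_cur + r_dur, condition = "resting")
    t_cur <- t_cur + r_dur
    if (i <= n_ep) {
      ep <- episodes[[i]]
      dur <- length(ep$wave) / fs
      pieces[[length(pieces) + 1L]] <- ep$wave
      ann_rows[[length(ann_rows) + 1L]] <- tibble::tibble(
        start = t_cur, end = t_cur + dur, condition = conds[i])
      ep_meta[[i]] <- tibble::tibble(
        episode = i, condition = conds[i], start = t_cur, end = t_cur + dur,
        cryCE = ep$truth$cryCE, unvoicedCE = ep$truth$unvoicedCE)
      t_cur <- t_cur + dur
    }
  }
  audio <- unlist(pieces, use.names = FALSE)
  annotations <- dplyr::bind_rows(ann_rows)
  ep_tab <- dplyr::bind_rows(ep_meta)

  ## effort: standardized vocalized time per episode
  z <- as.numeric(scale(ep_tab$cryCE))
  if (any(!is.finite(z))) z <- rep(0, nrow(ep_tab))
  ep_tab$effort_z <- z

  eeg <- synth_eeg(annotations, profiles, seed = cs_subseed(seed, "eeg"),
                   artifact_rate = eeg_artifact_rate)
  nirs <- synth_nirs(annotations, profiles, seed = cs_subseed(seed, "nirs"),
                     episode_effort = ep_tab[c("start", "end", "effort_z")])

  comfort <- dplyr::bind_rows(lapply(seq_len(nrow(ep_tab)), function(i) {
    prof <- profiles[[ep_tab$condition[i]]]
    mu <- pmin(5, pmax(1, prof$comfort_item_means +
                         comfort_effort_slope * ep_tab$effort_z[i]))
    prof_i <- prof; prof_i$comfort_item_means <- mu
    sc <- synth_comfort(prof_i, seed = cs_subseed(seed, paste0("comfort", i)))
    dplyr::bind_cols(tibble::tibble(episode = i, condition = ep_tab$condition[i]),
                     validate_and_total(sc))
  }))

  bundle <- structure(list(
    audio = structure(audio, fs = fs), fs = fs,
    annotations = annotations,
    eeg = eeg, nirs = nirs, comfort = comfort,
    truth = list(episodes = ep_tab,
                 unit_params = lapply(episodes, function(e) e$truth$unit_params),
                 units = lapply(seq_along(episodes), function(i) {
                   u <- episodes[[i]]$units
                   u$start <- u$start + ep_tab$start[i]
                   u$end <- u$end + ep_tab$start[i]
                   u$episode <- i
                   u
                 }),
                 profiles = profiles, seed = seed)
  ), class = "session_bundle")
  validate_session_bundle(bundle)
  bundle
}

#' Check the internal consistency of a session bundle
#'
#' All streams must span the same wall-clock duration (within one 2-s NIRS
#' sample), annotations must be sorted and non-overlapping, and every
#' cry/distress annotation must have a COMFORT record.
#'
#' @param bundle a `session_bundle`.
#' @return the bundle, invisibly; errors describe any violation.
#' @export
validate_session_bundle <- function(bundle) {
  t_audio <- length(bundle$audio) / bundle$fs
  t_eeg <- nrow(bundle$eeg$data) / bundle$eeg$fs
  t_nirs <- max(bundle$nirs$t_s) + cs_default("nirs_step_s") / 2
  t_ann <- max(bundle$annotations$end)
  step <- cs_default("nirs_step_s")
  cs_assert(max(abs(c(t_audio, t_eeg, t_nirs) - t_ann)) <= step,
            "streams disagree on session duration by more than one NIRS sample")
  a <- bundle$annotations
  cs_assert(!is.unsorted(a$start), "annotations must be sorted")
  cs_assert(all(a$start[-1] >= a$end[-nrow(a)] - 1e-9),
            "annotations must not overlap")
  n_epis <- sum(a$condition != "resting")
  cs_assert(nrow(bundle$comfort) == n_epis,
            "every cry/distress annotation needs a COMFORT record")
  invisible(bundle)
}

#' @export
print.session_bundle <- function(x, ...) {
  a <- x$annotations
  cat(sprintf("<session_bundle: %.1f min, %d cry + %d distress episodes, seed %d>\n",
              max(a$end) / 60, sum(a$condition == "cry"),
              sum(a$condition == "distress"), x$truth$seed))
  invisible(x)
}
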