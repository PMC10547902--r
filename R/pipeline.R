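## End-to-end pipeline: simulate -> acoustics -> EEG -> NIRS -> COMFORT ->
## merged feature table -> statistics -> classifier.

#' Build a run configuration
#'
#' All tunable pipeline parameters with their defaults: the analysis
#' constants (200--1200 Hz pitch band, 800/1000 Hz pitch thresholds,
#' 1--45 Hz EEG band, 4-s epochs, 200 uV rejection, 0.5 SD floor, 1.5*IQR
#' fences, 15-s trimming, 80/50/70 floors, 10,000 bootstrap repetitions,
#' 0.8 training fraction) plus the session layout and classifier settings.
#' Serializes losslessly through [save_config()] / [load_config()].
#'
#' @param seed master seed for every stochastic stage.
#' @param ... overrides of any default (unknown names are an error).
#' @return a named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- .cryscope_defaults
  cfg$seed <- as.integer(seed)
  cfg$n_cry_episodes <- 4L
  cfg$n_distress_episodes <- 3L
  cfg$resting_dur_range <- c(45, 70)
  cfg$classifier <- "rf"
  cfg$classifier_units <- 150L
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm, call. = FALSE)
    cfg[[nm]] <- ov[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML-like JSON path.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- .cryscope_defaults
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  ## restore types that JSON round-trips as lists/doubles
  cfg$eeg_bands <- lapply(cfg$eeg_bands, as.numeric)
  for (nm in c("seed", "n_cry_episodes", "n_distress_episodes",
               "classifier_units", "boot_reps", "rf_trees"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- as.integer(cfg[[nm]])
  structure(cfg, class = "run_config")
}

#' Merge per-episode features from all modalities into one table
#'
#' One row per cry/distress episode: time-domain features, episode means of
#' the per-unit acoustic features, channel-averaged EEG relative power per
#' band over the episode's epochs, NIRS segment means, and the COMFORT
#' items and total.
#'
#' @param acoustic output of [acoustic_feature_table()].
#' @param band_power tibble from [band_power_table()] (with epoch starts in
#'   `epoch_start`).
#' @param nirs_segments filtered tibble from [nirs_threshold_filter()].
#' @param comfort tibble from [comfort_table()] / the session bundle.
#' @param annotations session annotations.
#' @return tibble (the merged feature table).
#' @export
merge_feature_table <- function(acoustic, band_power, nirs_segments, comfort,
                                annotations) {
  ep <- acoustic$episodes
  acoustic_cols <- c("f0_mean", "f0_min", "f0_max", "f0_sd", "high_pitch_pct",
                     "hyperphonation_pct", "jitter_local", "shimmer_local",
                     "hnr", "f1", "f2", "f3")
  unit_means <- acoustic$units |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$episode) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(acoustic_cols),
                                   ~ mean(.x, na.rm = TRUE)), .groups = "drop")
  out <- dplyr::left_join(ep, unit_means, by = "episode")

  if (!is.null(band_power) && nrow(band_power) > 0) {
    eeg_ep <- band_power |>
      dplyr::group_by(.data$episode_id, .data$band) |>
      dplyr::summarise(rp = mean(.data$rel_power), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "band", values_from = "rp",
                         names_prefix = "eeg_")
    out <- dplyr::left_join(out, eeg_ep, by = c(episode = "episode_id"))
  }
  if (!is.null(nirs_segments) && nrow(nirs_segments) > 0) {
    nir_ep <- nirs_segments |>
      dplyr::filter(.data$keep) |>
      dplyr::select("segment", "variable", "mean") |>
      tidyr::pivot_wider(names_from = "variable", values_from = "mean")
    ## map segment index (annotation row) to episode index
    ep_of_segment <- match(seq_len(nrow(annotations)),
                           which(annotations$condition != "resting"))
    nir_ep$episode <- ep_of_segment[nir_ep$segment]
    out <- dplyr::left_join(out, dplyr::select(nir_ep, -"segment"),
                            by = "episode")
  }
  if (!is.null(comfort) && nrow(comfort) > 0) {
    out <- dplyr::left_join(out,
                            dplyr::select(comfort, -dplyr::any_of("condition")),
                            by = "episode")
  }
  out
}

## per-episode EEG band power: epochs assigned to the episode whose
## annotation interval contains them
episode_band_power <- function(epochs, annotations, fs = attr(epochs, "fs")) {
  bp <- band_power_table(epochs, fs)
  if (nrow(bp) == 0) return(bp)
  starts <- vapply(epochs, `[[`, numeric(1), "start")
  ep_idx <- match(seq_len(nrow(annotations)),
                  which(annotations$condition != "resting"))
  ann_of <- findInterval(starts + 1e-9, annotations$start)
  bp$episode_id <- ep_idx[ann_of[bp$epoch]]
  bp
}

#' Run the full multimodal analysis pipeline on a synthetic session
#'
#' simulate -> segment audio -> acoustic features -> EEG preprocessing,
#' epoching and relative band power with percent change vs resting -> NIRS
#' cleaning, segmentation and floor filtering -> COMFORT scores -> merged
#' feature table -> statistical battery (condition comparisons, Spearman
#' matrix, pairwise Kendall concordance) -> cry/distress classifier.
#' Every stage logs its in/out counts to the returned `log`.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory for the CSV/JSON report bundle.
#' @return list of class `run_report`: `session`, `acoustic`, `band_power`,
#'   `percent_change`, `nirs_segments`, `features`, `stats`, `classifier`,
#'   `log`, `provenance`.
#' @export
run_all <- function(config = run_config(), out_dir = NULL) {
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message("[cryscope] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  seed <- config$seed
  profiles <- default_condition_profiles()

  bundle <- stage("simulate", synth_session(
    profiles, seed = seed,
    n_cry = config$n_cry_episodes, n_distress = config$n_distress_episodes,
    resting_dur_range = config$resting_dur_range))
  note("simulate: %.1f min session, %d episodes", max(bundle$annotations$end) / 60,
       nrow(bundle$truth$episodes))

  ## --- acoustics ----------------------------------------------------------
  acoustic <- stage("acoustics", {
    episodes <- detect_voiced_regions(bundle$audio, bundle$fs)
    ## label detected episodes by annotation overlap
    ann_ep <- bundle$annotations[bundle$annotations$condition != "resting", ]
    for (i in seq_along(episodes)) {
      mid <- (episodes[[i]]$start + episodes[[i]]$end) / 2
      hit <- which(ann_ep$start <= mid & ann_ep$end >= mid)
      episodes[[i]]$condition <- if (length(hit)) ann_ep$condition[hit[1]] else NA
    }
    episodes <- episodes[!vapply(episodes, function(e) is.na(e$condition), logical(1))]
    acoustic_feature_table(episodes, bundle$audio, bundle$fs)
  })
  note("acoustics: %d episodes, %d units (%d valid)",
       nrow(acoustic$episodes), nrow(acoustic$units), sum(acoustic$units$valid))

  ## --- EEG ----------------------------------------------------------------
  eeg_out <- stage("eeg", {
    rec <- bundle$eeg
    bad <- detect_bad_channels(rec)
    if (length(bad) == 1) rec <- interpolate_spherical_spline(rec, bad)
    rec <- preprocess_eeg(rec)
    epochs <- epoch_and_reject(rec, bundle$annotations)
    bp <- episode_band_power(epochs, bundle$annotations)
    list(epochs = epochs, bp = bp, pc = percent_change(bp), bad = bad)
  })
  note("eeg: %d epochs (%d good), %d bad channels",
       length(eeg_out$epochs),
       sum(vapply(eeg_out$epochs, `[[`, character(1), "quality") == "good"),
       length(eeg_out$bad))

  ## --- NIRS ---------------------------------------------------------------
  nirs_seg <- stage("nirs", {
    cleaned <- nirs_clean(bundle$nirs)
    nirs_threshold_filter(nirs_segment(cleaned, bundle$annotations))
  })
  note("nirs: %d segment-variables, %d kept", nrow(nirs_seg), sum(nirs_seg$keep))

  ## --- merge --------------------------------------------------------------
  features <- stage("merge", merge_feature_table(
    acoustic, eeg_out$bp, nirs_seg, bundle$comfort, bundle$annotations))
  note("merge: %d episodes x %d columns", nrow(features), ncol(features))

  ## --- statistics ---------------------------------------------------------
  stats_out <- stage("integrate", {
    by_cond <- split(eeg_out$bp$rel_power[eeg_out$bp$band == "delta"],
                     eeg_out$bp$condition[eeg_out$bp$band == "delta"])
    bal <- balanced_subsample(by_cond, seed = cs_subseed(seed, "balance"))
    kw <- kruskal_dunn(bal)
    mw <- if (all(c("cry", "resting") %in% names(bal)))
      mann_whitney(bal$cry, bal$resting) else NULL
    num_cols <- names(features)[vapply(features, is.numeric, logical(1))]
    num_cols <- setdiff(num_cols, c("episode", "start", "end", "effort_z"))
    sp <- spearman_matrix(features[num_cols])
    audio_f <- intersect(c("cryCE", "unvoicedCE", "cryCE_pct", "unvoicedCE_pct",
                           "f0_mean", "f0_min", "f0_max", "f0_sd", "jitter_local",
                           "shimmer_local", "hnr", "f1", "f2", "f3",
                           "high_pitch_pct", "hyperphonation_pct"), num_cols)
    partner_f <- setdiff(num_cols, audio_f)
    cw <- concordance_report(features, audio_f, partner_f)
    list(kruskal_dunn = kw, mann_whitney = mw, spearman = sp, concordance = cw)
  })
  note("integrate: spearman %dx%d, %d concordance pairs",
       nrow(stats_out$spearman$rho), ncol(stats_out$spearman$rho),
       nrow(stats_out$concordance))

  ## --- classifier ---------------------------------------------------------
  clf <- stage("classify", {
    ds <- synth_unit_dataset(config$classifier_units, profiles,
                             seed = cs_subseed(seed, "clf"))
    split <- make_split(length(ds$labels), config$train_frac,
                        seed = cs_subseed(seed, "split"))
    if (identical(config$classifier, "cnn")) {
      mod <- train_cnn(ds$spectrograms, ds$labels, split = split,
                       seed = cs_subseed(seed, "cnn"))
      pred <- predict(mod, ds$spectrograms[split$validation])
    } else {
      mod <- train_rf(ds$mfcc, ds$labels, split = split,
                      seed = cs_subseed(seed, "rf"))
      pred <- predict(mod, ds$mfcc[split$validation, , drop = FALSE])
    }
    list(model = mod, kind = config$classifier,
         report = evaluate_classifier(pred, ds$labels[split$validation]))
  })
  note("classify (%s): accuracy %.3f sensitivity %.3f specificity %.3f",
       clf$kind, clf$report$accuracy, clf$report$sensitivity,
       clf$report$specificity)

  report <- structure(list(
    session = bundle, acoustic = acoustic,
    band_power = eeg_out$bp, percent_change = eeg_out$pc,
    nirs_segments = nirs_seg, features = features,
    stats = stats_out, classifier = clf, log = log,
    provenance = list(
      seed = seed,
      config_hash = digest_config(config),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("cryscope")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  ), class = "run_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

## deterministic config fingerprint (polynomial rolling hash)
digest_config <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a run report as CSV/JSON files
#'
#' @param report a `run_report` from [run_all()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$features, file.path(dir, "features.csv"))
  readr::write_csv(report$acoustic$units, file.path(dir, "unit_features.csv"))
  readr::write_csv(report$percent_change, file.path(dir, "eeg_percent_change.csv"))
  readr::write_csv(report$nirs_segments, file.path(dir, "nirs_segments.csv"))
  readr::write_csv(report$stats$concordance, file.path(dir, "concordance.csv"))
  utils::write.csv(report$stats$spearman$rho, file.path(dir, "spearman_rho.csv"))
  jsonlite::write_json(list(
    classifier = as.list(report$classifier$report),
    classifier_kind = report$classifier$kind,
    log = report$log,
    provenance = report$provenance
  ), file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<cryscope run_report>\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}
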