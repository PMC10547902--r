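## Cry-versus-distress classification: data splitting, random forest on
## MFCC summaries, evaluation with distress as the positive class.

#' Random train/validation split
#'
#' Training size is `ceiling(frac_train * n)` (remainder to training),
#' validation is the rest; plain random (unstratified) by default.
#'
#' @param n_items number of items.
#' @param frac_train training fraction.
#' @param seed integer seed; fixed seed reproduces the split.
#' @param groups optional grouping vector (length `n_items`): when given,
#'   whole groups are assigned to one side (group-wise split, avoiding
#'   subject leakage), targeting the same training fraction.
#' @return list with integer index vectors `train` and `validation`.
#' @examples
#' s <- make_split(1964, seed = 1)
#' lengths(s)  # 1572 training, 392 validation
#' @export
make_split <- function(n_items, frac_train = cs_default("train_frac"),
                       seed = 1L, groups = NULL) {
  cs_assert(n_items >= 2, "need at least two items")
  n_train <- ceiling(frac_train * n_items)
  if (is.null(groups)) {
    tr <- with_seed(seed, sample.int(n_items, n_train))
    return(list(train = sort(tr), validation = sort(setdiff(seq_len(n_items), tr))))
  }
  cs_assert(length(groups) == n_items, "groups length mismatch")
  gs <- with_seed(seed, sample(unique(groups)))
  tr <- integer(0)
  for (g in gs) {
    if (length(tr) >= n_train) break
    tr <- c(tr, which(groups == g))
  }
  list(train = sort(tr), validation = sort(setdiff(seq_len(n_items), tr)))
}

#' Train a random forest on MFCC summary features
#'
#' @param features numeric matrix/data frame (rows = cry units, columns =
#'   the 26 MFCC summary values).
#' @param labels two-class factor/character vector.
#' @param split list with `train`/`validation` indices ([make_split()]);
#'   seeded 80/20 split when `NULL`.
#' @param seed integer seed.
#' @param n_trees number of trees.
#' @return object of class `rf_model` wrapping the fitted forest.
#' @export
train_rf <- function(features, labels, split = NULL, seed = 1L,
                     n_trees = cs_default("rf_trees")) {
  labels <- factor(labels)
  cs_assert(nlevels(labels) == 2, "need exactly two classes")
  features <- as.data.frame(features)
  if (is.null(split)) split <- make_split(nrow(features), seed = seed)
  tr <- split$train
  cs_assert(nlevels(droplevels(labels[tr])) == 2,
            "single-class training set refused")
  fit <- with_seed(seed,
    randomForest::randomForest(x = features[tr, , drop = FALSE],
                               y = droplevels(labels[tr]),
                               ntree = n_trees))
  structure(list(fit = fit, split = split, levels = levels(labels)),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  stats::predict(object$fit, as.data.frame(newdata), ...)
}

#' Evaluate a two-class distress classifier
#'
#' Confusion-matrix metrics with distress as the positive class:
#' sensitivity is the distress detection rate TP/(TP+FN), specificity the
#' cry (non-distress) rejection rate TN/(TN+FP).
#'
#' @param predicted factor/character of predicted classes.
#' @param actual factor/character of true classes.
#' @param positive positive class label.
#' @return one-row tibble of class `classifier_report`: `tp`, `fp`, `tn`,
#'   `fn`, `accuracy`, `sensitivity`, `specificity`, `n`.
#' @examples
#' evaluate_classifier(rep(c("distress", "cry"), c(5, 5)),
#'                     rep("distress", 10))$sensitivity  # 0.5
#' @export
evaluate_classifier <- function(predicted, actual, positive = "distress") {
  predicted <- as.character(predicted)
  actual <- as.character(actual)
  cs_assert(length(predicted) == length(actual), "length mismatch")
  tp <- sum(predicted == positive & actual == positive)
  fp <- sum(predicted == positive & actual != positive)
  tn <- sum(predicted != positive & actual != positive)
  fn <- sum(predicted != positive & actual == positive)
  out <- tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / length(actual),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    n = length(actual))
  class(out) <- c("classifier_report", class(out))
  out
}

#' Generate a labelled synthetic cry-unit dataset for classification
#'
#' Draws per-unit generator parameters from the cry and distress profiles,
#' synthesizes each unit, and extracts both MFCC summaries and
#' fixed-size mel-spectrogram images.
#'
#' @param n_per_class units per class.
#' @param profiles named list with `cry` and `distress`
#'   [condition_profile()]s.
#' @param seed integer seed.
#' @param fs sampling rate, Hz.
#' @param dur_range unit duration range, s.
#' @return list: `mfcc` (matrix n x 26), `spectrograms` (list of matrices),
#'   `labels` (factor), `params` (list of the true per-unit [cry_params()]).
#' @export
synth_unit_dataset <- function(n_per_class, profiles = default_condition_profiles(),
                               seed = 1L, fs = cs_default("audio_fs"),
                               dur_range = c(0.5, 1.2)) {
  labels <- rep(c("cry", "distress"), each = n_per_class)
  params <- vector("list", 2 * n_per_class)
  mf <- matrix(NA_real_, 2 * n_per_class, 2 * cs_default("n_mfcc"))
  specs <- vector("list", 2 * n_per_class)
  for (i in seq_along(labels)) {
    si <- cs_subseed(seed, paste0("unit", i))
    prof <- profiles[[labels[i]]]
    p <- with_seed(si, draw_unit_params(prof))
    dur <- with_seed(cs_subseed(seed, paste0("dur", i)),
                     stats::runif(1, dur_range[1], dur_range[2]))
    w <- synth_cry_unit(p, dur, seed = cs_subseed(seed, paste0("wav", i)), fs = fs)
    m <- mfcc(as.numeric(w), fs)
    mf[i, ] <- m$summary
    specs[[i]] <- mel_spectrogram(as.numeric(w), fs)
    params[[i]] <- p
  }
  colnames(mf) <- names(mfcc(as.numeric(
    synth_cry_unit(profiles$cry$cry_params, 0.3, seed = 1, fs = fs)), fs)$summary)
  list(mfcc = mf, spectrograms = specs, labels = factor(labels), params = params)
}
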