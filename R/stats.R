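## Statistical battery: condition comparisons, correlation, concordance.

#' Balance groups by random down-sampling
#'
#' Every group is sampled without replacement down to the smallest group
#' size; deterministic under the seed.
#'
#' @param groups named list of numeric vectors.
#' @param seed integer seed.
#' @return named list of equally sized vectors.
#' @export
balanced_subsample <- function(groups, seed = 1L) {
  n_min <- min(lengths(groups))
  with_seed(seed, lapply(groups, function(g) {
    if (length(g) == n_min) g else g[sample.int(length(g), n_min)]
  }))
}

#' Mann-Whitney U test
#'
#' Exact two-sided p for small untied samples, normal approximation with
#' tie correction otherwise (via `stats::wilcox.test`); the reported
#' statistic is the U of the first sample.
#'
#' @param a,b numeric vectors (each of size >= 2).
#' @return one-row tibble: `statistic` (U), `p`, `method`, `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p  # 0.1 by exact enumeration
#' @export
mann_whitney <- function(a, b) {
  cs_assert(length(a) >= 2 && length(b) >= 2, "groups need at least 2 values")
  wt <- stats::wilcox.test(a, b)
  tibble::tibble(statistic = unname(wt$statistic), p = wt$p.value,
                 method = "mann-whitney", n1 = length(a), n2 = length(b))
}

#' Kruskal-Wallis test with Dunn post-hoc comparisons
#'
#' Kruskal-Wallis H with tie correction (via `stats::kruskal.test`),
#' followed by Dunn z-statistics on the rank sums for every pair, with
#' Holm adjustment within the family of pairwise comparisons.
#'
#' @param groups named list of numeric vectors (>= 2 values each).
#' @return list: `omnibus` (tibble with H, df, p) and `pairs` (tibble with
#'   the Dunn z, raw and Holm-adjusted p per pair).
#' @export
kruskal_dunn <- function(groups) {
  cs_assert(all(lengths(groups) >= 2), "groups need at least 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  rk <- rank(x)
  mean_rk <- tapply(rk, g, mean)
  n_g <- lengths(groups)
  ## tie correction to the rank variance
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  combs <- utils::combn(names(groups), 2)
  z <- apply(combs, 2, function(pr) {
    (mean_rk[pr[1]] - mean_rk[pr[2]]) /
      sqrt(s2 * (1 / n_g[pr[1]] + 1 / n_g[pr[2]]))
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  pairs <- tibble::tibble(
    group1 = combs[1, ], group2 = combs[2, ],
    z = as.numeric(z), p = p_raw,
    p_adj = holm_bonferroni(p_raw),
    method = "dunn")
  list(omnibus = tibble::tibble(statistic = unname(kw$statistic),
                                df = unname(kw$parameter),
                                p = kw$p.value, method = "kruskal-wallis"),
       pairs = pairs)
}

#' One-way ANOVA with bootstrap Tukey-Kramer pairwise comparisons
#'
#' Classic one-way F test, followed by Tukey-Kramer studentized-range
#' statistics whose null distribution is estimated by a within-group
#' resampling bootstrap (groups recentred to a common mean, resampled with
#' replacement; the maximum pairwise q over all pairs forms the familywise
#' reference distribution).
#'
#' @param groups named list of numeric vectors.
#' @param reps bootstrap repetitions.
#' @param seed integer seed.
#' @return list: `omnibus` (F, df, p) and `pairs` (q statistic and
#'   familywise bootstrap p per pair).
#' @export
anova_tukey_bootstrap <- function(groups, reps = cs_default("boot_reps"), seed = 1L) {
  cs_assert(all(lengths(groups) >= 2), "groups need at least 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  fit <- stats::aov(x ~ g)
  an <- summary(fit)[[1]]
  mse <- an["Residuals", "Mean Sq"]
  n_g <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))

  q_obs <- function(m, s2) {
    combs <- utils::combn(seq_along(n_g), 2)
    apply(combs, 2, function(pr) {
      abs(m[pr[1]] - m[pr[2]]) /
        sqrt(s2 / 2 * (1 / n_g[pr[1]] + 1 / n_g[pr[2]]))
    })
  }
  qs <- q_obs(means, mse)

  centred <- lapply(groups, function(v) v - mean(v))
  qmax_null <- with_seed(seed, vapply(seq_len(reps), function(r) {
    bm <- vapply(centred, function(v) mean(sample(v, replace = TRUE)), numeric(1))
    bs2 <- sum(vapply(centred, function(v) {
      s <- sample(v, replace = TRUE); sum((s - mean(s))^2)
    }, numeric(1))) / (length(x) - length(groups))
    max(q_obs(bm, bs2))
  }, numeric(1)))

  combs <- utils::combn(names(groups), 2)
  pairs <- tibble::tibble(
    group1 = combs[1, ], group2 = combs[2, ],
    q = as.numeric(qs),
    p = vapply(qs, function(q0) mean(qmax_null >= q0), numeric(1)),
    method = "tukey-kramer-bootstrap")
  list(omnibus = tibble::tibble(statistic = an["g", "F value"],
                                df1 = an["g", "Df"], df2 = an["Residuals", "Df"],
                                p = an["g", "Pr(>F)"], method = "anova"),
       pairs = pairs)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Order-preserving wrapper around `stats::p.adjust(method = "holm")`.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the input order.
#' @examples
#' holm_bonferroni(c(0.01, 0.04))  # 0.02, 0.04
#' @export
holm_bonferroni <- function(p) {
  stats::p.adjust(p, method = "holm")
}

#' Spearman correlation matrix with p-values
#'
#' Pairwise-complete Spearman rank correlations over all numeric columns,
#' with the correlation-test p-value per pair. The matrix is symmetric with
#' a unit diagonal.
#'
#' @param table data frame; non-numeric columns are dropped.
#' @param min_n minimum complete pairs required for a cell.
#' @return list of matrices `rho` and `p`.
#' @export
spearman_matrix <- function(table, min_n = 4L) {
  num <- as.data.frame(table)[vapply(as.data.frame(table), is.numeric, logical(1))]
  vars <- names(num)
  k <- length(vars)
  rho <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  pm <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(rho) <- 1
  diag(pm) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- stats::complete.cases(num[[i]], num[[j]])
      if (sum(ok) >= min_n && stats::sd(num[[i]][ok]) > 0 && stats::sd(num[[j]][ok]) > 0) {
        ct <- suppressWarnings(
          stats::cor.test(num[[i]][ok], num[[j]][ok], method = "spearman"))
        rho[i, j] <- rho[j, i] <- unname(ct$estimate)
        pm[i, j] <- pm[j, i] <- ct$p.value
      }
    }
  }
  list(rho = rho, p = pm)
}

#' Kendall coefficient of concordance (W) with tie correction
#'
#' `W = 12 * sum((R_i - mean(R))^2) / (m^2 (n^3 - n) - m * sum(T_j))` for
#' `m` rankers over `n` items, where `T_j = sum(t^3 - t)` over tie groups
#' of ranker `j`. W is 1 for identical rankings and 0 for maximal
#' disagreement; values of 0.5 and above are read as strong agreement.
#'
#' @param rankings m x n matrix (rows = rankers/variables, columns = items);
#'   values are ranked within rows.
#' @return W in `[0, 1]`.
#' @examples
#' kendall_w(rbind(1:4, 1:4))  # 1
#' kendall_w(rbind(1:4, 4:1))  # 0
#' @export
kendall_w <- function(rankings) {
  rankings <- as.matrix(rankings)
  m <- nrow(rankings)
  n <- ncol(rankings)
  cs_assert(m >= 2 && n >= 2, "need at least 2 rankers and 2 items")
  R <- apply(rankings, 1, rank)           # n x m of within-ranker ranks
  Ri <- rowSums(R)
  T_j <- apply(R, 2, function(r) {
    t <- table(r)
    sum(t^3 - t)
  })
  denom <- m^2 * (n^3 - n) - m * sum(T_j)
  if (denom <= 0) return(NA_real_)
  W <- 12 * sum((Ri - mean(Ri))^2) / denom
  min(max(W, 0), 1)
}

#' Pairwise concordance report between audio features and other modalities
#'
#' For every (audio feature, partner feature) pair and condition, the two
#' features are treated as two rankers of the condition's segments and the
#' tie-corrected Kendall W is computed. Pairs are flagged at the strong
#' agreement threshold (W >= 0.5, starred) and at W > 0.7 (framed).
#'
#' @param table data frame of condition-matched rows.
#' @param audio_features,partner_features column name vectors.
#' @param condition_col name of the condition column.
#' @param conditions conditions to analyse.
#' @param min_n minimum complete rows per pair.
#' @return tibble: `audio_feature`, `partner_feature`, `condition`, `n`,
#'   `W`, `strong` (W >= 0.5), `framed` (W > 0.7).
#' @export
concordance_report <- function(table, audio_features, partner_features,
                               condition_col = "condition",
                               conditions = c("cry", "distress"),
                               min_n = 4L) {
  rows <- list()
  thr_s <- cs_default("kendall_strong")
  thr_f <- cs_default("kendall_framed")
  for (cond in conditions) {
    sub <- table[table[[condition_col]] == cond, , drop = FALSE]
    for (af in audio_features) {
      for (pf in partner_features) {
        ok <- stats::complete.cases(sub[[af]], sub[[pf]])
        W <- if (sum(ok) >= min_n) {
          kendall_w(rbind(sub[[af]][ok], sub[[pf]][ok]))
        } else NA_real_
        rows[[length(rows) + 1L]] <- tibble::tibble(
          audio_feature = af, partner_feature = pf, condition = cond,
          n = sum(ok), W = W,
          strong = !is.na(W) & W >= thr_s,
          framed = !is.na(W) & W > thr_f)
      }
    }
  }
  dplyr::bind_rows(rows)
}
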