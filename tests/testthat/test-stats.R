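test_that("balanced subsampling equalizes group sizes deterministically", {
  g <- list(a = stats::rnorm(300), b = stats::rnorm(295))
  b1 <- balanced_subsample(g, seed = 4)
  expect_equal(lengths(b1), c(a = 295L, b = 295L))
  b2 <- balanced_subsample(g, seed = 4)
  expect_identical(b1, b2)
  same <- balanced_subsample(list(a = 1:5, b = 6:10), seed = 1)
  expect_identical(same, list(a = 1:5, b = 6:10))
})

test_that("Mann-Whitney matches exact enumeration on disjoint samples", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  ## 2/20 arrangements are as extreme (two-sided): p = 0.100
  expect_equal(mw$p, 0.1, tolerance = 1e-9)
  expect_error(mann_whitney(1, c(2, 3)), "at least 2")
})

test_that("Kruskal-Wallis with Dunn is null-calibrated on identical groups", {
  g <- with_seed(81, {x <- stats::rnorm(20); list(a = x, b = x, c = x)})
  kd <- kruskal_dunn(g)
  expect_gt(kd$omnibus$p, 0.99)
  expect_true(all(kd$pairs$p_adj > 0.9))
  expect_true(all(kd$pairs$p_adj >= kd$pairs$p))
})

test_that("Holm adjustment matches hand-stepped values and preserves order", {
  expect_equal(holm_bonferroni(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_bonferroni(0.03), 0.03)
  ## step-down with monotonicity: sorted (0.02, 0.03) -> (0.04, cummax -> 0.04)
  expect_equal(holm_bonferroni(c(0.03, 0.02)), c(0.04, 0.04))
  p <- c(0.001, 0.2, 0.04, 0.01)
  adj <- holm_bonferroni(p)
  expect_true(all(adj >= p))
  perm <- c(3, 1, 4, 2)
  expect_equal(holm_bonferroni(p[perm]), adj[perm])
})

test_that("Spearman matrix matches the rank formula and is symmetric", {
  x <- c(2.2, 1.1, 5.3, 4.1, 3.7)
  y <- c(0.4, 0.2, 1.0, 0.9, 0.6)
  tb <- tibble::tibble(x = x, y = y, lin = 2 * x + 1, neg = -x)
  sm <- spearman_matrix(tb)
  expect_equal(sm$rho["x", "lin"], 1)
  expect_equal(sm$rho["x", "neg"], -1)
  ## brute-force rank formula oracle (no ties): 1 - 6*sum(d^2)/(n(n^2-1))
  d <- rank(x) - rank(y)
  rho_brute <- 1 - 6 * sum(d^2) / (5 * 24)
  expect_equal(sm$rho["x", "y"], rho_brute, tolerance = 1e-12)
  expect_identical(sm$rho, t(sm$rho))
  expect_equal(unname(diag(sm$rho)), rep(1, 4))
  expect_true(all(sm$rho >= -1 & sm$rho <= 1, na.rm = TRUE))
})

test_that("Kendall W matches the direct formula, the reference implementation, and is invariant to monotone transforms", {
  expect_equal(kendall_w(rbind(1:5, 1:5, 1:5)), 1)
  expect_equal(kendall_w(rbind(1:5, 5:1)), 0)
  ## direct-formula oracle on random m=3, n=4 tables (with tie correction)
  w_direct <- function(M) {
    R <- apply(M, 1, rank)
    Ri <- rowSums(R)
    Tj <- apply(R, 2, function(r) {t <- table(r); sum(t^3 - t)})
    m <- nrow(M); n <- ncol(M)
    12 * sum((Ri - mean(Ri))^2) / (m^2 * (n^3 - n) - m * sum(Tj))
  }
  for (s in 1:5) {
    M <- with_seed(90 + s, matrix(stats::runif(12), 3, 4))
    expect_equal(kendall_w(M), w_direct(M), tolerance = 1e-12)
    expect_equal(kendall_w(M), unname(
      vegan::kendall.global(t(M))$Concordance_analysis[1, 1]),
      tolerance = 1e-10)
  }
  ## strictly monotone transforms do not change W
  M <- with_seed(96, matrix(stats::runif(8), 2, 4))
  expect_equal(kendall_w(M), kendall_w(rbind(exp(M[1, ]), M[2, ]^3)),
               tolerance = 1e-12)
  expect_true(kendall_w(M) >= 0 && kendall_w(M) <= 1)
})

test_that("bootstrap Tukey-Kramer detects a shifted group and not a null one", {
  detect <- vapply(1:8, function(r) {
    g <- with_seed(200 + r, list(a = stats::rnorm(30), b = stats::rnorm(30) + 2,
                                 c = stats::rnorm(30)))
    at <- anova_tukey_bootstrap(g, reps = 1000, seed = 300 + r)
    shifted <- at$pairs$p[at$pairs$group1 == "a" & at$pairs$group2 == "b"] < 0.05 &
      at$pairs$p[at$pairs$group1 == "b" & at$pairs$group2 == "c"] < 0.05
    null_ok <- at$pairs$p[at$pairs$group1 == "a" & at$pairs$group2 == "c"] > 0.05
    shifted && null_ok
  }, logical(1))
  expect_gte(mean(detect), 7 / 8)
})

test_that("concordance report stars W >= 0.5 and frames W > 0.7", {
  ## construct pairs with controlled agreement
  n <- 30
  base <- with_seed(97, stats::rnorm(n))
  tb <- tibble::tibble(
    condition = "cry",
    a_strong = base,
    p_strong = base + with_seed(98, stats::rnorm(n, sd = 0.2)),
    p_noise = with_seed(99, stats::rnorm(n)))
  rep <- concordance_report(tb, "a_strong", c("p_strong", "p_noise"),
                            conditions = "cry")
  strong <- rep[rep$partner_feature == "p_strong", ]
  expect_true(strong$W > 0.7 && strong$strong && strong$framed)
  noisy <- rep[rep$partner_feature == "p_noise", ]
  expect_false(noisy$framed)
  ## null Monte-Carlo: with two rankers W = (rho + 1)/2, so independent
  ## features centre W at 0.5 (the star threshold is the null median) and
  ## almost never reach the framed threshold
  W_null <- vapply(1:20, function(s) {
    tb2 <- tibble::tibble(condition = "cry",
                          a = with_seed(400 + s, stats::rnorm(n)),
                          p = with_seed(500 + s, stats::rnorm(n)))
    concordance_report(tb2, "a", "p", conditions = "cry")$W
  }, numeric(1))
  expect_lt(abs(mean(W_null) - 0.5), 0.1)
  expect_gte(mean(W_null <= 0.7), 0.9)
})
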