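mk_series <- function(n = 300, seed = 61, pr_mean = 130) {
  with_seed(seed, nirs_series(
    t_s = seq(1, by = 2, length.out = n),
    rSO2 = stats::rnorm(n, 75, 3),
    SpO2 = pmin(100, stats::rnorm(n, 96, 1.5)),
    PR = stats::rnorm(n, pr_mean, 8)))
}

test_that("flat-line runs are removed by the sliding-SD rule", {
  s <- mk_series()
  s$PR[50:90] <- 123.4                        # ~80 s constant run
  out <- nirs_clean(s)
  ## samples whose whole 60-s window lies inside the run are removed
  expect_true(all(is.na(out$PR[66:74])))
  expect_false(anyNA(out$PR[150:200]))        # clean stretch untouched
})

test_that("Tukey fences remove far outliers and keep near ones", {
  s <- mk_series(seed = 62)
  q <- stats::quantile(s$rSO2, c(0.25, 0.75)); iqr <- q[2] - q[1]
  s$rSO2[10] <- q[2] + 2.0 * iqr
  s$rSO2[20] <- q[2] + 1.4 * iqr
  out <- nirs_clean(s)
  expect_true(is.na(out$rSO2[10]))
  expect_false(is.na(out$rSO2[20]))
})

test_that("a clean Gaussian series loses at most a few percent of points", {
  ## expected Tukey outlier mass for a normal is ~0.7%
  s <- mk_series(seed = 63)
  out <- nirs_clean(s)
  removed <- mean(is.na(out$rSO2) | is.na(out$SpO2) | is.na(out$PR))
  expect_lte(removed, 0.03)
})

test_that("the cascade is idempotent", {
  s <- mk_series(seed = 64)
  s$PR[100:140] <- 111
  s$SpO2[5] <- 60
  once <- nirs_clean(s)
  twice <- nirs_clean(once)
  expect_identical(once, twice)
})

test_that("segmentation trims 15 s borders and drops unannotated samples", {
  ann <- tibble::tibble(start = c(0, 100), end = c(60, 130),
                        condition = c("cry", "resting"))
  s <- mk_series(n = 100)
  seg <- nirs_segment(s, ann)
  ## 60-s interval at centre-of-bin timestamps: interior (15, 45) holds 14
  expect_equal(seg$n[seg$segment == 1 & seg$variable == "PR"], 14)
  ## 30-s interval: nothing survives the trimming
  expect_equal(seg$n[seg$segment == 2 & seg$variable == "PR"], 0)
  ## samples between 60 and 100 s belong to no segment
  expect_equal(sum(seg$n[seg$variable == "PR"]), 14)
})

test_that("no sample is assigned to two conditions", {
  ann <- tibble::tibble(start = c(0, 60), end = c(60, 150),
                        condition = c("cry", "distress"))
  s <- mk_series(n = 80)
  seg <- nirs_segment(s, ann)
  n_assigned <- sum(seg$n[seg$variable == "PR"])
  in1 <- sum(s$t_s > 15 & s$t_s < 45)
  in2 <- sum(s$t_s > 75 & s$t_s < 135)
  expect_equal(n_assigned, in1 + in2)
})

test_that("floor filtering is strict and per-variable", {
  seg <- tibble::tibble(
    segment = 1:4, condition = "cry", start = 0, end = 60,
    variable = c("SpO2", "rSO2", "PR", "SpO2"),
    n = c(10, 10, 10, 10),
    mean = c(75, 65, 120, 80))
  out <- nirs_threshold_filter(seg)
  expect_false(out$keep[1])     # SpO2 75 < 80
  expect_true(out$keep[2])      # rSO2 65 >= 50
  expect_true(out$keep[3])      # PR 120 >= 70
  expect_true(out$keep[4])      # exactly at the floor: retained
})

test_that("condition means follow the programmed physiological directions", {
  ann <- tibble::tibble(start = c(0, 120, 240), end = c(120, 240, 360),
                        condition = c("resting", "cry", "distress"))
  s <- synth_nirs(ann, default_condition_profiles(), seed = 66)
  seg <- nirs_threshold_filter(nirs_segment(nirs_clean(s), ann))
  m <- function(v) {
    x <- seg$mean[seg$variable == v & seg$keep]
    stats::setNames(x, seg$condition[seg$variable == v & seg$keep])
  }
  pr <- m("PR"); sp <- m("SpO2"); rs <- m("rSO2")
  expect_true(pr["distress"] > pr["cry"] && pr["cry"] > pr["resting"])
  expect_true(sp["distress"] < sp["cry"] && sp["cry"] < sp["resting"])
  expect_true(rs["distress"] < rs["cry"] && rs["cry"] < rs["resting"])
})

test_that("effort coupling yields the published cross-modal correlation signs", {
  ## many annotated episodes with known vocalized time: pulse rate should
  ## correlate positively and oxygenation negatively with crying time
  n_ep <- 40
  starts <- (0:(n_ep - 1)) * 100
  ann <- tibble::tibble(start = starts, end = starts + 80,
                        condition = rep(c("cry", "distress"), n_ep / 2))
  cryce <- with_seed(150, stats::runif(n_ep, 5, 60))
  eff <- tibble::tibble(start = ann$start, end = ann$end,
                        effort_z = as.numeric(scale(cryce)))
  s <- synth_nirs(ann, default_condition_profiles(), seed = 151,
                  episode_effort = eff)
  seg <- nirs_segment(nirs_clean(s), ann)
  pr <- seg$mean[seg$variable == "PR"]
  rs <- seg$mean[seg$variable == "rSO2"]
  expect_gt(stats::cor(cryce, pr, method = "spearman", use = "complete.obs"), 0)
  expect_lt(stats::cor(cryce, rs, method = "spearman", use = "complete.obs"), 0)
})
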