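channels <- cs_default("eeg_channels")
eeg_fs <- cs_default("eeg_fs")

test_that("preprocessing removes line noise, DC and re-references", {
  n <- 10 * eeg_fs
  tt <- seq_len(n) / eeg_fs
  X <- matrix(stats::rnorm(n * 8, sd = 5), n, 8, dimnames = list(NULL, channels))
  X50 <- X + 50 * sin(2 * pi * 50 * tt)        # line contamination
  rec <- preprocess_eeg(eeg_recording(X50, eeg_fs), average_reference = FALSE)
  sine_in <- 50 / sqrt(2)
  ## project the filtered signal back onto the 50 Hz component
  amp_out <- 2 * abs(mean(rec$data[, 1] * exp(-2i * pi * 50 * tt))) / sqrt(2)
  expect_gt(20 * log10(sine_in / amp_out), 20)
  ## DC offset vanishes
  recDC <- preprocess_eeg(eeg_recording(X + 100, eeg_fs), average_reference = FALSE)
  expect_lt(abs(mean(recDC$data[, 1])), 0.5)
  ## average reference: channel mean is zero at every sample
  rec2 <- preprocess_eeg(eeg_recording(X, eeg_fs))
  expect_lt(max(abs(rowMeans(rec2$data))), 1e-9)
})

test_that("bad-channel detection flags flat and extreme channels", {
  fx <- eeg_fixture()
  expect_length(detect_bad_channels(fx$rec), 0)
  X <- fx$rec$data
  X[, "T7"] <- stats::rnorm(nrow(X), sd = 0.01)
  expect_equal(detect_bad_channels(eeg_recording(X, eeg_fs)), "T7")
  X[, "P4"] <- stats::rnorm(nrow(X), sd = 0.01)
  expect_setequal(detect_bad_channels(eeg_recording(X, eeg_fs)), c("T7", "P4"))
  X2 <- fx$rec$data
  X2[, "F3"] <- X2[, "F3"] * 20
  expect_equal(detect_bad_channels(eeg_recording(X2, eeg_fs)), "F3")
})

test_that("spherical splines reproduce constants and smooth dipolar fields", {
  X <- matrix(7.5, 512, 8, dimnames = list(NULL, channels))
  rec <- eeg_recording(X, eeg_fs, bad_channels = "C4")
  out <- interpolate_spherical_spline(rec)
  expect_lt(max(abs(out$data[, "C4"] - 7.5)), 1e-6)

  ## forward-model oracle: potential of a dipole inside the head sphere,
  ## evaluated analytically at the electrodes; leave one channel out
  pos <- electrode_positions()
  P <- as.matrix(pos[, c("x", "y", "z")])
  r0 <- c(0.1, 0.1, 0); p_mom <- c(0.2, -0.5, 1)
  dip <- function(e) { d <- e - r0; sum(p_mom * d) / sum(d^2)^1.5 }
  v <- apply(P, 1, dip)
  rng <- diff(range(v))
  for (bad in c("C3", "F4", "P3")) {
    X <- matrix(v, nrow = 4, ncol = 8, byrow = TRUE,
                dimnames = list(NULL, pos$channel))
    rec <- eeg_recording(X, eeg_fs, bad_channels = bad)
    out <- interpolate_spherical_spline(rec)
    err <- abs(out$data[1, bad] - v[pos$channel == bad])
    expect_lt(err, 0.15 * rng)
  }

  ## more than one bad channel is a rejection, not an interpolation
  rec2 <- eeg_recording(matrix(v, 4, 8, byrow = TRUE,
                               dimnames = list(NULL, pos$channel)),
                        eeg_fs, bad_channels = c("C3", "C4"))
  expect_error(interpolate_spherical_spline(rec2), "one channel")
})

test_that("epoching tiles 4-s windows inside conditions and rejects bursts", {
  fx <- eeg_fixture()
  rec <- preprocess_eeg(fx$rec)
  eps <- epoch_and_reject(rec, fx$ann)
  expect_length(eps, 45)                     # 3 x 60 s / 4 s
  ## no epoch crosses an annotation boundary
  for (e in eps) {
    hit <- fx$ann[fx$ann$start <= e$start + 1e-9 &
                    fx$ann$end >= e$start + 4 - 1e-9, ]
    expect_equal(nrow(hit), 1)
    expect_identical(e$condition, hit$condition)
  }
  expect_equal(sum(vapply(eps, `[[`, character(1), "quality") == "rejected"), 0)
  ## inject a 500 uV burst into one epoch
  X <- rec$data
  X[round(10.5 * eeg_fs):round(10.8 * eeg_fs), ] <- 500
  eps2 <- epoch_and_reject(eeg_recording(X, eeg_fs), fx$ann)
  qual <- vapply(eps2, `[[`, character(1), "quality")
  expect_equal(sum(qual == "rejected"), 1)
  expect_identical(qual[3], "rejected")      # epoch covering 8-12 s
})

test_that("artifact injection drives rejections; none when rate is zero", {
  ann <- tibble::tibble(start = 0, end = 120, condition = "cry")
  rec0 <- synth_eeg(ann, default_condition_profiles(), seed = 9, artifact_rate = 0)
  eps0 <- epoch_and_reject(preprocess_eeg(rec0), ann)
  expect_equal(sum(vapply(eps0, `[[`, character(1), "quality") == "rejected"), 0)
  rec1 <- synth_eeg(ann, default_condition_profiles(), seed = 9, artifact_rate = 6)
  eps1 <- epoch_and_reject(preprocess_eeg(rec1), ann)
  expect_gt(sum(vapply(eps1, `[[`, character(1), "quality") == "rejected"), 0)
})

test_that("Welch PSD satisfies Parseval and nails narrowband signals", {
  n <- 4 * eeg_fs
  x <- with_seed(71, stats::rnorm(n))
  w <- welch_psd(matrix(x, ncol = 1), eeg_fs)
  df <- w$freq[2] - w$freq[1]
  expect_equal(sum(w$psd) * df, stats::var(x), tolerance = 0.05 * stats::var(x))
  ## pure 10 Hz sinusoid + tiny noise: alpha dominates
  tt <- seq_len(n) / eeg_fs
  x10 <- sin(2 * pi * 10 * tt) + 0.01 * with_seed(72, stats::rnorm(n))
  w10 <- welch_psd(matrix(x10, ncol = 1), eeg_fs)
  rp <- relative_band_power(w10$psd, w10$freq)
  expect_gt(rp["alpha", 1], 0.95)
})

test_that("relative band power uses half-open bins normalized over 1-45 Hz", {
  freq <- 0:256
  flat <- matrix(1, length(freq), 2)
  rp <- relative_band_power(flat, freq)
  expect_equal(unname(rp["delta", 1]), 3 / 44, tolerance = 1e-12)
  expect_equal(unname(rp["theta", 1]), 4 / 44, tolerance = 1e-12)
  expect_equal(unname(rp["alpha", 2]), 4 / 44, tolerance = 1e-12)
  ## all relative powers over the full range sum to one
  all_bins <- relative_band_power(flat, freq,
                                  bands = list(all = c(1, 45)))
  expect_equal(unname(all_bins["all", 1]), 1, tolerance = 1e-9)
})

test_that("percent change is zero for identical distributions, exact otherwise", {
  tb <- tibble::tibble(
    epoch = rep(1:4, each = 2),
    condition = rep(c("resting", "cry"), each = 4),
    channel = "C3", band = rep(c("delta", "theta"), 4),
    rel_power = c(0.1, 0.2, 0.1, 0.2, 0.2, 0.2, 0.2, 0.2))
  pc <- percent_change(tb)
  expect_equal(pc$pct_change[pc$band == "delta"], 100)   # 0.1 -> 0.2
  expect_equal(pc$pct_change[pc$band == "theta"], 0)
})
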