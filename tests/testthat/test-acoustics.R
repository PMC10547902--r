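fs <- 48000

test_that("local jitter and shimmer follow the printed formulas", {
  expect_equal(jitter_local(c(2.0, 2.0, 2.0) / 1000), 0)
  ## hand evaluation: (0.2 + 0.2)/2 / mean(2.0, 2.2, 2.0)
  expect_equal(jitter_local(c(2.0, 2.2, 2.0) / 1000), 0.2 / (6.2 / 3),
               tolerance = 1e-9)
  expect_true(is.na(jitter_local(2e-3)))
  expect_equal(shimmer_local(c(1, 1, 1)), 0)
  expect_equal(shimmer_local(c(1, 1.2, 1)), 0.2 / (3.2 / 3), tolerance = 1e-9)
})

test_that("time features are exact arithmetic and percentages sum to one", {
  ep <- cry_episode(tibble::tibble(start = c(0, 12, 25), end = c(10, 22, 35)),
                    tibble::tibble(start = c(10, 22), end = c(12, 25)))
  tf <- time_features(ep)
  expect_equal(tf$cryCE, 30)
  expect_equal(tf$unvoicedCE, 5)
  expect_equal(tf$cryCE_pct, 30 / 35)
  expect_equal(tf$cryCE_pct + tf$unvoicedCE_pct, 1, tolerance = 1e-9)
  ## zero gaps
  ep2 <- cry_episode(tibble::tibble(start = 0, end = 3))
  tf2 <- time_features(ep2)
  expect_equal(tf2$unvoicedCE, 0)
  expect_equal(tf2$cryCE_pct, 1)
})

test_that("F0 contour recovers exact-period signals and flags noise unvoiced", {
  ## 440 Hz sawtooth has an exact period
  t <- seq(0, 0.5, by = 1 / fs)
  saw <- 0.3 * (2 * ((440 * t) %% 1) - 1)
  ctr <- f0_contour(saw, fs)
  expect_lt(abs(stats::median(ctr$f0, na.rm = TRUE) - 440), 1)
  ## white noise: no stable periodicity
  wn <- with_seed(31, stats::rnorm(fs / 2) * 0.1)
  ctn <- f0_contour(wn, fs)
  expect_gte(mean(!ctn$voiced), 0.9)
})

test_that("a linear F0 sweep is tracked to within 2% at the endpoints", {
  ## pulse train with analytic instantaneous frequency 400 -> 800 Hz
  dur <- 1; f0a <- 400; f0b <- 800
  inst_f <- function(t) f0a + (f0b - f0a) * t / dur
  t_k <- c(); t_cur <- 0
  while (t_cur < dur) { t_k <- c(t_k, t_cur); t_cur <- t_cur + 1 / inst_f(t_cur) }
  x <- numeric(round(dur * fs))
  x[round(t_k * fs) + 1] <- 1
  x <- as.numeric(signal::filter(signal::Arma(b = 0.03, a = c(1, -0.97)), x))
  ctr <- f0_contour(x, fs)
  v <- ctr[ctr$voiced, ]
  first <- v$f0[1]; last <- v$f0[nrow(v)]
  expect_lt(abs(first - inst_f(v$time[1])) / inst_f(v$time[1]), 0.02)
  expect_lt(abs(last - inst_f(v$time[nrow(v)])) / inst_f(v$time[nrow(v)]), 0.02)
})

test_that("F0 statistics cover voiced frames only with pitch-class fractions", {
  ctr <- tibble::tibble(time = 1:10 / 10,
                        f0 = c(rep(500, 6), rep(850, 2), NA, NA),
                        voiced = c(rep(TRUE, 8), FALSE, FALSE),
                        r = rep(0.9, 10))
  st <- f0_statistics(ctr)
  expect_equal(st$f0_min, 500)
  expect_equal(st$f0_max, 850)
  expect_equal(st$high_pitch_pct, 0.25)
  expect_equal(st$hyperphonation_pct, 0)
  ## constant contour: zero spread, zero fractions
  ctr2 <- tibble::tibble(time = 1:5, f0 = rep(500, 5), voiced = TRUE, r = 0.9)
  st2 <- f0_statistics(ctr2)
  expect_equal(st2$f0_sd, 0)
  expect_equal(st2$high_pitch_pct, 0)
})

test_that("HNR has the closed form in r and saturates for clean phonation", {
  expect_equal(hnr_from_correlation(0.5), 0)
  expect_equal(hnr_from_correlation(0.9), 10 * log10(9), tolerance = 1e-9)
  expect_gte(hnr(as.numeric(clean_unit()), fs), 30)
})

test_that("segmentation finds units at annotated boundaries within 50 ms", {
  prof <- default_condition_profiles()
  ep <- synth_episode(prof$cry, seed = 41, n_units = 4,
                      unit_durs = c(1.0, 0.8, 1.2, 0.9),
                      gap_durs = c(0.5, 0.6, 0.5))
  eps <- detect_voiced_regions(ep$wave, fs)
  expect_length(eps, 1)
  det <- eps[[1]]$units
  expect_equal(nrow(det), 4)
  expect_lt(max(abs(det$start - ep$units$start)), 0.05)
  expect_lt(max(abs(det$end - ep$units$end)), 0.05)
})

test_that("silence and single continuous units segment as expected", {
  expect_length(detect_voiced_regions(numeric(fs), fs), 0)
  quiet <- as.numeric(synth_resting_audio(2, seed = 5))
  expect_length(detect_voiced_regions(quiet, fs), 0)
  one <- synth_cry_unit(cry_params(f0_mean = 450), 3, seed = 6)
  eps <- detect_voiced_regions(as.numeric(one), fs)
  expect_length(eps, 1)
  expect_equal(nrow(eps[[1]]$units), 1)
  expect_equal(nrow(eps[[1]]$unvoiced), 0)
})

test_that("formants recover synthetic resonators and refuse noise", {
  w <- synth_cry_unit(cry_params(f0_mean = 478, f0_sd = 0,
                                 f0_contour_shape = "flat",
                                 jitter_frac = 0.01, shimmer_frac = 0.05,
                                 hnr_db = 12, formants = c(1400, 3500, 5900)),
                      0.8, seed = 51)
  fm <- formants(as.numeric(w), fs)
  expect_lt(abs(fm[["f1"]] - 1400) / 1400, 0.05)
  expect_lt(abs(fm[["f2"]] - 3500) / 3500, 0.05)
  expect_lt(abs(fm[["f3"]] - 5900) / 5900, 0.05)
  wn <- with_seed(52, stats::rnorm(fs / 2) * 0.1)
  expect_true(all(is.na(formants(wn, fs))))
})

test_that("MFCCs are deterministic, discriminative, and level-separable", {
  w1 <- as.numeric(cry_unit())
  m1 <- mfcc(w1, fs); m1b <- mfcc(w1, fs)
  expect_identical(m1$summary, m1b$summary)
  w2 <- synth_cry_unit(cry_params(f0_mean = 800, f0_sd = 0,
                                  f0_contour_shape = "flat"), 0.8, seed = 53)
  m2 <- mfcc(as.numeric(w2), fs)
  expect_gt(sqrt(sum((m1$summary - m2$summary)^2)), 0)
  ## amplitude scaling moves only the 0th coefficient
  m_scaled <- mfcc(w1 * 2, fs)
  d <- abs(m_scaled$summary - m1$summary)
  expect_gt(d[["mfcc0_mean"]], 0.1)
  expect_lt(max(d[setdiff(names(d), "mfcc0_mean")]), 1e-6)
})

test_that("mel spectrograms have a fixed canvas regardless of unit length", {
  s1 <- mel_spectrogram(as.numeric(cry_unit()), fs)
  s2 <- mel_spectrogram(as.numeric(clean_unit()), fs)
  expect_equal(dim(s1), c(cs_default("spec_mel_bands"), cs_default("spec_frames")))
  expect_identical(dim(s1), dim(s2))
})

test_that("features are invariant to overall gain", {
  w <- as.numeric(cry_unit())
  ctr1 <- f0_contour(w, fs); ctr2 <- f0_contour(0.5 * w, fs)
  expect_equal(ctr1$f0, ctr2$f0, tolerance = 1e-6)
  c1 <- pick_cycles(w, fs); c2 <- pick_cycles(0.5 * w, fs)
  expect_equal(jitter_local(c1$periods), jitter_local(c2$periods),
               tolerance = 1e-6)
  expect_equal(shimmer_local(c1$amplitudes), shimmer_local(c2$amplitudes),
               tolerance = 1e-6)
  expect_equal(hnr(w, fs, cycles = c1), hnr(0.5 * w, fs, cycles = c2),
               tolerance = 0.05)
  expect_equal(formants(w, fs), formants(0.5 * w, fs), tolerance = 1e-6)
})

test_that("perturbation estimates increase monotonically with synthesis levels", {
  base <- function(jit, shim, hnr_db) cry_params(
    f0_mean = 478, f0_sd = 0, f0_contour_shape = "flat",
    jitter_frac = jit, shimmer_frac = shim, hnr_db = hnr_db)
  batch <- function(params, what, n = 3) {
    mean(vapply(seq_len(n), function(i) {
      w <- synth_cry_unit(params, 0.7, seed = 700 + 13 * i)
      cyc <- pick_cycles(as.numeric(w), fs, f0_hint = 478)
      switch(what,
             jitter = jitter_local(cyc$periods),
             shimmer = shimmer_local(cyc$amplitudes),
             hnr = cyc$hnr_db)
    }, numeric(1)), na.rm = TRUE)
  }
  jit_est <- vapply(c(0, 0.01, 0.02, 0.04), function(j)
    batch(base(j, 0.02, 15), "jitter"), numeric(1))
  expect_false(is.unsorted(jit_est))
  shim_est <- vapply(c(0.02, 0.06, 0.12, 0.18), function(s)
    batch(base(0.01, s, 15), "shimmer"), numeric(1))
  expect_false(is.unsorted(shim_est))
  hnr_est <- vapply(c(5, 12, 25), function(h)
    batch(base(0.01, 0.05, h), "hnr"), numeric(1))
  expect_false(is.unsorted(hnr_est))   # more noise, lower HNR
})
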