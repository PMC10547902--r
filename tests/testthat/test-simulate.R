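test_that("cry_params enforces its physical invariants", {
  expect_error(cry_params(f0_mean = 150), "200")
  expect_error(cry_params(jitter_frac = 0.5), "jitter")
  expect_error(cry_params(formants = c(3000, 2000, 5000)), "increasing")
  expect_error(cry_params(unit_dur_range = c(-1, 1)), "positive")
  expect_error(cry_params(hnr_db = 60), "hnr")
})

test_that("synth_cry_unit rejects formants above Nyquist and bad durations", {
  p <- cry_params(f0_mean = 500)
  expect_error(synth_cry_unit(p, dur = 0.001, seed = 1), "periods")
  p2 <- cry_params(formants = c(1400, 3500, 9000))
  expect_error(synth_cry_unit(p2, dur = 0.3, seed = 1, fs = 16000), "Nyquist")
})

test_that("unperturbed synthesis has exact period and analytic HNR truth", {
  w <- clean_unit()
  tr <- attr(w, "truth")
  expect_lt(tr$jitter_realized, 0.005)     # sample-grid rounding floor only
  expect_lt(tr$shimmer_realized, 1e-12)
  expect_equal(tr$hnr_analytic_db, 40, tolerance = 1e-6)
  expect_lte(max(abs(w)), 0.99)
})

test_that("fixed seed gives byte-identical waveforms and sessions", {
  p <- cry_params(f0_mean = 478)
  w1 <- synth_cry_unit(p, 0.4, seed = 7)
  w2 <- synth_cry_unit(p, 0.4, seed = 7)
  expect_identical(as.numeric(w1), as.numeric(w2))
  prof <- default_condition_profiles()
  e1 <- synth_episode(prof$cry, seed = 3, n_units = 3)
  e2 <- synth_episode(prof$cry, seed = 3, n_units = 3)
  expect_identical(e1$wave, e2$wave)
  expect_identical(e1$truth$cryCE, e2$truth$cryCE)
})

test_that("episode time bookkeeping is additive", {
  prof <- default_condition_profiles()
  ep <- synth_episode(prof$cry, seed = 11, n_units = 3,
                      unit_durs = c(2, 2, 2), gap_durs = c(1, 1))
  expect_equal(ep$truth$cryCE, 6, tolerance = 1e-3)
  expect_equal(ep$truth$unvoicedCE, 2, tolerance = 1e-3)
  expect_equal(nrow(ep$units), 3)
})

test_that("distress defaults generate Table-1-calibrated perturbations", {
  ## batch of distress-profile units: the realized cycle perturbations of
  ## the generated waveforms must match the programmed targets; the
  ## analyzer's estimates must track them within its own (wider) accuracy
  ## under the profile's low-HNR, wide-contour draws
  prof <- default_condition_profiles()
  n <- 40
  jit <- shim <- jit_true <- shim_true <- numeric(n)
  for (i in seq_len(n)) {
    p <- with_seed(cs_subseed(500 + i, "draw"),
                   cryscope:::draw_unit_params(prof$distress))
    w <- synth_cry_unit(p, 0.7, seed = 600 + i)
    tr <- attr(w, "truth")
    jit_true[i] <- tr$jitter_realized
    shim_true[i] <- tr$shimmer_realized
    cyc <- pick_cycles(as.numeric(w), audio_fs(),
                       contour = f0_contour(as.numeric(w), audio_fs()))
    jit[i] <- jitter_local(cyc$periods)
    shim[i] <- shimmer_local(cyc$amplitudes)
  }
  expect_gt(mean(jit_true), 0.022 * 0.8)
  expect_lt(mean(jit_true), 0.022 * 1.2)
  expect_gt(mean(shim_true), 0.143 * 0.8)
  expect_lt(mean(shim_true), 0.143 * 1.2)
  expect_gt(mean(jit, na.rm = TRUE), 0.022 * 0.8)
  expect_lt(mean(jit, na.rm = TRUE), 0.022 * 1.5)
  expect_gt(mean(shim, na.rm = TRUE), 0.143 * 0.8)
  expect_lt(mean(shim, na.rm = TRUE), 0.143 * 1.5)
})

test_that("session bundle streams agree and every episode has a COMFORT record", {
  bundle <- fixture("small_session", synth_session(
    seed = 21, n_cry = 1, n_distress = 1, resting_dur_range = c(32, 36)))
  expect_s3_class(bundle, "session_bundle")
  t_ann <- max(bundle$annotations$end)
  expect_lt(abs(length(bundle$audio) / bundle$fs - t_ann), 2)
  expect_lt(abs(nrow(bundle$eeg$data) / bundle$eeg$fs - t_ann), 2)
  expect_equal(nrow(bundle$comfort),
               sum(bundle$annotations$condition != "resting"))
  a <- bundle$annotations
  expect_false(is.unsorted(a$start))
  expect_true(all(a$start[-1] >= a$end[-nrow(a)] - 1e-9))
})

test_that("NIRS generator samples at 2-s bin centres and honours injections", {
  ann <- tibble::tibble(start = 0, end = 120, condition = "resting")
  prof <- default_condition_profiles()
  ns <- synth_nirs(ann, prof, seed = 5)
  expect_equal(ns$t_s[1:3], c(1, 3, 5))
  expect_equal(diff(ns$t_s), rep(2, length(ns$t_s) - 1))
  ## injected flat run freezes all variables
  ns2 <- synth_nirs(ann, prof, seed = 5,
                    flat_runs = tibble::tibble(start = 20, end = 80))
  sel <- ns2$t_s >= 20 & ns2$t_s <= 80
  expect_equal(stats::sd(ns2$PR[sel]), 0)
})

test_that("comfort draws respect the 1-5 scale and condition ordering", {
  prof <- default_condition_profiles()
  totals <- function(p, seeds) vapply(seeds, function(s)
    sum(synth_comfort(p, seed = s)), numeric(1))
  rest <- totals(prof$resting, 1:25)
  dis <- totals(prof$distress, 1:25)
  expect_true(all(rest >= 6 & rest <= 30))
  expect_true(all(dis >= 6 & dis <= 30))
  ## Monte-Carlo ordering check: distress means 4.5 vs resting 1.5
  expect_gt(mean(dis), mean(rest))
})
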