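## Source-filter synthesis of newborn cry audio with known ground truth.
##
## A unit is built pitch-synchronously: each glottal cycle is an
## independently scaled copy of the formant-cascade impulse response,
## truncated at the next glottal instant. Consecutive cycles are therefore
## exact copies up to the cycle amplitude and additive noise, which makes the
## programmed jitter, shimmer and harmonics-to-noise ratio analytically
## recoverable (they are the oracles of the round-trip tests).

## impulse response of the glottal source (one-pole -6 dB/oct tilt giving
## the fundamental a realistic share of the energy without smearing pulse
## timing) followed by the cascade of three 2nd-order all-pole resonators
formant_cascade_ir <- function(formants, bw, fs, dur_s = 0.05, tilt_a = 0.97) {
  n <- round(dur_s * fs)
  g <- c(1, numeric(n - 1))
  g <- as.numeric(signal::filter(signal::Arma(b = 1 - tilt_a,
                                              a = c(1, -tilt_a)), g))
  for (k in seq_along(formants)) {
    r <- exp(-pi * bw[k] / fs)
    w <- 2 * pi * formants[k] / fs
    a <- c(1, -2 * r * cos(w), r^2)
    g <- as.numeric(signal::filter(signal::Arma(b = 1 - 2 * r * cos(w) + r^2, a = a), g))
  }
  g
}

## evaluate the F0 contour (Hz) at time t in [0, dur]
f0_contour_value <- function(t, dur, f0_mean, f0_sd, shape) {
  u <- t / dur
  f <- switch(shape,
    "flat"      = rep(f0_mean, length(t)),
    ## arch with the programmed mean and SD: sd(sin(pi u)) = 0.308 on [0,1]
    "rise-fall" = f0_mean + (f0_sd / 0.3078) * (sin(pi * u) - 2 / pi),
    ## linear fall with the programmed mean and SD: sd = A / sqrt(12)
    "falling"   = f0_mean + f0_sd * sqrt(12) * (0.5 - u)
  )
  pmin(pmax(f, 210), 1190)
}

#' Synthesize one cry unit with known acoustic ground truth
#'
#' Source-filter synthesis of a single expiratory cry vocalization: a glottal
#' pulse train whose period is perturbed multiplicatively per cycle (local
#' jitter), whose per-cycle amplitude is perturbed (local shimmer), shaped by
#' three second-order resonators at the formant frequencies, and mixed with
#' Gaussian noise scaled analytically to the requested harmonics-to-noise
#' ratio. The returned waveform is normalized to peak `|x| <= 0.99`.
#'
#' @param params a [cry_params()] object.
#' @param dur unit duration in seconds (must exceed two pitch periods).
#' @param seed integer seed; fixed seed gives a bit-identical waveform.
#' @param fs sampling rate, Hz (>= 16 kHz).
#' @return numeric waveform with attributes `fs` and `truth`; `truth` records
#'   the realized pulse times, periods and amplitudes, the realized local
#'   jitter/shimmer of the period/amplitude sequences, and the analytic
#'   harmonic and noise powers behind the HNR target.
#' @examples
#' w <- synth_cry_unit(cry_params(f0_mean = 500, jitter_frac = 0, shimmer_frac = 0,
#'                                hnr_db = 40, f0_sd = 0, f0_contour_shape = "flat"),
#'                     dur = 0.5, seed = 1)
#' attr(w, "truth")$jitter_realized
#' @export
synth_cry_unit <- function(params, dur, seed = 1L, fs = cs_default("audio_fs")) {
  cs_assert(inherits(params, "cry_params"), "params must be a cry_params object")
  cs_assert(fs >= 16000, "sample rate must be at least 16 kHz")
  cs_assert(dur > 2 / params$f0_mean, "dur must exceed two pitch periods")
  cs_assert(all(params$formants < fs / 2), "formants must lie below Nyquist")
  lim <- cs_default("hnr_limits_db")
  cs_assert(params$hnr_db >= lim[1] && params$hnr_db <= lim[2],
            "hnr_db outside the supported range")

  with_seed(seed, {
    ## ---- glottal instants -------------------------------------------------
    ## multiplicative period perturbation scaled so the expected local jitter
    ## (mean |T[i+1]-T[i]| / mean T) equals jitter_frac:
    ## for T_i = T0 (1 + s e_i), e_i ~ N(0,1), E|e' - e| = 2/sqrt(pi),
    ## hence s = jitter_frac * sqrt(pi) / 2.
    sj <- params$jitter_frac * sqrt(pi) / 2
    ss <- params$shimmer_frac * sqrt(pi) / 2
    t_k <- numeric(0); t_cur <- 0
    while (t_cur < dur) {
      f <- f0_contour_value(t_cur, dur, params$f0_mean, params$f0_sd,
                            params$f0_contour_shape)
      t_k <- c(t_k, t_cur)
      t_cur <- t_cur + (1 / f) * max(0.2, 1 + sj * stats::rnorm(1))
    }
    n_k <- round(t_k * fs) + 1L          # integer-sample pulse placement
    n_k <- n_k[!duplicated(n_k)]
    cs_assert(length(n_k) >= 3, "unit too short for synthesis")
    amps <- pmax(0.05, 1 + ss * stats::rnorm(length(n_k)))

    ## ---- per-cycle grains -------------------------------------------------
    n_total <- round(dur * fs)
    g <- formant_cascade_ir(params$formants, params$formant_bw, fs)
    x <- numeric(n_total + length(g))
    bounds <- c(n_k, n_total + 1L)
    for (k in seq_along(n_k)) {
      len <- min(bounds[k + 1] - bounds[k], length(g))
      if (len > 0) x[n_k[k]:(n_k[k] + len - 1L)] <- amps[k] * g[seq_len(len)]
    }
    x <- x[seq_len(n_total)]

    ## ---- additive noise at the analytic HNR -------------------------------
    ## aspiration noise passes through the same vocal tract, but as a
    ## distributed turbulence source it sees broader effective resonances
    ## (3x the voiced bandwidths); shaped white noise is scaled to the
    ## analytic power ratio
    p_harm <- mean(x^2)
    p_noise <- p_harm / 10^(params$hnr_db / 10)
    noise <- as.numeric(stats::rnorm(n_total))
    for (k in seq_along(params$formants)) {
      r <- exp(-pi * 3 * params$formant_bw[k] / fs)
      w <- 2 * pi * params$formants[k] / fs
      noise <- as.numeric(signal::filter(
        signal::Arma(b = 1 - 2 * r * cos(w) + r^2, a = c(1, -2 * r * cos(w), r^2)),
        noise))
    }
    x <- x + noise * sqrt(p_noise) / sqrt(mean(noise^2))

    ## ---- level ------------------------------------------------------------
    target_rms <- 10^(params$level_db / 20)
    x <- x * target_rms / sqrt(mean(x^2))
    if (max(abs(x)) > 0.99) x <- x * 0.99 / max(abs(x))

    periods <- diff(n_k) / fs
    structure(x,
      fs = fs,
      truth = list(
        pulse_samples = n_k, periods = periods, amplitudes = amps,
        jitter_realized = if (length(periods) >= 2)
          mean(abs(diff(periods))) / mean(periods) else NA_real_,
        shimmer_realized = mean(abs(diff(amps))) / mean(amps),
        p_harm = p_harm, p_noise = p_noise,
        hnr_analytic_db = 10 * log10(p_harm / p_noise)
      )
    )
  })
}

## low-amplitude pink noise used for resting audio and inter-unit gaps
pink_noise <- function(n, level_db = -55) {
  w <- stats::rnorm(n)
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(1, -2.494956002, 2.017265875, -0.522189400)
  p <- as.numeric(signal::filter(signal::Arma(b = b, a = a), w))
  p * 10^(level_db / 20) / stats::sd(p)
}

## draw per-unit generator parameters around a condition profile
draw_unit_params <- function(profile) {
  base <- profile$cry_params
  sdv <- profile$cry_param_sd
  g <- function(name, mu, lo, hi) {
    s <- if (!is.null(sdv[[name]])) sdv[[name]] else 0
    min(max(stats::rnorm(1, mu, s), lo), hi)
  }
  f1 <- g("f1", base$formants[1], 900, 2600)
  f2 <- g("f2", base$formants[2], max(2800, f1 + 600), 4600)
  f3 <- g("f3", base$formants[3], max(5000, f2 + 600), 7500)
  shape <- if (!is.null(profile$contour_probs)) {
    sample(names(profile$contour_probs), 1, prob = profile$contour_probs)
  } else base$f0_contour_shape
  cry_params(
    f0_mean = g("f0_mean", base$f0_mean, 250, 900),
    f0_sd = base$f0_sd, f0_contour_shape = shape,
    jitter_frac = g("jitter_frac", base$jitter_frac, 0.001, 0.12),
    shimmer_frac = g("shimmer_frac", base$shimmer_frac, 0.01, 0.2),
    hnr_db = g("hnr_db", base$hnr_db, -5, 35),
    formants = c(f1, f2, f3), formant_bw = base$formant_bw,
    unit_dur_range = base$unit_dur_range, gap_dur_range = base$gap_dur_range,
    n_units = base$n_units,
    level_db = g("level_db", base$level_db, -40, -6)
  )
}

#' Synthesize one cry episode (alternating cry units and unvoiced gaps)
#'
#' Draws per-unit generator parameters around the profile's means and
#' between-unit spreads, alternates cry units with low-level unvoiced gaps,
#' and records the ground-truth segmentation and time bookkeeping
#' (`cryCE` = total vocalized seconds, `unvoicedCE` = total gap seconds).
#'
#' @param profile a non-resting [condition_profile()].
#' @param seed integer seed.
#' @param fs sampling rate, Hz.
#' @param n_units optional override of the profile's units-per-episode count.
#' @param unit_durs,gap_durs optional explicit duration vectors (seconds); by
#'   default drawn uniformly from the profile's ranges.
#' @return list of class `cry_episode_synth` with elements `wave`, `fs`,
#'   `units` (tibble of true unit boundaries), `truth` (per-unit
#'   [cry_params()] draws plus `cryCE`/`unvoicedCE` seconds).
#' @export
synth_episode <- function(profile, seed = 1L, fs = cs_default("audio_fs"),
                          n_units = NULL, unit_durs = NULL, gap_durs = NULL) {
  cs_assert(inherits(profile, "condition_profile"), "profile required")
  cs_assert(profile$condition != "resting", "resting has no cry episodes")
  base <- profile$cry_params
  with_seed(cs_subseed(seed, "episode-plan"), {
    n <- if (!is.null(n_units)) {
      as.integer(n_units)
    } else if (isTRUE(base$n_units_cv > 0)) {
      ## negative-binomial episode sizes reproduce the broad spread of
      ## per-episode vocalized time seen in spontaneous crying
      mu <- base$n_units
      size <- mu / max(base$n_units_cv^2 * mu - 1, 0.1)
      max(2L, stats::rnbinom(1, mu = mu, size = size))
    } else base$n_units
    if (is.null(unit_durs))
      unit_durs <- stats::runif(n, base$unit_dur_range[1], base$unit_dur_range[2])
    if (is.null(gap_durs) && n > 1)
      gap_durs <- stats::runif(n - 1, base$gap_dur_range[1], base$gap_dur_range[2])
    if (n == 1) gap_durs <- numeric(0)
    unit_params <- replicate(n, draw_unit_params(profile), simplify = FALSE)
  })

  waves <- lapply(seq_len(length(unit_durs)), function(k)
    synth_cry_unit(unit_params[[k]], unit_durs[k],
                   seed = cs_subseed(seed, paste0("unit", k)), fs = fs))
  gaps <- lapply(seq_along(gap_durs), function(k)
    with_seed(cs_subseed(seed, paste0("gap", k)),
              pink_noise(round(gap_durs[k] * fs))))

  pieces <- vector("list", length(waves) + length(gaps))
  pieces[seq(1, length(pieces), by = 2)] <- lapply(waves, as.numeric)
  if (length(gaps)) pieces[seq(2, length(pieces), by = 2)] <- gaps
  wave <- unlist(pieces, use.names = FALSE)

  ## true boundaries from realized sample counts
  lens <- vapply(pieces, length, integer(1)) / fs
  starts <- cumsum(c(0, lens[-length(lens)]))
  idx_unit <- seq(1, length(pieces), by = 2)
  units <- tibble::tibble(
    start = starts[idx_unit],
    end = starts[idx_unit] + lens[idx_unit],
    condition = profile$condition
  )
  structure(list(
    wave = wave, fs = fs, units = units,
    truth = list(
      unit_params = unit_params,
      cryCE = sum(lens[idx_unit]),
      unvoicedCE = sum(lens[-idx_unit]),
      condition = profile$condition
    )
  ), class = "cry_episode_synth")
}

#' Synthesize resting-condition audio (near-silence with faint pink noise)
#'
#' @param dur duration, s.
#' @param seed integer seed.
#' @param fs sampling rate, Hz.
#' @param level_db noise level, dB re full scale.
#' @return numeric waveform with attribute `fs`.
#' @export
synth_resting_audio <- function(dur, seed = 1L, fs = cs_default("audio_fs"),
                                level_db = -55) {
  with_seed(seed, structure(pink_noise(round(dur * fs), level_db), fs = fs))
}
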