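#' Specification for a synthetic APD series
#'
#' Describes a stationary synthetic per-beat APD series composed of a mean
#' level, an AR(1) component (emulating slowly drifting, long-term-dominated
#' variability such as that produced by Langevin gating) and white noise
#' (emulating the uncorrelated beat-to-beat fluctuations characteristic of
#' Markov channel gating).
#'
#' @param n_beats number of beats.
#' @param mean mean APD (ms).
#' @param white_sd standard deviation of the white component (ms).
#' @param ar1_rho AR(1) autocorrelation, in `[0, 1)`.
#' @param ar1_sd innovation standard deviation of the AR(1) component (ms).
#' @param seed integer seed.
#' @return a `synthetic_apd_spec` list.
#' @export
synthetic_apd_spec <- function(n_beats = 100L, mean = 250, white_sd = 2,
                               ar1_rho = 0, ar1_sd = 0, seed = 1L) {
  stopifnot(n_beats >= 1, mean > 0, white_sd >= 0, ar1_sd >= 0,
            ar1_rho >= 0, ar1_rho < 1)
  structure(list(n_beats = as.integer(n_beats), mean = mean,
                 white_sd = white_sd, ar1_rho = ar1_rho, ar1_sd = ar1_sd,
                 seed = as.integer(seed)),
            class = "synthetic_apd_spec")
}

#' Generate a synthetic APD series
#'
#' `APD[i] = mean + z[i] + e[i]` with `z` a stationary AR(1) process
#' (initialized from its stationary distribution) and `e` i.i.d. Gaussian.
#'
#' @param spec a [synthetic_apd_spec()].
#' @return an [apd_series()].
#' @export
generate_apd_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_apd_spec"))
  n <- spec$n_beats
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  z <- numeric(n)
  if (spec$ar1_sd > 0) {
    z[1] <- rnorm(1, 0, spec$ar1_sd / sqrt(1 - spec$ar1_rho^2))
    if (n > 1) {
      innov <- rnorm(n - 1, 0, spec$ar1_sd)
      for (i in 2:n) z[i] <- spec$ar1_rho * z[i - 1] + innov[i - 1]
    }
  }
  e <- if (spec$white_sd > 0) rnorm(n, 0, spec$white_sd) else numeric(n)
  apd_series(spec$mean + z + e)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a stylized action-potential trace
#'
#' Builds a piecewise-linear membrane-potential trace with prescribed APD90
#' values, for exercising the APD detector without running the simulator.
#' Each beat rests at `baseline`, rises to `peak` over `rise_time` starting
#' `upstroke_delay` after the stimulus, optionally holds a plateau, then
#' repolarizes linearly back to `baseline`. The repolarization duration is
#' chosen so that the 90%-repolarization level (`baseline + 0.1 * amplitude`)
#' is crossed exactly `apd_targets[k]` after the upstroke.
#'
#' @param apd_targets per-beat APD90 targets (ms), all positive.
#' @param cl stimulus interval (ms).
#' @param dt sample spacing (ms).
#' @param baseline,peak resting and peak potentials (mV). Equal values yield
#'   a zero-amplitude trace that the detector flags invalid.
#' @param plateau_fraction fraction of the repolarization interval spent at
#'   the peak before the linear decline (0 = triangular).
#' @param upstroke_delay latency from stimulus to upstroke (ms).
#' @param rise_time upstroke duration (ms).
#' @return list with `time`, `vm` and `stimulus_times`.
#' @export
generate_stylized_trace <- function(apd_targets, cl = 1000, dt = 0.1,
                                    baseline = -85, peak = 35,
                                    plateau_fraction = 0,
                                    upstroke_delay = 1, rise_time = 0.02) {
  stopifnot(all(apd_targets > 0), cl > 0, dt > 0,
            plateau_fraction >= 0, plateau_fraction < 1)
  nb <- length(apd_targets)
  total <- nb * cl
  time <- seq(0, total, by = dt)
  vm <- rep(baseline, length(time))
  stim <- (seq_len(nb) - 1) * cl
  p <- plateau_fraction
  for (k in seq_len(nb)) {
    apd <- apd_targets[k]
    t_up <- stim[k] + upstroke_delay
    t_pk <- t_up + rise_time
    T_rep <- apd / (0.9 + 0.1 * p)       # decline so 90% level is hit at apd
    t_pl_end <- t_pk + p * T_rep
    t_end <- t_pk + T_rep
    if (t_end > stim[k] + cl) {
      warning("APD target ", apd, " does not fit within the cycle length")
    }
    seg <- function(t0, t1) which(time >= t0 & time < t1)
    i_rise <- seg(t_up, t_pk)
    if (length(i_rise)) {
      vm[i_rise] <- baseline + (peak - baseline) * (time[i_rise] - t_up) / rise_time
    }
    i_pl <- seg(t_pk, t_pl_end)
    vm[i_pl] <- peak
    i_rep <- seg(t_pl_end, t_end)
    if (length(i_rep)) {
      vm[i_rep] <- peak + (baseline - peak) * (time[i_rep] - t_pl_end) / (t_end - t_pl_end)
    }
  }
  list(time = time, vm = vm, stimulus_times = stim)
}
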