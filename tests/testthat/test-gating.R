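test_that("channel-count estimation follows the conductance ratio", {
  expect_identical(estimate_channel_count(5, 5), 1000L)
  # density scaling with reciprocal single-channel conductance keeps the
  # total conductance, with a five-fold larger count
  n1 <- estimate_channel_count(5, 5)
  n5 <- estimate_channel_count(5, 1)
  expect_identical(n5, 5L * n1)
  expect_warning(n <- estimate_channel_count(0.001, 10), "floor")
  expect_identical(n, 1L)
  expect_error(estimate_channel_count(-1, 5), "positive")
  expect_error(estimate_channel_count(5, 0), "positive")
})

test_that("scheme validation rejects malformed definitions", {
  r <- rate_function("constant", k = 1)
  expect_error(markov_scheme("a", list(list(from = "a", to = "b", rate = r)),
                             "a"), "unknown state")
  expect_error(markov_scheme(c("a", "b"),
                             list(list(from = "a", to = "a", rate = r)),
                             "a"), "self-transitions")
  expect_error(markov_scheme(c("a", "b", "c"),
                             list(list(from = "a", to = "b", rate = r)),
                             "a"), "not connected")
  expect_error(markov_scheme(c("a", "b"),
                             list(list(from = "a", to = "b", rate = r)),
                             c(a = 1.5)), "weights")
  expect_error(rate_function("sigmoid", a = 1), "needs parameters")
})

test_that("rate templates evaluate finitely over the physiological range", {
  vms <- seq(-120, 80, by = 5)
  rates <- list(
    rate_function("constant", k = 0.5),
    rate_function("exponential", a = 0.02, b = 0.03),
    rate_function("sigmoid", a = 2, v_half = -20, s = 6),
    rate_function("linoid", a = 0.32, v0 = -47, s = 10),
    rate_function("ca_hill", a = 3, km = 6e-4, h = 2),
    rate_function("sr_hill", a = 1, k = 2, h = 4))
  for (r in rates) {
    v <- eval_rate(r, vms, ca = 1e-4, ca_sr = 1)
    expect_true(all(is.finite(v) & v >= 0))
  }
  # linoid removable singularity
  lin <- rate_function("linoid", a = 0.32, v0 = -47.13, s = 10)
  expect_equal(eval_rate(lin, -47.13), 0.32 * 10, tolerance = 1e-6)
})

test_that("deterministic two-state relaxation matches the closed form", {
  sch <- two_state(alpha = 1, beta = 1)
  fr <- c(closed = 1, open = 0)
  dt <- 0.005
  for (k in 1:200) fr <- step_markov_deterministic(fr, sch, vm = 0, dt = dt)
  t <- 200 * dt
  expect_equal(unname(fr["open"]), 0.5 * (1 - exp(-2 * t)), tolerance = 1e-4)
  # stationary input is a fixed point to O(dt^2)
  st <- c(closed = 0.5, open = 0.5)
  st2 <- step_markov_deterministic(st, sch, vm = 0, dt = 0.01)
  expect_equal(unname(st2), unname(st), tolerance = 1e-6)
  # all rates zero: unchanged
  sch0 <- two_state(alpha = 0, beta = 0)
  expect_equal(step_markov_deterministic(c(closed = 0.3, open = 0.7), sch0,
                                         vm = 0, dt = 1),
               c(closed = 0.3, open = 0.7))
})

test_that("stochastic stepping conserves channel count and honors dt = 0", {
  set.seed(1)
  rng <- gating_rng(5)
  pop <- channel_population(two_state(1, 1), g_single = 5, N = 500)
  p0 <- step_markov_stochastic(pop, vm = 0, dt = 0, rng = rng)
  expect_identical(p0$occupancy, pop$occupancy)
  # property fuzz: random voltage-dependent schemes, occupancy always sums N
  for (rep in 1:15) {
    a <- runif(1, 0.1, 5); b <- runif(1, 0.1, 5)
    sch <- markov_scheme(
      c("c1", "c2", "o"),
      list(list(from = "c1", to = "c2",
                rate = rate_function("exponential", a = a, b = 0.02)),
           list(from = "c2", to = "c1",
                rate = rate_function("exponential", a = b, b = -0.03)),
           list(from = "c2", to = "o", rate = rate_function("constant", k = a)),
           list(from = "o", to = "c2", rate = rate_function("constant", k = b))),
      conducting = "o")
    pp <- channel_population(sch, g_single = 5, N = 1234)
    for (k in 1:40) {
      pp <- step_markov_stochastic(pp, vm = runif(1, -90, 40),
                                   dt = runif(1, 0.01, 0.3), rng = rng)
      expect_true(all(pp$occupancy >= 0))
      expect_equal(sum(pp$occupancy), 1234)
    }
  }
})

test_that("stationary open fraction of a symmetric two-state channel is one half", {
  # alpha = beta at fixed Vm: analytic stationary open fraction alpha/(alpha+beta)
  sch <- two_state(1, 1)
  N <- 1e6
  pop <- channel_population(sch, g_single = 5, N = N)
  rng <- gating_rng(17)
  nsteps <- 1500
  burn <- 300
  fracs <- numeric(nsteps - burn)
  for (k in 1:nsteps) {
    pop <- step_markov_stochastic(pop, vm = 0, dt = 0.05, rng = rng)
    if (k > burn) fracs[k - burn] <- pop$occupancy[["open"]] / N
  }
  # effective sample count accounts for the tau = 0.5 ms autocorrelation
  n_eff <- (nsteps - burn) * 0.05 / (2 * 0.5)
  se <- sqrt(0.25 / N) / sqrt(n_eff)
  expect_lt(abs(mean(fracs) - 0.5), 3 * se + 1e-6)
})

test_that("single-step transition counts follow the binomial law", {
  # N = 2 channels, one step: openings ~ Binomial(2, 1 - exp(-alpha dt))
  alpha <- 2; dt <- 0.05
  sch <- two_state(alpha, 0)
  rng <- gating_rng(23)
  reps <- 1e5
  Q <- rate_matrix(sch, vm = 0)
  counts <- integer(reps)
  for (i in seq_len(reps)) {
    occ <- bvrsim:::cpp_markov_step_stoch(c(2, 0), Q, dt, rng$ptr)
    counts[i] <- occ[2]
  }
  p <- 1 - exp(-alpha * dt)
  expected <- dbinom(0:2, 2, p) * reps
  observed <- tabulate(counts + 1L, nbins = 3)
  # 4-sigma bands per cell
  for (k in 1:3) {
    se <- sqrt(expected[k] * (1 - expected[k] / reps))
    expect_lt(abs(observed[k] - expected[k]), 4 * se)
  }
})

test_that("ensemble mean of stochastic gating converges to the deterministic solution", {
  sch <- two_state(1.2, 0.6)
  N <- 1e4; reps <- 40
  rng <- gating_rng(31)
  nstep <- 40; dt <- 0.05
  acc <- matrix(0, reps, nstep)
  for (r in 1:reps) {
    pop <- channel_population(sch, g_single = 5, N = N, vm_init = 0)
    # start from all closed for a non-trivial transient
    pop$occupancy[] <- c(N, 0)
    for (k in 1:nstep) {
      pop <- step_markov_stochastic(pop, vm = 0, dt = dt, rng = rng)
      acc[r, k] <- pop$occupancy[["open"]] / N
    }
  }
  fr <- c(1, 0)
  for (k in 1:nstep) {
    fr <- step_markov_deterministic(fr, sch, vm = 0, dt = dt)
    p <- fr[2]
    tol <- 3 * sqrt(max(p * (1 - p), 1e-6) / (N * reps)) + 2e-3
    expect_lt(abs(mean(acc[, k]) - p), tol)
  }
})

test_that("stationary open-count variance scales as N p (1-p)", {
  sch <- two_state(1, 1)          # p = 0.5
  N <- 1e4
  pop <- channel_population(sch, g_single = 5, N = N)
  rng <- gating_rng(41)
  nsteps <- 4000; burn <- 500
  xs <- numeric(nsteps - burn)
  for (k in 1:nsteps) {
    pop <- step_markov_stochastic(pop, vm = 0, dt = 0.25, rng = rng)
    if (k > burn) xs[k - burn] <- pop$occupancy[["open"]]
  }
  expect_equal(var(xs), N * 0.25, tolerance = 0.1)
})

test_that("Langevin gating behaves correctly in its limits", {
  rng <- gating_rng(51)
  # N_eff -> infinity reduces to the deterministic update
  x <- step_hh_sde(0.3, alpha = 1, beta = 1, n_eff = 1e18, dt = 0.01,
                   rng = rng)
  expect_equal(x, 0.3 + (1 * 0.7 - 1 * 0.3) * 0.01, tolerance = 1e-7)
  # absorbing boundary: x = 1 with beta = 0 stays exactly 1
  expect_identical(step_hh_sde(1, alpha = 2, beta = 0, n_eff = 100,
                               dt = 0.01, rng = rng), 1)
  # stationary mean ~ 1/2 for alpha = beta
  x <- 0.5; xs <- numeric(4000)
  for (k in 1:4000) {
    x <- step_hh_sde(x, 1, 1, n_eff = 1000, dt = 0.05, rng = rng)
    xs[k] <- x
  }
  n_eff_samples <- 4000 * 0.05 / (2 * 0.5)
  se <- sqrt(0.25 / 1000) / sqrt(n_eff_samples)
  expect_lt(abs(mean(xs[-(1:200)]) - 0.5), 4 * se)
})

test_that("population current converts occupancy to pA/pF correctly", {
  sch <- two_state(1, 1)
  pop <- channel_population(sch, g_single = 5, N = 2000)
  pop$occupancy[] <- c(1000, 1000)
  # N_open 1000, g 5 pS, driving 100 mV, Cm 100 pF -> 5 pA/pF
  expect_equal(population_current(pop, vm = 100, e_rev = 0, cm = 100), 5)
  expect_equal(population_current(pop, vm = -30, e_rev = -30, cm = 100), 0)
  pop$occupancy[] <- c(2000, 0)
  expect_equal(population_current(pop, vm = 50, e_rev = 0, cm = 100), 0)
})

test_that("seeded gating streams are reproducible and schemes load from config", {
  sch <- two_state(2, 1)
  run_traj <- function(seed) {
    rng <- gating_rng(seed)
    pop <- channel_population(sch, g_single = 5, N = 300)
    out <- numeric(30)
    for (k in 1:30) {
      pop <- step_markov_stochastic(pop, vm = 0, dt = 0.1, rng = rng)
      out[k] <- pop$occupancy[["open"]]
    }
    out
  }
  expect_identical(run_traj(7), run_traj(7))
  expect_false(identical(run_traj(7), run_traj(8)))

  cfg <- read_scheme_config(system.file("extdata", "two_state_scheme.json",
                                        package = "bvrsim"))
  expect_s3_class(cfg$scheme, "markov_scheme")
  expect_equal(cfg$g_single, 5)
  pop <- channel_population(cfg$scheme, g_single = cfg$g_single,
                            g_max = cfg$g_max)
  expect_identical(pop$N, 800L)
})

test_that("negative rates are refused by the stepping kernels", {
  rng <- gating_rng(3)
  Q <- matrix(c(0, -1, 1, 0), 2, 2, byrow = TRUE)
  expect_error(bvrsim:::cpp_markov_step_stoch(c(10, 0), Q, 0.1, rng$ptr),
               "negative")
  expect_error(bvrsim:::cpp_markov_step_det(c(0.5, 0.5), Q, 0.1), "negative")
})
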