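test_that("STV/LTV/CV match brute-force formula evaluation on random series", {
  set.seed(42)
  for (i in 1:50) {
    x <- rnorm(sample(10:80, 1), mean = 250, sd = sample(c(1, 5, 20), 1))
    expect_equal(stv(x), oracle_stv(x), tolerance = 1e-12)
    expect_equal(ltv(x), oracle_ltv(x), tolerance = 1e-12)
    expect_equal(cv(x), 100 * sd(x) / mean(x), tolerance = 1e-12)
  }
})

test_that("canonical series reproduce hand-computed variability values", {
  expect_equal(stv(rep(250, 31)), 0)
  expect_equal(ltv(rep(250, 31)), 0)
  alt31 <- rep(c(240, 260), length.out = 31)
  expect_equal(stv(alt31), 20 / sqrt(2), tolerance = 1e-12)
  alt30 <- rep(c(240, 260), 15)   # even length: pair sums all equal 2*mean
  expect_equal(ltv(alt30), 0, tolerance = 1e-12)
  ramp <- seq(200, 240, by = 1)
  expect_equal(stv(ramp), 1 / sqrt(2), tolerance = 1e-12)
  # step change: LTV large in the interior, STV small
  step <- c(rep(240, 15), rep(260, 16))
  expect_equal(stv(step), oracle_stv(step), tolerance = 1e-12)
  expect_equal(ltv(step), oracle_ltv(step), tolerance = 1e-12)
  expect_gt(ltv(step), stv(step))
  # CV of a [90, 110] alternation and scale invariance
  x <- rep(c(90, 110), 10)
  expect_equal(cv(x), 100 * sd(x) / 100, tolerance = 1e-12)
  expect_equal(cv(x * 2), cv(x), tolerance = 1e-12)
})

test_that("STV/LTV invariances hold", {
  set.seed(7)
  x <- rnorm(40, 250, 5)
  expect_equal(stv(x + 37), stv(x), tolerance = 1e-12)
  expect_equal(ltv(x + 37), ltv(x), tolerance = 1e-10)
  expect_equal(stv(rev(x)), stv(x), tolerance = 1e-12)
  expect_equal(stv(3 * x), 3 * stv(x), tolerance = 1e-12)
  expect_equal(ltv(3 * x), 3 * ltv(x), tolerance = 1e-12)
})

test_that("insufficient or invalid beats are rejected", {
  expect_error(stv(apd_series(250)), "consecutive valid beats")
  expect_error(analysis_window(apd_series(c(NA, NA))), "no valid beats")
  # invalid beats break runs: longest consecutive valid run is used
  x <- apd_series(c(200, 201, NA, 240, 241, 242, 243),
                  valid = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(stv(x), oracle_stv(c(240, 241, 242, 243)), tolerance = 1e-12)
})

test_that("Poincare geometry reproduces STV and LTV", {
  set.seed(11)
  for (i in 1:50) {
    x <- rnorm(sample(5:60, 1), 250, 8)
    p <- poincare(x)
    expect_equal(p$perpendicular, stv(x), tolerance = 1e-10)
    expect_equal(p$along, ltv(x), tolerance = 1e-10)
  }
  # constant series: single point on the identity line
  p <- poincare(rep(250, 10))
  expect_true(all(p$pairs$apd_i == p$pairs$apd_next))
  expect_equal(p$perpendicular, 0)
  # alternating series: perpendicular spread only
  p <- poincare(rep(c(240, 260), 10))
  expect_gt(p$perpendicular, 10)
  expect_lt(p$along, 1e-10)
})

test_that("APD90 detection recovers the stylized triangular AP geometry", {
  tr <- generate_stylized_trace(270, cl = 1000, dt = 0.1)
  det <- detect_apd90(tr$time, tr$vm, tr$stimulus_times)
  expect_true(det$valid[1])
  expect_equal(det$apd[1], 270, tolerance = 0.1)
  # 2x sub-sampling changes the estimate by < 0.25 ms (linear interpolation)
  sub <- seq(1, length(tr$time), by = 5)   # 0.5 ms sampling
  det2 <- detect_apd90(tr$time[sub], tr$vm[sub], tr$stimulus_times)
  expect_lt(abs(det2$apd[1] - det$apd[1]), 0.25)
})

test_that("flat or zero-amplitude traces yield no valid beats", {
  t <- seq(0, 2000, by = 0.5)
  det <- detect_apd90(t, rep(-85, length(t)), c(0, 1000))
  expect_equal(sum(det$valid), 0)
  tr <- generate_stylized_trace(c(250, 250), baseline = -85, peak = -85)
  det2 <- detect_apd90(tr$time, tr$vm, tr$stimulus_times)
  expect_equal(sum(det2$valid), 0)
})

test_that("beats without repolarization are flagged as failures", {
  # AP that never returns below the 90% level before the next stimulus
  t <- seq(0, 1999.5, by = 0.5)
  vm <- rep(-85, length(t))
  up <- t >= 100 & t < 1000
  vm[up] <- 30                      # stuck depolarized for the whole cycle
  vm[t >= 100 & t < 102] <- seq(-85, 30, length.out = sum(t >= 100 & t < 102))
  det <- detect_apd90(t, vm, c(99, 1000))
  expect_false(det$valid[1])
})

test_that("Im fluctuation profile recovers pointwise noise and is zero for identical traces", {
  base <- sin(seq(0, pi, length.out = 200))
  ident <- matrix(rep(base, each = 40), nrow = 40, byrow = FALSE)
  prof <- im_std_profile(ident)
  expect_true(all(prof$std_im < 1e-12))
  expect_equal(prof$auc_std_im, 0, tolerance = 1e-10)
  set.seed(5)
  noisy <- ident + matrix(rnorm(40 * 200, 0, 0.3), 40, 200)
  prof2 <- im_std_profile(noisy)
  expect_equal(mean(prof2$std_im), 0.3, tolerance = 0.1 * 0.3)
  expect_error(im_std_profile(list(1:5, 1:4)), "mismatched")
})

test_that("monoexponential STV-APD fit recovers known parameters", {
  apd <- seq(150, 320, by = 10)
  y <- 1 + 0.01 * exp(0.02 * apd)
  fit <- fit_stv_apd(apd, y)
  expect_equal(fit$a, 1, tolerance = 0.01)
  expect_equal(fit$b, 0.01, tolerance = 0.01)
  expect_equal(fit$c, 0.02, tolerance = 0.01)
  expect_gt(fit$r_squared, 0.999)
  # degenerate constant data: b ~ 0, a ~ mean
  yc <- rep(4, length(apd)) + rnorm(length(apd), 0, 1e-4)
  fitc <- fit_stv_apd(apd, yc)
  expect_lt(abs(fitc$b * exp(fitc$c * max(apd))), 0.5)
  expect_equal(fitc$a + fitc$b * exp(fitc$c * mean(apd)), 4, tolerance = 0.1)
  expect_error(fit_stv_apd(apd[1:4], y[1:4]), "at least 5")
  expect_error(fit_stv_apd(rep(200, 6), y[1:6]), "span")
})
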