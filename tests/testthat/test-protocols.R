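test_that("protocol validation enforces its preconditions", {
  expect_error(pacing_protocol("fixed_DI", di = 10, n_beats = 40),
               "di > 20")
  expect_error(pacing_protocol("fixed_DI", n_beats = 40), "di > 20")
  expect_error(pacing_protocol("fixed_CL", n_beats = 10, n_discard = 10))
  expect_warning(pacing_protocol("fixed_CL", n_beats = 35, n_discard = 10),
                 "fewer than 30")
  expect_warning(injection_spec(0.3), "outside")
  expect_silent(injection_spec(-0.1))
})

test_that("protocol transforms commute on the configuration", {
  cfg <- default_cell_config("markov")
  cond <- condition_spec(ikr_block = 0.3, beta_ars = TRUE)
  morph <- morphology_spec("triangular")
  a <- apply_morphology(apply_condition(cfg, cond), morph)
  b <- apply_condition(apply_morphology(cfg, morph), cond)
  expect_equal(a, b)
})

test_that("morphology presets scale and freeze the four shaping currents", {
  cfg <- default_cell_config("markov")
  ctrl <- apply_morphology(cfg, morphology_spec("control"))
  for (t in c("ik1", "ikur", "ito", "ical")) {
    expect_identical(ctrl$targets[[t]]$mode, "deterministic")
    expect_equal(ctrl$targets[[t]]$scale, 1)
  }
  # remaining 9 targets keep their stochastic mode
  others <- setdiff(target_names(), c("ik1", "ikur", "ito", "ical"))
  for (t in others) expect_identical(ctrl$targets[[t]]$mode, "markov")
  tri <- apply_morphology(cfg, morphology_spec("triangular"))
  expect_gt(tri$targets$ikur$scale, 1)
  sq <- apply_morphology(cfg, morphology_spec("square"))
  expect_lt(sq$targets$ikur$scale, 1)
})

test_that("zero-amplitude injection is bit-identical to plain pacing", {
  cell <- control_cell()
  p <- short_protocol(n_beats = 4L, n_discard = 0L)
  plain <- suppressWarnings(pace_fixed_cl(cell, p, seed = 3))
  inj <- suppressWarnings(inject_during_ap(cell, injection_spec(0), p, seed = 3))
  expect_identical(plain$final_state, inj$final_state)
  expect_identical(plain$apd$apd, inj$apd$apd)
})

test_that("depolarizing injection strictly prolongs the deterministic APD", {
  cell <- det_cell()
  p <- short_protocol(n_beats = 16L, n_discard = 14L)
  apds <- vapply(c(-0.1, -0.05, 0, 0.05, 0.1), function(a) {
    run <- suppressWarnings(inject_during_ap(cell, injection_spec(a), p))
    mean(run$apd$apd[run$apd$valid])
  }, numeric(1))
  expect_true(all(diff(apds) < 0))   # negative = depolarizing = longer APD
})

test_that("fixed-DI pacing schedules stimuli at APD90 + DI", {
  cell <- det_cell()
  p <- suppressWarnings(pacing_protocol("fixed_DI", di = 500, n_beats = 8L,
                                        n_discard = 4L))
  run <- suppressWarnings(pace_fixed_di(cell, p))
  apd <- run$apd_all$apd
  gaps <- diff(run$stim_times)
  # inter-stimulus interval = this beat's APD + DI (+ upstroke latency)
  lat <- run$apd_all$upstroke_times - run$stim_times
  expected <- apd[-length(apd)] + 500 + lat[-length(lat)]
  expect_equal(gaps, expected, tolerance = 0.02)
  expect_equal(run$effective_cl, mean(run$apd$apd) + 500, tolerance = 1e-6)
})

test_that("reported statistics are invariant to extra discarded beats", {
  cell <- det_cell()
  p1 <- short_protocol(n_beats = 40L, n_discard = 20L)
  p2 <- short_protocol(n_beats = 40L, n_discard = 30L)
  r1 <- suppressWarnings(pace_fixed_cl(cell, p1))
  r2 <- suppressWarnings(pace_fixed_cl(cell, p2))
  expect_equal(mean(r1$apd$apd), mean(r2$apd$apd), tolerance = 2)
  expect_lt(stv(r1$apd), 0.35)
  expect_lt(stv(r2$apd), 0.35)
})

test_that("noise calibration is monotone and matches its target", {
  cell <- det_cell()
  # STV rises monotonically with the Vm-noise amplitude
  p <- short_protocol(n_beats = 45L, n_discard = 10L, cl = 500)
  stvs <- vapply(c(0.5, 1.5, 3), function(a) {
    pa <- suppressWarnings(pacing_protocol("fixed_CL", cl = 500,
                                           n_beats = 45L, n_discard = 10L,
                                           vm_noise_alpha = a))
    stv(suppressWarnings(pace_fixed_cl(cell, pa, seed = 2))$apd)
  }, numeric(1))
  expect_true(all(diff(stvs) > 0))
  # zero reference: alpha = 0
  expect_equal(calibrate_vm_noise(cell, 0)$alpha, 0)
  # calibration brackets and matches a positive reference
  cal <- calibrate_vm_noise(cell, reference_stv = 2, calibration_cl = 500,
                            n_beats = 45L, n_discard = 10L, seeds = 1:2)
  expect_gt(cal$alpha, 0)
  expect_equal(cal$achieved_stv, 2, tolerance = 0.3)
})
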