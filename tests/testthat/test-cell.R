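test_that("the balanced resting state is an equilibrium of the cell", {
  cell <- det_cell()
  cur <- compute_currents(cell)
  expect_lt(abs(cur$im), 1e-6)
  # 2 s unstimulated: Vm and concentrations stay put
  st <- cell$state
  cfg <- cell$config
  for (k in 1:20000) {
    st <- bvrsim:::cpp_step_cell(cfg, st, 0.1, 0, 0, 0, 1L)
  }
  expect_lt(abs(st[["vm"]] - cell$state[["vm"]]), 0.5)
  expect_lt(abs(st[["nai"]] / cell$state[["nai"]] - 1), 0.01)
  expect_lt(abs(st[["cai1"]] / cell$state[["cai1"]] - 1), 0.05)
})

test_that("condition modifiers scale the configured targets", {
  cfg <- default_cell_config("deterministic")
  # identity spec changes nothing
  expect_identical(apply_condition(cfg, condition_spec()), cfg)
  # full IKr block makes IKr vanish at any voltage
  blocked <- suppressWarnings(build_cell(cfg, condition_spec(ikr_block = 1),
                                         find_threshold = FALSE))
  st <- blocked$state
  for (vm in c(-80, -40, 0, 40)) {
    st[["vm"]] <- vm
    st[["ikr_o"]] <- 0.8   # even with channels forced open
    expect_equal(compute_currents(blocked, st)$ikr, 0)
  }
  # doubling G_Kr doubles IKr instantaneously (linearity in G)
  base <- det_cell()
  st <- base$state; st[["vm"]] <- -30; st[["ikr_o"]] <- 0.3
  i1 <- compute_currents(base, st)$ikr
  doubled <- base
  doubled$config <- scale_targets(base$config, c(ikr = 2))
  expect_equal(compute_currents(doubled, st)$ikr, 2 * i1, tolerance = 1e-12)
  # IK1 vanishes at the potassium reversal potential
  ek <- 26.712838 * log(5.4 / st[["ki"]])
  st[["vm"]] <- ek
  expect_equal(compute_currents(base, st)$ik1, 0, tolerance = 1e-9)
})

test_that("condition modifiers act on their designated parameters", {
  cfg <- default_cell_config("markov")
  c1 <- apply_condition(cfg, condition_spec(iks_block = 0.4))
  expect_equal(c1$targets$iks$scale, 0.6)
  c2 <- apply_condition(cfg, condition_spec(persistent_ina_scale = 5))
  expect_equal(c2$targets$ina$persist_scale, 5)
  c3 <- apply_condition(cfg, condition_spec(inak_inhibition = 0.1))
  expect_equal(c3$targets$inak$scale, 0.9)
  c4 <- apply_condition(cfg, condition_spec(beta_ars = TRUE))
  expect_equal(c4$targets$iks$scale, 3.0)
  expect_lt(c4$targets$ical$f_tau_scale, 1)
  expect_error(condition_spec(ikr_block = 1.5))
  expect_error(condition_spec(persistent_ina_scale = 0.5))
})

test_that("IKr block monotonically prolongs the action potential", {
  apds <- vapply(c(0, 0.35, 0.7), function(b) {
    cell <- suppressWarnings(build_cell(default_cell_config("deterministic"),
                                        condition_spec(ikr_block = b)))
    p <- short_protocol(n_beats = 25L, n_discard = 20L)
    run <- suppressWarnings(pace_fixed_cl(cell, p))
    mean(run$apd$apd[run$apd$valid])
  }, numeric(1))
  expect_true(all(diff(apds) > 3))
})

test_that("multi-domain construction divides calcium machinery equally", {
  cfg <- default_cell_config("markov")
  cell4 <- suppressWarnings(build_cell(cfg, domains = domain_config(4),
                                       find_threshold = FALSE))
  st <- cell4$state
  # per-domain RyR occupancies each sum to total/4
  per_dom <- vapply(1:4, function(d) {
    sum(st[sprintf("ryr_%s%d", c("c", "o", "i", "r"), d)])
  }, numeric(1))
  expect_equal(per_dom, rep(cfg$targets$jrel$n_channels / 4, 4))
  expect_equal(sum(per_dom), cfg$targets$jrel$n_channels)
  # identical domains at rest
  expect_equal(st[["cai1"]], st[["cai4"]])
  expect_equal(st[["casr2"]], st[["casr3"]])
})

test_that("calcium diffusion conserves mass and relaxes as the closed form", {
  # two domains (1, 0): both approach 0.5, sum conserved to 1e-12
  ca <- c(1, 0)
  for (k in 1:4000) ca <- ca_diffusion_step(ca, tau = 20, dt = 0.05)
  expect_equal(sum(ca), 1, tolerance = 1e-12)
  expect_equal(ca[1], 0.5, tolerance = 1e-3)
  # difference decays as exp(-2 t / tau)
  ca <- c(1, 0); dt <- 0.01; tau <- 20
  for (k in 1:1000) ca <- ca_diffusion_step(ca, tau, dt)
  expect_equal(ca[1] - ca[2], exp(-2 * 10 / tau), tolerance = 1e-4)
  # uniform vector unchanged; 4-domain mass conservation
  expect_equal(ca_diffusion_step(rep(0.3, 4), 20, 0.1), rep(0.3, 4))
  set.seed(2)
  ca <- runif(4)
  expect_equal(sum(ca_diffusion_step(ca, 20, 0.1)), sum(ca), tolerance = 1e-12)
})

test_that("deterministic trajectories are bit-identical across seeds", {
  cell <- det_cell()
  p <- short_protocol(n_beats = 3L, n_discard = 0L)
  r1 <- suppressWarnings(pace_fixed_cl(cell, p, seed = 1))
  r2 <- suppressWarnings(pace_fixed_cl(cell, p, seed = 999))
  expect_identical(r1$apd$apd, r2$apd$apd)
  expect_identical(r1$final_state, r2$final_state)
})

test_that("stochastic trajectories are reproducible by seed", {
  cell <- control_cell()
  p <- short_protocol(n_beats = 4L, n_discard = 0L)
  r1 <- suppressWarnings(pace_fixed_cl(cell, p, seed = 5))
  r2 <- suppressWarnings(pace_fixed_cl(cell, p, seed = 5))
  r3 <- suppressWarnings(pace_fixed_cl(cell, p, seed = 6))
  expect_identical(r1$final_state, r2$final_state)
  expect_false(identical(r1$final_state, r3$final_state))
})

test_that("zeroing every conductance zeroes the membrane current", {
  cfg <- default_cell_config("deterministic")
  for (t in target_names()) cfg$targets[[t]]$scale <- 0
  cell <- suppressWarnings(build_cell(cfg, find_threshold = FALSE))
  cur <- compute_currents(cell)
  expect_equal(cur$im, 0, tolerance = 1e-9)
})

test_that("a numerical blow-up raises a diagnostic error", {
  cell <- det_cell()
  expect_error(
    bvrsim:::cpp_step_cell(cell$config, cell$state, 1.0, -500, 0, 0, 1L),
    "blow-up")
})
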