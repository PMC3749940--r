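test_that("uncoupled cells evolve exactly as in separate runs", {
  cell <- control_cell()
  p <- short_protocol(n_beats = 4L, n_discard = 0L)
  pair <- run_coupled(cell, n_cells = 2, g_gap = 0, protocol = p, seed = 9)
  solo_a <- suppressWarnings(pace_fixed_cl(cell, p, seed = 9))
  expect_identical(pair$apd[[1]]$apd, solo_a$apd$apd)
  # cell 2 reproduced by a single-cell run on its stream offset
  solo_b <- run_coupled(cell, n_cells = 1, g_gap = 0, protocol = p, seed = 9,
                        stream_offsets = 1L)
  expect_identical(pair$apd[[2]]$apd, solo_b$apd[[1]]$apd)
})

test_that("identical deterministic cells stay identical under coupling", {
  cell <- det_cell()
  p <- short_protocol(n_beats = 3L, n_discard = 0L)
  pair <- run_coupled(cell, n_cells = 2, g_gap = 2, protocol = p, seed = 1)
  # symmetry: zero coupling current, same trajectory as uncoupled
  solo <- suppressWarnings(pace_fixed_cl(cell, p, seed = 1))
  expect_equal(pair$apd[[1]]$apd, solo$apd$apd, tolerance = 1e-10)
  expect_equal(pair$apd[[1]]$apd, pair$apd[[2]]$apd, tolerance = 1e-10)
})

test_that("strong coupling space-clamps an asymmetric pair", {
  cell <- det_cell()
  p <- short_protocol(n_beats = 8L, n_discard = 5L)
  res <- run_pair_sweep(cell, cell, g_gap_grid = 50, protocol = p,
                        inject_amp = c(0, -0.1), seeds = 1)
  expect_lt(abs(res$apd_a - res$apd_b), 0.5)
})

test_that("coupling reduces but does not eliminate variability", {
  cell <- control_cell()
  p <- short_protocol(n_beats = 45L, n_discard = 10L)
  un <- vapply(1:3, function(s)
    stv(suppressWarnings(pace_fixed_cl(cell, p, seed = s))$apd), numeric(1))
  cp <- run_pair_sweep(cell, cell, g_gap_grid = 1, protocol = p, seeds = 1:3)
  expect_lt(mean(cp$mean_stv), mean(un))
  expect_true(all(cp$mean_stv > 0))
})

test_that("a one-cell strand reduces to the single-cell simulation", {
  cell <- control_cell()
  p <- short_protocol(n_beats = 4L, n_discard = 0L)
  st <- run_coupled(cell, n_cells = 1, g_gap = 1, protocol = p, seed = 4)
  solo <- suppressWarnings(pace_fixed_cl(cell, p, seed = 4))
  expect_identical(st$apd[[1]]$apd, solo$apd$apd)
})
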