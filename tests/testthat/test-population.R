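test_that("conductance-scale sampling has the prescribed moments", {
  # sd = 0: all scales equal the mean
  t0 <- sample_scales(10, mean = 1, sd = 0, seed = 1)
  expect_true(all(t0 == 1))
  # n = 200, sd = 0.3: per-column moments within 3-sigma sampling bounds
  tm <- sample_scales(200, mean = 1, sd = 0.3, seed = 2)
  # 3.5-sigma per-column bounds (13 columns tested jointly)
  expect_true(all(abs(colMeans(tm) - 1) < 0.075))
  expect_true(all(abs(apply(tm, 2, sd) - 0.3) < 0.055))
  # truncation: no draw at or below the redraw bound
  t3 <- sample_scales(500, mean = 0.3, sd = 0.4, seed = 3)
  expect_true(all(t3 > 0.05))
  # seed reproducibility
  expect_identical(sample_scales(50, seed = 11), sample_scales(50, seed = 11))
})

test_that("standardized regression recovers known linear structure", {
  set.seed(1)
  X <- sample_scales(300, sd = 0.3, seed = 4)
  z <- scale(X)
  y <- 2 * z[, "ikr"] - 1 * z[, "ina"] + rnorm(300, 0, 0.1)
  reg <- regress_sensitivity(X, data.frame(y = y))
  expect_equal(unname(reg$coefficients["ikr", "y"]),
               2 / sd(y), tolerance = 0.05)
  expect_equal(unname(reg$coefficients["ina", "y"]),
               -1 / sd(y), tolerance = 0.05)
  others <- setdiff(rownames(reg$coefficients), c("ikr", "ina"))
  expect_true(all(abs(reg$coefficients[others, "y"]) < 0.1))
  expect_gt(reg$r_squared[["y"]], 0.95)
})

test_that("regression handles degenerate inputs as specified", {
  X <- sample_scales(100, seed = 5)
  # constant response: all coefficients zero, R^2 = 0
  reg <- regress_sensitivity(X, data.frame(y = rep(3, 100)))
  expect_true(all(reg$coefficients == 0))
  expect_equal(unname(reg$r_squared), 0)
  # collinear predictors are refused with the offending column named
  Xbad <- cbind(X, dup = X[, 1])
  class(Xbad) <- class(X)
  expect_error(regress_sensitivity(Xbad, data.frame(y = rnorm(100))),
               "collinear|constant")
  # too few trials
  expect_error(regress_sensitivity(X[1:10, ], data.frame(y = rnorm(10))),
               "more valid trials")
})

test_that("regression on orthogonalized predictors matches simple regressions", {
  set.seed(6)
  raw <- sample_scales(400, sd = 0.3, seed = 6)
  # orthogonalize the columns, then rescale to unit variance
  Qm <- qr.Q(qr(scale(raw, scale = FALSE)))
  X <- scale(Qm)
  colnames(X) <- colnames(raw)
  class(X) <- class(raw)
  y <- as.numeric(1.5 * X[, "ical"] - 0.7 * X[, "ina"] + rnorm(400, 0, 0.2))
  reg <- regress_sensitivity(X, data.frame(y = y))
  yz <- as.numeric(scale(y))
  simple <- apply(scale(X), 2, function(col) sum(col * yz) / sum(col^2))
  expect_equal(unname(reg$coefficients[, "y"]), unname(simple),
               tolerance = 1e-8)
})

test_that("coefficients are invariant to affine rescaling of the outputs", {
  X <- sample_scales(150, seed = 7)
  set.seed(7)
  y <- as.numeric(scale(X)[, "ikr"]) + rnorm(150, 0, 0.3)
  r1 <- regress_sensitivity(X, data.frame(y = y))
  r2 <- regress_sensitivity(X, data.frame(y = 40 + 7 * y))
  expect_equal(r1$coefficients, r2$coefficients, tolerance = 1e-10)
})

test_that("failed trials yield missing rows that the regression drops", {
  X <- sample_scales(60, seed = 8)
  out <- data.frame(mean_apd = rnorm(60, 200, 10), stv = rnorm(60, 4, 1),
                    ltv = rnorm(60, 4, 1))
  out$mean_apd[c(5, 12)] <- NA
  reg <- regress_sensitivity(X, out)
  expect_equal(reg$n_used, 58)
})
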