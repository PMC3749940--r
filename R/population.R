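#' Sample per-target conductance scale factors for a population of models
#'
#' Independent Gaussian draws (default mean 1.0, SD 0.3) per trial and
#' target, truncated below at 0.05 by redrawing; reproducible by seed.
#'
#' @param n_trials number of virtual myocytes (default 200).
#' @param targets character vector of scaled targets.
#' @param mean,sd Gaussian parameters of the scale distribution.
#' @param seed integer seed.
#' @param lower truncation bound (redrawn below this value).
#' @return a `trial_matrix`: numeric matrix `n_trials x length(targets)`
#'   with attributes `seed`, `mean`, `sd`.
#' @export
sample_scales <- function(n_trials = 200L, targets = target_names(),
                          mean = 1.0, sd = 0.3, seed = 1L, lower = 0.05) {
  stopifnot(sd >= 0, n_trials >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  k <- length(targets)
  m <- matrix(rnorm(n_trials * k, mean, sd), n_trials, k,
              dimnames = list(NULL, targets))
  while (any(bad <- m < lower)) m[bad] <- rnorm(sum(bad), mean, sd)
  structure(m, seed = seed, mean = mean, sd = sd, class = c("trial_matrix", class(m)))
}

#' Simulate a population of conductance-scaled myocytes
#'
#' Each trial applies its scale vector multiplicatively to the maximal
#' conductances/rates of the thirteen targets, rebuilds the cell and paces
#' it; mean APD, STV and LTV at steady-state pacing are recorded. Trials in
#' which the cell fails (numerical blow-up or no analyzable beats) yield
#' missing rows, which are excluded pairwise from the regression.
#'
#' @param config base cell configuration.
#' @param trials a [sample_scales()] matrix.
#' @param protocol a fixed-CL [pacing_protocol()].
#' @param seed gating seed used for every trial (one fixed seed per trial
#'   keeps output differences attributable to the scale factors).
#' @param condition optional [condition_spec()] applied to every trial.
#' @return data.frame with columns `mean_apd`, `stv`, `ltv` (NA for failed
#'   trials), rows aligned with `trials`.
#' @export
run_population <- function(config, trials, protocol, seed = 1L,
                           condition = condition_spec()) {
  stopifnot(inherits(trials, "trial_matrix"))
  n <- nrow(trials)
  out <- data.frame(mean_apd = rep(NA_real_, n), stv = NA_real_,
                    ltv = NA_real_)
  for (i in seq_len(n)) {
    res <- tryCatch({
      cfg <- scale_targets(config, trials[i, ])
      cell <- build_cell(cfg, condition = condition, seed = seed)
      run <- suppressWarnings(pace_fixed_cl(cell, protocol, seed = seed))
      s <- bvr_summary(run$apd, min_beats = 2L)
      c(s$mean_apd, s$stv, s$ltv)
    }, error = function(e) rep(NA_real_, 3))
    out[i, ] <- res
  }
  n_fail <- sum(is.na(out$mean_apd))
  if (n_fail > 0.2 * n) {
    warning(n_fail, " of ", n, " trials failed: ",
            paste(which(is.na(out$mean_apd)), collapse = ", "))
  }
  out
}

#' Standardized linear regression of outputs on conductance scales
#'
#' Z-scores every predictor column and every response, then fits ordinary
#' least squares per response; the standardized coefficient magnitudes rank
#' the contribution of each target to each output.
#'
#' @param trials a [sample_scales()] matrix (predictors).
#' @param outputs data.frame of responses (e.g. from [run_population()]);
#'   rows align with `trials`, missing rows are dropped.
#' @return list with `coefficients` (targets x outputs matrix of
#'   standardized coefficients) and `r_squared` (per output).
#' @export
regress_sensitivity <- function(trials, outputs) {
  X <- as.matrix(trials)
  Y <- as.matrix(outputs)
  keep <- stats::complete.cases(Y) & stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; Y <- Y[keep, , drop = FALSE]
  if (nrow(X) <= ncol(X) + 5) {
    stop("need more valid trials than targets + 5", call. = FALSE)
  }
  Xz <- scale(X)
  if (any(!is.finite(Xz))) {
    const <- colnames(X)[apply(X, 2, function(c) sd(c) == 0)]
    stop("constant/collinear predictor column(s): ",
         paste(const, collapse = ", "), call. = FALSE)
  }
  qrX <- qr(cbind(1, Xz))
  if (qrX$rank < ncol(Xz) + 1) {
    stop("rank-deficient predictor matrix; collinear columns present",
         call. = FALSE)
  }
  coefs <- matrix(0, ncol(X), ncol(Y),
                  dimnames = list(colnames(X), colnames(Y)))
  r2 <- setNames(numeric(ncol(Y)), colnames(Y))
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    if (sd(y) == 0) { coefs[, j] <- 0; r2[j] <- 0; next }
    yz <- as.numeric(scale(y))
    fit <- stats::lm.fit(cbind(1, Xz), yz)
    coefs[, j] <- fit$coefficients[-1]
    r2[j] <- 1 - sum(fit$residuals^2) / sum((yz - mean(yz))^2)
  }
  list(coefficients = coefs, r_squared = r2, n_used = nrow(X))
}
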