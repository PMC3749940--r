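#' Per-beat action-potential-duration series
#'
#' Container for per-beat APD90 values together with upstroke times and
#' validity flags. Beats flagged invalid (e.g. repolarization failure) break
#' consecutive runs; variability statistics are computed over the longest
#' consecutive run of valid beats.
#'
#' @param apd numeric vector of per-beat APD90 values (ms).
#' @param upstroke_times optional numeric vector of upstroke times (ms).
#' @param valid optional logical vector flagging analyzable beats.
#' @return an object of class `apd_series`.
#' @export
apd_series <- function(apd, upstroke_times = NULL, valid = NULL) {
  apd <- as.numeric(apd)
  n <- length(apd)
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (is.null(upstroke_times)) upstroke_times <- rep(NA_real_, n)
  stopifnot(length(valid) == n, length(upstroke_times) == n)
  valid <- valid & is.finite(apd)
  structure(list(apd = apd, upstroke_times = as.numeric(upstroke_times),
                 valid = as.logical(valid)),
            class = "apd_series")
}

#' @export
print.apd_series <- function(x, ...) {
  cat(sprintf("<apd_series> %d beats (%d valid), mean APD %.1f ms\n",
              length(x$apd), sum(x$valid),
              mean(x$apd[x$valid])))
  invisible(x)
}

as_apd_series <- function(x) {
  if (inherits(x, "apd_series")) x else apd_series(x)
}

# Longest run of consecutive valid beats; invalid beats break runs.
analysis_window <- function(x, min_beats = 2L) {
  x <- as_apd_series(x)
  r <- rle(x$valid)
  if (!any(r$values)) stop("no valid beats in series", call. = FALSE)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  best <- ok[which.max(r$lengths[ok])]
  run <- seq.int(starts[best], ends[best])
  if (length(run) < min_beats) {
    stop(sprintf("need >= %d consecutive valid beats, have %d",
                 min_beats, length(run)), call. = FALSE)
  }
  x$apd[run]
}

#' Short-term variability of APD
#'
#' Mean absolute difference between successive APDs, normalized by sqrt(2):
#' `sum(|APD[i+1] - APD[i]|) / (n_pairs * sqrt(2))`. Geometrically this is
#' the mean distance of Poincare points perpendicular to the identity line.
#' The denominator counts successive pairs, so an alternating series with
#' step `D` has STV exactly `D / sqrt(2)`.
#'
#' @param x an [apd_series()] or numeric vector of APDs (ms).
#' @return STV in ms.
#' @export
stv <- function(x) {
  a <- analysis_window(x, min_beats = 2L)
  d <- diff(a)
  sum(abs(d)) / (length(d) * sqrt(2))
}

#' Long-term variability of APD
#'
#' `sum(|APD[i+1] + APD[i] - 2*mean(APD)|) / (n_pairs * sqrt(2))`: the mean
#' distance of Poincare points along the identity line from the series
#' centroid.
#'
#' @inheritParams stv
#' @return LTV in ms.
#' @export
ltv <- function(x) {
  a <- analysis_window(x, min_beats = 2L)
  n <- length(a)
  s <- a[-1] + a[-n] - 2 * mean(a)
  sum(abs(s)) / ((n - 1) * sqrt(2))
}

#' Coefficient of variation of APD
#'
#' `100 * sd(APD) / mean(APD)` (sample standard deviation, n-1 denominator)
#' over the valid analysis window.
#'
#' @inheritParams stv
#' @return coefficient of variation in percent.
#' @export
cv <- function(x) {
  a <- analysis_window(x, min_beats = 2L)
  m <- mean(a)
  if (m <= 0) stop("mean APD must be positive for CV", call. = FALSE)
  100 * sd(a) / m
}

#' Poincare pairs and geometric variability decomposition
#'
#' Returns successive-beat pairs `(APD[i], APD[i+1])` together with the mean
#' distance of the points perpendicular to the identity line (equals [stv()])
#' and along the identity line relative to the centroid (equals [ltv()]).
#'
#' @inheritParams stv
#' @return list with elements `pairs` (data.frame `apd_i`, `apd_next`),
#'   `perpendicular` and `along` (ms).
#' @export
poincare <- function(x) {
  a <- analysis_window(x, min_beats = 2L)
  n <- length(a)
  xi <- a[-n]; xj <- a[-1]
  # distance from (xi, xj) to the line y = x is |xj - xi| / sqrt(2);
  # the projection onto the line has arclength coordinate (xi + xj)/sqrt(2)
  perp <- mean(abs(xj - xi)) / sqrt(2)
  center <- 2 * mean(a) / sqrt(2)
  along <- mean(abs((xi + xj) / sqrt(2) - center))
  list(pairs = data.frame(apd_i = xi, apd_next = xj),
       perpendicular = perp, along = along)
}

#' Summary of beat-to-beat repolarization variability
#'
#' @inheritParams stv
#' @param min_beats minimum number of consecutive valid beats required for a
#'   trustworthy read-out (default 30); fewer beats produce a warning.
#' @return list with `stv`, `ltv`, `mean_apd`, `sd_apd` (ms), `cv` (percent)
#'   and `n_beats` (size of the analysis window).
#' @export
bvr_summary <- function(x, min_beats = 30L) {
  a <- analysis_window(x, min_beats = 2L)
  if (length(a) < min_beats) {
    warning(sprintf("only %d consecutive valid beats (< %d); BVR statistics may be unreliable",
                    length(a), min_beats))
  }
  list(stv = stv(a), ltv = ltv(a), mean_apd = mean(a), sd_apd = sd(a),
       cv = cv(a), n_beats = length(a))
}

#' Detect per-beat APD90 from a membrane-potential trace
#'
#' For each stimulus, the beat amplitude is `peak Vm - pre-stimulus Vm` and
#' APD90 is the time from the upstroke (first crossing of -40 mV with
#' dVm/dt > 5 mV/ms after stimulus onset) to the first downward crossing of
#' `pre-stimulus Vm + 0.1 * amplitude` after the peak, with linear
#' interpolation between samples. Beats without such a crossing before the
#' next stimulus are flagged as repolarization failures; beats with amplitude
#' below 30 mV are flagged invalid.
#'
#' @param time numeric vector of sample times (ms), strictly increasing,
#'   sampled at 0.5 ms resolution or finer.
#' @param vm membrane potential (mV) at `time`.
#' @param stimulus_times stimulus onset times (ms).
#' @return an [apd_series()].
#' @export
detect_apd90 <- function(time, vm, stimulus_times) {
  stopifnot(length(time) == length(vm), length(stimulus_times) >= 1)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  nb <- length(stimulus_times)
  apd <- rep(NA_real_, nb); ups <- rep(NA_real_, nb); ok <- rep(FALSE, nb)
  bounds <- c(stimulus_times, max(time) + 1e-9)
  for (k in seq_len(nb)) {
    i0 <- findInterval(bounds[k], time)           # last sample at/before stim
    i1 <- findInterval(bounds[k + 1] - 1e-9, time)
    if (i0 < 1 || i1 - i0 < 3) next
    idx <- i0:i1
    tt <- time[idx]; vv <- vm[idx]
    baseline <- vv[1]
    ipk <- which.max(vv)
    amp <- vv[ipk] - baseline
    if (amp < 30) next                            # no action potential
    # upstroke: first upward -40 mV crossing with fast depolarization
    up_t <- NA_real_
    dv <- diff(vv) / diff(tt)
    for (i in seq_len(ipk - 1)) {
      if (vv[i] < -40 && vv[i + 1] >= -40 && dv[i] > 5) {
        up_t <- tt[i] + (-40 - vv[i]) / (vv[i + 1] - vv[i]) * (tt[i + 1] - tt[i])
        break
      }
    }
    if (!is.finite(up_t)) next
    level <- baseline + 0.1 * amp
    cr_t <- NA_real_
    for (i in ipk:(length(vv) - 1)) {
      if (vv[i] > level && vv[i + 1] <= level) {
        cr_t <- tt[i] + (vv[i] - level) / (vv[i] - vv[i + 1]) * (tt[i + 1] - tt[i])
        break
      }
    }
    ups[k] <- up_t
    if (!is.finite(cr_t)) {
      apd[k] <- NA_real_; ok[k] <- FALSE          # repolarization failure
    } else {
      apd[k] <- cr_t - up_t; ok[k] <- TRUE
    }
  }
  apd_series(apd, upstroke_times = ups, valid = ok)
}

#' Beat-aligned membrane-current fluctuation profile
#'
#' Pointwise mean and standard deviation of the net membrane current over a
#' set of beat-aligned traces, plus the area under the Std curve (trapezoid
#' rule) as a global magnitude of current fluctuations.
#'
#' @param im matrix of net membrane current (pA/pF), one row per beat,
#'   columns beat-aligned on the stimulus; or a list of equal-length vectors.
#' @param time optional time grid (ms) for the columns; defaults to 0.5 ms
#'   spacing starting at 0.
#' @return list with `time`, `mean_im`, `std_im` (pA/pF) and `auc_std_im`
#'   (pA/pF*ms).
#' @export
im_std_profile <- function(im, time = NULL) {
  if (is.list(im) && !is.data.frame(im)) {
    len <- lengths(im)
    if (length(unique(len)) != 1) stop("traces have mismatched lengths", call. = FALSE)
    im <- do.call(rbind, im)
  }
  im <- as.matrix(im)
  if (nrow(im) < 2) stop("need at least 2 beat-aligned traces", call. = FALSE)
  if (is.null(time)) time <- (seq_len(ncol(im)) - 1) * 0.5
  if (length(time) != ncol(im)) stop("time grid does not match trace length", call. = FALSE)
  m <- colMeans(im)
  s <- apply(im, 2, sd)
  auc <- sum(diff(time) * (s[-1] + s[-length(s)]) / 2)
  list(time = time, mean_im = m, std_im = s, auc_std_im = auc)
}

#' Monoexponential fit of the STV-versus-APD relationship
#'
#' Fits `STV = a + b * exp(c * APD)` by nonlinear least squares with
#' multi-start over the rate constant `c`.
#'
#' @param apd mean APD per cell (ms).
#' @param stv_values STV per cell (ms).
#' @return list with `a`, `b` (ms), `c` (1/ms) and `r_squared`.
#' @export
fit_stv_apd <- function(apd, stv_values) {
  stopifnot(length(apd) == length(stv_values))
  keep <- is.finite(apd) & is.finite(stv_values)
  apd <- apd[keep]; stv_values <- stv_values[keep]
  if (length(apd) < 5) stop("need at least 5 points", call. = FALSE)
  if (diff(range(apd)) < 50) stop("APD values must span at least 50 ms", call. = FALSE)
  dat <- data.frame(x = apd, y = stv_values)
  best <- NULL; best_rss <- Inf
  for (c0 in c(0.002, 0.005, 0.01, 0.02, 0.04, 0.08)) {
    b0 <- max(1e-6, (max(dat$y) - min(dat$y)) / max(1e-12, exp(c0 * max(dat$x)) - exp(c0 * min(dat$x))))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a + b * exp(cc * x), data = dat,
                        start = list(a = min(dat$y), b = b0, cc = c0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  if (is.null(best)) stop("monoexponential fit did not converge; residuals unavailable", call. = FALSE)
  p <- coef(best)
  tss <- sum((dat$y - mean(dat$y))^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - best_rss / tss)) else 0
  list(a = unname(p["a"]), b = unname(p["b"]), c = unname(p["cc"]), r_squared = r2)
}
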