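#' Voltage/calcium-dependent transition-rate function
#'
#' Rates are built from named templates so that scheme definitions are fully
#' serializable. Available templates (all return 1/ms):
#' \describe{
#'   \item{`constant`}{`k`}
#'   \item{`exponential`}{`a * exp(b * Vm)`}
#'   \item{`sigmoid`}{`a / (1 + exp((Vm - v_half) / s))`}
#'   \item{`linoid`}{`a * (Vm - v0) / (1 - exp(-(Vm - v0) / s))`}
#'   \item{`ca_hill`}{`a * Ca^h / (Ca^h + km^h)` (local calcium activation)}
#'   \item{`sr_hill`}{`a / (1 + (k / Ca_SR)^h)` (luminal sensitization)}
#' }
#'
#' @param type template name.
#' @param ... template parameters (see above).
#' @return a `rate_function` object.
#' @export
rate_function <- function(type = c("constant", "exponential", "sigmoid",
                                   "linoid", "ca_hill", "sr_hill"), ...) {
  type <- match.arg(type)
  pars <- list(...)
  need <- switch(type,
    constant = "k", exponential = c("a", "b"),
    sigmoid = c("a", "v_half", "s"), linoid = c("a", "v0", "s"),
    ca_hill = c("a", "km", "h"), sr_hill = c("a", "k", "h"))
  missing <- setdiff(need, names(pars))
  if (length(missing)) {
    stop("rate_function '", type, "' needs parameters: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(type = type, pars = pars[need]), class = "rate_function")
}

#' Evaluate a rate function
#'
#' @param rate a [rate_function()].
#' @param vm membrane potential (mV); vectorized.
#' @param ca local cytosolic calcium (mM).
#' @param ca_sr luminal (SR) calcium (mM).
#' @return transition rate(s), 1/ms; always non-negative and finite over the
#'   physiological range.
#' @export
eval_rate <- function(rate, vm, ca = 1e-4, ca_sr = 1) {
  stopifnot(inherits(rate, "rate_function"))
  p <- rate$pars
  r <- switch(rate$type,
    constant = rep(p$k, length(vm)),
    exponential = p$a * exp(p$b * vm),
    sigmoid = p$a / (1 + exp((vm - p$v_half) / p$s)),
    linoid = {
      x <- vm - p$v0
      out <- p$a * x / (1 - exp(-x / p$s))
      out[abs(x) < 1e-9] <- p$a * p$s
      out
    },
    ca_hill = rep(p$a * ca^p$h / (ca^p$h + p$km^p$h), length(vm)),
    sr_hill = rep(p$a / (1 + (p$k / ca_sr)^p$h), length(vm)))
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("rate function produced a negative or non-finite rate", call. = FALSE)
  }
  r
}

#' Markov gating scheme
#'
#' @param states character vector of state names.
#' @param transitions data.frame with columns `from`, `to` (state names) and
#'   a list-column `rate` of [rate_function()] objects, or a list of
#'   `list(from, to, rate)` triplets.
#' @param conducting named numeric vector of unitary-conductance weights in
#'   (0, 1] for the conducting states (or a character vector, weight 1).
#' @return a `markov_scheme`.
#' @export
markov_scheme <- function(states, transitions, conducting) {
  states <- as.character(states)
  if (anyDuplicated(states)) stop("duplicate state names", call. = FALSE)
  if (is.data.frame(transitions)) {
    tl <- lapply(seq_len(nrow(transitions)), function(i)
      list(from = transitions$from[i], to = transitions$to[i],
           rate = transitions$rate[[i]]))
  } else tl <- transitions
  for (tr in tl) {
    if (!tr$from %in% states || !tr$to %in% states) {
      stop("transition references unknown state", call. = FALSE)
    }
    if (tr$from == tr$to) stop("self-transitions are not allowed", call. = FALSE)
    stopifnot(inherits(tr$rate, "rate_function"))
  }
  if (is.character(conducting)) {
    conducting <- setNames(rep(1, length(conducting)), conducting)
  }
  if (length(conducting) == 0) stop("at least one conducting state required", call. = FALSE)
  if (!all(names(conducting) %in% states)) {
    stop("conducting states must be scheme states", call. = FALSE)
  }
  if (any(conducting <= 0 | conducting > 1)) {
    stop("conductance weights must be in (0, 1]", call. = FALSE)
  }
  # connectivity of the undirected transition graph
  n <- length(states)
  adj <- matrix(FALSE, n, n, dimnames = list(states, states))
  for (tr in tl) adj[tr$from, tr$to] <- adj[tr$to, tr$from] <- TRUE
  seen <- logical(n); seen[1] <- TRUE; frontier <- 1L
  while (length(frontier)) {
    nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
    seen[nxt] <- TRUE; frontier <- nxt
  }
  if (!all(seen)) stop("state graph is not connected", call. = FALSE)
  structure(list(states = states, transitions = tl, conducting = conducting),
            class = "markov_scheme")
}

#' Build the transition-rate matrix of a scheme at given conditions
#'
#' @param scheme a [markov_scheme()].
#' @param vm membrane potential (mV).
#' @param ca,ca_sr local and luminal calcium (mM).
#' @return square matrix of rates (1/ms), `Q[i, j]` from state i to state j.
#' @export
rate_matrix <- function(scheme, vm, ca = 1e-4, ca_sr = 1) {
  stopifnot(inherits(scheme, "markov_scheme"), length(vm) == 1)
  n <- length(scheme$states)
  Q <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  for (tr in scheme$transitions) {
    Q[tr$from, tr$to] <- Q[tr$from, tr$to] + eval_rate(tr$rate, vm, ca, ca_sr)
  }
  Q
}

#' Estimate channel count from whole-cell and single-channel conductance
#'
#' `N = round(1000 * G_max / g_single)` with `G_max` in nS and `g_single` in
#' pS, floored at one channel (with a warning). A k-fold change in channel
#' density offset by a reciprocal change in single-channel conductance leaves
#' the total conductance `N * g_single` unchanged.
#'
#' @param g_max whole-cell maximal conductance (nS).
#' @param g_single single-channel conductance (pS).
#' @return integer channel count (>= 1).
#' @export
estimate_channel_count <- function(g_max, g_single) {
  if (!is.numeric(g_max) || !is.numeric(g_single) ||
      any(g_max <= 0) || any(g_single <= 0)) {
    stop("g_max and g_single must be positive", call. = FALSE)
  }
  n <- round(1000 * g_max / g_single)
  if (any(n < 1)) {
    warning("estimated channel count below 1; flooring at 1 channel")
    n <- pmax(n, 1)
  }
  as.integer(n)
}

#' Population of ion channels governed by a Markov scheme
#'
#' @param scheme a [markov_scheme()].
#' @param g_single single-channel conductance (pS).
#' @param N channel count; if `NULL`, estimated from `g_max` via
#'   [estimate_channel_count()].
#' @param g_max whole-cell conductance (nS), used when `N` is missing.
#' @param mode gating mode: `"deterministic"`, `"markov_stochastic"` or
#'   `"sde_langevin"`; fixed for the lifetime of the population.
#' @param vm_init membrane potential at which the population is initialized
#'   to its stationary distribution.
#' @return a `channel_population` with occupancy (integer counts in
#'   stochastic mode, fractions otherwise).
#' @export
channel_population <- function(scheme, g_single, N = NULL, g_max = NULL,
                               mode = c("markov_stochastic", "deterministic",
                                        "sde_langevin"),
                               vm_init = -85) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "markov_scheme"), g_single > 0)
  if (is.null(N)) {
    if (is.null(g_max)) stop("provide N or g_max", call. = FALSE)
    N <- estimate_channel_count(g_max, g_single)
  }
  N <- as.integer(N)
  stopifnot(N >= 1)
  pi0 <- stationary_distribution(scheme, vm_init)
  if (mode == "markov_stochastic") {
    occ <- floor(pi0 * N)
    occ[which.max(pi0)] <- occ[which.max(pi0)] + (N - sum(occ))
  } else {
    occ <- pi0
  }
  structure(list(scheme = scheme, N = N, g_single = g_single, mode = mode,
                 occupancy = setNames(as.numeric(occ), scheme$states)),
            class = "channel_population")
}

#' Stationary occupancy distribution of a scheme at fixed conditions
#'
#' @inheritParams rate_matrix
#' @return named probability vector over states.
#' @export
stationary_distribution <- function(scheme, vm, ca = 1e-4, ca_sr = 1) {
  Q <- rate_matrix(scheme, vm, ca, ca_sr)
  setNames(cpp_stationary_dist(Q), scheme$states)
}

#' Reproducible random-number stream for gating kernels
#'
#' @param seed integer seed.
#' @return an opaque stream object that advances across calls.
#' @export
gating_rng <- function(seed) {
  structure(list(ptr = cpp_rng_create(as.integer(seed)), seed = seed),
            class = "gating_rng")
}

#' Advance a stochastic channel population by one time step
#'
#' Integer occupancies move between states by multinomial sampling with
#' per-transition probability `rate * dt` (internally sub-stepped whenever
#' any occupied state's total exit probability would exceed 0.1), so the
#' expectation of one step equals the deterministic forward-Euler update and
#' the total channel count is conserved exactly.
#'
#' @param pop a [channel_population()] in `markov_stochastic` mode.
#' @param vm membrane potential (mV).
#' @param ca,ca_sr local and luminal calcium (mM).
#' @param dt time step (ms); `dt = 0` returns the population unchanged.
#' @param rng a [gating_rng()].
#' @return the population with updated occupancy.
#' @export
step_markov_stochastic <- function(pop, vm, ca = 1e-4, ca_sr = 1, dt, rng) {
  stopifnot(inherits(pop, "channel_population"),
            pop$mode == "markov_stochastic",
            inherits(rng, "gating_rng"), dt >= 0)
  Q <- rate_matrix(pop$scheme, vm, ca, ca_sr)
  occ <- cpp_markov_step_stoch(unname(pop$occupancy), Q, dt, rng$ptr)
  pop$occupancy <- setNames(occ, pop$scheme$states)
  pop
}

#' Advance deterministic state fractions by one time step
#'
#' Forward-Euler update (sub-stepped for stiff schemes, keeping the local
#' error at O(dt^2)); the fraction sum is preserved and entries stay in
#' `[0, 1]`.
#'
#' @param fractions named or plain numeric vector summing to 1 (tol 1e-10).
#' @param scheme a [markov_scheme()].
#' @inheritParams step_markov_stochastic
#' @return updated fractions.
#' @export
step_markov_deterministic <- function(fractions, scheme, vm, ca = 1e-4,
                                      ca_sr = 1, dt) {
  stopifnot(inherits(scheme, "markov_scheme"), dt >= 0)
  if (abs(sum(fractions) - 1) > 1e-10) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  Q <- rate_matrix(scheme, vm, ca, ca_sr)
  setNames(cpp_markov_step_det(unname(fractions), Q, dt), scheme$states)
}

#' Langevin update of state fractions (chemical-Langevin diffusion)
#'
#' @inheritParams step_markov_deterministic
#' @param n_channels population size controlling the noise amplitude.
#' @param rng a [gating_rng()].
#' @return updated fractions.
#' @export
step_markov_sde <- function(fractions, scheme, vm, ca = 1e-4, ca_sr = 1,
                            dt, n_channels, rng) {
  stopifnot(inherits(scheme, "markov_scheme"), inherits(rng, "gating_rng"))
  Q <- rate_matrix(scheme, vm, ca, ca_sr)
  setNames(cpp_markov_step_cle(unname(fractions), Q, dt, n_channels, rng$ptr),
           scheme$states)
}

#' Langevin update of a Hodgkin-Huxley gating variable
#'
#' `x' = x + [a(1-x) - b x] dt + sqrt([a(1-x) + b x] dt / N_eff) xi`,
#' clipped to `[0, 1]`. As `N_eff` grows the update reduces to the
#' deterministic relaxation.
#'
#' @param x gating variable in `[0, 1]`.
#' @param alpha,beta opening and closing rates (1/ms) at the current Vm.
#' @param n_eff effective channel count (>= 1) scaling the noise.
#' @param dt time step (ms).
#' @param rng a [gating_rng()].
#' @return updated gating variable.
#' @export
step_hh_sde <- function(x, alpha, beta, n_eff, dt, rng) {
  stopifnot(dt > 0, n_eff >= 1, alpha >= 0, beta >= 0,
            inherits(rng, "gating_rng"))
  cpp_hh_sde_step(x, alpha, beta, n_eff, dt, rng$ptr)
}

#' Whole-cell current carried by a channel population
#'
#' `I = g_single * N_open * (Vm - E_rev) / Cm * 1e-3` (pA/pF), where
#' `N_open` is the conductance-weighted occupancy of the conducting states
#' (`N * fraction` in deterministic/Langevin modes).
#'
#' @param pop a [channel_population()].
#' @param vm membrane potential (mV).
#' @param e_rev reversal potential (mV).
#' @param cm membrane capacitance (pF).
#' @return current in pA/pF.
#' @export
population_current <- function(pop, vm, e_rev, cm) {
  stopifnot(inherits(pop, "channel_population"), cm > 0)
  w <- pop$conducting_weights %||% pop$scheme$conducting
  occ <- pop$occupancy[names(w)]
  n_open <- sum(occ * w)
  if (pop$mode != "markov_stochastic") n_open <- n_open * pop$N
  pop$g_single * n_open * (vm - e_rev) / cm * 1e-3
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a Markov scheme from a structured text (JSON) definition
#'
#' The file holds `states`, `conducting` (names or name->weight map) and
#' `transitions`, each with `from`, `to`, `type` and the template parameters
#' of [rate_function()]; optional top-level `g_single`, `N`, `g_max`.
#'
#' @param path file path.
#' @return list with `scheme` and any population parameters found.
#' @export
read_scheme_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  states <- unlist(cfg$states)
  trans <- lapply(cfg$transitions, function(tr) {
    pars <- tr[setdiff(names(tr), c("from", "to", "type"))]
    list(from = tr$from, to = tr$to,
         rate = do.call(rate_function, c(list(type = tr$type), pars)))
  })
  cond <- cfg$conducting
  cond <- if (is.null(names(cond)) || all(names(cond) == "")) {
    unlist(cond)
  } else unlist(cond)
  scheme <- markov_scheme(states, trans, cond)
  list(scheme = scheme,
       g_single = cfg$g_single %||% NULL,
       N = cfg$N %||% NULL, g_max = cfg$g_max %||% NULL)
}
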