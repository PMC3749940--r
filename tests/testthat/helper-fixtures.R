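# Shared fixtures, built once per test run. Cells are expensive to build
# (stimulus-threshold bisection), so they are cached in this environment.
.fx <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fx, inherits = FALSE)) {
    assign(key, force(expr), envir = .fx)
  }
  get(key, envir = .fx, inherits = FALSE)
}

control_cell <- function() {
  fixture("control_markov", suppressWarnings(build_cell(default_cell_config("markov"))))
}

det_cell <- function() {
  fixture("control_det", suppressWarnings(build_cell(default_cell_config("deterministic"))))
}

short_protocol <- function(n_beats = 40L, n_discard = 10L, cl = 1000) {
  suppressWarnings(pacing_protocol("fixed_CL", cl = cl, n_beats = n_beats,
                                   n_discard = n_discard))
}

# simple two-state scheme with constant rates
two_state <- function(alpha = 1, beta = 1) {
  markov_scheme(
    c("closed", "open"),
    list(list(from = "closed", to = "open", rate = rate_function("constant", k = alpha)),
         list(from = "open", to = "closed", rate = rate_function("constant", k = beta))),
    conducting = c(open = 1))
}

# brute-force metric oracles, written independently of the implementation
oracle_stv <- function(x) {
  s <- 0; n <- 0
  for (i in seq_len(length(x) - 1)) { s <- s + abs(x[i + 1] - x[i]); n <- n + 1 }
  s / (n * sqrt(2))
}
oracle_ltv <- function(x) {
  m <- sum(x) / length(x); s <- 0; n <- 0
  for (i in seq_len(length(x) - 1)) { s <- s + abs(x[i + 1] + x[i] - 2 * m); n <- n + 1 }
  s / (n * sqrt(2))
}
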