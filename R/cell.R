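#' Build a myocyte ready for simulation
#'
#' Applies condition modifiers and the domain configuration, initializes all
#' gating populations at their stationary distribution for the resting
#' potential, and balances the background conductances (Na+, Ca2+, K+ leaks
#' and the SR leak rate) so that the configured resting state is an exact
#' equilibrium of every ion species. The stimulus amplitude is set to 1.5x
#' the diastolic excitation threshold, determined programmatically.
#'
#' @param config cell configuration, see [default_cell_config()].
#' @param condition a [condition_spec()] (identity by default).
#' @param domains a [domain_config()].
#' @param seed integer seed stored with the cell and used as the default for
#'   simulations.
#' @param find_threshold logical; determine the stimulus threshold (brief
#'   deterministic test beats). Disable for speed when a stimulus amplitude
#'   is always supplied explicitly.
#' @return an object of class `bvr_cell` with elements `config` (with
#'   balanced backgrounds), `state` (named numeric vector), `stim_amp`
#'   (pA/pF, negative = depolarizing) and `seed`.
#' @export
build_cell <- function(config = default_cell_config(),
                       condition = condition_spec(),
                       domains = domain_config(), seed = 1L,
                       find_threshold = TRUE) {
  config <- apply_condition(config, condition)
  stopifnot(inherits(domains, "domain_config"))
  config$domains <- list(n_domains = domains$n_domains,
                         tau_diffusion = domains$tau_diffusion)
  init <- cpp_init_cell(config)
  if (!init$balanced) {
    warning("resting-state balance required clamping a background ",
            "conductance at zero; the cell may drift slowly at rest")
  }
  config$background <- list(gnab = init$gnab, gcab = init$gcab,
                            gkb = init$gkb)
  config$targets$jleak$vleak <- init$vleak
  config$targets$jleak$scale <- 1   # balanced value is absolute
  cell <- structure(list(config = config, state = init$state,
                         stim_amp = NA_real_, seed = as.integer(seed)),
                    class = "bvr_cell")
  if (find_threshold) {
    thr <- find_stim_threshold(cell)
    cell$stim_amp <- 1.5 * thr
  }
  cell
}

#' @export
print.bvr_cell <- function(x, ...) {
  nd <- x$config$domains$n_domains
  modes <- vapply(x$config$targets, function(t) t$mode, "")
  cat(sprintf("<bvr_cell> Vm %.1f mV, %d Ca domain(s); %d/%d stochastic targets\n",
              x$state[["vm"]], nd, sum(modes != "deterministic"), length(modes)))
  invisible(x)
}

#' Determine the diastolic stimulation threshold
#'
#' Bisects the amplitude of a rectangular stimulus (default duration 0.5 ms)
#' until the minimal amplitude that elicits an action potential (peak Vm
#' above 0 mV within 60 ms) is found, using a deterministic copy of the cell.
#'
#' @param cell a `bvr_cell`.
#' @param stim_dur stimulus duration (ms).
#' @param max_amp largest depolarizing amplitude tried (pA/pF, magnitude).
#' @return threshold amplitude (pA/pF, negative = depolarizing).
#' @export
find_stim_threshold <- function(cell, stim_dur = 0.5, max_amp = 120) {
  cfg <- set_gating_mode(cell$config, "all", "deterministic")
  det <- cpp_init_cell(cfg)
  triggers <- function(amp) {
    proto <- list(mode = "fixed_CL", cl = 60, n_beats = 1L,
                  stim_amp = -abs(amp), stim_dur = stim_dur,
                  record_trace = TRUE, record_im = FALSE, record_dt = 0.5)
    out <- cpp_simulate(list(cfg), list(det$state), proto, 0,
                        0, 1L, 0L)
    max(out$trace$vm) > 0
  }
  if (!triggers(max_amp)) {
    stop("no stimulus amplitude up to ", max_amp,
         " pA/pF elicits an action potential", call. = FALSE)
  }
  lo <- 0; hi <- max_amp
  for (i in 1:12) {
    mid <- (lo + hi) / 2
    if (triggers(mid)) hi <- mid else lo <- mid
  }
  -hi
}

#' Compute all membrane currents and fluxes at the cell's current state
#'
#' @param cell a `bvr_cell` (or a configuration list plus `state`).
#' @param state optional state vector overriding the cell's own.
#' @return list of per-target currents (pA/pF), per-domain SR fluxes
#'   (mM/ms) and the net membrane current `im` (stimulus excluded).
#' @export
compute_currents <- function(cell, state = NULL) {
  stopifnot(inherits(cell, "bvr_cell"))
  cpp_compute_currents(cell$config, state %||% cell$state)
}

#' Advance the cell by a single time step
#'
#' One forward step of the full model: currents, gating in each target's
#' configured mode, concentration flux balance, inter-domain calcium
#' diffusion and the membrane-potential update
#' `Vm' = Vm - (Im + Istim + Iinj) dt + alpha sqrt(dt) xi`.
#'
#' @param cell a `bvr_cell`.
#' @param dt time step (ms).
#' @param i_stim stimulus current (pA/pF, negative = depolarizing).
#' @param i_inject injected current (pA/pF).
#' @param vm_noise_alpha Gaussian Vm-noise amplitude (mV ms^-1/2).
#' @param seed RNG seed for the step's stochastic draws.
#' @return the cell with updated state.
#' @export
step_cell <- function(cell, dt, i_stim = 0, i_inject = 0,
                      vm_noise_alpha = 0, seed = cell$seed) {
  stopifnot(inherits(cell, "bvr_cell"), dt >= 0, vm_noise_alpha >= 0)
  cell$state <- cpp_step_cell(cell$config, cell$state, dt, i_stim, i_inject,
                              vm_noise_alpha, as.integer(seed))
  cell
}

#' Diffusional exchange step between calcium domains
#'
#' `dCa_i/dt = sum_j (Ca_j - Ca_i) / tau` over all other domains; total
#' calcium mass is conserved exactly and a uniform vector is unchanged.
#'
#' @param ca numeric vector of per-domain concentrations (mM).
#' @param tau diffusion time constant (ms).
#' @param dt time step (ms).
#' @return updated concentration vector.
#' @export
ca_diffusion_step <- function(ca, tau, dt) {
  stopifnot(tau > 0, dt >= 0)
  cpp_ca_diffusion_step(as.numeric(ca), tau, dt)
}
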