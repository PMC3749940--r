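# Default parameterization of the reduced canine-like ventricular myocyte.
# Units: potentials mV, time ms, concentrations mM, conductances mS/uF
# (equivalently nS/pF), single-channel conductances pS, currents pA/pF,
# volumes L. Channel counts derive from whole-cell and single-channel
# conductance (N = 1000 * Gmax * Cm / g_single).

#' Names of the thirteen stochastic-capable targets
#' @return character vector.
#' @export
target_names <- function() {
  c("ina", "ical", "ito", "ikur", "ikr", "iks", "ik1",
    "inak", "inaca", "ipca", "jrel", "jup", "jleak")
}

#' Default cell configuration
#'
#' Returns the full parameter set of the reduced myocyte: thirteen targets
#' (each with gating mode, maximal conductance/rate, single-channel
#' conductance and a multiplicative scale), gate kinetics, calcium handling,
#' buffers, geometry and integration steps. The control cell gives an APD90
#' of roughly 180 ms at a 1000-ms cycle length with a dome-plateau
#' morphology.
#'
#' @param mode default gating mode applied to all targets
#'   (`"markov"`, `"deterministic"` or `"sde"`).
#' @return nested configuration list.
#' @export
default_cell_config <- function(mode = "markov") {
  list(
    cm = 100, nao = 140, ko = 5.4, cao = 1.8,
    vrest = -85.5,
    vcyt = 16.4e-12, vsr = 1.1e-12,
    dt_up = 0.005, dt_ap = 0.05, dt_dia = 0.1,
    init = list(nai = 8, ki = 140, cai = 1e-4, casr = 1.0),
    domains = list(n_domains = 1, tau_diffusion = 20),
    targets = list(
      ina = list(mode = mode, gmax = 12, g_single = 15, scale = 1,
                 mu1 = 6e-6, mu2 = 0.02, persist_scale = 1,
                 h_gate = list(vh = -80, k = -4.5, tau0 = 0.25,
                               tau_samp = 7.5, tau_svmid = -62, tau_sk = 8)),
      ical = list(mode = mode, gmax = 0.09, g_single = 0.9, scale = 1,
                  kmfca = 1.2e-3, tau_fca = 2, f_tau_scale = 1,
                  d_gate = list(vh = -10, k = 6.24, tau0 = 0.6, tau_amp = 5,
                                tau_vmid = -15, tau_w = 25),
                  f_gate = list(vh = -25.5, k = -6, tau0 = 25, tau_amp = 250,
                                tau_vmid = -30, tau_w = 35,
                                tau_samp = 100, tau_svmid = -70, tau_sk = 6)),
      ito = list(mode = mode, gmax = 0.25, g_single = 13, scale = 1,
                 a_gate = list(vh = 10, k = 11, tau0 = 0.5, tau_amp = 2.5,
                               tau_vmid = 0, tau_w = 30),
                 i_gate = list(vh = -38, k = -5, tau0 = 8,
                               tau_samp = 35, tau_svmid = -50, tau_sk = 8)),
      ikur = list(mode = mode, gmax = 0.008, g_single = 2, scale = 1,
                  a_gate = list(vh = 5, k = 12, tau0 = 2, tau_amp = 8,
                                tau_vmid = -10, tau_w = 40)),
      ikr = list(mode = mode, gmax = 0.12, g_single = 2.5, scale = 1,
                 rate_scale = 0.5, deact_scale = 0.25),
      iks = list(mode = mode, gmax = 0.015, g_single = 4, scale = 1,
                 x1_gate = list(vh = 10, k = 15, tau0 = 150, tau_amp = 700,
                                tau_vmid = 20, tau_w = 70),
                 x2_gate = list(vh = 10, k = 15, tau0 = 300, tau_amp = 1400,
                                tau_vmid = 20, tau_w = 70)),
      ik1 = list(mode = mode, gmax = 0.45, g_single = 30, scale = 1,
                 x_gate = list(vh = -80, k = -14.29, tau0 = 1)),
      inak = list(mode = mode, imax = 2.2, scale = 1,
                  km_ko = 1.5, km_nai = 10),
      inaca = list(mode = mode, knaca = 450, scale = 1, km_na = 87.5,
                   km_ca = 1.38, ksat = 0.1, gamma = 0.35, alpha = 2.5),
      ipca = list(mode = mode, gpca = 0.2, scale = 1, km = 5e-4),
      jrel = list(mode = mode, grel = 0.02, scale = 1, n_channels = 20000),
      jup = list(mode = mode, vup = 6e-4, scale = 1, km = 2.5e-4),
      jleak = list(mode = mode, vleak = 1e-4, scale = 1)
    ),
    ryr = list(k_open = 15, k_trig = 1.7, km_ca = 6e-4, h_ca = 6, k_csr = 2.6, h_csr = 10,
               floor = 0.05, k_close = 0.6, k_inact = 1.0,
               k_recover = 0.008, k_reset = 0.01),
    buffers = list(cmdn_b = 0.05, cmdn_kd = 2.38e-3,
                   trpn_b = 0.07, trpn_kd = 5e-4,
                   csqn_b = 10, csqn_kd = 0.8),
    background = list(gnab = 0, gcab = 0, gkb = 0)
  )
}

#' Set the gating mode of one or more targets
#'
#' @param config a cell configuration.
#' @param targets character vector of target names, or `"all"`.
#' @param mode `"deterministic"`, `"markov"` or `"sde"`.
#' @return modified configuration.
#' @export
set_gating_mode <- function(config, targets = "all", mode) {
  if (identical(targets, "all")) targets <- target_names()
  unknown <- setdiff(targets, target_names())
  if (length(unknown)) {
    stop("unknown target(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (t in targets) config$targets[[t]]$mode <- mode
  config
}

#' Scale the maximal conductance / rate of targets
#'
#' Applies a multiplicative factor to the target's `scale` entry (used for
#' condition modifiers, morphology presets and population sampling).
#'
#' @param config a cell configuration.
#' @param scales named numeric vector, names in [target_names()].
#' @return modified configuration.
#' @export
scale_targets <- function(config, scales) {
  unknown <- setdiff(names(scales), target_names())
  if (length(unknown)) {
    stop("unknown target(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(scales < 0)) stop("scale factors must be >= 0", call. = FALSE)
  for (t in names(scales)) {
    config$targets[[t]]$scale <- config$targets[[t]]$scale * scales[[t]]
  }
  config
}

#' Scale the channel density of targets at constant total conductance
#'
#' Multiplies the channel count by `factor` with a reciprocal change in
#' single-channel conductance, leaving `N * g_single` (and hence all
#' deterministic behavior) unchanged while scaling gating noise like
#' `1/sqrt(factor)`.
#'
#' @param config a cell configuration.
#' @param factor density factor (> 0), e.g. 5 or 1/5.
#' @param targets targets to modify (default all channel-type targets).
#' @return modified configuration.
#' @export
scale_channel_density <- function(config, factor,
                                  targets = c("ina", "ical", "ito", "ikur",
                                              "ikr", "iks", "ik1", "jrel")) {
  stopifnot(factor > 0)
  for (t in targets) {
    tg <- config$targets[[t]]
    if (!is.null(tg$g_single)) {
      config$targets[[t]]$g_single <- tg$g_single / factor
    }
    if (!is.null(tg$n_channels)) {
      config$targets[[t]]$n_channels <- round(tg$n_channels * factor)
    }
  }
  config
}

#' Pathophysiological condition modifiers
#'
#' Composable specification of the simulated conditions: LQT1 (fractional
#' slow delayed-rectifier block, as by HMR1556), LQT2 (fractional rapid
#' delayed-rectifier block, as by dofetilide), LQT3 (enhanced persistent
#' sodium current, as by ATXII), partial sodium-potassium pump inhibition,
#' and a phenomenological beta-adrenergic stimulation scale set. The
#' identity specification changes nothing.
#'
#' @param iks_block fraction of IKs blocked, in `[0, 1]`.
#' @param ikr_block fraction of IKr blocked, in `[0, 1]`.
#' @param persistent_ina_scale multiplier (>= 1) on the burst-pathway entry
#'   rate of the sodium channel (the persistent-INa lever).
#' @param inak_inhibition fraction of the pump inhibited, in `[0, 1]`.
#' @param beta_ars logical; apply the beta-adrenergic scale set
#'   (IKs x3, ICaL x1.5, SERCA x1.4, INaK x1.4, ICaL inactivation
#'   accelerated by 1/0.5).
#' @param extra_scales optional named vector of additional per-target
#'   conductance scales.
#' @return a `condition_spec`.
#' @export
condition_spec <- function(iks_block = 0, ikr_block = 0,
                           persistent_ina_scale = 1, inak_inhibition = 0,
                           beta_ars = FALSE, extra_scales = NULL) {
  stopifnot(iks_block >= 0, iks_block <= 1, ikr_block >= 0, ikr_block <= 1,
            persistent_ina_scale >= 1, inak_inhibition >= 0,
            inak_inhibition <= 1, is.logical(beta_ars))
  if (!is.null(extra_scales)) {
    unknown <- setdiff(names(extra_scales), target_names())
    if (length(unknown)) {
      stop("unknown target(s) in extra_scales: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(iks_block = iks_block, ikr_block = ikr_block,
                 persistent_ina_scale = persistent_ina_scale,
                 inak_inhibition = inak_inhibition, beta_ars = beta_ars,
                 extra_scales = extra_scales),
            class = "condition_spec")
}

# beta-adrenergic phenomenological factors (documented design choice)
.bars_factors <- c(iks = 3.0, ical = 1.5, jup = 1.4, inak = 1.4)
.bars_f_tau_scale <- 0.5

#' Apply condition modifiers to a cell configuration
#'
#' @param config a cell configuration (the target set).
#' @param condition a [condition_spec()].
#' @return modified configuration.
#' @export
apply_condition <- function(config, condition) {
  stopifnot(inherits(condition, "condition_spec"))
  sc <- c(iks = 1 - condition$iks_block, ikr = 1 - condition$ikr_block,
          inak = 1 - condition$inak_inhibition)
  config <- scale_targets(config, sc)
  config$targets$ina$persist_scale <-
    config$targets$ina$persist_scale * condition$persistent_ina_scale
  if (condition$beta_ars) {
    config <- scale_targets(config, .bars_factors)
    config$targets$ical$f_tau_scale <-
      config$targets$ical$f_tau_scale * .bars_f_tau_scale
  }
  if (!is.null(condition$extra_scales)) {
    config <- scale_targets(config, condition$extra_scales)
  }
  config
}

#' Multi-domain calcium configuration
#'
#' Divides the cell's calcium handling into `n_domains` identical domains
#' (equal volumes and channel allocation) connected by diffusional exchange
#' with time constant `tau_diffusion`; membrane potential remains shared.
#'
#' @param n_domains integer >= 1.
#' @param tau_diffusion inter-domain diffusion time constant (ms).
#' @return a `domain_config`.
#' @export
domain_config <- function(n_domains = 1, tau_diffusion = 20) {
  stopifnot(n_domains >= 1, tau_diffusion > 0)
  structure(list(n_domains = as.integer(n_domains),
                 tau_diffusion = tau_diffusion),
            class = "domain_config")
}
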