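---
title: "Stochastic myocyte simulation and repolarization variability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic myocyte simulation and repolarization variability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and intent

bvrsim simulates beat-to-beat variability of repolarization duration (BVR)
in a reduced canine-like ventricular myocyte in which each of thirteen major
ionic currents and calcium-handling fluxes can be switched independently
between a deterministic formulation, explicit stochastic Markov channel
gating over integer channel counts, and a Langevin (chemical
stochastic-differential-equation) approximation. The cell model is
deliberately compact: the analysis machinery (APD90 detection, short- and
long-term variability, Poincare decomposition, membrane-current fluctuation
profiles, population-of-models regression, cable coupling) is model-agnostic
and would apply unchanged to a richer ionic model.

## The reduced myocyte

The membrane carries INa (a seven-state Markov chain: closed states C3-C2-C1,
an open state, a single inactivated state, and a two-state burst pathway
whose occupancy produces the persistent sodium current), ICaL (d and f gates
with calcium-dependent inactivation per calcium domain), Ito (a, i gates),
IKur (one activation gate), IKr (a five-state Markov chain with
published-style HERG rate shapes), IKs (two slow activation gates), IK1 (one
fast gate carrying the inward-rectifier profile), the NaK pump, the NaCa
exchanger, the sarcolemmal Ca pump, and the sarcoplasmic-reticulum fluxes
Jrel (a four-state ryanodine-receptor chain: closed, open, inactivated,
refractory), Jup (SERCA) and Jleak. Background Na/Ca/K leaks close the ion
budgets. Units: mV, ms, mM, pA/pF; conductances in mS/uF; single-channel
conductances in pS.

Channel counts derive from the whole-cell and single-channel conductance,
`N = 1000 * Gmax * Cm / g_single`, so a k-fold change in channel density
offset by a reciprocal change in single-channel conductance leaves every
deterministic property unchanged while scaling gating noise as `1/sqrt(k)`.

Three design choices matter for the emergent behavior:

* **IKr as the repolarization clock.** The plateau is a contest between ICaL
  inactivation and slowly activating IKr; IKur is small. The IKr closing
  pathway is additionally slowed four-fold relative to its activation
  template (`deact_scale = 0.25`, giving a deactivation time constant of
  roughly 3 s at the resting potential), so the channel's availability
  integrates diastolic time over several beats. This multi-beat rate memory
  is what makes BVR grow with cycle length *and* makes fixed-diastolic-
  interval pacing reproduce the fixed-cycle-length BVR relationship: a
  single-beat restitution memory would couple each beat's APD to the
  preceding diastolic interval and the two pacing modes would diverge.
  The corresponding trade-off is discussed under *Known limitations*.
* **Flux-triggered calcium release.** In a common-pool cell the bulk
  cytosolic calcium rise from ICaL alone is too small to trigger
  regenerative release reliably, so the ryanodine-receptor opening rate
  carries a term proportional to the local L-type current (the common-pool
  stand-in for subspace calcium) in addition to a steep (Hill-6) cytosolic
  calcium activation, both modulated by luminal-calcium sensitization that
  rises sharply when the SR content exceeds `k_csr` (2.6 mM). Below that
  threshold diastolic release is negligible; above it, spontaneous diastolic
  release appears, which is the substrate for the overload experiments.
* **Balanced backgrounds.** At construction the background conductances
  (Na, Ca, K, and the SR leak rate) are solved so that the configured
  resting state is an exact equilibrium of every ion species, whatever
  condition modifiers or scale factors are active. The K background carries
  the inward-rectifier voltage profile so the balancing leak cannot oppose
  the plateau. The cell therefore rests indefinitely without pacing, and
  every paced run starts from the same documented resting state with the
  initial transient removed by `n_discard`.

The control cell yields APD90 of about 175-190 ms at a cycle length (CL) of
1000 ms with a dome-plateau morphology, short-term variability (STV) of
2-3 ms in the fully stochastic configuration, and monotone APD and STV rate
dependence over CL 500-2000 ms. An APD90 nearer 250 ms is achievable, but in
this reduced current set it trades directly against the rate-dependence
signatures, which we prioritized as they are the scientific point of the
simulator.

## Stochastic gating formulations

**Markov sampling.** Integer occupancies move between states by multinomial
draws. Per sub-step, the number of channels leaving state i is binomial with
the exact single-channel departure probability `1 - exp(-r_tot * h)`, split
over destinations proportionally to their rates (sequential conditional
binomials). The expectation of one step equals the deterministic update to
O(h^2), counts are conserved exactly, and the update is stable for
arbitrarily stiff schemes. Sub-stepping keeps per-state exit probabilities
near 0.1 where affordable (at most 4 sub-steps per time step); beyond that,
the exponential departure probabilities remain exact for single transitions
and only multi-hop corrections within one step are neglected - these affect
the microdistribution among fast-flickering closed states, not the
conducting states. Binomial draws use exact Bernoulli counting for small
populations, waiting-time sampling for small means, and a Gaussian
approximation with continuity correction above a mean of 10 (the standard
numerical approximation for multinomial channel sampling at these scales).

**Deterministic mode.** State fractions relax by the same exponential
departures (two half-passes per step; exact for two-state schemes), which
agrees with forward Euler to O(dt^2) and is unconditionally stable.
Hodgkin-Huxley gates use Rush-Larsen updates.

**Langevin mode.** The chemical-Langevin diffusion term
`sqrt(f / N) * xi` is attached per transition to the deterministic drift.
The diffusion approximation is only valid when many reaction events occur
per step, so transitions expecting fewer than 10 events per step advance by
drift alone: without this validity gate, clamping the noise at the zero
boundary inflates rare conducting states (notably the sodium burst pathway)
and can latch the action-potential plateau. A consequence is that our
Langevin mode tracks the Markov mode closely rather than producing the
distinct long-term-dominated variability signature that other SDE
conventions can produce; the package demonstrates that signature on
synthetic AR(1) APD series instead.

**Transporters.** The NaK pump, NaCa exchanger, sarcolemmal Ca pump, SERCA
and the SR leak carry shot noise on their elementary transport events
(Poisson counts per step, Gaussian above 1e5 events). Because their
throughput per unit charge is enormous, their relative fluctuations are
negligible - reproducing the observation that high-density transporters
contribute little to BVR. The ryanodine receptor is a genuine sampled
channel population (default 20000 units).

**Random numbers.** Each cell and target owns an independent
`mt19937_64` stream derived from the master seed by SplitMix64 expansion,
so toggling one target's stochasticity or adding cells to a strand does not
perturb the draws of the others. Runs are bit-reproducible for a given
seed, configuration and platform.

## Integration scheme

A piecewise time step: 0.005 ms whenever the deterministic rate of change of
Vm exceeds 10 mV/ms or a stimulus is active, 0.05 ms elsewhere during the
action potential (Vm > -70 mV), 0.1 ms in diastole. Voltage and
concentrations advance by forward Euler; gates as described above; the
inter-domain calcium exchange relaxes deviations from the domain mean
exactly as `exp(-n_domains * dt / tau)`, conserving total calcium to
floating-point precision. Halving all time steps changes the control APD90
by well under 1 ms. Vm outside [-150, 100] mV aborts with a diagnostic
dump. Traces are recorded at 0.5 ms resolution.

## Protocols and analysis conventions

* **APD90**: per beat, amplitude = peak Vm minus pre-stimulus Vm (the
  pre-stimulus baseline is robust to delayed afterdepolarizations); APD90 is
  the time from the upstroke (first -40 mV crossing with dVm/dt > 5 mV/ms
  after stimulus onset) to the first downward crossing of baseline + 10% of
  the amplitude, linearly interpolated. Beats that never cross before the
  next stimulus are flagged repolarization failures and break the
  consecutive-beat runs used for statistics.
* **STV/LTV**: mean absolute successive difference / mean absolute deviation
  of successive-pair sums from twice the series mean, each divided by
  sqrt(2); the denominator counts pairs, so an alternating series with step
  D has STV exactly `D / sqrt(2)`. These equal the mean Poincare distances
  perpendicular to and along the identity line.
* **Stimulus**: rectangular, 0.5 ms, at 1.5x the diastolic threshold found
  by bisection on a deterministic copy of the cell at build time.
* **Fixed-DI pacing** schedules each stimulus at the online-detected APD90
  crossing plus the requested diastolic interval; the effective cycle
  length is reported as mean APD + DI.
* **Current injection** adds a constant deterministic current from upstroke
  detection to the APD90 crossing of each beat (terminated at the crossing
  regardless of any later depolarizations).
* **Vm-noise calibration** bisects the amplitude of a Gaussian term
  `alpha * sqrt(dt) * xi` added to the Vm update of the fully deterministic
  cell until its STV at the calibration CL matches a stochastic reference.
  We expose the calibration rather than a fixed amplitude because the
  matching value is model-specific.
* **Morphology presets** scale IK1, IKur, Ito and ICaL (simulated
  deterministically so the altered amplitudes add no gating noise of their
  own): triangular = IK1 x2.6, IKur x2.4, Ito x0.6, ICaL x1.6; square =
  IK1 x0.8, IKur x0.35, Ito x1.0, ICaL x0.75. These factors were re-tuned
  for the reduced model - the literature factors for fuller models
  destabilize it (the square preset collapses the dome into alternans).
* **Coupling** is gap-junctional conductance per capacitance (nS/pF) in a
  chain with sealed ends; all cells are stimulated simultaneously so the
  read-outs isolate repolarization coupling from conduction delays. Fully
  uncoupled cells run on independent adaptive timebases and are
  bit-identical to separate single-cell runs.
* **Condition modifiers** compose multiplicatively: LQT1 = fractional IKs
  block, LQT2 = fractional IKr block (a fractional reduction of available
  channels), LQT3 = multiplying the burst-pathway entry rate, partial NaK
  inhibition, and a phenomenological beta-adrenergic scale set (IKs x3.0,
  ICaL x1.5, SERCA x1.4, NaK x1.4, ICaL inactivation accelerated two-fold).
  The SERCA factor was chosen so the overload condition (full IKs block +
  10% NaK inhibition + beta-adrenergic stimulation at CL 500 ms) loads the
  SR to just above the spontaneous-release threshold, the borderline regime
  in which domain-resolved stochastic release widens the APD distribution.

## Population analysis

`sample_scales()` draws independent Gaussian per-target conductance factors
(default 200 trials, mean 1.0, SD 0.3, redrawn below 0.05); each trial is
rebuilt, re-balanced, paced with one fixed gating seed (so output
differences are attributable to the scale factors) and summarized as mean
APD, STV and LTV. `regress_sensitivity()` z-scores predictors and responses
and fits ordinary least squares per response. With a few hundred
near-orthogonal Gaussian predictors, OLS on z-scores is equivalent in
expectation to the partial-least-squares variant often used for this
analysis; we chose OLS for transparency. Failed trials become missing rows
and are dropped pairwise.

## What the synthetic generators emulate

`generate_apd_series()` produces stationary mean + AR(1) + white-noise APD
series: white noise mimics the uncorrelated beat-to-beat fluctuations of
Markov channel gating (circular Poincare cloud, STV = LTV), while a slow
AR(1) component mimics long-term-dominated variability (elongated cloud,
LTV > STV). `generate_stylized_trace()` builds piecewise-linear action
potentials with prescribed APD90 for exercising the detector. Neither
emulates morphology dynamics, rate adaptation or calcium handling; tests
built on them validate the analysis machinery, not cardiac physiology.

## Problem sizes used by the test-suite and acceptance script

Statistical read-outs use 40-50 analyzed beats after discarding 10-15
transient beats, with 6-10 gating seeds per condition; the density sweep
uses 50 analyzed beats and 10 seeds at CL 1000; the population analysis 60
trials of 35 analyzed beats; strands up to 8 cells with 3 seeds. These sizes
were chosen so the full battery runs on a laptop-class single core in well
under an hour while leaving each qualitative comparison several standard
errors of margin where the model provides one.

## Known limitations

* The equal-APD constraint for morphology presets is only achievable to
  about +-15% here: in a reduced action potential the four shaping currents
  control duration and shape jointly, so shape can not be varied at strictly
  constant APD. The variability ordering (square > control > triangular) is
  reproduced at those slightly mismatched durations.
* The pointwise fluctuation magnitude of the net membrane current falls
  with cycle length in this model (more IKr channels are available, and the
  SR is fuller, at short CL), so the area under the Std(Im) profile
  decreases with CL even though STV increases. The rate dependence of BVR
  here is carried by the intrinsic (duration/slope) pathway and the IKr
  availability memory rather than by a growing current-noise amplitude.
  This is a genuine departure of the reduced model from fuller ones, and it
  is reported honestly by the corresponding acceptance check.
* The asymmetric-pair coupling effect (a larger BVR reduction when an
  APD-prolonged cell is coupled to a normal one) is present but small at
  the -0.1 pA/pF injection used, because constant-current injection moves
  this model's APD only weakly.
* In the population regression, the INa conductance ranks among the top
  contributors for APD but not for STV: with one fixed gating seed per
  trial, across-trial STV differences are dominated by duration- and
  morphology-mediated effects (ICaL, Ito, INaK), while INa's direct
  square-root-of-scale noise effect ranks low. The direct stochastic-gating
  contribution of INa (an otherwise-deterministic cell with only INa
  stochastic) remains the largest of the thirteen targets.
* Common-pool calcium: no dyadic local control, no calcium waves; the
  four-domain option resolves domain-scale release heterogeneity only.
* The Langevin mode is a diffusion approximation with a validity gate (see
  above); it is not intended to reproduce alternative SDE conventions.
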