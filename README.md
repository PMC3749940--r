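# bvrsim

Stochastic simulation of a ventricular myocyte and analysis of
beat-to-beat variability of repolarization (BVR).

## The problem

Deterministic cardiac action-potential models converge to a fixed action
potential duration (APD) at a given pacing rate, so they cannot address a
question with direct proarrhythmic relevance: why does the APD of a real
myocyte fluctuate from beat to beat, which ionic processes drive those
fluctuations, and why do drugs that prolong repolarization amplify them?
bvrsim is a research tool for cardiac electrophysiologists and modelers
that answers such questions in a reduced canine-like ventricular myocyte
whose thirteen major ionic currents and Ca²⁺-handling fluxes — I_Na,
I_CaL, I_to, I_Kur, I_Kr, I_Ks, I_K1, I_NaK, I_NaCa, I_pCa, J_rel, J_up,
J_leak — can each be switched independently between deterministic gating,
explicit stochastic Markov gating over integer channel counts, and a
Langevin (SDE) approximation.

## The statistic at the core

APD is measured per beat at 90 % repolarization (APD90). Variability of the
series APD₁ … APDₙ is quantified, following the standard Poincaré
decomposition, as

    STV = Σ |APD_{i+1} − APD_i|             / (n_pairs · √2)
    LTV = Σ |APD_{i+1} + APD_i − 2·APD_mean| / (n_pairs · √2)

— the mean distances of the points (APD_i, APD_{i+1}) perpendicular to and
along the identity line. Channel counts follow from whole-cell and
single-channel conductance, N = 1000·G_max·C_m/g_single, so a k-fold change
in channel density at constant total conductance scales gating noise as
1/√k without touching any deterministic property.

The package provides pacing protocols (fixed cycle length and fixed
diastolic interval, constant current injection during the AP, Vm-noise
calibration, AP-morphology presets), condition modifiers (long-QT syndromes
1–3, β-adrenergic stimulation, partial Na⁺/K⁺-pump inhibition), coupled
cell pairs and 1-D strands, multi-domain Ca²⁺ handling with diffusional
exchange, and a population-of-models sensitivity analysis with standardized
regression.

## Worked example

```r
library(bvrsim)

cell  <- build_cell(default_cell_config("markov"), seed = 1)
proto <- pacing_protocol("fixed_CL", cl = 1000, n_beats = 65, n_discard = 15)
run   <- pace_fixed_cl(cell, proto, seed = 1)
bvr_summary(run$apd)
```

```
$stv
[1] 3.432857

$ltv
[1] 3.861294

$mean_apd
[1] 184.4747

$sd_apd
[1] 4.646106

$cv
[1] 2.518559

$n_beats
[1] 50
```

Fifty analyzed beats of the fully stochastic control cell at a cycle length
of 1000 ms: mean APD90 ≈ 184 ms with short-term variability ≈ 3.4 ms and a
coefficient of variation ≈ 2.5 % — the magnitude seen in isolated ventricular
myocytes. Block 60 % of I_Kr (a dofetilide-like LQT2 condition) and both the
APD and its variability rise:

```r
lqt2 <- build_cell(default_cell_config("markov"),
                   condition_spec(ikr_block = 0.6), seed = 1)
s <- bvr_summary(pace_fixed_cl(lqt2, proto, seed = 1)$apd)
round(c(apd = s$mean_apd, stv = s$stv), 1)
```

```
  apd   stv 
220.6   7.8 
```

A command-line interface wraps the same functions
(`inst/cli/bvrsim simulate --cl 1000 --n-beats 50 --seed 7`, plus `bvr`,
`sensitivity`, `pair`, `strand` and `calibrate-noise` subcommands).

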