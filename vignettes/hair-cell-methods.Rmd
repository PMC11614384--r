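---
title: "Models and methods for vestibular hair-cell electrophysiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for vestibular hair-cell electrophysiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vestephys)
```

This vignette documents the models behind `vestephys`: the cell simulator,
each analysis stage and its conventions, the numerical choices, and what
the validation on synthetic cells does and does not establish about real
recordings.

## Units and sign conventions

All quantities use mV, pA, ms, nS, pF and GΩ (series resistance appears in
metadata as MΩ). With these units the products work out without conversion
factors: nS·mV = pA, GΩ·pF = ms, mV/pA = GΩ. Outward current is positive.
The corrected membrane potential is `command − I·Rs,residual − LJP`, i.e.
a liquid junction potential reported as +4 mV makes the true membrane
potential 4 mV more negative than the command. The sources report only the
magnitude of the junction correction; the sign convention here is the
standard one (pipette potential minus junction potential) and is a
documented choice, not an inference.

## The cell model

A cell is a capacitance plus a set of conductances
`I = Σ g_max · mᵖ · h_mix · (V − E_rev)`. Every gate has a Boltzmann
steady state `B(V) = 1/(1 + exp((V½ − V)/S))`, with S > 0 for activation
and S < 0 for inactivation.

Two structural choices matter for validation:

* **Gate steady state.** For a conductance with gate power n the
  activation gate's steady state is `m∞ = B(V)^(1/n)`, so the steady-state
  conductance `g_max·m∞ⁿ = g_max·B(V)` is *exactly* Boltzmann in V. The
  G–V analysis therefore recovers the preset `V½`, `S`, and `g_max`
  without model error, and at fixed voltage the onset from rest follows
  `(1 − e^(−t/τ))ⁿ` — the activation template the kinetics module fits.

* **Inactivation.** Availability is
  `h_mix(t) = 1 − Z(V)·(f·u_f(t) + (1 − f)·u_s(t))`, with `u_f`, `u_s`
  first-order gates (time constants τ_zf < τ_zs) relaxing toward
  `1 − h∞(V)`. After a hyperpolarizing prestep both gates are ≈ 0, so a
  depolarizing step produces exactly the bi-exponential inactivation
  template with total depth `Z·(1 − h∞(V))`. Because the steady-state
  scaling is shared between both gates, the steady-state inactivation
  curve in conditioning voltage is exactly Boltzmann-shaped whatever the
  conditioning duration — only its amplitude depends on equilibration.

Time constants are voltage independent by default (an optional bell-shaped
τ(V) triple exists for realism). This keeps every fixed-voltage segment in
closed form, which is what makes the simulator auditable: the integrator's
fixed-voltage output must match `analytic_step_current` to floating-point
accuracy, and the test suite checks this across presets and step voltages.

### Integration

Voltage-clamp segments use the exact exponential gate solution. Current
clamp (and the optional non-ideal clamp, where the membrane charges
through the residual series resistance) uses an operator-split exponential
integrator: a Rush–Larsen update for each gate, then an exact linear
update of V with the conductances frozen over one step
(`dt = 0.005` ms by default). This scheme is unconditionally stable, which
matters because the wild-type type I cell has a membrane time constant of
tens of microseconds at rest. The suite cross-checks the integrator
against an independent adaptive ODE solver on a reference cell; agreement
is well under 0.2 mV.

### Presets

`make_preset(cell_type, genotype, zone)` assembles a cell from the
published group means: the large negatively activating conductance
(V½ −85 to −88 mV, S 4.3–5.2 mV, 210–310 nS) for wild-type/heterozygote
type I cells; for type II cells an A conductance (activation V½ −23 mV,
S 11.2 mV, h∞ midpoint −42 mV and slope 11 mV, density 2.6–5 nS/pF, τ_act
1.6–2.9 ms, τ_zf 15–300 ms by zone/genotype), a Kv1.8-type delayed
rectifier (steady-state V½ ≈ −25 to −28 mV, S 8.2–9 mV), and a Kv7-type
delayed rectifier (the conductance remaining in knockouts: V½ ≈ −19 to
−22 mV in type II, −38 to −40.2 mV in type I). All presets carry a lumped
HCN/Kir inward conductance (reversal −44 mV) and a leak.

Free parameters the sources do not print, fixed once here:

* τ for the type I low-voltage-activated conductance: 30 ms ("activates
  slowly"; any value ≫ the 1 ms tail-readout offset gives exact tail
  recovery).
* The HCN/Kir gate: midpoint −95 mV, slope 7 mV, τ 60 ms; sizes 3 nS
  (type I extrastriola), 1.5 nS (type I striola), 0.5 nS (type II).
* Kv7 activation τ: taken from the knockout activation time constants
  (4.4–10 ms in type II, 6 ms in type I).
* Slow inactivation of the type II Kv1.8 delayed rectifier: Z = 0.8 with
  τ_zs = 200 ms. This reconciles an internal tension in the published
  group means: the peak (≈11 nS/pF) and 200 ms steady-state (7.1 nS/pF)
  conductance densities alone imply only ~36% whole-cell inactivation at
  +30 mV, while the printed inactivation percentage is 45 ± 2%. Giving
  the delayed rectifier deep slow inactivation reproduces both the
  steady-state density and the ~45% figure; the cost is that this
  component, alone, would itself lose ~47% in 200 ms — acceptable because
  it never occurs alone in any preset.
* The Kv1.8 delayed-rectifier size is then solved per preset so that the
  summed steady-state conductance at 200 ms matches the published density.

The leak of each preset is calibrated by `calibrate_leak`: solve
`(g_L, E_L)` so that the zero-current potential and the slope resistance
match the published resting potential and input resistance. When the gated
conductances already exceed the target slope conductance — the wild-type
type I case, where the simulated input resistance (≈4–5 MΩ) is necessarily
lower than the reported 44 MΩ once the full 270 nS conductance is present —
only the resting potential is matched. Direction contrasts (knockout vs
wild type) are preserved either way.

`make_cell_variant` adds between-cell variability (log-normal conductance
scaling, CV 0.12; Gaussian midpoint jitter, SD 1 mV) for cohort
simulations; these values are a plausible scale of biological scatter and
are fixed, not tuned.

## Analysis conventions

* **Tail G–V**: current at the sample nearest 1 ms after the step end,
  divided by the tail driving force (tail at −44 mV, E_K from the
  solutions ≈ −86.1 mV). No interpolation: at ≥10 kHz the placement error
  is <0.1 ms. Reported `g_max` for a fit is `Gmin + Gmax`, the saturating
  conductance of the Boltzmann — with a 1 ms readout the small uniform
  deactivation/activation offset lands in `Gmin` and the saturating total
  recovers the underlying conductance.
* **Peak/steady-state G–V**: peak from the fitted kinetic model by default
  (raw maximum after 0.5 ms capacitive blanking as fallback); steady state
  at 1 ms before the end of a ≥200 ms step. Steps within 1 mV of E_K are
  dropped.
* **Steady-state inactivation**: conditioning steps (500 ms, −124 to
  0 mV) followed by the −44 mV tail. The readout is taken 15 ms into the
  tail — after the activation gates have re-equilibrated there — because
  an early "peak" reading indexes the activation state carried over from
  depolarized conditioning (channels still open), not availability. After
  settling, the tail current is an affine function of the inactivated
  fraction, so the normalized curve is exactly Boltzmann-shaped and the
  fit recovers the h∞ midpoint and slope (to ~0.1 mV and a few percent on
  noiseless presets).
* **Kinetics**: fits start 0.5 ms after step onset; n is fixed at 3;
  τ_zs is parameterized as `τ_zf(1 + e^u)` so the ordering constraint can
  never pin the optimizer at a boundary and swapped starting guesses
  converge to the same canonical fit. Model selection compares the full
  model's adjusted R² against the single-exponential (activation-only)
  fit; f is freed only for an improvement strictly greater than 0.01.
  The comparison baseline matters: against the slow-inactivation-only
  model even strongly fast-inactivating traces gain only ~0.003 adjusted
  R² (a single free exponential approximates a bi-exponential decay that
  well), which would leave f always constrained — inconsistent with the
  fast-inactivation parameters the population tables report. The
  activation-only baseline selects the full model on A-current-like
  traces and the constrained model on delayed rectifiers, as intended.
* **Passive properties**: input resistance is the mean of ΔV_ss/ΔI over
  all responses below 15 mV, averaging polarities so first-order
  rectification cancels; the time constant comes from a single-exponential
  fit of the charging onset (to the first extremum) of the smallest
  depolarizing response, because hyperpolarizing responses engage the HCN
  sag. `cm_est = τ/R_in` by construction.
* **Capacitance from the clamp transient**: a ≤10 mV step delivered
  negative to −90 mV with the electrode model active; exponential fit of
  the decay, `Rs = ΔV/I(0)`, `R_in` from the steady-state current change
  relative to the prestep baseline, `Cm = τ(1/Rs + 1/R_in)`.
* **Resonance**: the damped-sinusoid model is fitted with time inside the
  sinusoid argument, `sin(2π f_e t − θ)`, the dimensionally consistent
  standard form, with t measured from the start of the fit window.
  The fit window runs from the first half-maximum crossing of the initial
  depolarizing peak (found on a 1 ms median-smoothed copy; raw samples are
  fitted) to the step end; multi-starts over θ and over frequency guesses
  from zero crossings avoid phase local minima. `f_e` is bounded below by
  0 so overdamped responses converge to the `Q_e = 0.5` limit.
* **Pharmacology**: sweep pairing by step voltage (1 mV tolerance),
  steady state as the mean of the final 10 ms, no rundown correction
  (none was applied in the source workflow either). The XE991 emulation
  halves the Kv7 conductance (10 µM is near the half-blocking
  concentration); iberiotoxin targets BK channels, which the model does
  not carry, so its measured block is 0 — consistent with the reported
  2 ± 6%.
* **Statistics**: Shapiro–Wilk for group sizes ≤50 (the n = 50 boundary is
  unassigned in the sources; it is grouped with the small-sample test
  here), Kolmogorov–Smirnov above, Levene's test for variance homogeneity,
  then ANOVA + Tukey / Welch + Games–Howell / Kruskal–Wallis + Dunn.
  Games–Howell and Dunn are computed from their standard formulas
  (studentized range with Welch degrees of freedom; rank-based z with tie
  correction, Holm-adjusted). Hedge's g uses the exact gamma-function
  small-sample correction. Age dependence is a partial correlation after
  residualizing on dummy-coded genotype and zone.

## What the synthetic validation shows — and what it does not

The generator reproduces the *structure* of the study's data: protocol
timing, conductance families with the published voltage dependence and
kinetics, passive properties, seeded Gaussian recording noise, and
(optionally) series-resistance and junction-potential artifacts. Passing
recovery tests therefore establishes that the analysis chain is correct
and unbiased for data of this form, at these SNRs.

It does not establish robustness to everything real recordings contain:
K⁺ accumulation in the calyceal cleft (which makes large tail currents
decay), rundown across drug epochs, seal leak and drift, temperature
variation, or truly voltage-dependent time constants. Population means in
the simulated cohorts are means over the preset variability model, not
over biology; simulated group contrasts are therefore direction checks,
not effect-size reproductions.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by design:
16-step protocols at 50 kHz output, 50-seed noise studies for the kinetic
fits, three cells per group for cohort direction checks, and 10⁴
replicates per dispatch path for the type-I-error calibration. All are
fixed choices; enlarging them changes runtimes, not conclusions.

## Known limitations

* The wild-type type I input resistance cannot be matched simultaneously
  with the full-size conductance (see Presets); reported table values for
  that group likely reflect in-situ factors the model omits.
* Whole-cell kinetic fits on *composite* simulated type II currents yield
  effective parameters (e.g. τ_act ≈ 2.5 ms, smaller f) rather than the
  single-conductance values, because several conductances with different
  kinetics overlap; single-conductance fixtures recover the published
  values exactly.
* The h∞ readout convention (15 ms settle) is required by the physics of
  the tail measurement; with a protocol using a strongly depolarized test
  step instead of the −44 mV tail, a true peak readout would work as
  well.
* `Sweep` supports only uniform time grids; vendor acquisition formats
  are out of scope (the on-disk format is `meta.json` plus one delimited
  file per sweep).
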