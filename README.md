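# vestephys

Analysis of whole-cell patch-clamp recordings from vestibular hair cells,
with a conductance-based simulator of those cells.

## The scientific problem

Vestibular type I and type II hair cells carry strikingly different
outwardly rectifying K⁺ conductances. Mature type I cells express g_K,L — a
very large, non-inactivating conductance with an unusually negative
activation midpoint (V½ ≈ −85 mV) — which holds the resting potential near
E_K, collapses input resistance to tens of MΩ, and makes voltage responses
fast and linear. Type II cells instead carry a fast-inactivating A-type
conductance (g_A) plus delayed rectifiers that activate positive to rest;
losing them raises input resistance and unmasks electrical resonance.
Quantifying these phenotypes from voltage-clamp and current-clamp data
requires a consistent chain of analyses, which this package implements:

- **Conductance–voltage relations** from tail, peak, and steady-state
  currents, `G = I / (V − E_K)`, fitted with the first-order Boltzmann

  `G(V) = Gmin + Gmax / (1 + exp((V½ − V) / S))`

- **Activation/inactivation kinetics** at fixed voltage,

  `I(t) = Imax (1 − e^(−t/τw))ⁿ [1 − Z(f(1 − e^(−t/τzf)) + (1 − f)(1 − e^(−t/τzs)))] + I₀`

  with n fixed at 3, an adjusted-R² rule that constrains the fast fraction
  f to 0 when it does not improve on a single-exponential fit by more than
  0.01, percent inactivation `100(Ipeak − Iss)/Ipeak`, and the A-current
  classification rule (inactivates by >30% within 200 ms).

- **Passive membrane properties**: resting potential, input resistance
  ΔV/ΔI from small current steps, membrane time constant from
  single-exponential charging fits, and capacitance from the decay of the
  clamp transient via the two-resistor model `Cm = τ(1/Rs + 1/Rin)`.

- **Electrical resonance**: damped-sinusoid fits
  `V(t) = Vss + Vp e^(−t/τe) sin(2π fe t − θ)` from the half-maximum of the
  initial peak to the step end, with quality factor
  `Qe = sqrt((π fe τe)² + 0.25)`.

- **Pharmacological subtraction**: control-minus-drug traces, percent block
  of steady-state current, and Boltzmann fits of the drug-sensitive
  conductance (the XE991/K_V7 workflow).

- **Statistics**: the normality/variance-homogeneity dispatch
  (two-way ANOVA + Tukey, Welch ANOVA + Games–Howell, or Kruskal–Wallis +
  Dunn), Hedge's g effect sizes, mean ± SEM summary tables, and age
  partial correlations.

A Hodgkin–Huxley-style simulator (`make_preset`, `simulate_voltage_clamp`,
`simulate_current_clamp`) generates recordings from genotype/zone/cell-type
presets whose gating parameters are the published group means, so every
analysis stage can be validated against known ground truth. An exact
closed-form gate solution (`analytic_step_current`) serves as the
fixed-voltage oracle.

## Worked example

```r
library(vestephys)

# a wild-type type I hair cell, extrastriolar zone
cell <- make_preset("type_I", "+/+", "LES")
rec  <- simulate_voltage_clamp(cell, build_protocol("type_I"))
fit  <- fit_boltzmann(extract_tail_gv(rec))
print(fit)
#> Boltzmann fit (tail): V_half -84.87 mV, S 4.46 mV, Gmax 265 nS (Gmin 4.92, saturating 270)
#>   16 points, RSS 30.74
```

The tail G–V analysis of the simulated cell recovers the conductance it was
built from: midpoint −84.9 mV, slope 4.5 mV, saturating conductance 270 nS
— the signature of g_K,L. The knockout preset retains only a small
delayed rectifier near −40 mV:

```r
ko <- make_preset("type_I", "-/-", "LES")
fit_boltzmann(extract_tail_gv(simulate_voltage_clamp(
  ko, build_protocol("type_I", step_voltages = seq(-124, 40, 10)))))
#> Boltzmann fit (tail): V_half -40.20 mV, S 5.70 mV, Gmax 4.57 nS (Gmin 0.294, saturating 4.87)
```

Current-clamp analysis of the same two presets shows the passive-property
phenotype (knockouts rest less negative, with input resistance higher by
more than an order of magnitude):

```r
fit_passive_response(simulate_current_clamp(ko, c(-2, 2, 5),
                     config = sim_config(out_dt = 0.005)))
#> Passive fit: V_rest -63.0 mV, R_in 1.26 GOhm, tauRC 7.11 ms, Cm 5.63 pF (step 2 pA)
```

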