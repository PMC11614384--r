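# Conductance-based hair-cell model: gate specifications, conductance
# specifications, and whole-cell models.
#
# Gating convention: every gate has a Boltzmann steady state
#   B(V) = 1 / (1 + exp((v_half - V) / s))
# with s > 0 for activation (increasing with V) and s < 0 for inactivation
# (decreasing with V). For a conductance with gate power n, the activation
# gate steady state is m_inf = B^(1/n), so that the steady-state conductance
# g_max * m_inf^n is exactly Boltzmann in V -- the form the analysis module
# fits. Inactivation is a weighted pair of first-order gates reproducing
#   h_mix(t) = 1 - Z*(f*(1 - exp(-t/tau_zf)) + (1-f)*(1 - exp(-t/tau_zs)))
# at fixed voltage, with the steady-state inactivated fraction scaled by the
# h-infinity curve so the depth of inactivation is voltage dependent.

#' Gate specification
#'
#' @param v_half Boltzmann midpoint, mV.
#' @param s Slope factor, mV; positive for activation, negative for
#'   inactivation.
#' @param tau Time constant: a single positive number (ms,
#'   voltage-independent) or a triple `c(tau_max, v_peak, width)` describing
#'   a bell-shaped tau(V) (ms, mV, mV).
#' @param power Integer gate exponent (>= 1).
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(v_half, s, tau, power = 1L) {
  if (!length(tau) %in% c(1L, 3L)) stop("tau must be length 1 or 3")
  if (any(tau[1] <= 0)) stop("tau must be positive")
  if (power < 1) stop("power must be >= 1")
  structure(list(v_half = unname(v_half), s = unname(s),
                 tau = unname(as.numeric(tau)), power = as.integer(power)),
            class = "gate_spec")
}

# Boltzmann steady state of a gate's underlying conductance factor.
boltz <- function(v, v_half, s) 1 / (1 + exp((v_half - v) / s))

gate_tau <- function(gate, v) {
  if (length(gate$tau) == 1L) return(rep(gate$tau, length.out = length(v)))
  tmax <- gate$tau[1]; vp <- gate$tau[2]; w <- gate$tau[3]
  0.1 + (tmax - 0.1) * exp(-((v - vp) / w)^2)
}

# Steady state of the activation *gate* variable (conductance factor^(1/n)).
gate_minf <- function(gate, v) boltz(v, gate$v_half, gate$s)^(1 / gate$power)

#' Conductance specification
#'
#' Bundles maximal conductance, reversal potential, activation gating and
#' (optionally) bi-exponential inactivation. `z_total` is the total
#' steady-state inactivation depth at strongly depolarized potentials
#' (0 <= z < 1; 0 disables inactivation) and `f_fast` the fraction carried by
#' the fast gate. `inact_fast`/`inact_slow` share the h-infinity midpoint and
#' slope but have their own time constants.
#'
#' @param name Label, e.g. `"gKL"`, `"gA"`, `"gDR_Kv1.8"`, `"gDR_Kv7"`,
#'   `"gHCN_Kir"`, `"gLeak"`.
#' @param g_max Maximal conductance, nS.
#' @param e_rev Reversal potential, mV.
#' @param activation A [gate_spec()] or `NULL` for an ohmic (leak)
#'   conductance.
#' @param inact_fast,inact_slow [gate_spec()]s for the fast/slow inactivation
#'   gates (s < 0), or `NULL`.
#' @param z_total Steady-state inactivation depth, in `[0, 1)`.
#' @param f_fast Fraction of inactivation carried by the fast gate, `[0, 1]`.
#' @return An object of class `conductance_spec`.
#' @export
conductance_spec <- function(name, g_max, e_rev, activation = NULL,
                             inact_fast = NULL, inact_slow = NULL,
                             z_total = 0, f_fast = 0) {
  if (g_max < 0) stop("g_max must be non-negative")
  if (z_total < 0 || z_total >= 1) stop("z_total must be in [0, 1)")
  if (f_fast < 0 || f_fast > 1) stop("f_fast must be in [0, 1]")
  if (!is.null(inact_fast) && !is.null(inact_slow) &&
      inact_fast$tau[1] >= inact_slow$tau[1])
    stop("fast inactivation tau must be smaller than slow tau")
  structure(list(name = name, g_max = g_max, e_rev = e_rev,
                 activation = activation, inact_fast = inact_fast,
                 inact_slow = inact_slow, z_total = z_total,
                 f_fast = f_fast),
            class = "conductance_spec")
}

#' @export
print.conductance_spec <- function(x, ...) {
  act <- if (is.null(x$activation)) "ohmic"
         else sprintf("V1/2 %g mV, S %g mV, n %d", x$activation$v_half,
                      x$activation$s, x$activation$power)
  cat(sprintf("<conductance_spec> %s: g_max %g nS, E %g mV, %s%s\n",
              x$name, x$g_max, x$e_rev, act,
              if (x$z_total > 0) sprintf(", Z %g f %g", x$z_total, x$f_fast)
              else ""))
  invisible(x)
}

#' Whole-cell model
#'
#' @param cm Membrane capacitance, pF.
#' @param conductances List of [conductance_spec()]s.
#' @param e_k Potassium equilibrium potential, mV.
#' @param label Preset identifier.
#' @return An object of class `cell_model`.
#' @export
cell_model <- function(cm, conductances, e_k = nernst_potential(165, 5.77, 25),
                       label = "custom") {
  if (cm <= 0) stop("cm must be positive")
  stopifnot(all(vapply(conductances, inherits, TRUE, "conductance_spec")))
  structure(list(cm = cm, conductances = conductances, e_k = e_k,
                 label = label),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model> %s: Cm %g pF, E_K %.1f mV, %d conductance(s)\n",
              x$label, x$cm, x$e_k, length(x$conductances)))
  for (g in x$conductances) print(g)
  invisible(x)
}

# Equilibrium gate state of one conductance at voltage v:
# list(m, uf, us) where u are the inactivated-fraction gates.
gate_equilibrium <- function(spec, v) {
  m <- if (is.null(spec$activation)) 1 else gate_minf(spec$activation, v)
  uf <- if (is.null(spec$inact_fast)) 0 else
    1 - boltz(v, spec$inact_fast$v_half, spec$inact_fast$s)
  us <- if (is.null(spec$inact_slow)) 0 else
    1 - boltz(v, spec$inact_slow$v_half, spec$inact_slow$s)
  list(m = m, uf = uf, us = us)
}

# Availability factor given inactivation gate values.
avail_factor <- function(spec, uf, us) {
  if (spec$z_total == 0) return(rep(1, length.out = max(length(uf), 1L)))
  1 - spec$z_total * (spec$f_fast * uf + (1 - spec$f_fast) * us)
}

# Instantaneous conductance (nS) given gate states.
conductance_now <- function(spec, m, uf, us) {
  act <- if (is.null(spec$activation)) 1 else m^spec$activation$power
  spec$g_max * act * avail_factor(spec, uf, us)
}

# Steady-state whole-cell current (pA) at voltage v (vectorised over v).
steady_state_current <- function(cell, v) {
  total <- numeric(length(v))
  for (spec in cell$conductances) {
    act <- if (is.null(spec$activation)) 1
           else boltz(v, spec$activation$v_half, spec$activation$s)
    uf <- if (is.null(spec$inact_fast)) 0 else
      1 - boltz(v, spec$inact_fast$v_half, spec$inact_fast$s)
    us <- if (is.null(spec$inact_slow)) 0 else
      1 - boltz(v, spec$inact_slow$v_half, spec$inact_slow$s)
    total <- total + spec$g_max * act * avail_factor(spec, uf, us) *
      (v - spec$e_rev)
  }
  total
}

# Zero-current (resting) potential of a model, mV.
zero_current_potential <- function(cell, lower = -120, upper = 20) {
  f <- function(v) steady_state_current(cell, v)
  stats::uniroot(f, c(lower, upper), tol = 1e-10)$root
}

# Slope conductance dI/dV (nS) at voltage v, by central difference.
slope_conductance <- function(cell, v, h = 0.01) {
  (steady_state_current(cell, v + h) - steady_state_current(cell, v - h)) /
    (2 * h)
}
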