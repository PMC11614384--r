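# Shared fixture builders. All fixtures are generated in code.

e_k_std <- vestephys::nernst_potential(165, 5.77, 25)

# A pure RC cell (leak only).
rc_cell <- function(r_in = 1, cm = 5, e_rev = -70) {
  cell_model(cm = cm, label = "rc",
             conductances = list(
               conductance_spec("gLeak", g_max = 1 / r_in, e_rev = e_rev)))
}

# A-current-like conductance with the published kinetic parameters as truth.
ga_spec <- function(g_max = 20, tau_w = 2.11, z = 0.45, f = 0.46,
                    tau_zf = 23, tau_zs = 200, v_half_act = -23,
                    s_act = 11.2, hinf_vhalf = -70, hinf_s = 11) {
  # hinf_vhalf = -70 keeps the inactivation gates saturated at +30 mV so
  # that the fixture's effective Z equals z exactly.
  conductance_spec("gA", g_max = g_max, e_rev = e_k_std,
    activation = gate_spec(v_half_act, s_act, tau = tau_w, power = 3),
    inact_fast = gate_spec(hinf_vhalf, -hinf_s, tau = tau_zf),
    inact_slow = gate_spec(hinf_vhalf, -hinf_s, tau = tau_zs),
    z_total = z, f_fast = f)
}

# Non-inactivating delayed rectifier.
dr_spec <- function(g_max = 20, v_half = -25, s = 8.7, tau = 2.5) {
  conductance_spec("gDR", g_max = g_max, e_rev = e_k_std,
    activation = gate_spec(v_half, s, tau = tau, power = 3))
}

# Current-clamp sweep holding an exact damped sinusoid in its step segment.
damped_sinusoid_sweep <- function(f_e, tau_e, v_ss = -50, v_p = 8,
                                  theta = pi / 2, step_dur = 400,
                                  dt = 0.1, v_rest = -65) {
  t_base <- seq(0, 100 - dt, by = dt)
  t_step <- seq(0, step_dur - dt, by = dt)
  v_step <- v_ss + v_p * exp(-t_step / tau_e) *
    sin(2 * pi * f_e * t_step * 1e-3 - theta)
  hc_sweep(c(t_base, 100 + t_step),
           rep(c(0, 30), c(length(t_base), length(t_step))),
           c(rep(v_rest, length(t_base)), v_step),
           mode = "current_clamp",
           segments = list(baseline = c(0, 100),
                           step = c(100, 100 + step_dur)))
}

# Eq-2/Eq-3-form traces evaluated directly (independent of the simulator).
eq2_trace <- function(t, i_ss, tau_w, n = 3, i_0 = 0) {
  i_ss * (1 - exp(-t / tau_w))^n + i_0
}

eq3_trace <- function(t, i_max, tau_w, z, f, tau_zf, tau_zs, n = 3,
                      i_0 = 0) {
  i_max * (1 - exp(-t / tau_w))^n *
    (1 - z * (f * (1 - exp(-t / tau_zf)) +
              (1 - f) * (1 - exp(-t / tau_zs)))) + i_0
}
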