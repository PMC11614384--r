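# G-V extraction, Boltzmann fitting, h-infinity curves, densities.

test_that("tail conductance is current over driving force at +1 ms", {
  # hand-built sweep: 50 pA at the sample 1 ms after step end, tail -44 mV
  proto <- step_protocol(-74, -124, 10, c(-60), 10, -44, 10,
                         holding_dur = 5)
  segs <- vestephys:::protocol_segments(proto)
  t <- seq(0, 35 - 0.1, by = 0.1)
  i <- rep(0, length(t))
  i[which.min(abs(t - (segs$tail[1] + 1)))] <- 50
  sw <- hc_sweep(t, rep(-60, length(t)), i, "voltage_clamp",
                 segments = segs)
  meta <- recording_meta()
  curve <- extract_tail_gv(hc_recording(meta, proto, list(sw)),
                           e_k = -86.1)
  expect_equal(curve$g, 50 / (-44 + 86.1), tolerance = 1e-9)
  # degenerate driving force
  proto2 <- step_protocol(-74, -124, 10, c(-60), 10, -86.1, 10,
                          holding_dur = 5)
  sw2 <- hc_sweep(t, rep(-60, length(t)), i, "voltage_clamp",
                  segments = vestephys:::protocol_segments(proto2))
  expect_error(extract_tail_gv(hc_recording(meta, proto2, list(sw2)),
                               e_k = -86.1), "driving force")
})

test_that("zero-conductance recordings give zero tail conductance", {
  cell <- cell_model(cm = 5, conductances = list(
    conductance_spec("gLeak", g_max = 0, e_rev = -70)), label = "null")
  rec <- simulate_voltage_clamp(
    cell, build_protocol("type_I", step_voltages = seq(-124, -24, 20)))
  curve <- extract_tail_gv(rec)
  expect_true(all(abs(curve$g) < 1e-9))
})

test_that("fit_boltzmann recovers exact curves and scales correctly", {
  v <- seq(-80, 0, by = 5)
  g <- 0 + 1 / (1 + exp((-40 - v) / 6))
  fit <- fit_boltzmann(gv_curve(v, g, "tail", e_k = -86))
  expect_equal(fit$v_half, -40, tolerance = 1e-4)
  expect_equal(fit$s, 6, tolerance = 1e-4)
  expect_equal(fit$g_max, 1, tolerance = 1e-4)
  expect_equal(fit$g_min, 0, tolerance = 1e-4)
  # scale invariance: V_half and S unchanged, amplitudes scale
  fit10 <- fit_boltzmann(gv_curve(v, 10 * g, "tail", e_k = -86))
  expect_equal(fit10$v_half, fit$v_half, tolerance = 1e-6)
  expect_equal(fit10$s, fit$s, tolerance = 1e-6)
  expect_equal(fit10$g_sat, 10 * fit$g_sat, tolerance = 1e-6)
  expect_error(fit_boltzmann(gv_curve(v[1:4], g[1:4], "tail", -86)),
               "5 points")
})

test_that("noisy Boltzmann fits recover the midpoint to sub-mV accuracy", {
  v <- seq(-124, 30, by = 10)
  g_true <- 270 / (1 + exp((-85 - v) / 4.3))
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    g <- g_true + stats::rnorm(length(v), 0, 0.02 * max(g_true))
    fit_boltzmann(gv_curve(v, g, "tail", -86))$v_half - (-85)
  }, 0)
  expect_lt(stats::median(abs(errs)), 0.5)
})

test_that("tail- and step-based midpoints agree for a non-inactivating g", {
  # first-order gate: the tail current is then exactly linear in the
  # steady-state activation, so both measures see the same midpoint
  cell <- cell_model(cm = 5, label = "dr", conductances = list(
    conductance_spec("gDR", g_max = 20, e_rev = e_k_std,
                     activation = gate_spec(-30, 7, tau = 3, power = 1)),
    conductance_spec("gLeak", g_max = 0.2, e_rev = -86.15)))
  rec <- simulate_voltage_clamp(
    cell, build_protocol("type_II", step_voltages = seq(-74, 30, 8)))
  tail_fit <- fit_boltzmann(extract_tail_gv(rec))
  curves <- extract_peak_ss_gv(rec, use_fit = FALSE)
  ss_fit <- fit_boltzmann(curves$steady_state)
  expect_lt(abs(tail_fit$v_half - ss_fit$v_half), 1)
  # without inactivation, peak and steady-state conductance agree
  expect_equal(curves$peak$g, curves$steady_state$g, tolerance = 0.02)
})

test_that("type II steady-state and peak G-V behave like the population", {
  cell <- make_preset("type_II", "+/+", "LES")
  rec <- simulate_voltage_clamp(cell, build_protocol("type_II"))
  curves <- extract_peak_ss_gv(rec, use_fit = FALSE)
  ss_fit <- fit_boltzmann(curves$steady_state)
  # composite of Kv1.8 DR (-25 mV) with smaller Kv7/A components
  expect_lt(abs(ss_fit$v_half - (-25)), 3)
  # peak G-V sits above steady state at +30 mV (A current contributes)
  k30 <- which.min(abs(curves$peak$step_v - 30))
  expect_gt(curves$peak$g[k30], curves$steady_state$g[k30])
  # a step near -124 reports the inward HCN/Kir current
  expect_lt(curves$i_inward_124, 0)
})

test_that("peak/steady-state ratio reflects the inactivation depth (Z = 0.45)", {
  spec <- ga_spec(g_max = 20, z = 0.45)
  t <- seq(0, 200, by = 0.05)
  i <- analytic_step_current(spec, 30, t)
  pct <- percent_inactivation(max(i), i[length(i)])
  # independent template evaluation of the same parameters
  b <- 1 / (1 + exp((-23 - 30) / 11.2))
  ref <- eq3_trace(t, i_max = 20 * b * (30 - e_k_std), tau_w = 2.11,
                   z = 0.45, f = 0.46, tau_zf = 23, tau_zs = 200)
  pct_ref <- percent_inactivation(max(ref), ref[length(ref)])
  expect_equal(pct, pct_ref, tolerance = 1e-3)
  # the 200 ms readout understates the full asymptotic depth 100*Z
  expect_lt(pct, 45)
  expect_gt(pct, 25)
})

test_that("h-infinity protocol recovers the inactivation midpoint", {
  cell <- make_preset("type_II", "+/+", "LES")
  rec <- simulate_voltage_clamp(cell, build_protocol("inactivation"))
  fit <- fit_inactivation_curve(rec)
  expect_lt(abs(fit$v_half - (-42)), 2.5)
  expect_equal(fit$s, 11, tolerance = 0.1)
  expect_gt(fit$s, 0) # reported positive by convention
  # normalization anchor: the most negative conditioning voltage gives 1
  expect_equal(max(fit$data$g), 1)
  expect_equal(fit$data$g[1], 1, tolerance = 0.01)
})

test_that("a conductance without inactivation gives a flat, degenerate curve", {
  cell <- cell_model(cm = 5, label = "dr", conductances = list(
    dr_spec(g_max = 10, v_half = -25, s = 9, tau = 2.5),
    conductance_spec("gLeak", g_max = 0.2, e_rev = -86.15)))
  rec <- simulate_voltage_clamp(cell, build_protocol("inactivation"))
  fit <- suppressWarnings(fit_inactivation_curve(rec))
  expect_true(fit$degenerate)
  expect_lt(diff(range(fit$data$g)), 0.05)
})

test_that("conductance density is a guarded ratio", {
  expect_equal(conductance_density(270, 6.1), 270 / 6.1)
  expect_equal(conductance_density(5.4, 5.0), 1.08)
  expect_equal(conductance_density(0, 3), 0)
  expect_error(conductance_density(10, 0), "cm")
})
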