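# Passive membrane properties, capacitance from clamp transients,
# resonance fits, quality factor, peak metrics.

test_that("resting potential is the pre-step baseline mean", {
  t <- seq(0, 200 - 0.1, by = 0.1)
  cmd <- rep(c(0, 10), each = length(t) / 2)
  v <- rep(c(-87, -80), each = length(t) / 2)
  sw <- hc_sweep(t, cmd, v, "current_clamp",
                 segments = list(baseline = c(0, 100), step = c(100, 200)))
  expect_equal(resting_potential(sw), -87)
  set.seed(1)
  swn <- sw; swn$response <- swn$response + rnorm(length(t), 0, 0.5)
  expect_equal(resting_potential(swn), -87, tolerance = 0.05)
  swv <- hc_sweep(t, rep(10, length(t)), v, "current_clamp",
                  segments = list(step = c(100, 200)))
  expect_error(resting_potential(swv), "baseline")
})

test_that("passive fit recovers RC cells exactly and keeps the identity", {
  for (r in c(0.05, 1, 3)) {
    cell <- rc_cell(r_in = r, cm = 5)
    steps <- c(-8, 8) / r # ~8 mV deflections
    cc <- simulate_current_clamp(cell, steps, step_dur = max(100, 10 * r * 5),
                                 config = sim_config(out_dt = 0.005))
    p <- fit_passive_response(cc)
    expect_equal(p$r_in, r, tolerance = 0.02)
    expect_equal(p$tau_rc, r * 5, tolerance = 0.02)
    expect_equal(p$cm_est, p$tau_rc / p$r_in, tolerance = 1e-12)
  }
  # all-large responses are rejected with advice
  cell <- rc_cell(r_in = 1, cm = 5)
  cc_big <- simulate_current_clamp(cell, c(40), step_dur = 100)
  expect_error(fit_passive_response(cc_big), "smaller current steps")
})

test_that("knockout type I passive properties approximate the population", {
  cc <- simulate_current_clamp(make_preset("type_I", "-/-", "LES"),
                               c(-2, 2, 5),
                               config = sim_config(out_dt = 0.005))
  p <- fit_passive_response(cc)
  expect_equal(p$r_in, 1.4, tolerance = 0.25)
  expect_equal(p$tau_rc, 6.4, tolerance = 0.25)
})

test_that("resting potential orders by genotype in type I cells", {
  v_wt <- vestephys:::zero_current_potential(make_preset("type_I", "+/+",
                                                         "LES"))
  v_ko <- vestephys:::zero_current_potential(make_preset("type_I", "-/-",
                                                         "LES"))
  expect_gt(v_ko, v_wt) # knockout rests less negative
  expect_lt(abs(v_wt - (-84)), 0.5)
})

test_that("capacitance is recovered from the clamp transient", {
  mkvc <- function(cm, dv) {
    cell <- cell_model(cm = cm, label = "rc", conductances = list(
      conductance_spec("gLeak", g_max = 1, e_rev = -70)))
    simulate_voltage_clamp(
      cell,
      build_protocol("type_I", step_voltages = c(-94 - dv),
                     prestep_v = -94, prestep_dur = 50, step_dur = 50),
      config = sim_config(rs_artifact = TRUE, rs_total = 10,
                          rs_compensation = 0.8, ljp = 0, dt = 0.002,
                          out_dt = 0.002))
  }
  cm6 <- estimate_cm_transient(mkvc(6, 10))
  expect_equal(as.numeric(cm6), 6, tolerance = 0.05)
  # scale invariance: halving the step leaves the estimate unchanged
  cm6b <- estimate_cm_transient(mkvc(6, 5))
  expect_equal(as.numeric(cm6b), as.numeric(cm6), tolerance = 0.01)
  # type II preset lands near its nominal capacitance
  vc2 <- simulate_voltage_clamp(
    make_preset("type_II", "+/+", "LES"),
    build_protocol("type_I", step_voltages = c(-102), prestep_v = -94,
                   prestep_dur = 100, step_dur = 50),
    config = sim_config(rs_artifact = TRUE, rs_total = 10,
                        rs_compensation = 0.8, ljp = 0, dt = 0.002,
                        out_dt = 0.002))
  expect_equal(as.numeric(estimate_cm_transient(vc2)), 4.6,
               tolerance = 0.15)
  # a step positive to -90 mV is rejected
  cell <- rc_cell()
  vc_bad <- simulate_voltage_clamp(
    cell, build_protocol("type_I", step_voltages = c(-60), prestep_v = -64,
                         prestep_dur = 50, step_dur = 50),
    config = sim_config(rs_artifact = TRUE, ljp = 0, dt = 0.002,
                        out_dt = 0.002))
  expect_error(estimate_cm_transient(vc_bad), "-90")
})

test_that("quality factor follows its closed form and limits", {
  expect_equal(quality_factor(19.6, 20), sqrt((pi * 19.6 * 0.020)^2 + 0.25),
               tolerance = 1e-12)
  expect_equal(quality_factor(19.6, 20), 1.329, tolerance = 1e-3)
  expect_equal(quality_factor(0, 50), 0.5)
  # tau -> 0 limit
  expect_equal(quality_factor(100, 1e-9), 0.5, tolerance = 1e-6)
  # Q >= 0.5 with equality iff f_e = 0
  for (f in c(0, 1, 10, 50)) for (tau in c(1, 20, 80)) {
    q <- quality_factor(f, tau)
    if (f == 0) expect_equal(q, 0.5) else expect_gt(q, 0.5)
  }
  expect_error(quality_factor(-1, 10), "non-negative")
})

test_that("damped-sinusoid fits recover frequency and decay within 1%", {
  for (f_e in c(5, 20, 35)) for (tau_e in c(5, 20, 50)) {
    sw <- damped_sinusoid_sweep(f_e, tau_e)
    fit <- fit_resonance(sw)
    expect_lt(abs(fit$f_e - f_e) / f_e, 0.01)
    expect_lt(abs(fit$tau_e - tau_e) / tau_e, 0.01)
    expect_equal(fit$q_e, quality_factor(f_e, tau_e), tolerance = 0.02)
  }
})

test_that("overdamped responses collapse to the Q = 0.5 limit", {
  t_base <- seq(0, 100 - 0.1, by = 0.1)
  t_step <- seq(0, 400 - 0.1, by = 0.1)
  v <- c(rep(-70, length(t_base)), -60 + 8 * exp(-t_step / 15))
  sw <- hc_sweep(c(t_base, 100 + t_step),
                 rep(c(0, 20), c(length(t_base), length(t_step))), v,
                 "current_clamp",
                 segments = list(baseline = c(0, 100), step = c(100, 500)))
  fit <- fit_resonance(sw)
  expect_lt(fit$q_e, 0.55)
})

test_that("peak metrics report the initial transient exactly", {
  # triangular pulse of known height and width on a flat baseline
  dt <- 0.1
  t <- seq(0, 300 - dt, by = dt)
  v <- rep(-70, length(t))
  seg <- list(baseline = c(0, 100), step = c(100, 300))
  up <- t >= 110 & t < 120
  down <- t >= 120 & t < 130
  v[up] <- -70 + (t[up] - 110)
  v[down] <- -60 - (t[down] - 120)
  sw <- hc_sweep(t, rep(c(0, 50), c(1000, 2000)), v, "current_clamp",
                 segments = seg)
  pm <- peak_metrics(sw)
  expect_true(pm$present)
  expect_equal(pm$height, 10, tolerance = 0.02)
  expect_equal(pm$peak_v, -60, tolerance = 0.1)
  expect_equal(pm$time_to_peak, 20, tolerance = 0.2)
  expect_equal(pm$width_half_max, 10, tolerance = 0.3)
  # flat response: metrics absent
  v_flat <- rep(-70, length(t))
  sw_flat <- hc_sweep(t, rep(c(0, 50), c(1000, 2000)), v_flat,
                      "current_clamp", segments = seg)
  expect_false(peak_metrics(sw_flat)$present)
})

test_that("type II knockouts resonate more and peak later than wild type", {
  q <- list(); ttp <- list()
  for (g in c("+/+", "-/-")) {
    cell <- make_preset("type_II", g, "LES")
    cc <- simulate_current_clamp(cell, c(30, 170), step_dur = 300,
                                 config = sim_config(out_dt = 0.01))
    q[[g]] <- fit_resonance(cc$sweeps[[1]])$q_e
    ttp[[g]] <- peak_metrics(cc$sweeps[[2]])$time_to_peak
  }
  expect_gt(q[["-/-"]], q[["+/+"]])
  expect_gt(ttp[["-/-"]], ttp[["+/+"]])
})
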