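# Simulator: presets, voltage/current clamp, closed-form oracle, noise.

test_that("presets carry the published gating parameters", {
  p <- make_preset("type_I", "+/+", "LES")
  gkl <- Filter(function(s) s$name == "gKL", p$conductances)[[1]]
  expect_equal(gkl$activation$v_half, -85)
  expect_equal(gkl$activation$s, 4.3)
  expect_equal(gkl$g_max, 270)
  k <- make_preset("type_I", "-/-", "LES")
  expect_false(any(vapply(k$conductances, function(s) s$name == "gKL",
                          TRUE)))
  kv7 <- Filter(function(s) s$name == "gDR_Kv7", k$conductances)[[1]]
  expect_equal(kv7$g_max, 5.4)
  expect_equal(kv7$activation$v_half, -40.2)
  t2 <- make_preset("type_II", "+/+", "LES")
  ga <- Filter(function(s) s$name == "gA", t2$conductances)[[1]]
  expect_equal(ga$inact_fast$v_half, -42)
  expect_equal(abs(ga$inact_fast$s), 11)
  expect_equal(ga$g_max / t2$cm, 4.0)
  dr <- Filter(function(s) s$name == "gDR_Kv1.8", t2$conductances)[[1]]
  expect_equal(dr$activation$v_half, -25.0)
  expect_equal(dr$activation$s, 8.7)
  expect_error(make_preset("type_III", "+/+", "LES"))
  expect_error(make_preset("type_I", "+/+", "elsewhere"))
})

test_that("zero-conductance model yields only constant leak current", {
  cell <- rc_cell(r_in = 1, e_rev = -70)
  proto <- build_protocol("type_I", step_voltages = c(-104, -44, 16))
  rec <- simulate_voltage_clamp(cell, proto)
  segs <- vestephys:::protocol_segments(proto)
  for (k in seq_along(rec$sweeps)) {
    sw <- rec$sweeps[[k]]
    in_step <- sw$time >= segs$step[1] & sw$time < segs$step[2]
    i <- sw$response[in_step]
    expect_lt(diff(range(i)), 1e-9)
    expect_equal(i[1], (proto$step_voltages[k] + 70) * 1, tolerance = 1e-9)
  }
})

test_that("fixed-voltage simulator output matches the closed-form oracle", {
  cell <- make_preset("type_II", "+/+", "LES")
  proto <- build_protocol("type_II", step_voltages = c(-64, -24, 30))
  rec <- simulate_voltage_clamp(cell, proto)
  segs <- vestephys:::protocol_segments(proto)
  gt <- vestephys:::gate_tables(cell)
  for (k in seq_along(rec$sweeps)) {
    sw <- rec$sweeps[[k]]
    in_step <- sw$time >= segs$step[1] & sw$time < segs$step[2]
    tt <- sw$time[in_step] - segs$step[1]
    v <- proto$step_voltages[k]
    # compose the oracle: per conductance, closed-form current with the
    # initial state reached after holding equilibrium + the -124 prestep
    i_oracle <- 0
    for (spec in cell$conductances) {
      st_hold <- vestephys:::gate_equilibrium(spec, proto$holding)
      adv <- function(st, v_at, dur) {
        out <- st
        if (!is.null(spec$activation)) {
          minf <- vestephys:::gate_minf(spec$activation, v_at)
          out$m <- minf + (st$m - minf) *
            exp(-dur / spec$activation$tau[1])
        }
        for (nm in c("uf", "us")) {
          gate <- if (nm == "uf") spec$inact_fast else spec$inact_slow
          if (!is.null(gate)) {
            uinf <- 1 - vestephys:::boltz(v_at, gate$v_half, gate$s)
            out[[nm]] <- uinf + (st[[nm]] - uinf) * exp(-dur / gate$tau[1])
          }
        }
        out
      }
      st <- adv(st_hold, proto$prestep_v, proto$prestep_dur)
      i_oracle <- i_oracle + analytic_step_current(spec, v, tt, init = st)
    }
    i_sim <- sw$response[in_step]
    rel_rms <- sqrt(mean((i_sim - i_oracle)^2)) /
      max(sqrt(mean(i_oracle^2)), 1e-9)
    expect_lt(rel_rms, 1e-3)
  }
})

test_that("analytic_step_current limits behave", {
  spec <- dr_spec(g_max = 10)
  v <- 0
  tinf <- 1e5
  b <- 1 / (1 + exp((-25 - v) / 8.7))
  expect_equal(analytic_step_current(spec, v, tinf),
               10 * b * (v - e_k_std), tolerance = 1e-9)
  # starting at equilibrium the activation factor is constant
  minf <- b^(1 / 3)
  i <- analytic_step_current(spec, v, seq(0, 10, 0.1),
                             init = list(m = minf, uf = 0, us = 0))
  expect_lt(diff(range(i)), 1e-9)
  # cube-law onset from rest matches the activation template
  tt <- seq(0, 50, by = 0.01)
  i3 <- analytic_step_current(spec, v, tt)
  expect_equal(i3, 10 * b * (v - e_k_std) * (1 - exp(-tt / 2.5))^3,
               tolerance = 1e-12)
})

test_that("type I wild-type preset shows the inward-transient hallmark", {
  cell <- make_preset("type_I", "+/+", "LES")
  proto <- build_protocol("type_I", step_voltages = c(-124))
  rec <- simulate_voltage_clamp(cell, proto)
  segs <- vestephys:::protocol_segments(proto)
  sw <- rec$sweeps[[1]]
  early <- sw$time >= segs$prestep[1] & sw$time < segs$prestep[1] + 5
  late <- sw$time >= segs$prestep[2] - 20 & sw$time < segs$prestep[2]
  expect_lt(min(sw$response[early]), -2000) # large inward transient
  # decays toward the (much smaller) standing leak + HCN/Kir current
  expect_gt(mean(sw$response[late]), min(sw$response[early]) * 0.1)
})

test_that("gate variables stay within [0, 1] for every preset", {
  for (lab in c("type_I:+/+:LES", "type_I:-/-:striola", "type_II:+/+:LES",
                "type_II:-/-:MES")) {
    parts <- strsplit(lab, ":")[[1]]
    cell <- make_preset(parts[1], parts[2], parts[3])
    gt <- vestephys:::gate_tables(cell)
    for (v in c(-130, -90, -44, 0, 40)) {
      st <- vestephys:::gate_state_equilibrium(gt, v)
      expect_true(all(unlist(st) >= 0 & unlist(st) <= 1))
      adv <- vestephys:::advance_gates_fixed_v(gt, st, v + 60,
                                               seq(0, 100, 1))
      expect_true(all(adv$m >= 0 & adv$m <= 1))
      expect_true(all(adv$uf >= 0 & adv$uf <= 1))
    }
  }
})

test_that("depolarized steady-state conductance approaches the gated total", {
  cell <- make_preset("type_II", "-/-", "LES") # Kv7 + HCN + leak
  v <- 60
  i <- vestephys:::steady_state_current(cell, v)
  g_k_only <- sum(vapply(cell$conductances, function(s)
    if (s$e_rev < -60 && !is.null(s$activation) && s$activation$s > 0)
      s$g_max * (1 - s$z_total) else 0, 0))
  # remove leak and HCN contributions from the measured current first
  i_other <- sum(vapply(cell$conductances, function(s)
    if (s$e_rev >= -60 || is.null(s$activation) || s$activation$s < 0)
      s$g_max * (v - s$e_rev) *
        (if (is.null(s$activation)) 1 else
           vestephys:::boltz(v, s$activation$v_half, s$activation$s))
    else 0, 0))
  g_meas <- (i - i_other) / (v - cell$e_k)
  expect_equal(g_meas, g_k_only, tolerance = 0.01)
})

test_that("current clamp settles at the zero-current potential", {
  cell <- make_preset("type_II", "-/-", "LES")
  rec <- simulate_current_clamp(cell, c(0), baseline_dur = 50,
                                step_dur = 100, post_dur = 10)
  v <- rec$sweeps[[1]]$response
  v_eq <- vestephys:::zero_current_potential(cell)
  expect_lt(max(abs(v - v_eq)), 0.1)
})

test_that("type I wild-type rests within 3 mV of E_K", {
  cell <- make_preset("type_I", "+/+", "LES")
  rec <- simulate_current_clamp(cell, c(0), baseline_dur = 20,
                                step_dur = 50, post_dur = 10)
  v_rest <- mean(rec$sweeps[[1]]$response)
  expect_lt(abs(v_rest - e_k_std), 3)
})

test_that("current-clamp integrator agrees with an independent ODE solver", {
  # small two-conductance cell, compared against deSolve::lsoda
  cell <- cell_model(cm = 5, label = "check", conductances = list(
    dr_spec(g_max = 10, v_half = -40, s = 8, tau = 5),
    conductance_spec("gLeak", g_max = 0.5, e_rev = -70)))
  rec <- simulate_current_clamp(cell, c(20), baseline_dur = 20,
                                step_dur = 180, post_dur = 10,
                                config = sim_config(dt = 0.005,
                                                    out_dt = 0.02))
  v0 <- vestephys:::zero_current_potential(cell)
  m0 <- vestephys:::boltz(v0, -40, 8)^(1 / 3)
  rhs <- function(t, y, parms) {
    v <- y[1]; m <- y[2]
    minf <- (1 / (1 + exp((-40 - v) / 8)))^(1 / 3)
    i_inj <- if (t >= 20 && t < 200) 20 else 0
    i_ion <- 10 * m^3 * (v - e_k_std) + 0.5 * (v + 70)
    list(c((i_inj - i_ion) / 5, (minf - m) / 5))
  }
  sol <- deSolve::lsoda(c(v = v0, m = m0), times = seq(0, 210, by = 0.02),
                        func = rhs, rtol = 1e-8, atol = 1e-8)
  sw <- rec$sweeps[[1]]
  v_ref <- stats::approx(sol[, 1], sol[, 2], xout = sw$time)$y
  expect_lt(max(abs(sw$response - v_ref), na.rm = TRUE), 0.2)
})

test_that("noise injection is seeded, unbiased, and optional", {
  cell <- rc_cell()
  rec <- simulate_voltage_clamp(
    cell, build_protocol("type_II", step_voltages = c(-44, 0)))
  cfg0 <- sim_config(noise_sd = 0, seed = 7)
  expect_identical(add_noise(rec, cfg0), rec)
  cfg <- sim_config(noise_sd = 5, seed = 7)
  n1 <- add_noise(rec, cfg)
  n2 <- add_noise(rec, cfg)
  expect_identical(n1$sweeps[[1]]$response, n2$sweeps[[1]]$response)
  resid <- unlist(lapply(seq_along(rec$sweeps), function(k)
    n1$sweeps[[k]]$response - rec$sweeps[[k]]$response))
  expect_gt(length(resid), 1e4)
  expect_equal(stats::sd(resid), 5, tolerance = 0.05)
})
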