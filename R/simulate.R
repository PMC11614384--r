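# Forward simulation: voltage-clamp and current-clamp recordings from a
# cell_model, plus the closed-form fixed-voltage oracle and noise injection.
#
# Voltage clamp (ideal): at a fixed command voltage every gate is a
# first-order relaxation, so each protocol segment is advanced with the exact
# exponential gate solution carried over segment boundaries.
#
# Current clamp and non-ideal clamp: operator-split exponential integrator
# (Rush-Larsen update for the gates, exact linear update for V with gates
# frozen over one dt). Unconditionally stable, which matters for type I cells
# whose membrane time constant is tens of microseconds.

#' Simulation configuration
#'
#' @param dt Integration step, ms (current clamp / non-ideal clamp).
#' @param out_dt Output sampling interval, ms. The reciprocal is the sweep
#'   sample rate; the default 0.02 ms corresponds to 50 kHz.
#' @param seed Integer seed for noise injection.
#' @param noise_sd Gaussian noise SD added to the response channel
#'   (pA in voltage clamp, mV in current clamp). 0 disables noise.
#' @param rs_artifact If `TRUE`, voltage-clamp simulations model the
#'   electrode: the membrane is charged through the residual series
#'   resistance and the recorded current is the electrode current, producing
#'   realistic capacitive transients and clamp error.
#' @param rs_total,rs_compensation,ljp Electrode parameters used when
#'   `rs_artifact` is `TRUE` (MOhm, fraction, mV); also stored in metadata.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.005, out_dt = 0.02, seed = 1L, noise_sd = 0,
                       rs_artifact = FALSE, rs_total = 10,
                       rs_compensation = 0.8, ljp = 4) {
  if (dt <= 0 || out_dt < dt) stop("need 0 < dt <= out_dt")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(dt = dt, out_dt = out_dt, seed = as.integer(seed),
                 noise_sd = noise_sd, rs_artifact = rs_artifact,
                 rs_total = rs_total, rs_compensation = rs_compensation,
                 ljp = ljp),
            class = "sim_config")
}

# ---- internal gate bookkeeping -------------------------------------------

# Flatten a cell's gating parameters into parallel vectors for fast updates.
gate_tables <- function(cell) {
  specs <- cell$conductances
  has_act <- !vapply(specs, function(s) is.null(s$activation), TRUE)
  list(
    n = length(specs),
    gmax = vapply(specs, function(s) s$g_max, 0),
    erev = vapply(specs, function(s) s$e_rev, 0),
    z = vapply(specs, function(s) s$z_total, 0),
    f = vapply(specs, function(s) s$f_fast, 0),
    has_act = has_act,
    power = vapply(specs, function(s)
      if (is.null(s$activation)) 1 else s$activation$power, 0),
    vh_a = vapply(specs, function(s)
      if (is.null(s$activation)) 0 else s$activation$v_half, 0),
    s_a = vapply(specs, function(s)
      if (is.null(s$activation)) 1 else s$activation$s, 0),
    act_gate = lapply(specs, function(s) s$activation),
    tau_a_const = vapply(specs, function(s)
      if (is.null(s$activation) || length(s$activation$tau) != 1L) NA_real_
      else s$activation$tau, 0),
    has_if = !vapply(specs, function(s) is.null(s$inact_fast), TRUE),
    has_is = !vapply(specs, function(s) is.null(s$inact_slow), TRUE),
    vh_if = vapply(specs, function(s)
      if (is.null(s$inact_fast)) 0 else s$inact_fast$v_half, 0),
    s_if = vapply(specs, function(s)
      if (is.null(s$inact_fast)) -1 else s$inact_fast$s, 0),
    tau_if = vapply(specs, function(s)
      if (is.null(s$inact_fast)) 1 else s$inact_fast$tau[1], 0),
    vh_is = vapply(specs, function(s)
      if (is.null(s$inact_slow)) 0 else s$inact_slow$v_half, 0),
    s_is = vapply(specs, function(s)
      if (is.null(s$inact_slow)) -1 else s$inact_slow$s, 0),
    tau_is = vapply(specs, function(s)
      if (is.null(s$inact_slow)) 1 else s$inact_slow$tau[1], 0))
}

# Equilibrium gate state vectors at voltage v.
gate_state_equilibrium <- function(gt, v) {
  m <- ifelse(gt$has_act, boltz(v, gt$vh_a, gt$s_a)^(1 / gt$power), 1)
  uf <- ifelse(gt$has_if, 1 - boltz(v, gt$vh_if, gt$s_if), 0)
  us <- ifelse(gt$has_is, 1 - boltz(v, gt$vh_is, gt$s_is), 0)
  list(m = m, uf = uf, us = us)
}

min_gate_tau <- function(cell, v_range = c(-130, 40)) {
  taus <- unlist(lapply(cell$conductances, function(s) {
    vgrid <- seq(v_range[1], v_range[2], by = 5)
    out <- c()
    if (!is.null(s$activation)) out <- c(out, gate_tau(s$activation, vgrid))
    if (!is.null(s$inact_fast)) out <- c(out, s$inact_fast$tau[1])
    if (!is.null(s$inact_slow)) out <- c(out, s$inact_slow$tau[1])
    out
  }))
  if (length(taus) == 0) Inf else min(taus)
}

# Advance all gates of a cell at fixed voltage v over relative times t
# (vector, from 0) using the exact exponential solution; returns per-
# conductance gate matrices (time x conductance) and the state at t_end.
advance_gates_fixed_v <- function(gt, state, v, t, t_end = max(t)) {
  nt <- length(t)
  m <- matrix(1, nt, gt$n); uf <- matrix(0, nt, gt$n)
  us <- matrix(0, nt, gt$n)
  m_end <- state$m; uf_end <- state$uf; us_end <- state$us
  for (i in seq_len(gt$n)) {
    if (gt$has_act[i]) {
      tau <- gate_tau(gt$act_gate[[i]], v)[1]
      minf <- boltz(v, gt$vh_a[i], gt$s_a[i])^(1 / gt$power[i])
      m[, i] <- minf + (state$m[i] - minf) * exp(-t / tau)
      m_end[i] <- minf + (state$m[i] - minf) * exp(-t_end / tau)
    }
    if (gt$has_if[i]) {
      uinf <- 1 - boltz(v, gt$vh_if[i], gt$s_if[i])
      uf[, i] <- uinf + (state$uf[i] - uinf) * exp(-t / gt$tau_if[i])
      uf_end[i] <- uinf + (state$uf[i] - uinf) * exp(-t_end / gt$tau_if[i])
    }
    if (gt$has_is[i]) {
      uinf <- 1 - boltz(v, gt$vh_is[i], gt$s_is[i])
      us[, i] <- uinf + (state$us[i] - uinf) * exp(-t / gt$tau_is[i])
      us_end[i] <- uinf + (state$us[i] - uinf) * exp(-t_end / gt$tau_is[i])
    }
  }
  list(m = m, uf = uf, us = us,
       end = list(m = m_end, uf = uf_end, us = us_end))
}

# Whole-cell ionic current (pA) from gate matrices at fixed voltage v.
current_from_gates <- function(gt, gates, v) {
  tot <- 0
  for (i in seq_len(gt$n)) {
    act <- if (gt$has_act[i]) gates$m[, i]^gt$power[i] else 1
    avail <- 1 - gt$z[i] *
      (gt$f[i] * gates$uf[, i] + (1 - gt$f[i]) * gates$us[, i])
    tot <- tot + gt$gmax[i] * act * avail * (v - gt$erev[i])
  }
  tot
}

# ---- shared time stepper --------------------------------------------------
# Integrates the membrane over segments. Each segment is a list with
# duration (ms) and either inj (current clamp, pA) or vc + rs (clamped
# through a series resistance rs in GOhm). Records V (and electrode current
# in clamp mode) every `keep` steps. State carried across segments.
integrate_segments <- function(cell, gt, segments, v0, state0, dt, keep) {
  ia <- which(gt$has_act); iif <- which(gt$has_if); iis <- which(gt$has_is)
  pinv <- 1 / gt$power[ia]
  vh_a <- gt$vh_a[ia]; s_a <- gt$s_a[ia]; pw <- gt$power[ia]
  bell <- is.na(gt$tau_a_const[ia])
  eda_const <- exp(-dt / gt$tau_a_const[ia])  # NA where bell-shaped
  act_gates <- gt$act_gate[ia]
  vh_if <- gt$vh_if[iif]; s_if <- gt$s_if[iif]
  edf <- exp(-dt / gt$tau_if[iif])
  vh_is <- gt$vh_is[iis]; s_is <- gt$s_is[iis]
  eds <- exp(-dt / gt$tau_is[iis])
  gmax <- gt$gmax; erev <- gt$erev; z <- gt$z; f <- gt$f
  has_inact <- gt$z > 0
  act_full <- rep(1, gt$n); avail <- rep(1, gt$n)
  cm <- cell$cm
  v <- v0
  m <- state0$m[ia]; uf <- state0$uf[iif]; us <- state0$us[iis]
  out_t <- vector("list", length(segments))
  out_v <- vector("list", length(segments))
  out_ie <- vector("list", length(segments))
  t_off <- 0
  for (k in seq_along(segments)) {
    seg <- segments[[k]]
    clamp <- !is.null(seg$vc)
    ginv_rs <- if (clamp) 1 / seg$rs else 0
    inj <- if (clamp) 0 else seg$inj
    vc <- if (clamp) seg$vc else 0
    nstep <- round(seg$duration / dt)
    idx_keep <- seq(1L, nstep, by = keep)
    nkeep <- length(idx_keep)
    buf_v <- numeric(nkeep); buf_ie <- numeric(nkeep)
    ptr <- 1L; nxt <- idx_keep[1L]
    for (j in seq_len(nstep)) {
      if (j == nxt) {
        buf_v[ptr] <- v
        if (clamp) buf_ie[ptr] <- (vc - v) * ginv_rs
        ptr <- ptr + 1L
        nxt <- if (ptr <= nkeep) idx_keep[ptr] else 0L
      }
      if (length(ia)) {
        minf <- (1 / (1 + exp((vh_a - v) / s_a)))^pinv
        eda <- eda_const
        if (any(bell))
          eda[bell] <- exp(-dt / vapply(act_gates[bell],
                                        function(g) gate_tau(g, v)[1], 0))
        m <- minf + (m - minf) * eda
        act_full[ia] <- m^pw
      }
      if (length(iif)) {
        uinf <- 1 - 1 / (1 + exp((vh_if - v) / s_if))
        uf <- uinf + (uf - uinf) * edf
      }
      if (length(iis)) {
        uinf <- 1 - 1 / (1 + exp((vh_is - v) / s_is))
        us <- uinf + (us - uinf) * eds
      }
      if (any(has_inact)) {
        ufull <- numeric(gt$n); usull <- numeric(gt$n)
        ufull[iif] <- uf; usull[iis] <- us
        avail <- 1 - z * (f * ufull + (1 - f) * usull)
      }
      geff <- gmax * act_full * avail
      g_tot <- sum(geff) + ginv_rs
      v_inf <- (sum(geff * erev) + inj + vc * ginv_rs) / g_tot
      v <- v_inf + (v - v_inf) * exp(-dt * g_tot / cm)
    }
    if (!is.finite(v))
      stop("integration blow-up in segment ", k, " (V non-finite)")
    out_t[[k]] <- t_off + (idx_keep - 1L) * dt
    out_v[[k]] <- buf_v
    out_ie[[k]] <- buf_ie
    t_off <- t_off + seg$duration
  }
  list(time = unlist(out_t), v = unlist(out_v), i_electrode = unlist(out_ie))
}

# ---- voltage clamp --------------------------------------------------------

#' Simulate a voltage-clamp recording
#'
#' Runs the cell through a [step_protocol()]: holding, prestep, one sweep per
#' test step, tail. With `config$rs_artifact = FALSE` (default) the clamp is
#' ideal and each segment uses the exact exponential gate solution; with the
#' artifact on, the membrane is charged through the residual series
#' resistance, the recorded current is the electrode current, and the
#' command channel carries the uncorrected command (junction potential
#' included), to be undone by [correct_potentials()].
#'
#' @param cell A [cell_model()].
#' @param protocol A [step_protocol()].
#' @param config A [sim_config()].
#' @param meta Optional [recording_meta()]; a default is derived from the
#'   preset label when omitted.
#' @return An [hc_recording()] (voltage clamp; response in pA).
#' @export
simulate_voltage_clamp <- function(cell, protocol, config = sim_config(),
                                   meta = NULL) {
  stopifnot(inherits(cell, "cell_model"), inherits(protocol, "step_protocol"))
  tau_min <- min_gate_tau(cell)
  if (config$rs_artifact && tau_min < 5 * config$dt)
    stop(sprintf("dt too coarse for stability: min gate tau %.3g ms < 5*dt",
                 tau_min))
  if (is.null(meta)) meta <- meta_from_label(cell$label, config)
  gt <- gate_tables(cell)
  segs <- protocol_segments(protocol)
  dt <- config$out_dt
  sweeps <- lapply(protocol$step_voltages, function(vstep) {
    vseq <- c(protocol$holding, protocol$prestep_v, vstep, protocol$tail_v)
    dur <- c(protocol$holding_dur, protocol$prestep_dur, protocol$step_dur,
             protocol$tail_dur)
    if (!config$rs_artifact) {
      state <- gate_state_equilibrium(gt, protocol$holding)
      t_all <- vector("list", 4L); i_all <- vector("list", 4L)
      v_all <- vector("list", 4L); t_off <- 0
      for (k in seq_along(vseq)) {
        tt <- seq(0, dur[k] - dt, by = dt)
        adv <- advance_gates_fixed_v(gt, state, vseq[k], tt, t_end = dur[k])
        i_all[[k]] <- current_from_gates(gt, adv, vseq[k])
        v_all[[k]] <- rep(vseq[k], length(tt))
        t_all[[k]] <- t_off + tt
        state <- adv$end
        t_off <- t_off + dur[k]
      }
      hc_sweep(unlist(t_all), unlist(v_all), unlist(i_all),
               mode = "voltage_clamp", segments = segs)
    } else {
      rs_res <- config$rs_total * (1 - config$rs_compensation) * 1e-3 # GOhm
      if (rs_res <= 0) stop("rs_artifact requires a positive residual Rs")
      v_start <- vseq[1] - config$ljp
      state <- gate_state_equilibrium(gt, v_start)
      seglist <- lapply(seq_along(vseq), function(k)
        list(duration = dur[k], vc = vseq[k] - config$ljp, rs = rs_res))
      keep <- max(1L, round(config$out_dt / config$dt))
      res <- integrate_segments(cell, gt, seglist, v_start, state,
                                config$dt, keep)
      cmd <- rep(vseq, times = vapply(seglist, function(s)
        length(seq(1L, round(s$duration / config$dt), by = keep)), 0L))
      hc_sweep(res$time, cmd, res$i_electrode, mode = "voltage_clamp",
               segments = segs)
    }
  })
  rec <- hc_recording(meta, protocol, sweeps)
  if (config$noise_sd > 0) rec <- add_noise(rec, config)
  rec
}

meta_from_label <- function(label, config) {
  parts <- strsplit(label %||% "custom", ":", fixed = TRUE)[[1]]
  if (length(parts) == 3 && parts[1] %in% c("type_I", "type_II")) {
    recording_meta(cell_type = parts[1], genotype = parts[2], zone = parts[3],
                   rs_total = config$rs_total,
                   rs_compensation = config$rs_compensation,
                   ljp = if (config$rs_artifact) config$ljp else 0)
  } else {
    recording_meta(ljp = if (config$rs_artifact) config$ljp else 0)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- closed-form oracle ---------------------------------------------------

#' Closed-form current of one conductance at fixed voltage
#'
#' Evaluates the exact first-order-gating solution of one conductance held at
#' voltage `v`: with the activation gate starting at `m0`,
#' `I(t) = g_max * m(t)^n * h_mix(t) * (v - e_rev)` where
#' `m(t) = m_inf + (m0 - m_inf) exp(-t/tau)` and `h_mix` is the weighted
#' bi-exponential availability. With `m0 = 0` and fresh inactivation gates
#' this is exactly the activation/inactivation template
#' `I(t) = Imax*(1-exp(-t/tau_w))^n * [1 - Z*(f*(1-exp(-t/tau_zf)) +
#' (1-f)*(1-exp(-t/tau_zs)))]` that the kinetics module fits.
#'
#' @param spec A [conductance_spec()].
#' @param v Fixed membrane potential, mV.
#' @param t Time grid, ms, from segment start.
#' @param init Named list with elements `m`, `uf`, `us` (initial gate
#'   states); defaults to fully deactivated / fully available.
#' @return Current trace in pA.
#' @export
analytic_step_current <- function(spec, v, t,
                                  init = list(m = 0, uf = 0, us = 0)) {
  stopifnot(inherits(spec, "conductance_spec"))
  act <- if (is.null(spec$activation)) rep(1, length(t)) else {
    gate <- spec$activation
    minf <- boltz(v, gate$v_half, gate$s)^(1 / gate$power)
    tau <- gate_tau(gate, v)[1]
    (minf + (init$m - minf) * exp(-t / tau))^gate$power
  }
  h <- rep(1, length(t))
  if (spec$z_total > 0) {
    uf <- if (is.null(spec$inact_fast)) 0 else {
      uinf <- 1 - boltz(v, spec$inact_fast$v_half, spec$inact_fast$s)
      uinf + (init$uf - uinf) * exp(-t / spec$inact_fast$tau[1])
    }
    us <- if (is.null(spec$inact_slow)) 0 else {
      uinf <- 1 - boltz(v, spec$inact_slow$v_half, spec$inact_slow$s)
      uinf + (init$us - uinf) * exp(-t / spec$inact_slow$tau[1])
    }
    h <- 1 - spec$z_total * (spec$f_fast * uf + (1 - spec$f_fast) * us)
  }
  spec$g_max * act * h * (v - spec$e_rev)
}

# ---- current clamp --------------------------------------------------------

#' Simulate a current-clamp recording
#'
#' Integrates `cm dV/dt = I_inj - sum(I_ion)` with the operator-split
#' exponential integrator. Each sweep has a zero-current baseline (the cell
#' sits at its resting potential), the current step, and a zero-current
#' recovery segment.
#'
#' @param cell A [cell_model()].
#' @param current_steps Injected current amplitudes, pA (one sweep each).
#' @param config A [sim_config()].
#' @param baseline_dur,step_dur,post_dur Segment durations, ms.
#' @param meta Optional [recording_meta()].
#' @return An [hc_recording()] (current clamp; response in mV).
#' @export
simulate_current_clamp <- function(cell, current_steps,
                                   config = sim_config(),
                                   baseline_dur = 100, step_dur = 400,
                                   post_dur = 50, meta = NULL) {
  stopifnot(inherits(cell, "cell_model"))
  if (is.null(meta)) meta <- meta_from_label(cell$label, config)
  gt <- gate_tables(cell)
  keep <- max(1L, round(config$out_dt / config$dt))
  v0 <- zero_current_potential(cell)
  st0 <- gate_state_equilibrium(gt, v0)
  segs <- list(baseline = c(0, baseline_dur),
               step = c(baseline_dur, baseline_dur + step_dur),
               post = c(baseline_dur + step_dur,
                        baseline_dur + step_dur + post_dur))
  sweeps <- lapply(current_steps, function(iinj) {
    seglist <- list(list(duration = baseline_dur, inj = 0),
                    list(duration = step_dur, inj = iinj),
                    list(duration = post_dur, inj = 0))
    res <- integrate_segments(cell, gt, seglist, v0, st0, config$dt, keep)
    cmd <- rep(c(0, iinj, 0), times = vapply(seglist, function(s)
      length(seq(1L, round(s$duration / config$dt), by = keep)), 0L))
    hc_sweep(res$time, cmd, res$v, mode = "current_clamp", segments = segs)
  })
  rec <- hc_recording(meta, as.numeric(current_steps), sweeps)
  if (config$noise_sd > 0) rec <- add_noise(rec, config)
  rec
}

#' Add Gaussian recording noise
#'
#' Adds i.i.d. Gaussian noise of SD `config$noise_sd` to every response
#' channel. The same seed always yields the identical recording.
#'
#' @param recording An [hc_recording()].
#' @param config A [sim_config()]; `noise_sd` and `seed` are used.
#' @return The noisy recording.
#' @export
add_noise <- function(recording, config) {
  stopifnot(inherits(recording, "hc_recording"))
  if (config$noise_sd == 0) return(recording)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  recording$sweeps <- lapply(recording$sweeps, function(sw) {
    sw$response <- sw$response +
      stats::rnorm(length(sw$response), 0, config$noise_sd)
    sw
  })
  recording
}
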