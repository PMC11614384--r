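# Current-clamp and passive analyses: resting potential, input resistance
# and membrane time constant from small current steps, capacitance from the
# clamp transient, damped-sinusoid resonance fits and the quality factor,
# and step-response peak metrics.

#' Resting potential from the pre-step baseline
#'
#' Mean voltage over the final 50 ms of the zero-current baseline before the
#' step.
#'
#' @param sweep A current-clamp [hc_sweep()] with a zero-current baseline of
#'   at least 50 ms.
#' @param window_ms Baseline window, ms.
#' @return Resting potential, mV.
#' @export
resting_potential <- function(sweep, window_ms = 50) {
  stopifnot(inherits(sweep, "hc_sweep"))
  if (sweep$mode != "current_clamp")
    stop("resting potential requires a current-clamp sweep")
  base_end <- if (!is.null(sweep$segments$baseline))
    sweep$segments$baseline[2] else {
      nz <- which(sweep$command != 0)
      if (length(nz) == 0) max(sweep$time) else sweep$time[nz[1]]
    }
  sel <- sweep$time >= base_end - window_ms & sweep$time < base_end &
    sweep$command == 0
  if (sum(sel) < 2)
    stop("no zero-current baseline of ", window_ms, " ms before the step")
  mean(sweep$response[sel])
}

#' Passive properties from small current steps
#'
#' Uses the sweeps whose steady-state deflection is below `max_dv` (15 mV,
#' the smallness criterion for single-exponential charging fits). Input
#' resistance is the mean of `dV_ss / dI` over those sweeps, averaging
#' depolarizing and hyperpolarizing responses so that first-order
#' rectification cancels. The membrane time constant comes from a
#' single-exponential fit of the charging onset (up to the first extremum)
#' of the smallest qualifying depolarizing response; hyperpolarizing
#' responses are avoided for the fit because the HCN sag contaminates the
#' charging phase. Capacitance follows as `cm = tau / R_in`.
#'
#' @param recording A current-clamp [hc_recording()] (current steps).
#' @param max_dv Largest admissible steady-state deflection, mV.
#' @return An object of class `passive_fit` with `v_rest` (mV), `r_in`
#'   (GOhm), `tau_rc` (ms), `cm_est` (pF), and the step used for the time
#'   constant (`i_step`, pA).
#' @export
fit_passive_response <- function(recording, max_dv = 15) {
  stopifnot(inherits(recording, "hc_recording"))
  if (recording_mode(recording) != "current_clamp")
    stop("passive fit requires a current-clamp recording")
  steps <- as.numeric(recording$protocol)
  cands <- list()
  for (k in seq_along(recording$sweeps)) {
    if (steps[k] == 0) next
    sw <- recording$sweeps[[k]]
    v0 <- resting_potential(sw)
    seg <- sw$segments$step
    sel_ss <- sw$time >= seg[2] - 20 & sw$time < seg[2]
    dv_ss <- mean(sw$response[sel_ss]) - v0
    if (abs(dv_ss) < max_dv && abs(dv_ss) > 0.2)
      cands[[length(cands) + 1L]] <- list(k = k, sw = sw, v0 = v0,
                                          dv_ss = dv_ss)
  }
  if (length(cands) == 0)
    stop("no response smaller than ", max_dv,
         " mV; repeat with smaller current steps")
  r_all <- vapply(cands, function(cd) cd$dv_ss / steps[cd$k], 0)
  r_in <- mean(r_all) # mV/pA = GOhm
  dep <- Filter(function(cd) cd$dv_ss > 0, cands)
  pick <- if (length(dep)) dep[[which.min(vapply(dep, function(cd)
    abs(cd$dv_ss), 0))]] else cands[[which.min(vapply(cands, function(cd)
    abs(cd$dv_ss), 0))]]
  sw <- pick$sw
  seg <- sw$segments$step
  sel <- sw$time >= seg[1] & sw$time < seg[2]
  t <- sw$time[sel] - seg[1]
  dv <- sw$response[sel] - pick$v0
  iext <- which.max(abs(dv))
  win <- t <= max(t[iext], 20 * (t[2] - t[1]))
  tw <- t[win]; yw <- dv[win]
  best <- lm_multistart(
    list(c(a = dv[iext], tau = max(t[iext] / 3, t[2] - t[1])),
         c(a = pick$dv_ss, tau = max(t[iext], 1))),
    function(p) yw - p[["a"]] * (1 - exp(-tw / p[["tau"]])),
    lower = c(a = -Inf, tau = 1e-4), upper = c(a = Inf, tau = Inf),
    maxiter = 300)
  if (is.null(best)) stop("charging fit failed to converge")
  tau_rc <- unname(best$par["tau"])
  v_rest <- mean(vapply(cands, function(cd) cd$v0, 0))
  structure(list(v_rest = v_rest, r_in = r_in, tau_rc = tau_rc,
                 cm_est = tau_rc / r_in, i_step = steps[pick$k],
                 dv_ss = pick$dv_ss, n_sweeps = length(cands)),
            class = "passive_fit")
}

#' @export
print.passive_fit <- function(x, ...) {
  cat(sprintf(
    "Passive fit: V_rest %.1f mV, R_in %.3g GOhm, tauRC %.3g ms, Cm %.3g pF (step %.3g pA)\n",
    x$v_rest, x$r_in, x$tau_rc, x$cm_est, x$i_step))
  invisible(x)
}

#' @export
coef.passive_fit <- function(object, ...) {
  c(v_rest = object$v_rest, r_in = object$r_in, tau_rc = object$tau_rc,
    cm_est = object$cm_est)
}

#' Membrane capacitance from the clamp transient
#'
#' For a small voltage-clamp step delivered negative to -90 mV, fits a
#' single exponential to the decaying capacitive transient and applies the
#' standard two-resistor model: the transient peak estimates the series
#' resistance (`Rs = dV / I_peak`), the steady-state current estimates the
#' total resistance, and `Cm = tau * (1/Rs + 1/Rin)`.
#'
#' @param recording A voltage-clamp [hc_recording()] whose protocol contains
#'   a step of at most `max_step` mV starting from a potential at or below
#'   -90 mV, recorded with the series-resistance artifact enabled.
#' @param max_step Largest admissible step size, mV.
#' @return Estimated membrane capacitance, pF, with attributes `rs`
#'   (GOhm), `r_in` (GOhm) and `tau` (ms).
#' @export
estimate_cm_transient <- function(recording, max_step = 10) {
  stopifnot(inherits(recording, "hc_recording"))
  if (recording_mode(recording) != "voltage_clamp")
    stop("capacitance transient requires a voltage-clamp recording")
  proto <- recording$protocol
  segs <- protocol_segments(proto)
  # use the most negative step; it must lie negative to -90 mV
  k <- 1L
  v_from <- proto$prestep_v
  v_to <- proto$step_voltages[k]
  if (max(v_from, v_to) > -90)
    stop("transient step must be delivered negative to -90 mV")
  dv <- v_to - v_from
  if (abs(dv) > max_step)
    stop("step too large for a passive transient (", abs(dv), " mV)")
  sw <- recording$sweeps[[k]]
  pre <- sw$time >= segs$prestep[1] + 0.8 * proto$prestep_dur &
    sw$time < segs$prestep[2]
  i_base <- mean(sw$response[pre])
  sel <- sw$time >= segs$step[1] & sw$time < segs$step[2]
  t <- sw$time[sel] - segs$step[1]
  i <- sw$response[sel] - i_base # change relative to the prestep baseline
  i_ss <- mean(i[t > max(t) * 0.8])
  i_t <- i - i_ss
  pk <- which.max(abs(i_t))
  if (sign(i_t[pk]) != sign(dv)) stop("no capacitive transient found")
  # crude tau to check sampling, then exponential fit from the peak on
  amp0 <- i_t[pk]
  below <- which(abs(i_t[pk:length(i_t)]) < abs(amp0) / exp(1))[1]
  tau0 <- if (is.na(below)) max(t) / 5 else (below - 1) * (t[2] - t[1])
  if (tau0 < 5 * (t[2] - t[1]))
    stop("transient undersampled: fewer than 5 samples per time constant")
  td <- t[pk:length(i_t)] - t[pk]
  yd <- i_t[pk:length(i_t)]
  best <- lm_multistart(
    list(c(a = amp0, tau = tau0), c(a = amp0, tau = tau0 * 3)),
    function(p) yd - p[["a"]] * exp(-td / p[["tau"]]),
    lower = c(a = -Inf, tau = 1e-4), upper = c(a = Inf, tau = Inf),
    maxiter = 300)
  if (is.null(best)) stop("transient decay fit failed to converge")
  cf <- best$par
  tau <- unname(cf["tau"])
  i0 <- unname(cf["a"]) # transient amplitude extrapolated to step onset
  rs <- dv / (i0 + i_ss) # GOhm (mV / pA)
  r_tot <- dv / i_ss
  r_in <- r_tot - rs
  if (!is.finite(r_in) || r_in <= 0)
    stop("two-resistor model degenerate: non-positive input resistance")
  cm <- tau * (1 / rs + 1 / r_in)
  structure(cm, rs = rs, r_in = r_in, tau = tau)
}

#' Resonance quality factor
#'
#' `Q_e = sqrt((pi * f_e * tau_e)^2 + 0.25)` with `f_e` in Hz and `tau_e`
#' in ms. `Q_e >= 0.5` always, with equality exactly at `f_e = 0`.
#'
#' @param f_e Resonant frequency, Hz.
#' @param tau_e Decay time constant, ms.
#' @return Dimensionless quality factor.
#' @export
quality_factor <- function(f_e, tau_e) {
  if (any(f_e < 0)) stop("f_e must be non-negative")
  if (any(tau_e <= 0)) stop("tau_e must be positive")
  sqrt((pi * f_e * tau_e * 1e-3)^2 + 0.25)
}

#' Fit a damped sinusoid to a step response
#'
#' Fits `V(t) = V_ss + V_p * exp(-t/tau_e) * sin(2 pi f_e t - theta)` to the
#' voltage trace from the first half-maximum crossing of the initial
#' depolarizing peak until the end of the current step, with `t` measured
#' from the start of the fit window. (As printed, the damped-sinusoid
#' equation omits `t` inside the sinusoid; the standard form with
#' `2 pi f_e t` is dimensionally consistent and is what is fitted here.)
#' Multi-starts over the phase avoid local minima; the half-maximum crossing
#' is located on a 1 ms median-smoothed copy while the fit uses raw samples.
#'
#' @param sweep A current-clamp [hc_sweep()] containing a step response.
#' @param step_window Optional `c(start, end)` ms overriding the sweep's
#'   step segment.
#' @return An object of class `resonance_fit` with `v_ss`, `v_p`, `tau_e`
#'   (ms), `f_e` (Hz), `theta` (rad), `q_e`, `adj_r2`, `from_onset` (flag:
#'   no depolarizing peak found, fit from step onset).
#' @export
fit_resonance <- function(sweep, step_window = NULL) {
  stopifnot(inherits(sweep, "hc_sweep"))
  if (sweep$mode != "current_clamp")
    stop("resonance fit requires a current-clamp sweep")
  seg <- step_window %||% sweep$segments$step
  if (is.null(seg)) stop("no step window available")
  sel <- sweep$time >= seg[1] & sweep$time < seg[2]
  t_all <- sweep$time[sel]; v_all <- sweep$response[sel]
  v0 <- mean(sweep$response[sweep$time < seg[1] &
                              sweep$time >= seg[1] - 50])
  # locate the initial depolarizing peak on a median-smoothed copy
  dt <- sweep_dt(sweep)
  kmed <- max(3L, 2L * (round(0.5 / dt)) + 1L)
  vsm <- stats::runmed(v_all, min(kmed, length(v_all) -
                                    (1 - length(v_all) %% 2)))
  pk <- which.max(vsm)
  from_onset <- FALSE
  if (pk <= 2 || vsm[pk] - v0 < 0.5) {
    start_idx <- 1L
    from_onset <- TRUE
  } else {
    half <- v0 + (vsm[pk] - v0) / 2
    start_idx <- which(vsm >= half)[1]
  }
  t <- t_all[start_idx:length(t_all)] - t_all[start_idx]
  v <- v_all[start_idx:length(v_all)]
  if (length(t) > 4000L) {
    idx <- seq(1L, length(t), by = ceiling(length(t) / 4000L))
    t <- t[idx]; v <- v[idx]
  }
  v_ss0 <- mean(v[t > max(t) * 0.8])
  amp0 <- max(abs(v - v_ss0))
  # frequency guess from zero crossings of (v - v_ss)
  sgn <- sign(v - v_ss0)
  ncross <- sum(diff(sgn) != 0)
  f0 <- max(ncross / 2 / (max(t) * 1e-3), 1) # Hz
  starts <- list()
  for (theta0 in c(0, pi / 2, pi, 3 * pi / 2))
    for (fstart in unique(c(f0, f0 / 2, 2)))
      starts[[length(starts) + 1L]] <-
        c(v_ss = v_ss0, v_p = amp0, tau_e = max(t) / 4, f_e = fstart,
          theta = theta0)
  res_model <- function(p) {
    p[["v_ss"]] + p[["v_p"]] * exp(-t / p[["tau_e"]]) *
      sin(2 * pi * p[["f_e"]] * t * 1e-3 - p[["theta"]])
  }
  best <- lm_multistart(starts, function(p) v - res_model(p),
                        lower = c(v_ss = -Inf, v_p = -Inf, tau_e = 0.1,
                                  f_e = 0, theta = -2 * pi),
                        upper = c(v_ss = Inf, v_p = Inf, tau_e = Inf,
                                  f_e = 2000, theta = 2 * pi))
  if (is.null(best)) stop("resonance fit failed to converge from any start")
  cf <- best$par
  fitted_v <- res_model(as.list(cf))
  structure(list(v_ss = unname(cf["v_ss"]), v_p = unname(cf["v_p"]),
                 tau_e = unname(cf["tau_e"]), f_e = unname(cf["f_e"]),
                 theta = unname(cf["theta"]),
                 q_e = quality_factor(unname(cf["f_e"]), unname(cf["tau_e"])),
                 adj_r2 = adj_r2(v, fitted_v, 5), rss = best$rss,
                 from_onset = from_onset,
                 data = data.frame(t = t, v = v)),
            class = "resonance_fit")
}

#' @export
print.resonance_fit <- function(x, ...) {
  cat(sprintf(
    "Resonance fit%s: f_e %.3g Hz, tau_e %.3g ms, Q_e %.3f (V_ss %.1f mV, V_p %.2f mV), adj R^2 %.4f\n",
    if (x$from_onset) " (no peak; from onset)" else "",
    x$f_e, x$tau_e, x$q_e, x$v_ss, x$v_p, x$adj_r2))
  invisible(x)
}

#' @export
coef.resonance_fit <- function(object, ...) {
  c(v_ss = object$v_ss, v_p = object$v_p, tau_e = object$tau_e,
    f_e = object$f_e, theta = object$theta, q_e = object$q_e)
}

#' @export
predict.resonance_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t
       else if (is.data.frame(newdata)) newdata$t else newdata
  object$v_ss + object$v_p * exp(-t / object$tau_e) *
    sin(2 * pi * object$f_e * t * 1e-3 - object$theta)
}

#' Peak metrics of a current-clamp step response
#'
#' Height of the initial depolarizing transient relative to baseline, its
#' absolute peak potential, the time from step onset to the peak, and the
#' full width at half-maximum of the transient. Responses without an
#' initial extremum (monotone charging) return `NA` metrics with
#' `present = FALSE`.
#'
#' @param sweep A current-clamp [hc_sweep()].
#' @param min_prominence Required drop (mV) after the peak for it to count
#'   as a transient rather than monotone charging.
#' @return List with `present`, `height` (mV above baseline), `peak_v`
#'   (absolute mV), `time_to_peak` (ms), `width_half_max` (ms).
#' @export
peak_metrics <- function(sweep, min_prominence = 0.5) {
  stopifnot(inherits(sweep, "hc_sweep"))
  if (sweep$mode != "current_clamp")
    stop("peak metrics require a current-clamp sweep")
  seg <- sweep$segments$step
  if (is.null(seg)) stop("no step window available")
  v0 <- mean(sweep$response[sweep$time < seg[1] & sweep$time >= seg[1] - 50])
  sel <- sweep$time >= seg[1] & sweep$time < seg[2]
  t <- sweep$time[sel] - seg[1]
  v <- sweep$response[sel]
  pk <- which.max(v)
  drop_after <- v[pk] - min(v[pk:length(v)])
  if (pk == length(v) || drop_after < min_prominence) {
    return(list(present = FALSE, height = NA_real_, peak_v = NA_real_,
                time_to_peak = NA_real_, width_half_max = NA_real_))
  }
  height <- v[pk] - v0
  half <- v0 + height / 2
  above <- v >= half
  i_up <- which(above)[1]
  i_down <- pk + which(!above[pk:length(v)])[1] - 1L
  width <- if (is.na(i_down)) NA_real_ else t[i_down] - t[i_up]
  list(present = TRUE, height = height, peak_v = v[pk],
       time_to_peak = t[pk], width_half_max = width)
}
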