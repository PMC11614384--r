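# Conductance-voltage analysis: build G-V relations from tail, peak and
# steady-state currents, fit first-order Boltzmann activation/inactivation
# curves, and compute conductance densities.
#
# Sampling convention: "1 ms after the step end" / "1 ms before the step end"
# use the nearest sample at the stated offset (no interpolation; at >= 10 kHz
# the placement error is < 0.1 ms). Raw peak searches blank the first 0.5 ms
# of a segment to skip capacitive transients.

.blank_ms <- 0.5

#' Conductance-voltage relation
#'
#' @param step_v Test-step potentials, mV.
#' @param g Conductances, nS.
#' @param kind One of `"tail"`, `"peak"`, `"steady_state"`, `"h_inf"`.
#' @param e_k K+ equilibrium potential used for the driving force, mV.
#' @param measure_time Measurement time (ms from sweep start), if applicable.
#' @return An object of class `gv_curve`.
#' @export
gv_curve <- function(step_v, g, kind, e_k, measure_time = NA_real_) {
  stopifnot(length(step_v) == length(g))
  if (!all(is.finite(g))) stop("conductances must be finite")
  structure(list(step_v = as.numeric(step_v), g = as.numeric(g),
                 kind = match.arg(kind,
                   c("tail", "peak", "steady_state", "h_inf")),
                 e_k = e_k, measure_time = measure_time),
            class = "gv_curve")
}

#' @export
print.gv_curve <- function(x, ...) {
  cat(sprintf("<gv_curve> %s: %d points, V %g..%g mV, G max %.3g nS\n",
              x$kind, length(x$g), min(x$step_v), max(x$step_v), max(x$g)))
  invisible(x)
}

# Index of the sample nearest to time t within a sweep.
nearest_sample <- function(sweep, t) which.min(abs(sweep$time - t))

sweep_segments_or_stop <- function(recording) {
  if (!inherits(recording$protocol, "step_protocol"))
    stop("recording must carry a step protocol")
  protocol_segments(recording$protocol)
}

#' Tail-current G-V curve
#'
#' For each sweep, conductance is the current 1 ms after the end of the test
#' step divided by the tail driving force, plotted against the test-step
#' potential.
#'
#' @param recording A voltage-clamp [hc_recording()] with a tail segment of
#'   at least 2 ms.
#' @param e_k K+ equilibrium potential, mV (defaults to the value implied by
#'   the recording's solutions).
#' @return A [gv_curve()] of kind `"tail"`.
#' @export
extract_tail_gv <- function(recording, e_k = NULL) {
  stopifnot(inherits(recording, "hc_recording"))
  if (recording_mode(recording) != "voltage_clamp")
    stop("tail G-V requires a voltage-clamp recording")
  segs <- sweep_segments_or_stop(recording)
  proto <- recording$protocol
  if (proto$tail_dur < 2) stop("tail segment must be at least 2 ms")
  drive <- proto$tail_v - (e_k <- e_k %||%
    nernst_potential(recording$meta$k_in, recording$meta$k_out,
                     recording$meta$temperature))
  if (abs(drive) < 1)
    stop("degenerate driving force: tail potential within 1 mV of E_K")
  t_meas <- segs$tail[1] + 1
  g <- vapply(recording$sweeps, function(sw)
    sw$response[nearest_sample(sw, t_meas)] / drive, 0)
  gv_curve(proto$step_voltages, g, "tail", e_k, measure_time = t_meas)
}

#' Peak and steady-state G-V curves
#'
#' Peak conductance is taken per sweep from the maximum of the fitted
#' activation/inactivation time course (the default), or from the raw
#' maximum after capacitive blanking; steady-state conductance is the
#' current 1 ms before the end of the test step. Conductance is current over
#' driving force `V - E_K`; steps within 1 mV of `E_K` are dropped with a
#' warning. When the protocol contains a step at or below -124 mV, the peak
#' inward current on that step (HCN + Kir surrogate) is attached as
#' `i_inward_124`.
#'
#' @param recording A voltage-clamp [hc_recording()]; the test step must be
#'   at least 200 ms for the steady-state curve.
#' @param e_k K+ equilibrium potential, mV.
#' @param use_fit Take the peak from the fitted kinetic model
#'   ([select_kinetic_model()]) rather than the raw trace.
#' @return List with elements `peak` and `steady_state` ([gv_curve()]s) and
#'   `i_inward_124` (pA, or `NA`).
#' @export
extract_peak_ss_gv <- function(recording, e_k = NULL, use_fit = TRUE) {
  stopifnot(inherits(recording, "hc_recording"))
  if (recording_mode(recording) != "voltage_clamp")
    stop("peak/steady-state G-V requires a voltage-clamp recording")
  segs <- sweep_segments_or_stop(recording)
  proto <- recording$protocol
  if (proto$step_dur < 200)
    stop("test step must be >= 200 ms for a steady-state measure")
  e_k <- e_k %||% nernst_potential(recording$meta$k_in,
                                   recording$meta$k_out,
                                   recording$meta$temperature)
  keep <- abs(proto$step_voltages - e_k) >= 1
  if (!all(keep))
    warning("dropping step(s) within 1 mV of E_K: ",
            paste(proto$step_voltages[!keep], collapse = ", "))
  t_ss <- segs$step[2] - 1
  peak <- numeric(0); ss <- numeric(0)
  for (i in which(keep)) {
    sw <- recording$sweeps[[i]]
    v <- proto$step_voltages[i]
    drive <- v - e_k
    in_step <- sw$time >= segs$step[1] + .blank_ms & sw$time < segs$step[2]
    trace_t <- sw$time[in_step] - segs$step[1]
    trace_i <- sw$response[in_step]
    i_ss <- sw$response[nearest_sample(sw, t_ss)]
    i_peak <- NA_real_
    if (use_fit && drive > 0 && v > -50) {
      fit <- tryCatch(select_kinetic_model(trace_t, trace_i),
                      error = function(e) NULL)
      if (!is.null(fit)) i_peak <- max(predict(fit$fit))
    }
    if (!is.finite(i_peak))
      i_peak <- if (drive > 0) max(trace_i) else min(trace_i)
    peak <- c(peak, i_peak / drive)
    ss <- c(ss, i_ss / drive)
  }
  i_inward <- NA_real_
  i124 <- which(proto$step_voltages <= -124)
  if (length(i124)) {
    sw <- recording$sweeps[[i124[1]]]
    in_step <- sw$time >= segs$step[1] + .blank_ms & sw$time < segs$step[2]
    i_inward <- min(sw$response[in_step])
  }
  list(peak = gv_curve(proto$step_voltages[keep], peak, "peak", e_k),
       steady_state = gv_curve(proto$step_voltages[keep], ss,
                               "steady_state", e_k, measure_time = t_ss),
       i_inward_124 = i_inward)
}

# ---- Boltzmann fitting ----------------------------------------------------

#' Fit a first-order Boltzmann to a G-V curve
#'
#' Fits `G(V) = Gmin + Gmax / (1 + exp((Vhalf - V)/S))` by trust-region
#' least squares with multi-start initial guesses (midpoint from the
#' half-maximum crossing, slope from the 10-90% rise width / 4.4). For
#' curves of kind `"h_inf"` the decreasing Boltzmann
#' `G(V) = Gmin + Gmax / (1 + exp((V - Vhalf)/S))` is fitted and `S` is
#' reported positive, the convention for inactivation curves. `Gmin` is
#' constrained to be non-negative and `S` to (0.5, 40) mV.
#'
#' @param curve A [gv_curve()] with at least 5 points spanning the rising
#'   (or falling) phase.
#' @return An object of class `boltzmann_fit` with components `g_min`,
#'   `g_max` (the fitted Boltzmann amplitude), `g_sat` (`g_min + g_max`, the
#'   saturating conductance), `v_half`, `s`, `rss`, `n_points`, `kind`,
#'   `degenerate`.
#' @export
fit_boltzmann <- function(curve) {
  stopifnot(inherits(curve, "gv_curve"))
  v <- curve$step_v; g <- curve$g
  if (length(v) < 5) stop("need at least 5 points to fit a Boltzmann")
  decreasing <- curve$kind == "h_inf"
  span <- diff(range(g))
  degenerate <- span < 0.02 * max(abs(g), 1e-12) || span == 0
  if (degenerate) {
    # flat curve: report the level, flag it, skip the solver
    return(structure(list(g_min = min(g), g_max = span, g_sat = max(g),
                          v_half = NA_real_, s = NA_real_,
                          rss = sum((g - mean(g))^2), n_points = length(v),
                          kind = curve$kind, degenerate = TRUE,
                          decreasing = decreasing, nls = NULL,
                          data = data.frame(v = v, g = g)),
                     class = "boltzmann_fit"))
  }
  # initial guesses
  g_lo <- min(g); g_hi <- max(g)
  half <- (g_lo + g_hi) / 2
  ord <- order(v)
  vs <- v[ord]; gs <- g[ord]
  cross <- function(level) {
    idx <- if (decreasing) which(gs <= level) else which(gs >= level)
    if (length(idx) == 0) return(stats::median(vs))
    vs[idx[1]]
  }
  v50 <- cross(half)
  v10 <- cross(g_lo + 0.1 * span)
  v90 <- cross(g_lo + 0.9 * span)
  s0 <- max(abs(v90 - v10) / 4.4, 1)
  sgn <- if (decreasing) -1 else 1
  model <- function(p) {
    p[["gmin"]] + p[["gmax"]] / (1 + exp(sgn * (p[["vhalf"]] - v) / p[["s"]]))
  }
  starts <- list(
    c(gmin = max(g_lo, 0), gmax = span, vhalf = v50, s = s0),
    c(gmin = 0, gmax = g_hi, vhalf = stats::median(v), s = 8),
    c(gmin = 0, gmax = g_hi, vhalf = v50, s = 4))
  best <- lm_multistart(starts, function(p) g - model(p),
                        lower = c(gmin = 0, gmax = 0, vhalf = -150, s = 0.5),
                        upper = c(gmin = Inf, gmax = Inf, vhalf = 60,
                                  s = 40))
  if (is.null(best)) stop("Boltzmann fit failed to converge from any start")
  cf <- best$par
  structure(list(g_min = unname(cf["gmin"]), g_max = unname(cf["gmax"]),
                 g_sat = unname(cf["gmin"] + cf["gmax"]),
                 v_half = unname(cf["vhalf"]), s = unname(cf["s"]),
                 rss = best$rss, n_points = length(v), kind = curve$kind,
                 degenerate = degenerate, decreasing = decreasing,
                 data = data.frame(v = v, g = g)),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "Boltzmann fit (%s%s): V_half %.2f mV, S %.2f mV, Gmax %.3g nS (Gmin %.3g, saturating %.3g)\n",
    x$kind, if (x$degenerate) ", degenerate" else "",
    x$v_half, x$s, x$g_max, x$g_min, x$g_sat))
  cat(sprintf("  %d points, RSS %.4g\n", x$n_points, x$rss))
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(g_min = object$g_min, g_max = object$g_max, v_half = object$v_half,
    s = object$s)
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$data$v
       else if (is.data.frame(newdata)) newdata$v else newdata
  sgn <- if (object$decreasing) -1 else 1
  object$g_min + object$g_max /
    (1 + exp(sgn * (object$v_half - v) / object$s))
}

#' @export
residuals.boltzmann_fit <- function(object, ...) {
  object$data$g - predict(object)
}

#' Steady-state inactivation (h-infinity) curve
#'
#' From an inactivation-protocol recording (iterated conditioning voltages
#' followed by a fixed tail readout), measures the available tail current
#' per conditioning voltage, normalizes by the maximum (the most negative
#' conditioning voltage should release all inactivation), and fits the
#' decreasing Boltzmann. `S` is reported positive.
#'
#' The tail readout is the peak of the tail current after `settle_ms`
#' (default 10 ms), i.e. after the activation gates have re-equilibrated at
#' the tail potential. Reading earlier would index the activation state
#' carried over from the conditioning step (channels left open by
#' depolarized conditioning) rather than availability; after settling, the
#' tail current is proportional to the non-inactivated fraction, which is
#' what the h-infinity curve measures.
#'
#' @param recording A voltage-clamp [hc_recording()] from the
#'   `"inactivation"` protocol of [build_protocol()].
#' @param e_k K+ equilibrium potential, mV.
#' @param settle_ms Activation-settling delay before the tail readout, ms.
#' @return A [fit_boltzmann()] result of kind `"h_inf"`; the normalized
#'   curve is attached as `$data`.
#' @export
fit_inactivation_curve <- function(recording, e_k = NULL, settle_ms = 15) {
  stopifnot(inherits(recording, "hc_recording"))
  if (recording_mode(recording) != "voltage_clamp")
    stop("inactivation curve requires a voltage-clamp recording")
  segs <- sweep_segments_or_stop(recording)
  proto <- recording$protocol
  e_k <- e_k %||% nernst_potential(recording$meta$k_in,
                                   recording$meta$k_out,
                                   recording$meta$temperature)
  drive <- proto$tail_v - e_k
  if (abs(drive) < 1)
    stop("degenerate driving force: tail potential within 1 mV of E_K")
  t_read <- segs$tail[1] + settle_ms
  peak_tail <- vapply(recording$sweeps, function(sw)
    sw$response[nearest_sample(sw, t_read)], 0)
  g <- peak_tail / drive
  if (max(g) > g[1] * 1.02)
    warning("non-monotone normalization: maximum tail current is not at ",
            "the most negative conditioning voltage")
  g_norm <- g / max(g)
  curve <- gv_curve(proto$step_voltages, g_norm, "h_inf", e_k)
  fit_boltzmann(curve)
}

#' Conductance density
#'
#' @param g_max Maximal conductance, nS.
#' @param cm Membrane capacitance, pF.
#' @return Density in nS/pF.
#' @export
conductance_density <- function(g_max, cm) {
  if (any(cm <= 0)) stop("cm must be positive")
  g_max / cm
}
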