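# Drug-subtraction analysis: isolate drug-sensitive currents by
# control-minus-drug subtraction, percent block of steady-state current, and
# drug-sensitive tail G-V curves (the Kv7/XE991 and BK/iberiotoxin
# workflows). No rundown or drift correction is applied between control and
# drug epochs.

#' Pair a control and a drug recording
#'
#' Sweeps are paired by test-step voltage (nearest match within `tol` mV);
#' the two recordings must share the same protocol timing and cell
#' metadata.
#'
#' @param control,drug Voltage-clamp [hc_recording()]s.
#' @param drug_name Label, e.g. `"XE991"`.
#' @param dose Dose label (e.g. `"10 uM"`).
#' @param tol Sweep-pairing tolerance, mV.
#' @return An object of class `drug_comparison`.
#' @export
drug_comparison <- function(control, drug, drug_name = "drug", dose = NA,
                            tol = 1) {
  stopifnot(inherits(control, "hc_recording"), inherits(drug, "hc_recording"))
  if (recording_mode(control) != "voltage_clamp" ||
      recording_mode(drug) != "voltage_clamp")
    stop("drug comparison requires voltage-clamp recordings")
  pc <- control$protocol; pd <- drug$protocol
  fields <- c("holding", "holding_dur", "prestep_v", "prestep_dur",
              "step_dur", "tail_v", "tail_dur")
  differing <- fields[vapply(fields, function(f)
    !isTRUE(all.equal(pc[[f]], pd[[f]])), TRUE)]
  if (length(differing))
    stop("protocol mismatch between control and drug: ",
         paste(differing, collapse = ", "))
  matched <- vapply(pc$step_voltages, function(v) {
    j <- which.min(abs(pd$step_voltages - v))
    if (abs(pd$step_voltages[j] - v) > tol) NA_integer_ else j
  }, 0L)
  if (anyNA(matched))
    stop("protocol mismatch: no drug sweep within ", tol, " mV of step(s) ",
         paste(pc$step_voltages[is.na(matched)], collapse = ", "))
  structure(list(control = control, drug = drug, drug_name = drug_name,
                 dose = dose, matched = matched),
            class = "drug_comparison")
}

#' Drug-sensitive current by subtraction
#'
#' Per-sample `control - drug` current for every matched sweep pair. The
#' result is a voltage-clamp recording labeled as drug-sensitive.
#'
#' @param comparison A [drug_comparison()].
#' @return An [hc_recording()] of the drug-sensitive current.
#' @export
subtract_traces <- function(comparison) {
  stopifnot(inherits(comparison, "drug_comparison"))
  ctl <- comparison$control
  drg <- comparison$drug
  sweeps <- lapply(seq_along(ctl$sweeps), function(k) {
    sa <- ctl$sweeps[[k]]
    sb <- drg$sweeps[[comparison$matched[k]]]
    if (length(sa$time) != length(sb$time) ||
        max(abs(sa$time - sb$time)) > 1e-9)
      stop("matched sweeps have different time bases")
    sw <- sa
    sw$response <- sa$response - sb$response
    sw
  })
  out <- hc_recording(ctl$meta, ctl$protocol, sweeps)
  out$drug_sensitive <- comparison$drug_name
  out
}

# Steady-state current of a sweep: mean of the final 10 ms of the step.
step_ss_current <- function(sweep, segs, window_ms = 10) {
  sel <- sweep$time >= segs$step[2] - window_ms & sweep$time < segs$step[2]
  mean(sweep$response[sel])
}

#' Percent block of steady-state current
#'
#' `100 * (I_control - I_drug) / I_control` at the sweep nearest `at_v`,
#' with steady state taken as the mean of the final 10 ms of the step.
#'
#' @param comparison A [drug_comparison()].
#' @param at_v Test-step voltage at which to evaluate, mV.
#' @param noise_floor Currents with `|I_control|` below this (pA) are
#'   treated as undefined.
#' @return Percent block.
#' @export
percent_block <- function(comparison, at_v, noise_floor = 1) {
  stopifnot(inherits(comparison, "drug_comparison"))
  ctl <- comparison$control
  segs <- protocol_segments(ctl$protocol)
  k <- which.min(abs(ctl$protocol$step_voltages - at_v))
  i_c <- step_ss_current(ctl$sweeps[[k]], segs)
  i_d <- step_ss_current(comparison$drug$sweeps[[comparison$matched[k]]],
                         segs)
  if (abs(i_c) < noise_floor)
    stop("percent block undefined: control steady-state current below ",
         "noise floor at ", ctl$protocol$step_voltages[k], " mV")
  100 * (i_c - i_d) / i_c
}

#' Drug-sensitive tail G-V curve and Boltzmann fit
#'
#' Builds the tail G-V relation of the subtracted (drug-sensitive)
#' recording and fits the Boltzmann.
#'
#' @param comparison A [drug_comparison()].
#' @param e_k K+ equilibrium potential, mV.
#' @return List with `curve` (a [gv_curve()]) and `fit` (a
#'   [fit_boltzmann()] result; flagged degenerate when the drug had no
#'   effect).
#' @export
drug_sensitive_gv <- function(comparison, e_k = NULL) {
  sub <- subtract_traces(comparison)
  curve <- extract_tail_gv(sub, e_k)
  fit <- fit_boltzmann(curve)
  list(curve = curve, fit = fit)
}
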