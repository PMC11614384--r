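# Data model for whole-cell recordings: sweeps, step protocols, metadata,
# electrochemical/electrode corrections, and on-disk round-trip.
#
# Units, repo-wide: mV, pA, ms, nS, pF, GOhm (MOhm only in metadata);
# outward current positive.

#' Single whole-cell sweep
#'
#' A sweep is one trace of a voltage-clamp or current-clamp recording:
#' a uniform time grid, the command channel (mV in voltage clamp, pA in
#' current clamp) and the recorded response (pA in voltage clamp, mV in
#' current clamp).
#'
#' @param time Time grid in ms; strictly increasing, uniform step.
#' @param command Command waveform (mV or pA depending on `mode`).
#' @param response Recorded waveform (pA or mV depending on `mode`).
#' @param mode `"voltage_clamp"` or `"current_clamp"`.
#' @param segments Optional named list of segment boundaries (ms), used by
#'   analysis code to locate prestep/step/tail windows.
#' @return An object of class `hc_sweep`.
#' @export
hc_sweep <- function(time, command, response,
                     mode = c("voltage_clamp", "current_clamp"),
                     segments = NULL) {
  mode <- match.arg(mode)
  time <- as.numeric(time); command <- as.numeric(command)
  response <- as.numeric(response)
  n <- length(time)
  if (n < 2L) stop("sweep needs at least two samples")
  if (length(command) != n || length(response) != n)
    stop("command and response must have the same length as time")
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stop("time grid must be uniform within 1 ppm")
  sample_rate <- 1 / mean(dt) # kHz
  structure(list(time = time, command = command, response = response,
                 mode = mode, sample_rate = sample_rate,
                 segments = segments),
            class = "hc_sweep")
}

#' @export
print.hc_sweep <- function(x, ...) {
  cat(sprintf("<hc_sweep> %s, %d samples @ %.3g kHz, %.4g ms\n",
              x$mode, length(x$time), x$sample_rate,
              x$time[length(x$time)] - x$time[1]))
  invisible(x)
}

sweep_dt <- function(sweep) 1 / sweep$sample_rate

#' Voltage-step protocol
#'
#' Describes the standard hair-cell voltage protocol: a holding segment, a
#' conditioning prestep, a family of iterated test steps, and a fixed tail
#' segment used to read tail currents.
#'
#' @param holding Holding potential, mV.
#' @param prestep_v,prestep_dur Prestep potential (mV) and duration (ms).
#' @param step_voltages Test-step potentials, mV, sorted ascending.
#' @param step_dur Test-step duration, ms.
#' @param tail_v,tail_dur Tail potential (mV) and duration (ms).
#' @param holding_dur Duration of the initial holding segment, ms.
#' @param kind Optional label (`"type_I"`, `"type_II"`, `"inactivation"`).
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(holding, prestep_v, prestep_dur, step_voltages,
                          step_dur, tail_v, tail_dur, holding_dur = 10,
                          kind = NULL) {
  if (prestep_dur <= 0 || step_dur <= 0 || tail_dur <= 0 || holding_dur <= 0)
    stop("all segment durations must be positive")
  step_voltages <- as.numeric(step_voltages)
  if (length(step_voltages) == 0) stop("step_voltages must be non-empty")
  if (is.unsorted(step_voltages, strictly = FALSE))
    stop("step_voltages must be sorted ascending")
  structure(list(holding = holding, holding_dur = holding_dur,
                 prestep_v = prestep_v, prestep_dur = prestep_dur,
                 step_voltages = step_voltages, step_dur = step_dur,
                 tail_v = tail_v, tail_dur = tail_dur, kind = kind),
            class = "step_protocol")
}

#' @export
print.step_protocol <- function(x, ...) {
  cat(sprintf(
    "<step_protocol%s> hold %g mV | prestep %g mV/%g ms | %d steps %g..%g mV/%g ms | tail %g mV/%g ms\n",
    if (is.null(x$kind)) "" else paste0(": ", x$kind),
    x$holding, x$prestep_v, x$prestep_dur, length(x$step_voltages),
    min(x$step_voltages), max(x$step_voltages), x$step_dur,
    x$tail_v, x$tail_dur))
  invisible(x)
}

# Segment boundary times (ms from sweep start) for a protocol.
protocol_segments <- function(protocol) {
  t0 <- 0
  t1 <- t0 + protocol$holding_dur
  t2 <- t1 + protocol$prestep_dur
  t3 <- t2 + protocol$step_dur
  t4 <- t3 + protocol$tail_dur
  list(holding = c(t0, t1), prestep = c(t1, t2),
       step = c(t2, t3), tail = c(t3, t4))
}

#' Per-recording metadata
#'
#' @param cell_type `"type_I"` or `"type_II"`.
#' @param genotype `"+/+"`, `"+/-"` or `"-/-"`.
#' @param zone `"LES"`, `"MES"` or `"striola"`.
#' @param age Age in postnatal days.
#' @param temperature Recording temperature, degrees C.
#' @param rs_total Total series resistance, MOhm.
#' @param rs_compensation Compensated fraction of the series resistance, 0-1.
#' @param ljp Liquid junction potential, mV (magnitude as applied; the
#'   corrected membrane potential is command - ljp).
#' @param k_in,k_out Internal and external K+ concentrations, mM.
#' @param cm_reported Membrane capacitance reported by the amplifier, pF,
#'   or `NA` when absent.
#' @return An object of class `recording_meta`.
#' @export
recording_meta <- function(cell_type = c("type_I", "type_II"),
                           genotype = c("+/+", "+/-", "-/-"),
                           zone = c("LES", "MES", "striola"),
                           age = 30, temperature = 25,
                           rs_total = 10, rs_compensation = 0.7,
                           ljp = 4, k_in = 165, k_out = 5.77,
                           cm_reported = NA_real_) {
  cell_type <- match.arg(cell_type)
  genotype <- match.arg(genotype)
  zone <- match.arg(zone)
  if (rs_compensation < 0 || rs_compensation >= 1)
    stop("rs_compensation must be in [0, 1)")
  if (k_in <= 0 || k_out <= 0) stop("K+ concentrations must be positive")
  if (age < 0) stop("age must be non-negative")
  structure(list(cell_type = cell_type, genotype = genotype, zone = zone,
                 age = age, temperature = temperature, rs_total = rs_total,
                 rs_compensation = rs_compensation, ljp = ljp,
                 k_in = k_in, k_out = k_out, cm_reported = cm_reported),
            class = "recording_meta")
}

#' Whole-cell recording: metadata + protocol + sweeps
#'
#' @param meta A [recording_meta()].
#' @param protocol A [step_protocol()] (voltage clamp) or a numeric vector of
#'   injected current steps in pA (current clamp).
#' @param sweeps List of [hc_sweep()] objects, one per protocol step.
#' @return An object of class `hc_recording`.
#' @export
hc_recording <- function(meta, protocol, sweeps) {
  stopifnot(inherits(meta, "recording_meta"), is.list(sweeps),
            length(sweeps) > 0)
  modes <- vapply(sweeps, function(s) s$mode, "")
  if (length(unique(modes)) != 1L)
    stop("all sweeps must share one recording mode")
  rates <- vapply(sweeps, function(s) s$sample_rate, 0)
  if (diff(range(rates)) > 1e-6 * mean(rates))
    stop("all sweeps must share one sample rate")
  if (inherits(protocol, "step_protocol") &&
      length(sweeps) != length(protocol$step_voltages))
    stop("need one sweep per protocol step")
  structure(list(meta = meta, protocol = protocol, sweeps = sweeps),
            class = "hc_recording")
}

#' @export
print.hc_recording <- function(x, ...) {
  cat(sprintf("<hc_recording> %s %s %s: %d %s sweep(s)\n",
              x$meta$cell_type, x$meta$genotype, x$meta$zone,
              length(x$sweeps), x$sweeps[[1]]$mode))
  invisible(x)
}

recording_mode <- function(recording) recording$sweeps[[1]]$mode

#' Nernst equilibrium potential for K+
#'
#' `E_K = (R*T/F) * ln(k_out / k_in)` in mV. With the study's solutions
#' (165 mM internal, ~5.77 mM external, 25 C) this gives about -86.1 mV.
#'
#' @param k_in Internal K+ concentration, mM.
#' @param k_out External K+ concentration, mM.
#' @param temperature Temperature in degrees C.
#' @return Equilibrium potential in mV.
#' @examples
#' nernst_potential(165, 5.77, 25)
#' @export
nernst_potential <- function(k_in, k_out, temperature = 25) {
  if (any(k_in <= 0) || any(k_out <= 0))
    stop("concentrations must be positive")
  R <- 8.31446261815324      # J/(mol K)
  Fa <- 96485.33212          # C/mol
  tk <- temperature + 273.15
  1000 * (R * tk / Fa) * log(k_out / k_in)
}

#' Correct command potentials for residual series resistance and LJP
#'
#' Replaces the command channel of a voltage-clamp recording with the
#' estimated membrane potential
#' `V_m = command - I * Rs_residual - ljp`, where
#' `Rs_residual = rs_total * (1 - rs_compensation)` (MOhm; the product
#' `pA * MOhm` is scaled to mV). The uncorrected command is preserved in
#' each sweep as `command_raw`.
#'
#' @param recording A voltage-clamp [hc_recording()].
#' @return The recording with corrected command channels.
#' @export
correct_potentials <- function(recording) {
  stopifnot(inherits(recording, "hc_recording"))
  if (recording_mode(recording) != "voltage_clamp")
    stop("correct_potentials requires a voltage-clamp recording")
  meta <- recording$meta
  rs_res_gohm <- meta$rs_total * (1 - meta$rs_compensation) * 1e-3 # GOhm
  recording$sweeps <- lapply(recording$sweeps, function(sw) {
    raw <- if (is.null(sw$command_raw)) sw$command else sw$command_raw
    sw$command_raw <- raw
    sw$command <- raw - sw$response * rs_res_gohm - meta$ljp
    sw
  })
  recording
}

#' Build a standard voltage protocol
#'
#' The standard type I protocol holds near rest (-74 mV), presteps to
#' -124 mV for 200 ms to deactivate the low-voltage-activated conductance,
#' applies 500 ms test steps, and reads 50 ms tails at -44 mV. The type II
#' protocol holds at -64 mV with a 50 ms prestep (removing baseline
#' inactivation of the A current) and 200 ms test steps. The inactivation
#' protocol iterates 500 ms conditioning voltages from -124 to 0 mV and reads
#' the peak tail current at -44 mV.
#'
#' @param kind `"type_I"`, `"type_II"` or `"inactivation"`.
#' @param ... Named overrides of any [step_protocol()] field.
#' @return A [step_protocol()].
#' @export
build_protocol <- function(kind = c("type_I", "type_II", "inactivation"),
                           ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    type_I = list(holding = -74, prestep_v = -124, prestep_dur = 200,
                  step_voltages = seq(-124, 30, by = 10), step_dur = 500,
                  tail_v = -44, tail_dur = 50),
    type_II = list(holding = -64, prestep_v = -124, prestep_dur = 50,
                   step_voltages = seq(-124, 30, by = 10), step_dur = 200,
                   tail_v = -44, tail_dur = 50),
    inactivation = list(holding = -64, prestep_v = -124, prestep_dur = 50,
                        step_voltages = c(-124, seq(-110, 0, by = 10)),
                        step_dur = 500, tail_v = -44, tail_dur = 50))
  overrides <- list(...)
  bad <- setdiff(names(overrides),
                 c("holding", "prestep_v", "prestep_dur", "step_voltages",
                   "step_dur", "tail_v", "tail_dur", "holding_dur"))
  if (length(bad)) stop("unknown protocol fields: ", paste(bad, collapse = ", "))
  args <- utils::modifyList(defaults, overrides)
  args$kind <- kind
  do.call(step_protocol, args)
}

# ---- on-disk format -------------------------------------------------------
# One directory per recording: meta.json (RecordingMeta fields + protocol)
# and sweep_NNN.tsv files with columns time, command, response.

#' Write a recording to a directory
#'
#' @param recording An [hc_recording()].
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "hc_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- unclass(recording$meta)
  proto <- recording$protocol
  if (inherits(proto, "step_protocol")) {
    proto <- c(unclass(proto), list(.type = "step_protocol"))
  } else {
    proto <- list(.type = "current_steps", steps = as.numeric(proto))
  }
  obj <- list(meta = meta, protocol = proto,
              mode = recording_mode(recording),
              n_sweeps = length(recording$sweeps))
  jsonlite::write_json(obj, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  for (i in seq_along(recording$sweeps)) {
    sw <- recording$sweeps[[i]]
    df <- data.frame(time = sw$time, command = sw$command,
                     response = sw$response)
    utils::write.table(
      format(df, digits = 17, scientific = TRUE, trim = TRUE),
      file.path(path, sprintf("sweep_%03d.tsv", i)),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a recording from a directory written by [write_recording()]
#'
#' @param path Recording directory.
#' @return An [hc_recording()].
#' @export
read_recording <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file))
    stop("parse error: missing metadata file meta.json in ", path)
  obj <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  required <- c("meta", "protocol", "mode", "n_sweeps")
  missing <- setdiff(required, names(obj))
  if (length(missing))
    stop("parse error: meta.json missing field(s): ",
         paste(missing, collapse = ", "))
  m <- obj$meta
  meta <- recording_meta(
    cell_type = m$cell_type, genotype = m$genotype, zone = m$zone,
    age = m$age, temperature = m$temperature, rs_total = m$rs_total,
    rs_compensation = m$rs_compensation, ljp = m$ljp,
    k_in = m$k_in, k_out = m$k_out,
    cm_reported = if (is.null(m$cm_reported)) NA_real_ else m$cm_reported)
  p <- obj$protocol
  protocol <- if (identical(p$.type, "step_protocol")) {
    step_protocol(holding = p$holding, prestep_v = p$prestep_v,
                  prestep_dur = p$prestep_dur,
                  step_voltages = p$step_voltages, step_dur = p$step_dur,
                  tail_v = p$tail_v, tail_dur = p$tail_dur,
                  holding_dur = p$holding_dur,
                  kind = if (is.null(p$kind)) NULL else p$kind)
  } else as.numeric(p$steps)
  sweeps <- lapply(seq_len(obj$n_sweeps), function(i) {
    f <- file.path(path, sprintf("sweep_%03d.tsv", i))
    if (!file.exists(f)) stop("parse error: missing sweep file ", basename(f))
    df <- utils::read.delim(f)
    segs <- if (inherits(protocol, "step_protocol"))
      protocol_segments(protocol) else NULL
    hc_sweep(df$time, df$command, df$response, mode = obj$mode,
             segments = segs)
  })
  hc_recording(meta, protocol, sweeps)
}
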