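# End-to-end batch analysis: simulate cohorts of preset-based cells with
# between-cell variability (or load saved recordings), run the per-cell
# analyses (G-V, kinetics, passive, resonance, drug subtraction), and
# summarize by group.

#' Perturbed copy of a preset cell (between-cell variability)
#'
#' Scales each maximal conductance by a log-normal factor and jitters each
#' activation midpoint, emulating cell-to-cell scatter around the group
#' means. Deterministic for a given seed.
#'
#' @param cell A [cell_model()].
#' @param seed Integer seed.
#' @param cv_g Coefficient of variation of the conductance scale factors.
#' @param sd_vhalf SD of the midpoint jitter, mV.
#' @return A perturbed [cell_model()].
#' @export
make_cell_variant <- function(cell, seed, cv_g = 0.12, sd_vhalf = 1) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv_g^2))
  cell$conductances <- lapply(cell$conductances, function(spec) {
    spec$g_max <- spec$g_max * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    if (!is.null(spec$activation) && spec$name != "gLeak")
      spec$activation$v_half <- spec$activation$v_half +
        stats::rnorm(1, 0, sd_vhalf)
    spec
  })
  cell
}

#' Apply a pharmacological block to a model
#'
#' Scales the targeted conductance(s) by `1 - fraction`. `"XE991"` targets
#' the Kv7 delayed rectifier (default fraction 0.5, the approximate block at
#' 10 uM, near the half-blocking dose); `"IBTX"` targets BK channels, which
#' the model does not carry, so it is a no-op by construction.
#'
#' @param cell A [cell_model()].
#' @param drug `"XE991"` or `"IBTX"`.
#' @param fraction Blocked fraction of the targeted conductance.
#' @return The modified [cell_model()].
#' @export
apply_drug <- function(cell, drug = c("XE991", "IBTX"), fraction = 0.5) {
  drug <- match.arg(drug)
  target <- switch(drug, XE991 = "gDR_Kv7", IBTX = "gBK")
  cell$conductances <- lapply(cell$conductances, function(spec) {
    if (spec$name == target) spec$g_max <- spec$g_max * (1 - fraction)
    spec
  })
  cell
}

# Voltage-clamp measures for one recording.
measures_from_vc <- function(rec, analyses, cm = NA_real_) {
  out <- list()
  meta <- rec$meta
  if ("gv" %in% analyses) {
    if (meta$cell_type == "type_I") {
      fit <- fit_boltzmann(extract_tail_gv(rec))
      out$v_half <- fit$v_half; out$s <- fit$s; out$g_max <- fit$g_sat
    } else {
      curves <- extract_peak_ss_gv(rec, use_fit = FALSE)
      pf <- fit_boltzmann(curves$peak)
      sf <- fit_boltzmann(curves$steady_state)
      out$peak_v_half <- pf$v_half; out$peak_s <- pf$s
      out$ss_v_half <- sf$v_half; out$ss_s <- sf$s
      out$g_max <- pf$g_sat
      out$i_inward_124 <- curves$i_inward_124
    }
    if (is.finite(cm)) out$g_density <- out$g_max / cm
  }
  if ("kinetics" %in% analyses && meta$cell_type == "type_II") {
    k30 <- which.min(abs(rec$protocol$step_voltages - 30))
    sel <- select_kinetic_model(rec$sweeps[[k30]])
    out$kinetic_model <- sel$model
    out$tau_w <- sel$fit$tau_w
    out$z <- sel$fit$z
    out$f <- sel$fit$f
    out$tau_zf <- if (sel$model == "eq3-full") sel$fit$tau_zf else NA_real_
    cls <- classify_a_current(rec$sweeps[[k30]])
    out$a_type <- as.character(cls)
    out$pct_inact <- attr(cls, "percent_inactivation")
  }
  out
}

# Current-clamp measures for one recording.
measures_from_cc <- function(rec, analyses) {
  out <- list()
  if ("passive" %in% analyses) {
    pf <- fit_passive_response(rec)
    out$v_rest <- pf$v_rest; out$r_in <- pf$r_in
    out$tau_rc <- pf$tau_rc; out$cm_est <- pf$cm_est
  }
  if ("resonance" %in% analyses) {
    sw <- rec$sweeps[[length(rec$sweeps)]] # largest step
    rf <- fit_resonance(sw)
    out$f_e <- rf$f_e; out$tau_e <- rf$tau_e; out$q_e <- rf$q_e
    pm <- peak_metrics(sw)
    out$peak_height <- pm$height; out$time_to_peak <- pm$time_to_peak
  }
  out
}

#' Run every applicable analysis on one saved recording
#'
#' Dispatches on the recording mode: voltage-clamp recordings get G-V and
#' kinetic analyses, current-clamp recordings get passive and resonance
#' analyses.
#'
#' @param recording An [hc_recording()].
#' @param analyses Subset of `c("gv", "kinetics", "passive", "resonance")`.
#' @return Named list of per-cell measures.
#' @export
analyze_recording <- function(recording,
                              analyses = c("gv", "kinetics", "passive",
                                           "resonance")) {
  stopifnot(inherits(recording, "hc_recording"))
  meta <- recording$meta
  base <- list(cell_type = meta$cell_type, genotype = meta$genotype,
               zone = meta$zone, age = meta$age)
  more <- if (recording_mode(recording) == "voltage_clamp")
    measures_from_vc(recording, analyses, cm = meta$cm_reported)
  else measures_from_cc(recording, analyses)
  c(base, more)
}

# Simulate and analyse one model cell; returns a named list of measures.
analyze_cell <- function(cell, config, analyses, cc_steps = NULL) {
  meta <- meta_from_label(cell$label, config)
  out <- list(label = cell$label, cell_type = meta$cell_type,
              genotype = meta$genotype, zone = meta$zone)
  if (any(c("gv", "kinetics") %in% analyses)) {
    proto <- build_protocol(meta$cell_type)
    vc <- simulate_voltage_clamp(cell, proto, config, meta = meta)
    out <- c(out, measures_from_vc(vc, analyses, cm = cell$cm))
  }
  if (any(c("passive", "resonance") %in% analyses)) {
    if (is.null(cc_steps)) {
      r_guess <- 1 / max(slope_conductance(cell, zero_current_potential(cell)),
                         1e-3)
      small <- signif(8 / r_guess, 2) # ~8 mV deflection
      cc_steps <- c(-small, small, 4 * small)
    }
    config_cc <- sim_config(dt = config$dt, out_dt = config$dt,
                            seed = config$seed, noise_sd = config$noise_sd)
    cc <- simulate_current_clamp(cell, cc_steps, config_cc, meta = meta)
    out <- c(out, measures_from_cc(cc, analyses))
  }
  if ("drug" %in% analyses) {
    proto <- build_protocol(meta$cell_type)
    ctl <- simulate_voltage_clamp(cell, proto, config)
    drg <- simulate_voltage_clamp(apply_drug(cell, "XE991"), proto, config)
    cmp <- drug_comparison(ctl, drg, "XE991", "10 uM")
    out$xe991_block <- percent_block(cmp, at_v = 30)
  }
  out
}

#' Run the end-to-end cohort pipeline
#'
#' Each entry of `cohort` is either a preset label
#' (`"<cell_type>:<genotype>:<zone>"`, simulated `n_per_group` times with
#' between-cell variability and optional recording noise) or a directory
#' containing a saved recording (loaded with [read_recording()] and analysed
#' as-is). The requested analyses run per cell; per-cell failures are logged
#' and excluded, never fatal to the batch. Deterministic for a given seed.
#'
#' @param cohort Character vector of preset labels (see [preset_labels()])
#'   and/or recording directories.
#' @param n_per_group Simulated cells per preset label.
#' @param seed Integer master seed.
#' @param analyses Subset of `c("gv", "kinetics", "passive", "resonance",
#'   "drug")`.
#' @param noise_sd Recording noise SD passed to the simulator.
#' @param cv_g,sd_vhalf Between-cell variability (see
#'   [make_cell_variant()]).
#' @return An object of class `pipeline_report`: `cells` (per-cell data
#'   frame), `summaries` (list of [summarize_table()] outputs),
#'   `comparisons` (list of [compare_groups()] outputs), `failures`
#'   (character log).
#' @export
run_pipeline <- function(cohort, n_per_group = 6, seed = 1L,
                         analyses = c("gv", "passive"),
                         noise_sd = 0, cv_g = 0.12, sd_vhalf = 1) {
  if (length(cohort) == 0) {
    warning("empty cohort: returning an empty report")
    return(structure(list(cells = data.frame(), summaries = list(),
                          comparisons = list(), failures = character()),
                     class = "pipeline_report"))
  }
  rows <- list(); failures <- character()
  cell_idx <- 0L
  add_row <- function(row, id) {
    row$cell_id <- id
    rows[[length(rows) + 1L]] <<- as.data.frame(row, stringsAsFactors = FALSE)
  }
  for (lab in cohort) {
    if (dir.exists(lab)) {
      cell_idx <- cell_idx + 1L
      row <- tryCatch(analyze_recording(read_recording(lab), analyses),
                      error = function(e) e)
      if (inherits(row, "error"))
        failures <- c(failures, sprintf("%s: %s", lab,
                                        conditionMessage(row)))
      else add_row(c(list(label = lab), row), cell_idx)
      next
    }
    parts <- strsplit(lab, ":", fixed = TRUE)[[1]]
    base <- make_preset(parts[1], parts[2], parts[3])
    for (r in seq_len(n_per_group)) {
      cell_idx <- cell_idx + 1L
      cell_seed <- (seed * 10007L + cell_idx * 7919L) %% .Machine$integer.max
      cell <- make_cell_variant(base, cell_seed, cv_g, sd_vhalf)
      config <- sim_config(seed = cell_seed, noise_sd = noise_sd)
      row <- tryCatch(analyze_cell(cell, config, analyses),
                      error = function(e) e)
      if (inherits(row, "error"))
        failures <- c(failures, sprintf("%s #%d: %s", lab, r,
                                        conditionMessage(row)))
      else add_row(row, cell_idx)
    }
  }
  cells <- if (length(rows)) {
    all_names <- unique(unlist(lapply(rows, names)))
    do.call(rbind, lapply(rows, function(r) {
      r[setdiff(all_names, names(r))] <- NA
      r[all_names]
    }))
  } else data.frame()
  measures <- setdiff(names(cells)[vapply(cells, is.numeric, TRUE)],
                      c("cell_id", "age"))
  summaries <- list(); comparisons <- list()
  for (m in measures) {
    ok <- is.finite(cells[[m]])
    if (!any(ok)) next
    gm <- grouped_measure(cells[[m]][ok], cells$genotype[ok],
                          cells$zone[ok], cells$cell_type[ok], measure = m)
    summaries[[m]] <- summarize_table(gm)
    comparisons[[m]] <- tryCatch(compare_groups(gm),
                                 error = function(e) NULL)
  }
  structure(list(cells = cells, summaries = summaries,
                 comparisons = comparisons, failures = failures),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d cell(s), %d measure(s), %d failure(s)\n",
              nrow(x$cells), length(x$summaries), length(x$failures)))
  for (m in names(x$summaries)) {
    cat("\n--", m, "--\n")
    print(x$summaries[[m]][, c("genotype", "zone", "formatted")])
  }
  if (length(x$failures)) cat("\nFailures:\n ",
                              paste(x$failures, collapse = "\n  "), "\n")
  invisible(x)
}
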