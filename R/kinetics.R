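# Time-course fitting of outward K+ currents at fixed voltage:
# activation-only fits, activation plus bi-exponential inactivation, the
# adjusted-R^2 model-selection rule, percent inactivation, and the A-current
# classification rule (inactivates by over 30% within 200 ms).
#
# The fit window starts 0.5 ms after step onset (capacitive blanking); time
# is measured from step onset throughout. The state factor n is an integer
# fixed at 3 by default. The slow inactivation time constant is
# parameterized as tau_zs = tau_zf * (1 + exp(u)), which enforces
# tau_zf < tau_zs without a constraint boundary.

kin_blank_ms <- 0.5
.kin_max_points <- 4000L

# Accept (t, i) or an hc_sweep (+ its step segment) and return a blanked,
# decimated data frame with t measured from step onset.
kin_trace <- function(t, i = NULL) {
  if (inherits(t, "hc_sweep")) {
    sw <- t
    if (is.null(sw$segments$step))
      stop("sweep carries no step segment; pass t and i explicitly")
    on <- sw$segments$step[1]; off <- sw$segments$step[2]
    sel <- sw$time >= on & sw$time < off
    t <- sw$time[sel] - on
    i <- sw$response[sel]
  }
  keep <- t >= kin_blank_ms
  t <- t[keep]; i <- i[keep]
  if (length(t) > .kin_max_points) {
    idx <- seq(1L, length(t), by = ceiling(length(t) / .kin_max_points))
    t <- t[idx]; i <- i[idx]
  }
  data.frame(t = t, i = i)
}

eq2_eval <- function(t, i_ss, tau_w, n, i_0) {
  i_ss * (1 - exp(-t / tau_w))^n + i_0
}

eq3_eval <- function(t, i_max, tau_w, n, z, f, tau_zf, tau_zs, i_0) {
  i_max * (1 - exp(-t / tau_w))^n *
    (1 - z * (f * (1 - exp(-t / tau_zf)) +
              (1 - f) * (1 - exp(-t / tau_zs)))) + i_0
}

adj_r2 <- function(obs, fitted, p) {
  n <- length(obs)
  rss <- sum((obs - fitted)^2)
  tss <- sum((obs - mean(obs))^2)
  if (tss == 0) return(NA_real_)
  1 - (1 - (1 - rss / tss)) * (n - 1) / (n - p - 1)
}

# 10-63% rise-time initial guess for the activation time constant.
rise_tau_guess <- function(t, i) {
  lo <- min(i); span <- max(i) - lo
  if (span <= 0) return(1)
  t10 <- t[which(i >= lo + 0.1 * span)[1]]
  t63 <- t[which(i >= lo + 0.63 * span)[1]]
  max(t63 - t10, 0.05)
}

#' Fit the activation time course (no fast inactivation)
#'
#' Fits `I(t) = I_ss * (1 - exp(-t/tau_w))^n + I_0` with the state factor
#' `n` fixed (default 3).
#'
#' @param t Time from step onset (ms), or an [hc_sweep()] whose step segment
#'   is used.
#' @param i Current (pA); ignored when `t` is a sweep.
#' @param n_fixed Integer state factor.
#' @return An object of class `activation_fit` with `i_ss`, `tau_w`, `n`,
#'   `i_0`, `adj_r2`, `degenerate`.
#' @export
fit_activation <- function(t, i = NULL, n_fixed = 3L) {
  d <- kin_trace(t, i)
  span <- diff(range(d$i))
  degenerate <- span < 1e-6 * max(abs(d$i), 1) || span == 0
  tau0 <- rise_tau_guess(d$t, d$i)
  starts <- list(
    list(i_ss = max(d$i) - d$i[1], tau_w = tau0, i_0 = d$i[1]),
    list(i_ss = max(d$i), tau_w = tau0 * 3, i_0 = 0),
    list(i_ss = max(d$i), tau_w = max(d$t) / 10, i_0 = min(d$i)))
  best <- lm_multistart(
    starts,
    function(p) d$i - eq2_eval(d$t, p[["i_ss"]], p[["tau_w"]], n_fixed,
                               p[["i_0"]]),
    lower = c(i_ss = -Inf, tau_w = 1e-3, i_0 = -Inf),
    upper = c(i_ss = Inf, tau_w = Inf, i_0 = Inf), maxiter = 300)
  if (is.null(best))
    stop("activation fit failed to converge from any start")
  cf <- best$par
  fitted_i <- eq2_eval(d$t, cf["i_ss"], cf["tau_w"], n_fixed, cf["i_0"])
  structure(list(i_ss = unname(cf["i_ss"]), tau_w = unname(cf["tau_w"]),
                 n = as.integer(n_fixed), i_0 = unname(cf["i_0"]),
                 adj_r2 = adj_r2(d$i, fitted_i, 3),
                 rss = best$rss, degenerate = degenerate, data = d),
            class = "activation_fit")
}

#' @export
print.activation_fit <- function(x, ...) {
  cat(sprintf(
    "Activation fit%s: I_ss %.4g pA, tau_w %.3g ms (n = %d), I_0 %.3g pA, adj R^2 %.4f\n",
    if (x$degenerate) " (degenerate)" else "",
    x$i_ss, x$tau_w, x$n, x$i_0, x$adj_r2))
  invisible(x)
}

#' @export
coef.activation_fit <- function(object, ...) {
  c(i_ss = object$i_ss, tau_w = object$tau_w, n = object$n, i_0 = object$i_0)
}

#' @export
predict.activation_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t
       else if (is.data.frame(newdata)) newdata$t else newdata
  eq2_eval(t, object$i_ss, object$tau_w, object$n, object$i_0)
}

#' @export
residuals.activation_fit <- function(object, ...) {
  object$data$i - predict(object)
}

# Two-exponential peel of the post-peak decay for tau_zf/tau_zs guesses.
decay_tau_guess <- function(t, i) {
  pk <- which.max(i)
  if (pk >= length(i) - 10) return(c(10, 100))
  td <- t[pk:length(i)] - t[pk]
  id <- i[pk:length(i)]
  total <- max(td)
  c(max(total / 20, 1), max(total / 2, 10))
}

fit_eq3_engine <- function(d, n_fixed, f_fixed = NULL) {
  tau0 <- rise_tau_guess(d$t, d$i)
  dz <- decay_tau_guess(d$t, d$i)
  i_pk <- max(d$i)
  i_end <- mean(utils::tail(d$i, max(3L, length(d$i) %/% 50)))
  z0 <- if (i_pk > 0) max(min(1 - i_end / i_pk, 0.9), 0.05) else 0.1
  base <- list(i_max = i_pk, tau_w = tau0, z = z0, tau_zf = dz[1],
               u = log(max(dz[2] / dz[1] - 1, 0.5)), i_0 = 0)
  low_z <- utils::modifyList(base, list(z = 0.02, tau_zf = 20, u = 2))
  starts <- if (is.null(f_fixed)) {
    c(lapply(c(0.3, 0.5, 0.7), function(f0) c(base, list(f = f0))),
      list(c(low_z, list(f = 0.5))))
  } else {
    # swap-start robustness: also try initial taus reversed
    list(base,
         utils::modifyList(base, list(tau_zf = dz[2],
                                      u = log(max(dz[1] / dz[2] - 1, 0.5)))),
         low_z)
  }
  lower <- c(i_max = -Inf, tau_w = 1e-3, z = 0, tau_zf = 0.05, u = -12,
             i_0 = -Inf, f = 0)
  upper <- c(i_max = Inf, tau_w = Inf, z = 0.999, tau_zf = Inf, u = 12,
             i_0 = Inf, f = 1)
  resid_fn <- function(p) {
    f_val <- if (is.null(f_fixed)) p[["f"]] else f_fixed
    d$i - eq3_eval(d$t, p[["i_max"]], p[["tau_w"]], n_fixed, p[["z"]],
                   f_val, p[["tau_zf"]],
                   p[["tau_zf"]] * (1 + exp(p[["u"]])), p[["i_0"]])
  }
  lm_multistart(starts, resid_fn, lower, upper)
}

#' Fit activation plus bi-exponential inactivation
#'
#' Fits `I(t) = Imax*(1-exp(-t/tau_w))^n * [1 - Z*(f*(1-exp(-t/tau_zf)) +
#' (1-f)*(1-exp(-t/tau_zs)))] + I_0` with `n` fixed. `tau_zf < tau_zs` is
#' enforced by the parameterization, so a start with the time constants
#' swapped converges to the same canonical fit.
#'
#' @inheritParams fit_activation
#' @param f_fixed Optionally fix the fast fraction `f` (e.g. 0 for a
#'   single-exponential inactivation model).
#' @return An object of class `act_inact_fit` with `i_max`, `tau_w`, `n`,
#'   `z`, `f`, `tau_zf`, `tau_zs`, `i_0`, `adj_r2`.
#' @export
fit_act_inact <- function(t, i = NULL, n_fixed = 3L, f_fixed = NULL) {
  d <- kin_trace(t, i)
  if (!is.null(f_fixed) && f_fixed != 0)
    stop("only f_fixed = 0 (single-exponential inactivation) is supported")
  best <- fit_eq3_engine(d, n_fixed, f_fixed)
  if (is.null(best))
    stop("activation/inactivation fit failed to converge from any start")
  cf <- best$par
  f <- if (is.null(f_fixed)) unname(cf["f"]) else 0
  tau_zf <- unname(cf["tau_zf"])
  tau_zs <- tau_zf * (1 + exp(unname(cf["u"])))
  n_par <- if (is.null(f_fixed)) 7 else 6
  fitted_i <- eq3_eval(d$t, cf["i_max"], cf["tau_w"], n_fixed, cf["z"],
                       f, tau_zf, tau_zs, cf["i_0"])
  structure(list(i_max = unname(cf["i_max"]), tau_w = unname(cf["tau_w"]),
                 n = as.integer(n_fixed), z = unname(cf["z"]), f = f,
                 tau_zf = tau_zf, tau_zs = tau_zs, i_0 = unname(cf["i_0"]),
                 adj_r2 = adj_r2(d$i, fitted_i, n_par), rss = best$rss,
                 f_fixed = !is.null(f_fixed), data = d),
            class = "act_inact_fit")
}

#' @export
print.act_inact_fit <- function(x, ...) {
  cat(sprintf(
    "Activation/inactivation fit%s: Imax %.4g pA, tau_w %.3g ms (n = %d)\n",
    if (x$f_fixed) " (f = 0)" else "", x$i_max, x$tau_w, x$n))
  cat(sprintf(
    "  Z %.3f, f %.3f, tau_zf %.3g ms, tau_zs %.3g ms, I_0 %.3g pA, adj R^2 %.4f\n",
    x$z, x$f, x$tau_zf, x$tau_zs, x$i_0, x$adj_r2))
  invisible(x)
}

#' @export
coef.act_inact_fit <- function(object, ...) {
  c(i_max = object$i_max, tau_w = object$tau_w, n = object$n, z = object$z,
    f = object$f, tau_zf = object$tau_zf, tau_zs = object$tau_zs,
    i_0 = object$i_0)
}

#' @export
predict.act_inact_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t
       else if (is.data.frame(newdata)) newdata$t else newdata
  eq3_eval(t, object$i_max, object$tau_w, object$n, object$z, object$f,
           object$tau_zf, object$tau_zs, object$i_0)
}

#' @export
residuals.act_inact_fit <- function(object, ...) {
  object$data$i - predict(object)
}

#' Select between the full and f-constrained kinetic models
#'
#' Fits the full activation/inactivation model (fast fraction `f` free) and
#' compares its adjusted R^2 against the single-exponential fit (the
#' activation-only model, [fit_activation()]). The full model is kept only
#' if it improves by strictly more than 0.01; otherwise `f` is constrained
#' to 0 (single-exponential inactivation) to avoid overfitting, and that
#' constrained fit is returned.
#'
#' @inheritParams fit_activation
#' @return A list of class `kinetic_model_selection` with `model`
#'   (`"eq3-full"` or `"eq3-constrained"`), `fit` (the selected
#'   [fit_act_inact()] object), `fit_full`, `fit_constrained`,
#'   `fit_single` (the activation-only baseline), and `delta_adj_r2` (full
#'   minus single-exponential).
#' @export
select_kinetic_model <- function(t, i = NULL, n_fixed = 3L) {
  single <- fit_activation(t, i, n_fixed = n_fixed)
  full <- tryCatch(fit_act_inact(t, i, n_fixed = n_fixed),
                   error = function(e) NULL)
  constrained <- tryCatch(fit_act_inact(t, i, n_fixed = n_fixed,
                                        f_fixed = 0),
                          error = function(e) NULL)
  delta <- if (is.null(full)) -Inf else full$adj_r2 - single$adj_r2
  use_full <- is.finite(delta) && delta > 0.01
  if (!use_full && is.null(constrained))
    stop("kinetic fits failed to converge (full and constrained)")
  structure(list(model = if (use_full) "eq3-full" else "eq3-constrained",
                 fit = if (use_full) full else constrained,
                 fit_full = full, fit_constrained = constrained,
                 fit_single = single, delta_adj_r2 = delta),
            class = "kinetic_model_selection")
}

#' @export
print.kinetic_model_selection <- function(x, ...) {
  cat(sprintf("Kinetic model selection: %s (delta adj R^2 = %.4g)\n",
              x$model, x$delta_adj_r2))
  print(x$fit)
  invisible(x)
}

#' Percent inactivation
#'
#' `100 * (I_peak - I_ss) / I_peak`, with `I_ss` the current at the end of a
#' 200 ms step.
#'
#' @param i_peak Maximal current during the step, pA.
#' @param i_ss Current at the end of the 200 ms window, pA.
#' @return Percent inactivation.
#' @export
percent_inactivation <- function(i_peak, i_ss) {
  if (any(i_peak == 0)) stop("percent inactivation undefined for I_peak = 0")
  100 * (i_peak - i_ss) / i_peak
}

#' Classify a trace as A-type or not
#'
#' A current is A-type when the outward current inactivates by strictly more
#' than 30% within 200 ms of step onset (peak after capacitive blanking vs
#' current at 200 ms).
#'
#' @inheritParams fit_activation
#' @param window_ms Comparison window, ms (200 by default).
#' @return `"A_type"` or `"non_A"`, with the percent inactivation attached
#'   as attribute `"percent_inactivation"`.
#' @export
classify_a_current <- function(t, i = NULL, window_ms = 200) {
  d <- kin_trace(t, i)
  d <- d[d$t <= window_ms, ]
  if (max(d$t) < window_ms - 1)
    stop("trace shorter than the ", window_ms, " ms comparison window")
  i_peak <- max(d$i)
  i_ss <- d$i[which.min(abs(d$t - window_ms))]
  pct <- percent_inactivation(i_peak, i_ss)
  structure(if (pct > 30) "A_type" else "non_A",
            percent_inactivation = pct)
}
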