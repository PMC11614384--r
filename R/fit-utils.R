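# Shared nonlinear least-squares driver. minpack.lm::nls.lm is used
# directly (rather than the nls-style wrapper) because boundary solutions
# (e.g. an inactivation depth converging to 0) make the post-fit nls model
# matrix singular even though the least-squares solution itself is fine.

# starts: list of named lists/vectors of starting values.
# resid_fn: function(par named vector) -> residual vector.
# lower/upper: named bounds covering every parameter name used.
# Returns list(par, rss) of the best converged start, or NULL.
lm_multistart <- function(starts, resid_fn, lower, upper, maxiter = 400) {
  best <- NULL
  for (st in starts) {
    p0 <- unlist(st)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         lower = lower[names(p0)], upper = upper[names(p0)],
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(fit$fvec^2)
      if (is.finite(rss) && (is.null(best) || rss < best$rss))
        best <- list(par = fit$par, rss = rss)
    }
  }
  best
}
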