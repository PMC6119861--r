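#' Replicate-noise standard deviation of a normalized series
#'
#' Pooled standard deviation of the replicate deviations from the per-time
#' median trajectory, `sqrt(sum((y - median_t)^2) / (T * (R - 1)))`, floored
#' to keep the Gaussian likelihood proper on near-noise-free series.
#'
#' @param series a [normalize_series()] object.
#' @param floor minimum sd, normalized units (default 0.05).
#' @return positive scalar sd on the normalized scale.
#' @export
estimate_noise_sd <- function(series, floor = 0.05) {
  stopifnot(inherits(series, "NormalizedSeries"), floor > 0)
  v <- series$values
  med <- col_medians(v)
  dev <- sweep(v, 2, med)
  pooled <- sqrt(sum(dev^2) / (ncol(v) * (nrow(v) - 1)))
  max(pooled, floor)
}

#' Gaussian log likelihood of a model curve for a replicated series
#'
#' Independent Gaussian observation noise with a shared sd: the sum over all
#' replicates and times of `dnorm(observed - model, sd, log = TRUE)`.
#'
#' @param spec a [model_spec()].
#' @param params parameter vector within the prior ranges.
#' @param series a non-degenerate [normalize_series()] object.
#' @param noise_sd positive observation noise sd (normalized scale).
#' @return scalar log density.
#' @export
log_likelihood <- function(spec, params, series, noise_sd) {
  stopifnot(inherits(series, "NormalizedSeries"), !isTRUE(series$degenerate),
            noise_sd > 0)
  params <- check_params(spec, params)
  loglik_cpp(spec$code, params, series$times, series$values, noise_sd)
}

#' Marginal likelihood (log Z) of a model by nested sampling
#'
#' Runs nested sampling with uniform priors on the spec's ranges and a
#' Gaussian likelihood, returning the log evidence with its
#' information-based uncertainty `sqrt(H / n_live)` and posterior mean/sd
#' summaries of the parameters from the weighted samples (including the
#' derived peak time `t_p = td + ts` for peak fits). Deterministic given
#' `seed`.
#'
#' @inheritParams log_likelihood
#' @param n_live number of live points (`>= 50`).
#' @param seed integer seed for the sampler.
#' @param max_iter iteration cap; hitting it flags the fit as unconverged
#'   (such fits are excluded from classification).
#' @param n_steps constrained random-walk steps per live-point replacement.
#' @param stop_tol terminate when the estimated remaining evidence falls
#'   below this fraction of the accumulated evidence.
#' @return an object of class `ModelFit`: fields `model`, `variant`, `logZ`,
#'   `logZ_err`, `converged`, `n_iter`, `post` (data frame of parameter
#'   posterior means and sds), `tp_mean`, `tp_sd` (peak model only, `NA`
#'   otherwise).
#' @export
nested_sampling_logZ <- function(spec, series, noise_sd, n_live = 200,
                                 seed = 1, max_iter = 100000L, n_steps = 30L,
                                 stop_tol = 1e-3) {
  stopifnot(inherits(spec, "ModelSpec"), inherits(series, "NormalizedSeries"),
            !isTRUE(series$degenerate), noise_sd > 0, n_live >= 50)
  res <- ns_run_cpp(spec$code, unname(spec$lower), unname(spec$upper),
                    series$times, series$values, noise_sd,
                    as.integer(n_live), as.integer(seed),
                    as.integer(max_iter), as.integer(n_steps), stop_tol)
  structure(list(model = spec$name, variant = spec$variant,
                 logZ = res$logZ, logZ_err = res$logZ_err,
                 H = res$H, n_iter = res$n_iter, converged = res$converged,
                 post = data.frame(parameter = spec$par_names,
                                   mean = res$post_mean, sd = res$post_sd,
                                   stringsAsFactors = FALSE),
                 tp_mean = res$tp_mean, tp_sd = res$tp_sd,
                 n_live = n_live, seed = seed),
            class = "ModelFit")
}

#' @export
print.ModelFit <- function(x, ...) {
  cat(sprintf("ModelFit %s%s: logZ = %.3f +/- %.3f (%s, %d iterations)\n",
              x$model, if (x$variant != "none") paste0("/", x$variant) else "",
              x$logZ, x$logZ_err,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}
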