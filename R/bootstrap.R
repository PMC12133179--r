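# Nonparametric bootstrap confidence intervals for maximum-likelihood fits.

#' Bootstrap percentile confidence intervals
#'
#' Creates `n_boot` resamples of the dataset's (time, observation) pairs,
#' drawn with replacement to the original size, refits the model to each
#' (starting the local search from the full-data optimum plus a few fresh
#' global starts), and returns the 0.025/0.975 percentiles of the
#' resampled estimates. Resamples whose fit fails are dropped and counted.
#'
#' @inheritParams fit_ml
#' @param n_boot Number of bootstrap resamples (>= 2).
#' @param fit Optional full-data `fit_result` from [fit_ml()]; computed if
#'   missing.
#' @param n_starts_boot Fresh global starts per resample, in addition to
#'   the full-data optimum.
#' @return A list with `ci` (matrix: rows = parameters plus `mean_p`,
#'   columns lower/upper), `estimates` (resampled parameter matrix),
#'   `n_failed`, and the full-data `fit`.
#' @export
bootstrap_ci <- function(model, dataset, curve, n_boot = 500L, seed = 1L,
                         fit = NULL, n_starts_boot = 4L, N = 2L,
                         ratio_CE = NULL, p_upper = NULL,
                         d_star_upper = NULL) {
  stopifnot(n_boot >= 2L, inherits(dataset, "labelling_dataset"))
  if (is.null(fit)) {
    fit <- fit_ml(model, dataset, curve, seed = seed, N = N,
                  ratio_CE = ratio_CE, p_upper = p_upper,
                  d_star_upper = d_star_upper)
  }
  spec <- .model_spec(model, curve, N = N, ratio_CE = ratio_CE,
                      p_upper = p_upper, d_star_upper = d_star_upper,
                      bounds = sampling_bounds(delta = if (curve$perfect) 0.07 else curve$delta))
  sd <- .known_sd(dataset$noise, dataset$observations)
  n <- length(dataset$times)
  d <- length(spec$lower)
  set.seed(seed)
  est <- matrix(NA_real_, n_boot, d + 1L)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- .fit_ml_core(spec, dataset$times[idx], dataset$observations[idx],
                       dataset$noise, sd, n_starts = n_starts_boot,
                       n_refine = 2L, seed = NULL,
                       start_theta = if (!fit$diagnostics$failed) fit$theta_search)
    if (!fb$diagnostics$failed && is.finite(fb$logLik)) {
      est[b, ] <- c(fb$theta, fb$mean_p)
    }
  }
  ok <- stats::complete.cases(est)
  ci <- if (any(ok)) {
    t(apply(est[ok, , drop = FALSE], 2L,
            stats::quantile, probs = c(0.025, 0.975), names = FALSE))
  } else {
    matrix(NA_real_, d + 1L, 2L)
  }
  rownames(ci) <- c(spec$par_names, "mean_p")
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, estimates = est[ok, , drop = FALSE],
       n_failed = sum(!ok), fit = fit)
}
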