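# Maximum-likelihood fitting: Latin-hypercube multi-start global search
# followed by box-constrained local refinement.

#' Maximum-likelihood fit of a labelling model
#'
#' Maximises the likelihood implied by the dataset's noise specification
#' (lognormal noise: least squares on the log scale; Gaussian noise:
#' ordinary least squares; the noise scale is treated as known). The
#' search draws `n_starts` Latin-hypercube start points inside the model's
#' parameter box, refines the best `n_refine` of them with L-BFGS-B, and
#' keeps the best refined optimum. Deterministic under `seed`.
#'
#' Model ids: `"one_compartment"` (p, d*; box p in \[0, 5/b_w\], d* in
#' \[0, 1\]), `"implicit"` (p, d*; unit boxes), `"homogeneous"` (p only,
#' d* = p), `"explicit"` (`N`-subpopulation mixture), and
#' `"precursor_target"` / `"precursor_target_ratio"` (the two-compartment
#' cascade on the transformed scale, boxed by [sampling_bounds()]; the
#' ratio variant freezes the precursor/target size ratio at `ratio_CE`).
#'
#' Parameters of the cascade models are strongly collinear when only
#' target-compartment data are available; the fit reports an
#' `identifiable` diagnostic from the conditioning of the observed
#' information matrix rather than failing.
#'
#' @param model Model id string (see Details).
#' @param dataset A [labelling_dataset()].
#' @param curve The [body_water_curve()] the data were generated under
#'   (body-water parameters are assumed known).
#' @param n_starts Number of global start points.
#' @param n_refine Number of best starts refined locally.
#' @param seed Integer seed controlling the start points.
#' @param N Number of subpopulations (explicit model only).
#' @param ratio_CE Fixed precursor/target size ratio
#'   (`precursor_target_ratio` only).
#' @param p_upper,d_star_upper Optional box overrides for the
#'   one-compartment-type models.
#' @return Object of class `fit_result`: point `estimates` (natural
#'   scale), `mean_p` (the mean-proliferation summary), `logLik`,
#'   `pointwise` log-likelihood vector (one entry per observation),
#'   `theta` (internal scale), and `diagnostics` (`convergence`,
#'   `identifiable`, `rcond`).
#' @export
fit_ml <- function(model, dataset, curve, n_starts = 50L, n_refine = 5L,
                   seed = 1L, N = 2L, ratio_CE = NULL,
                   p_upper = NULL, d_star_upper = NULL) {
  stopifnot(inherits(dataset, "labelling_dataset"),
            inherits(curve, "body_water_curve"))
  spec <- .model_spec(model, curve, N = N, ratio_CE = ratio_CE,
                      p_upper = p_upper, d_star_upper = d_star_upper,
                      bounds = sampling_bounds(delta = if (curve$perfect) 0.07 else curve$delta))
  sd <- .known_sd(dataset$noise, dataset$observations)
  .fit_ml_core(spec, dataset$times, dataset$observations, dataset$noise, sd,
               n_starts = n_starts, n_refine = n_refine, seed = seed)
}

#' Precursor/target fit with the compartment size ratio fixed
#'
#' Convenience wrapper around [fit_ml()] for the scenario where the
#' precursor compartment's identity is known and its size relative to the
#' target can be supplied from the literature.
#'
#' @inheritParams fit_ml
#' @param ratio_CE The true (fixed) precursor-to-target size ratio.
#' @return A `fit_result`, as [fit_ml()].
#' @export
fit_ml_with_ratio <- function(dataset, ratio_CE, curve, n_starts = 50L,
                              n_refine = 5L, seed = 1L) {
  fit_ml("precursor_target_ratio", dataset, curve, n_starts = n_starts,
         n_refine = n_refine, seed = seed, ratio_CE = ratio_CE)
}

# core fitter on plain vectors (bootstrap resamples have duplicated times,
# so this path avoids the strictly-increasing container check)
.fit_ml_core <- function(spec, times, obs, noise, sd, n_starts = 50L,
                         n_refine = 5L, seed = NULL, start_theta = NULL) {
  nll0 <- .negloglik_fn(spec, times, obs, noise, sd)
  if (is.null(spec$search)) {
    s_lower <- spec$lower
    s_upper <- spec$upper
    map <- identity
  } else {
    s_lower <- spec$search$lower
    s_upper <- spec$search$upper
    map <- spec$search$map
  }
  nll <- function(s) nll0(map(s))
  d <- length(s_lower)
  if (!is.null(seed)) set.seed(seed)
  starts <- if (n_starts > 0L) {
    u <- lhs::randomLHS(max(n_starts, 2L), d)[seq_len(n_starts), , drop = FALSE]
    sweep(sweep(u, 2L, s_upper - s_lower, `*`), 2L, s_lower, `+`)
  } else {
    matrix(numeric(0), ncol = d)
  }
  if (!is.null(start_theta)) starts <- rbind(matrix(start_theta, nrow = 1L), starts)
  vals <- apply(starts, 1L, nll)
  ord <- order(vals)
  keep <- ord[seq_len(min(n_refine, sum(is.finite(vals))))]
  if (length(keep) == 0L) {
    return(structure(
      list(model_id = spec$id, estimates = NULL, mean_p = NA_real_,
           logLik = -Inf, pointwise = rep(NA_real_, length(obs)),
           theta = rep(NA_real_, d), n_obs = length(obs),
           diagnostics = list(convergence = FALSE, identifiable = FALSE,
                              rcond = NA_real_, failed = TRUE)),
      class = "fit_result"))
  }
  best <- NULL
  for (i in keep) {
    opt <- tryCatch(
      stats::optim(starts[i, ], nll, method = "L-BFGS-B",
                   lower = s_lower + 1e-12,
                   upper = s_upper - 1e-12,
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    i <- keep[1L]
    best <- list(par = starts[i, ], value = vals[i], convergence = 1L)
  }
  theta <- map(best$par)
  pred <- spec$predict(theta, times)
  pointwise <- .loglik_pointwise(pred, obs, noise, sd)
  hess <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  rc <- if (is.null(hess) || any(!is.finite(hess))) NA_real_ else rcond(hess)
  structure(
    list(model_id = spec$id,
         estimates = spec$natural(theta),
         mean_p = spec$mean_p(theta),
         logLik = -best$value,
         pointwise = pointwise,
         fitted = pred,
         theta = theta,
         theta_search = best$par,
         n_obs = length(obs),
         diagnostics = list(
           convergence = identical(best$convergence, 0L),
           identifiable = is.finite(rc) && rc > 1e-10,
           rcond = rc, failed = FALSE)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<%s fit: logLik = %.3f, mean p = %.5g%s>\n",
              x$model_id, x$logLik, x$mean_p,
              if (!is.null(x$diagnostics$identifiable) &&
                  !x$diagnostics$identifiable) ", non-identifiable" else ""))
  if (!is.null(x$estimates)) {
    utils::str(x$estimates, give.attr = FALSE, digits.d = 4)
  }
  invisible(x)
}
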