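# Bayesian fitting by adaptive random-walk Metropolis.
#
# All priors are flat on a bounded support (uniform boxes for rates; a
# symmetric Dirichlet over ordered subpopulation weights), so the
# log-posterior equals the log-likelihood plus a possible Dirichlet term,
# and proposals outside the support are simply rejected.

#' Prior specification for Bayesian fits
#'
#' @param p_upper Upper bound of the uniform prior for proliferation
#'   rate(s), day^-1. The lower bound is 0.
#' @param d_star_upper Upper bound of the uniform prior for the
#'   disappearance rate of labelled cells. Defaults to `p_upper` when that
#'   is widened, otherwise 1.
#' @param alpha_concentration Concentration of the symmetric Dirichlet
#'   prior over subpopulation weights (1 = uniform over the simplex).
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(p_upper = 1, d_star_upper = NULL,
                       alpha_concentration = 1) {
  stopifnot(p_upper > 0, alpha_concentration > 0)
  if (is.null(d_star_upper)) d_star_upper <- max(1, p_upper)
  structure(list(p_upper = p_upper, d_star_upper = d_star_upper,
                 alpha_concentration = alpha_concentration),
            class = "prior_spec")
}

#' Bayesian fit of a labelling model
#'
#' Samples the posterior with an adaptive random-walk Metropolis sampler:
#' during warm-up the proposal covariance is adapted to the accepted
#' history (scaled 2.38^2/d), after warm-up it is frozen so the kept draws
#' target the exact posterior. Runs `n_chains` chains from dispersed
#' starts; convergence is summarised by split-Rhat.
#'
#' Model ids as in [fit_ml()]: `"homogeneous"`, `"implicit"`,
#' `"one_compartment"`, `"explicit"` (with `N` subpopulations; weights
#' carry a symmetric Dirichlet prior and are kept in ascending order to
#' remove label switching).
#'
#' @inheritParams fit_ml
#' @param priors A [prior_spec()]. For `"one_compartment"` the default
#'   `p_upper` is `5 / b_w` (and `d_star_upper` 1), matching the broad
#'   production-rate prior appropriate for that context.
#' @param n_iter Iterations per chain (including warm-up).
#' @param n_warmup Warm-up (adaptation) iterations discarded per chain.
#' @param n_chains Number of chains.
#' @return Object of class `fit_result` with posterior `draws` (matrix),
#'   `loglik_draws` (draws x observations pointwise log-likelihood, for
#'   LOO), point `estimates` (posterior medians), credible `interval`
#'   (2.5/97.5 percentiles, including the mean-proliferation summary) and
#'   `diagnostics` (`rhat`, `accept_rate`, `convergence`).
#' @export
fit_bayes <- function(model, dataset, curve, priors = NULL,
                      n_iter = 6000L, n_warmup = 2000L, n_chains = 2L,
                      seed = 1L, N = 2L) {
  stopifnot(inherits(dataset, "labelling_dataset"),
            inherits(curve, "body_water_curve"))
  if (is.null(priors)) {
    priors <- if (model == "one_compartment") {
      prior_spec(p_upper = 5 / curve$b_w, d_star_upper = 1)
    } else {
      prior_spec()
    }
  }
  stopifnot(inherits(priors, "prior_spec"))
  spec <- .model_spec(model, curve, N = N,
                      p_upper = priors$p_upper,
                      d_star_upper = priors$d_star_upper)
  sd <- .known_sd(dataset$noise, dataset$observations)
  times <- dataset$times
  obs <- dataset$observations
  noise <- dataset$noise
  d <- length(spec$lower)
  conc <- priors$alpha_concentration
  n_alpha <- if (spec$id == "explicit") spec$N - 1L else 0L

  # the sampler works on log-rate coordinates (weights stay linear): rate
  # posteriors can be ridge-shaped over decades, which is compact on the
  # log scale; the Jacobian keeps the prior uniform on the natural scale
  is_rate <- if (spec$id == "explicit") {
    c(rep(TRUE, spec$N), rep(FALSE, n_alpha))
  } else {
    rep(TRUE, d)
  }
  to_sampling <- function(theta) {
    s <- theta
    s[is_rate] <- log(pmax(theta[is_rate], 1e-12))
    s
  }
  from_sampling <- function(s) {
    theta <- s
    theta[is_rate] <- exp(s[is_rate])
    theta
  }
  logpost_natural <- function(theta) {
    if (any(theta < spec$lower) || any(theta > spec$upper)) return(-Inf)
    if (!is.null(spec$support) && !spec$support(theta)) return(-Inf)
    pred <- spec$predict(theta, times)
    lp <- sum(.loglik_pointwise(pred, obs, noise, sd))
    if (n_alpha > 0L && conc != 1) {
      a <- theta[(spec$N + 1L):(2L * spec$N - 1L)]
      avec <- c(a, 1 - sum(a))
      lp <- lp + (conc - 1) * sum(log(avec))
    }
    lp
  }
  logpost <- function(s) {
    if (any(s[is_rate] < -27)) return(-Inf)   # rates below ~2e-12: cut off
    theta <- from_sampling(s)
    lp <- logpost_natural(theta)
    if (!is.finite(lp)) return(lp)
    lp + sum(s[is_rate])   # Jacobian of the log transform
  }

  set.seed(seed)
  keep_per_chain <- n_iter - n_warmup
  draws <- matrix(NA_real_, n_chains * keep_per_chain, d)
  chain_id <- rep(seq_len(n_chains), each = keep_per_chain)
  accept <- numeric(n_chains)

  # Laplace initialisation: a cheap ML fit locates the mode and its local
  # curvature seeds the proposal covariance (the data are precise, so the
  # posterior is far narrower than the prior box)
  ml <- tryCatch(
    .fit_ml_core(spec, times, obs, noise, sd, n_starts = 80L, n_refine = 8L,
                 seed = seed),
    error = function(e) NULL)
  nll_s <- function(s) {
    lp <- logpost(s)
    if (!is.finite(lp)) 1e10 else -lp
  }
  cov0 <- NULL
  theta0 <- NULL
  if (!is.null(ml) && !ml$diagnostics$failed && all(is.finite(ml$theta))) {
    th <- pmin(pmax(ml$theta, spec$lower + 1e-10), spec$upper - 1e-10)
    if (n_alpha == 0L || spec$support(th)) theta0 <- to_sampling(th)
  }
  if (!is.null(theta0)) {
    hess <- tryCatch(stats::optimHess(theta0, nll_s),
                     error = function(e) NULL)
    if (!is.null(hess) && all(is.finite(hess))) {
      cv <- tryCatch(solve(hess), error = function(e) NULL)
      if (!is.null(cv) && all(is.finite(cv)) && all(diag(cv) > 0)) {
        cov0 <- (cv + t(cv)) / 2
      }
    }
  }
  if (is.null(cov0)) {
    scale0 <- rep(0.5, d)
    scale0[!is_rate] <- 0.05
    cov0 <- diag(scale0^2, d)
  }
  sd_fac <- 2.38^2 / d
  chol_or_diag <- function(cv) {
    ch <- tryCatch(chol(cv + diag(1e-14 * max(diag(cv)) + 1e-300, d)),
                   error = function(e) NULL)
    if (is.null(ch)) diag(sqrt(pmax(diag(cv), 1e-300)), d) else ch
  }

  for (ch in seq_len(n_chains)) {
    # start at the (jittered) mode, or fall back to random support points
    theta <- NULL
    if (!is.null(theta0)) {
      for (try in 1:50) {
        cand <- theta0 + as.numeric(crossprod(chol_or_diag(cov0),
                                              stats::rnorm(d, 0, 2)))
        if (is.finite(logpost(cand))) { theta <- cand; break }
      }
      if (is.null(theta) && is.finite(logpost(theta0))) theta <- theta0
    }
    if (is.null(theta)) {
      for (try in 1:200) {
        cand <- stats::runif(d, spec$lower, spec$upper)
        if (n_alpha > 0L) {
          cand[(spec$N + 1L):(2L * spec$N - 1L)] <-
            sort(stats::runif(n_alpha, 0, 1 / spec$N))
        }
        cand <- to_sampling(cand)
        if (is.finite(logpost(cand))) { theta <- cand; break }
      }
    }
    if (is.null(theta)) stop("could not find a valid starting point")
    lp <- logpost(theta)

    lambda <- 1
    chol_prop <- chol_or_diag(sd_fac * lambda * cov0)
    hist_mat <- matrix(NA_real_, n_iter, d)
    n_acc <- 0L
    acc_win <- 0L
    for (it in seq_len(n_iter)) {
      prop <- theta + as.numeric(crossprod(chol_prop, stats::rnorm(d)))
      lp_prop <- logpost(prop)
      if (is.finite(lp_prop) && log(stats::runif(1L)) < lp_prop - lp) {
        theta <- prop
        lp <- lp_prop
        n_acc <- n_acc + 1L
        acc_win <- acc_win + 1L
      }
      hist_mat[it, ] <- theta
      # warm-up adaptation: rescale towards ~25% acceptance and refresh the
      # covariance from the recent history
      if (it <= n_warmup && it %% 50L == 0L) {
        lambda <- lambda * exp((acc_win / 50 - 0.25))
        acc_win <- 0L
        cv <- cov0
        if (it >= 300L) {
          recent <- hist_mat[max(1L, it - 1000L):it, , drop = FALSE]
          cve <- stats::cov(recent)
          if (all(is.finite(cve)) && all(diag(cve) > 0)) cv <- cve
        }
        chol_prop <- chol_or_diag(sd_fac * lambda * cv)
      }
      if (it > n_warmup) {
        draws[(ch - 1L) * keep_per_chain + (it - n_warmup), ] <-
          from_sampling(theta)
      }
    }
    accept[ch] <- n_acc / n_iter
  }

  colnames(draws) <- spec$par_names
  rhat <- vapply(seq_len(d), function(j) {
    .split_rhat(draws[, j], chain_id)
  }, numeric(1L))
  mean_p_draws <- apply(draws, 1L, spec$mean_p)
  loglik_draws <- t(apply(draws, 1L, function(th) {
    .loglik_pointwise(spec$predict(th, times), obs, noise, sd)
  }))
  qs <- function(x) stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
  par_q <- apply(draws, 2L, qs)
  mp_q <- qs(mean_p_draws)
  interval <- rbind(t(par_q), mean_p = mp_q)
  colnames(interval) <- c("lower", "median", "upper")
  theta_med <- par_q[2L, ]
  structure(
    list(model_id = spec$id,
         estimates = spec$natural(theta_med),
         mean_p = mp_q[2L],
         mean_p_draws = mean_p_draws,
         draws = draws,
         loglik_draws = loglik_draws,
         pointwise = .loglik_pointwise(spec$predict(theta_med, times),
                                       obs, noise, sd),
         logLik = sum(.loglik_pointwise(spec$predict(theta_med, times),
                                        obs, noise, sd)),
         interval = interval,
         interval_method = "posterior",
         theta = theta_med,
         n_obs = length(obs),
         priors = priors,
         diagnostics = list(
           rhat = rhat,
           accept_rate = accept,
           convergence = all(is.finite(rhat)) && max(rhat) < 1.1,
           identifiable = NA,
           failed = FALSE)),
    class = "fit_result")
}

# split-chain potential scale reduction factor
.split_rhat <- function(x, chain_id) {
  halves <- list()
  for (ch in unique(chain_id)) {
    xi <- x[chain_id == ch]
    h <- length(xi) %/% 2L
    halves <- c(halves, list(xi[seq_len(h)], xi[h + seq_len(h)]))
  }
  m <- length(halves)
  n <- length(halves[[1L]])
  means <- vapply(halves, mean, numeric(1L))
  vars <- vapply(halves, stats::var, numeric(1L))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
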