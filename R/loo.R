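# Leave-one-out predictive model comparison via Pareto-smoothed importance
# sampling (PSIS), computed from the per-draw pointwise log-likelihood
# matrix retained by fit_bayes().

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Generalized-Pareto fit to exceedances by the Zhang & Stephens (2009)
# profile-posterior method. Returns the shape on the heavy-tail-positive
# convention (xi > 0: heavy tail) and scale sigma.
.gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5L || x[n] <= 0) return(list(xi = -Inf, sigma = NA_real_))
  m <- 30L + floor(sqrt(n))
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  jj <- seq_len(m)
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  prof <- vapply(theta, function(th) {
    k <- -mean(log1p(-th * x))
    n * (log(th / k) + k - 1)
  }, numeric(1L))
  w <- 1 / vapply(jj, function(j) sum(exp(prof - prof[j])), numeric(1L))
  th_hat <- sum(theta * w)
  k_hat <- -mean(log1p(-th_hat * x))   # Zhang's k = -xi
  sigma <- k_hat / th_hat
  list(xi = -k_hat, sigma = sigma)
}

# smooth one observation's log importance ratios; returns the smoothed
# (unnormalised) log-weights and the Pareto shape diagnostic
.psis_smooth <- function(lw) {
  S <- length(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5L || length(unique(lw)) < 5L) return(list(lw = lw, k = -Inf))
  ord <- order(lw)
  cut <- lw[ord[S - M]]
  tail_idx <- ord[(S - M + 1L):S]
  exceed <- exp(lw[tail_idx] - cut) - 1
  fit <- .gpd_fit(exceed)
  if (!is.finite(fit$xi) || is.na(fit$sigma) || fit$sigma <= 0) {
    return(list(lw = lw, k = if (is.finite(fit$xi)) fit$xi else -Inf))
  }
  # replace tail by expected order statistics of the fitted distribution
  p <- (seq_len(M) - 0.5) / M
  q <- if (abs(fit$xi) < 1e-12) {
    -fit$sigma * log1p(-p)
  } else {
    fit$sigma / fit$xi * ((1 - p)^(-fit$xi) - 1)
  }
  smoothed <- lw
  smoothed[tail_idx[order(lw[tail_idx])]] <- cut + log1p(q)
  smoothed <- pmin(smoothed, max(lw))
  list(lw = smoothed, k = fit$xi)
}

#' Expected log pointwise predictive density by PSIS-LOO
#'
#' Estimates each observation's leave-one-out log predictive density by
#' importance sampling from the full posterior, with the largest
#' importance ratios stabilised by a generalized-Pareto fit to their tail
#' (Pareto-smoothed importance sampling). Observations whose Pareto shape
#' diagnostic exceeds 0.7 are flagged as unreliable.
#'
#' @param fit A `fit_result` from [fit_bayes()] (must carry the
#'   `loglik_draws` matrix).
#' @return A list of class `elpd_loo`: `elpd` (estimate), `se` (standard
#'   error), `pointwise` vector, `pareto_k` diagnostics, `n_flagged`.
#' @export
elpd_loo <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  if (is.null(fit$loglik_draws)) {
    stop("fit carries no pointwise log-likelihood draws; refit with fit_bayes()")
  }
  ll <- fit$loglik_draws
  n <- ncol(ll)
  S <- nrow(ll)
  pointwise <- numeric(n)
  ks <- numeric(n)
  for (i in seq_len(n)) {
    lli <- ll[, i]
    if (all(lli == lli[1L])) {
      # constant contribution (e.g. the t = 0 anchor): loo equals it
      pointwise[i] <- lli[1L]
      ks[i] <- -Inf
      next
    }
    sm <- .psis_smooth(-lli)
    lw <- sm$lw - .logsumexp(sm$lw)
    pointwise[i] <- .logsumexp(lw + lli)
    ks[i] <- sm$k
  }
  structure(
    list(elpd = sum(pointwise),
         se = sqrt(n * stats::var(pointwise)),
         pointwise = pointwise,
         pareto_k = ks,
         n_flagged = sum(is.finite(ks) & ks > 0.7)),
    class = "elpd_loo")
}

#' @export
print.elpd_loo <- function(x, ...) {
  cat(sprintf("<elpd_loo: %.2f (se %.2f), %d/%d Pareto-k flagged>\n",
              x$elpd, x$se, x$n_flagged, length(x$pointwise)))
  invisible(x)
}

#' Compare two fits by their LOO predictive density
#'
#' Computes `delta = elpd_loo(i) - elpd_loo(j)` with the paired standard
#' error `sqrt(n * var(pointwise_i - pointwise_j))`, and applies the
#' decision rule: the models are *tied* when the standard error exceeds
#' `|delta|` (tie takes precedence); otherwise model i is supported when
#' `delta > stringency * se`, model j when `-delta > stringency * se`.
#'
#' @param fit_i,fit_j `fit_result`s from [fit_bayes()], fitted to the same
#'   dataset, or `elpd_loo` objects.
#' @param stringency Multiplier on the standard error in the support rule;
#'   1 is the default decision threshold.
#' @return A list of class `model_comparison`: `delta`, `se`, `decision`
#'   (`"select_i"`, `"select_j"` or `"tie"`), and the two `elpd_loo`
#'   objects.
#' @export
compare_elpd <- function(fit_i, fit_j, stringency = 1) {
  li <- if (inherits(fit_i, "elpd_loo")) fit_i else elpd_loo(fit_i)
  lj <- if (inherits(fit_j, "elpd_loo")) fit_j else elpd_loo(fit_j)
  n <- length(li$pointwise)
  stopifnot(length(lj$pointwise) == n)
  diff <- li$pointwise - lj$pointwise
  delta <- sum(diff)
  se <- sqrt(n * stats::var(diff))
  decision <- if (se > abs(delta)) {
    "tie"
  } else if (delta > stringency * se) {
    "select_i"
  } else if (-delta > stringency * se) {
    "select_j"
  } else {
    "tie"
  }
  structure(list(delta = delta, se = se, decision = decision,
                 elpd_i = li, elpd_j = lj, stringency = stringency),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model comparison: delta elpd_loo = %.3f (se %.3f) -> %s>\n",
              x$delta, x$se, x$decision))
  invisible(x)
}
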