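# Latin-hypercube parameter sampling on the transformed scale, and the
# fixed grid of explicit two-subpopulation heterogeneity scenarios.

#' Sampling bounds for precursor/target parameters
#'
#' Bounds of the multivariate uniform distribution on the *transformed*
#' parameter scale. The defaults are the physiological/structural bounds
#' used throughout the package's simulation studies:
#' `log10 p_C`, `log10 p_E` in \[-4, -2\] (typical T-cell proliferation),
#' `log10(r / p_C)` in \[-2, 0\] (differentiation slower than precursor
#' proliferation), `k` in \[0, 20\], `log10(d_C* / (p_C - r))` in \[0, 2\]
#' (precursor heterogeneity up to 100-fold), and the interpolation
#' coordinates of `log10 d_E` and `log10 d_E*` between `log10 p_E` and
#' `log10 delta` in \[0, 1\] (so `p_E <= d_E, d_E* <= delta`).
#'
#' @param delta Body-water turnover rate used in the `d_E`/`d_E*`
#'   transforms, day^-1.
#' @param lower,upper Numeric length-7 vectors overriding the default
#'   bounds, in the order listed above.
#' @return Object of class `sampling_bounds`.
#' @export
sampling_bounds <- function(delta = 0.07,
                            lower = c(-4, -4, -2, 0, 0, 0, 0),
                            upper = c(-2, -2, 0, 20, 2, 1, 1)) {
  stopifnot(length(lower) == 7L, length(upper) == 7L, all(upper > lower),
            delta > 0)
  names(lower) <- names(upper) <- c(
    "log10_p_C", "log10_p_E", "log10_r_over_p_C", "k",
    "log10_d_C_star_ratio", "u_d_E", "u_d_E_star")
  structure(list(lower = lower, upper = upper, delta = delta),
            class = "sampling_bounds")
}

# back-transform one row of transformed draws to natural parameters
.back_transform_pt <- function(theta, delta) {
  theta <- unname(theta)
  p_C <- 10^theta[1L]
  p_E <- 10^theta[2L]
  r <- p_C * 10^theta[3L]
  k <- theta[4L]
  d_C_star <- (p_C - r) * 10^theta[5L]
  span <- log10(delta) - log10(p_E)
  d_E <- 10^(log10(p_E) + theta[6L] * span)
  d_E_star <- 10^(log10(p_E) + theta[7L] * span)
  precursor_target_params(p_C = p_C, r = r, k = k, p_E = p_E, d_E = d_E,
                          d_C_star = d_C_star, d_E_star = d_E_star)
}

#' Sample precursor/target parameter sets
#'
#' Latin-hypercube draws from the multivariate uniform distribution on the
#' transformed scale defined by [sampling_bounds()], back-transformed to
#' natural parameters. Only draws with `d_E* > d_E` are kept (the target
#' population is allowed to be kinetically heterogeneous); whole hypercubes
#' are redrawn until `n` survivors accumulate, which preserves the
#' stratification approximately.
#'
#' @param n Number of parameter sets to return.
#' @param bounds A [sampling_bounds()].
#' @param k_mode `"sampled"` draws `k` uniformly from its bounds;
#'   `"zero"` fixes `k = 0`.
#' @param seed Optional integer seed for reproducibility.
#' @return A list of `n` [precursor_target_params()] objects, with the
#'   matrix of accepted transformed draws attached as attribute
#'   `"transformed"`.
#' @export
sample_precursor_target_params <- function(n, bounds = sampling_bounds(),
                                           k_mode = c("sampled", "zero"),
                                           seed = NULL) {
  stopifnot(is.numeric(n), n >= 1)
  stopifnot(inherits(bounds, "sampling_bounds"))
  k_mode <- match.arg(k_mode)
  if (!is.null(seed)) set.seed(seed)
  lower <- bounds$lower
  upper <- bounds$upper
  kept <- matrix(numeric(0), ncol = 7L)
  guard <- 0L
  while (nrow(kept) < n) {
    u <- lhs::randomLHS(n, 7L)
    theta <- sweep(sweep(u, 2L, upper - lower, `*`), 2L, lower, `+`)
    if (k_mode == "zero") theta[, 4L] <- 0
    ok <- theta[, 7L] > theta[, 6L]   # implies d_E* > d_E
    kept <- rbind(kept, theta[ok, , drop = FALSE])
    guard <- guard + 1L
    if (guard > 1000L) stop("rejection rate too high for the given bounds")
  }
  kept <- kept[seq_len(n), , drop = FALSE]
  colnames(kept) <- names(lower)
  out <- lapply(seq_len(n), function(i) .back_transform_pt(kept[i, ], bounds$delta))
  attr(out, "transformed") <- kept
  out
}

#' Grid of explicit two-subpopulation heterogeneity scenarios
#'
#' All combinations of `p1` in \{0.0072, 0.018, 0.036, 0.12, 0.24, 0.36,
#' 0.72\}, `p2` in \{0.0036, 0.0072, 0.0108, 0.016\} and `alpha1` in
#' \{0.1, 0.3, 0.5, 0.7, 0.9\} (all rates day^-1), restricted to
#' `p1 > p2` - 125 combinations in total.
#'
#' @return A list of 125 [explicit_heterogeneity_params()] objects; the
#'   generating `(p1, p2, alpha1)` triples are attached as a data frame in
#'   attribute `"grid"`.
#' @export
heterogeneity_grid <- function() {
  combos <- expand.grid(
    p1 = c(0.0072, 0.018, 0.036, 0.12, 0.24, 0.36, 0.72),
    p2 = c(0.0036, 0.0072, 0.0108, 0.0160),
    alpha1 = c(0.1, 0.3, 0.5, 0.7, 0.9),
    KEEP.OUT.ATTRS = FALSE
  )
  combos <- combos[combos$p1 > combos$p2, , drop = FALSE]
  rownames(combos) <- NULL
  out <- lapply(seq_len(nrow(combos)), function(i) {
    explicit_heterogeneity_params(
      p = c(combos$p1[i], combos$p2[i]),
      alpha = c(combos$alpha1[i], 1 - combos$alpha1[i])
    )
  })
  attr(out, "grid") <- combos
  out
}

#' Sample precursor plus heterogeneous-target parameter sets
#'
#' Generates parameter sets for the two-subpopulation target model used for
#' realistic-data simulations. Upstream parameters (`p_C`, `r`, `k`,
#' `d_C*`) follow the [sampling_bounds()] scheme; the routing fraction
#' `gamma` is uniform on (0, 1); each target subpopulation's proliferation
#' rate is log-uniform on \[1e-4, 1e-2\] and its disappearance rate is
#' placed between its proliferation rate and `delta` by the same
#' interpolation transform as the single-target scheme, with each
#' subpopulation independently at equilibrium.
#'
#' @inheritParams sample_precursor_target_params
#' @return A list of `n` [realistic_target_params()] objects.
#' @export
sample_realistic_target_params <- function(n, bounds = sampling_bounds(),
                                           seed = NULL) {
  stopifnot(is.numeric(n), n >= 1, inherits(bounds, "sampling_bounds"))
  if (!is.null(seed)) set.seed(seed)
  lower <- bounds$lower
  upper <- bounds$upper
  delta <- bounds$delta
  u <- lhs::randomLHS(n, 9L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- function(j, lo, hi) unname(lo + u[i, j] * (hi - lo))
    p_C <- 10^sc(1L, lower[1L], upper[1L])
    r <- p_C * 10^sc(2L, lower[3L], upper[3L])
    k <- sc(3L, lower[4L], upper[4L])
    d_C_star <- (p_C - r) * 10^sc(4L, lower[5L], upper[5L])
    gamma <- u[i, 5L]
    sub <- function(jp, ju) {
      p <- 10^sc(jp, lower[2L], upper[2L])
      d <- 10^(log10(p) + u[i, ju] * (log10(delta) - log10(p)))
      c(p = p, d = d)
    }
    s1 <- sub(6L, 7L)
    s2 <- sub(8L, 9L)
    out[[i]] <- realistic_target_params(
      p_C = p_C, r = r, k = k, d_C_star = d_C_star, gamma = gamma,
      p1 = s1[["p"]], d1 = s1[["d"]], p2 = s2[["p"]], d2 = s2[["d"]])
  }
  out
}
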