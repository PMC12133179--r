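# Closed-form descriptors of the target compartment and the analytic error
# formulas for interpreting the one-compartment estimate p-hat.

#' Target-compartment descriptors
#'
#' Summarises a precursor/target parameter set by the three rates that a
#' one-compartment fit conflates, plus the influx ratio and case label:
#' * proliferation `p_E`;
#' * turnover `T = r * 2^k * C/E + p_E` (total inflow = outflow `d_E` at
#'   steady state);
#' * production by division `P = r * (2^k - 1) * C/E + p_E`;
#' * influx ratio `X = r * 2^k * C/E / d_E`, the fraction of target
#'   turnover supplied by differentiation from the precursor (at
#'   equilibrium `X = (d_E - p_E) / d_E`).
#'
#' @param params A [precursor_target_params()].
#' @param x_threshold Influx-ratio threshold separating the "large influx"
#'   cases (A, C) from the "small influx" cases (B, D); see
#'   [classify_case()].
#' @return A list with fields `proliferation`, `turnover`,
#'   `production_by_division`, `influx_ratio`, `case_label`.
#' @export
target_descriptors <- function(params, x_threshold = 0.1) {
  stopifnot(inherits(params, "precursor_target_params"))
  rr <- params$r * params$ratio_CE
  two_k <- 2^params$k
  turnover <- rr * two_k + params$p_E
  production <- rr * (two_k - 1) + params$p_E
  X <- if (turnover > 0) rr * two_k / turnover else 0
  list(
    proliferation = params$p_E,
    turnover = turnover,
    production_by_division = production,
    influx_ratio = X,
    case_label = classify_case(X, params$k, x_threshold)
  )
}

#' Theoretical error in proliferation from the one-compartment estimate
#'
#' The one-compartment estimate approximates production by division `P`;
#' equating it with the proliferation rate `p_E` incurs a relative error
#' `100 * (P - p_E) / p_E = 100 * X * (2^k - 1) / ((1 - X) * 2^k)` percent,
#' a function of the influx ratio `X` and the divisions-per-differentiation
#' `k` only.
#'
#' @param X Influx ratio(s), in [0, 1).
#' @param k Divisions per differentiation event (real, >= 0).
#' @return Percent error(s); vectorised over `X` and `k`.
#' @export
proliferation_error_theory <- function(X, k) {
  stopifnot(is.numeric(X), is.numeric(k), all(k >= 0))
  if (any(X < 0 | X >= 1)) stop("influx ratio X must lie in [0, 1)")
  100 * X * (2^k - 1) / ((1 - X) * 2^k)
}

#' Theoretical error in turnover from the one-compartment estimate
#'
#' Equating production by division `P` with the turnover rate `T` incurs a
#' relative error of magnitude `100 * X / 2^k` percent (`T` is
#' underestimated): the unlabelled part of the precursor influx is
#' invisible to the labelling experiment.
#'
#' @inheritParams proliferation_error_theory
#' @return Percent error magnitude(s); vectorised.
#' @export
turnover_error_theory <- function(X, k) {
  stopifnot(is.numeric(X), is.numeric(k), all(k >= 0))
  if (any(X < 0 | X >= 1)) stop("influx ratio X must lie in [0, 1)")
  100 * X / 2^k
}

#' Classify a target compartment into cases A-D
#'
#' Case A: `k > 0` and large influx ratio (labelled influx dominates);
#' case B: `k > 0`, small influx; case C: `k = 0`, large influx (unlabelled
#' influx dominates); case D: `k = 0`, small influx. "Large" means
#' `X >= threshold`.
#'
#' @inheritParams proliferation_error_theory
#' @param threshold Influx-ratio threshold, default 0.1.
#' @return Character vector of case labels.
#' @export
classify_case <- function(X, k, threshold = 0.1) {
  stopifnot(is.numeric(X), is.numeric(k), all(X >= 0), all(X < 1),
            all(k >= 0), threshold > 0)
  big <- X >= threshold
  ifelse(k > 0, ifelse(big, "A", "B"), ifelse(big, "C", "D"))
}

#' Upper bound on turnover minus production by division
#'
#' `T - P = r * C/E <= p_C * C/E` since the differentiation rate cannot
#' exceed the precursor proliferation rate at equilibrium. Knowledge of the
#' precursor proliferation rate and the compartment size ratio therefore
#' bounds the gap between the two descriptors even when `r` and `k` are
#' unknown.
#'
#' @param p_C Precursor proliferation rate, day^-1.
#' @param ratio_CE Precursor-to-target size ratio, dimensionless.
#' @return The bound `p_C * ratio_CE`, day^-1.
#' @export
upstream_bound <- function(p_C, ratio_CE) {
  stopifnot(is.numeric(p_C), is.numeric(ratio_CE),
            all(p_C >= 0), all(ratio_CE >= 0))
  p_C * ratio_CE
}
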