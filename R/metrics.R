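# Error and coverage metrics for simulation studies.

#' Percentage error of an estimate
#'
#' `100 * (estimate - truth) / truth`, the signed relative discrepancy in
#' percent; set `absolute = TRUE` for its magnitude.
#'
#' @param estimate,truth Numeric vectors (recycled to common length);
#'   `truth` must be non-zero.
#' @param absolute Return `|error|` instead of the signed error.
#' @return Percent error(s).
#' @export
percentage_error <- function(estimate, truth, absolute = FALSE) {
  stopifnot(is.numeric(estimate), is.numeric(truth))
  if (any(truth == 0)) stop("percentage error is undefined for truth = 0")
  out <- 100 * (estimate - truth) / truth
  if (absolute) abs(out) else out
}

#' Interval coverage
#'
#' Fraction of runs whose interval contains the true value. Runs with a
#' missing bound or truth are dropped and reported in `n_used`.
#'
#' @param lower,upper Interval bounds, one per run.
#' @param truth True values, one per run.
#' @return A list with `proportion` and `n_used`.
#' @export
coverage <- function(lower, upper, truth) {
  stopifnot(length(lower) == length(upper), length(lower) == length(truth))
  if (length(lower) == 0L) stop("coverage of an empty set of runs is undefined")
  ok <- is.finite(truth) & !is.na(lower) & !is.na(upper)
  if (!any(ok)) stop("no usable runs")
  inside <- truth[ok] >= lower[ok] & truth[ok] <= upper[ok]
  list(proportion = mean(inside), n_used = sum(ok))
}
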