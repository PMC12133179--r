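#' Body-water deuterium enrichment curve
#'
#' Empirical forcing function for label uptake. During the labelling phase
#' (`t <= tau`) enrichment rises as `f_plateau * (1 - exp(-delta * t))`;
#' after label withdrawal it decays exponentially from its value at `tau`
#' at the same rate `delta`. All times are in days, rates in day^-1.
#'
#' @param f_plateau Plateau enrichment (fraction of D2O in daily water
#'   intake), in (0, 1). Default 0.032.
#' @param delta Rate at which the plateau is approached and at which label
#'   washes out (the turnover rate of body water), day^-1. Default 0.07;
#'   a value of 0.064 also appears in published parameter tables for the
#'   kinetic-heterogeneity simulations and can be set here.
#' @param tau Length of the labelling phase, days. Default 49.
#' @param b_w Amplification (normalisation) factor for deuterium
#'   incorporation from water into DNA. Default 4.18.
#' @return An object of class `body_water_curve`.
#' @seealso [body_water_fraction()], [perfect_label_curve()]
#' @export
#' @examples
#' curve <- body_water_curve()
#' body_water_fraction(curve, c(0, 10, 49, 70))
body_water_curve <- function(f_plateau = 0.032, delta = 0.07, tau = 49,
                             b_w = 4.18) {
  stopifnot(
    is.numeric(f_plateau), length(f_plateau) == 1L,
    f_plateau > 0, f_plateau < 1,
    is.numeric(delta), length(delta) == 1L, delta > 0,
    is.numeric(tau), length(tau) == 1L, tau > 0,
    is.numeric(b_w), length(b_w) == 1L, b_w > 0
  )
  structure(
    list(f_plateau = f_plateau, delta = delta, tau = tau, b_w = b_w,
         perfect = FALSE),
    class = "body_water_curve"
  )
}

#' Idealised perfect-labelling curve
#'
#' Enrichment is exactly 1 during the labelling phase and 0 afterwards,
#' with no uptake or washout kinetics. Used to emulate label-administration
#' protocols analysed under the assumption of instantaneous, complete
#' labelling (the classic multi-subpopulation benchmark scenario).
#'
#' @param tau Length of the labelling phase, days.
#' @param b_w Amplification factor; defaults to 1 because the forcing is
#'   already saturating.
#' @return An object of class `body_water_curve` with the `perfect` flag set.
#' @export
perfect_label_curve <- function(tau = 49, b_w = 1) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0, b_w > 0)
  structure(
    list(f_plateau = 1, delta = Inf, tau = tau, b_w = b_w, perfect = TRUE),
    class = "body_water_curve"
  )
}

#' Evaluate the body-water enrichment
#'
#' @param curve A [body_water_curve()].
#' @param t Time point(s), days; must be non-negative.
#' @return Numeric vector of enrichment fractions, `U(t)`.
#' @export
body_water_fraction <- function(curve, t) {
  stopifnot(inherits(curve, "body_water_curve"), is.numeric(t))
  if (any(t < 0)) {
    stop("body_water_fraction: negative time points are outside the domain")
  }
  if (curve$perfect) {
    return(as.numeric(t <= curve$tau))
  }
  f <- curve$f_plateau
  delta <- curve$delta
  tau <- curve$tau
  u_tau <- f * (-expm1(-delta * tau))
  ifelse(t <= tau,
         f * (-expm1(-delta * t)),
         u_tau * exp(-delta * (t - tau)))
}

#' @export
print.body_water_curve <- function(x, ...) {
  if (x$perfect) {
    cat(sprintf("<perfect labelling curve: U=1 on [0, %g] d, b_w = %g>\n",
                x$tau, x$b_w))
  } else {
    cat(sprintf(
      "<body-water curve: f = %g, delta = %g /d, tau = %g d, b_w = %g>\n",
      x$f_plateau, x$delta, x$tau, x$b_w))
  }
  invisible(x)
}
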