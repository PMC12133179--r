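# Blood-versus-lymphoid-tissue label discrepancy analysis.

#' Maximum relative discrepancy between tissue and blood label
#'
#' Solves the blood/lymph recirculation model and returns
#' `D = max over the grid of (F_A - F_B) / F_A`: how badly the observable
#' blood label can misrepresent the (unobservable) tissue label. The
#' relative discrepancy diverges as t -> 0+ (both fractions start at
#' zero), so the default evaluation grid starts at day 1; the grid is a
#' sensitivity knob and is returned alongside the result.
#'
#' @param params A [blood_lymph_params()].
#' @param curve A [body_water_curve()].
#' @param times Evaluation grid, days; must exclude 0.
#' @return A list of class `discrepancy_result`: `D`, `times`, `params`.
#' @export
discrepancy <- function(params, curve, times = 1:100) {
  stopifnot(inherits(params, "blood_lymph_params"))
  if (any(times <= 0)) {
    stop("the relative discrepancy is undefined at t = 0; use a grid of positive times")
  }
  sol <- solve_blood_lymph(params, curve, times)
  F_A <- label_fractions(sol, "A")
  F_B <- label_fractions(sol, "B")
  if (any(F_A <= 0)) stop("F_A vanishes on the grid; discrepancy undefined")
  structure(list(D = max((F_A - F_B) / F_A), times = times, params = params),
            class = "discrepancy_result")
}

#' Discrepancy sweep over proliferation and recirculation rates
#'
#' Applies [discrepancy()] over a grid of tissue proliferation rates `p`
#' and recirculation rates `f_recirc`, with the equilibrium constraints
#' `d = p` and `g = f_recirc * ratio_BA` imposed in every cell. The
#' default grid spans `log10 p` in \[-4, -1\] and `log10 f` in \[-4, 8\]
#' and includes the physiological baseline `f = 28` per day.
#'
#' @param p_values Tissue proliferation rates, day^-1.
#' @param f_values Recirculation rates, day^-1.
#' @param curve A [body_water_curve()].
#' @param ratio_BA Blood-to-tissue size ratio (default 2/98).
#' @param times Evaluation grid passed to [discrepancy()].
#' @return A data frame with columns `p`, `f_recirc`, `D`.
#' @export
discrepancy_grid <- function(p_values = 10^seq(-4, -1, by = 1),
                             f_values = c(10^seq(-4, 8, by = 1), 28),
                             curve = body_water_curve(),
                             ratio_BA = 2 / 98, times = 1:100) {
  grid <- expand.grid(p = p_values, f_recirc = sort(f_values))
  grid$D <- vapply(seq_len(nrow(grid)), function(i) {
    discrepancy(blood_lymph_params(grid$p[i], grid$f_recirc[i], ratio_BA),
                curve, times)$D
  }, numeric(1L))
  grid
}

#' Lymphocyte recirculation rate from blood-exit fluxes
#'
#' The blood-to-tissue exit rate is the total daily efflux of lymphocytes
#' from blood divided by the blood lymphocyte count. Defaults: 2.5e11
#' cells/day exit to the spleen, 0.3e11 cells/day to lymph nodes, 1e10
#' lymphocytes in blood, giving 28 per day.
#'
#' @param exit_spleen,exit_lymph_node Daily effluxes, cells/day.
#' @param blood_count Lymphocytes in blood.
#' @return Recirculation rate, day^-1.
#' @export
recirculation_rate_from_fluxes <- function(exit_spleen = 2.5e11,
                                           exit_lymph_node = 0.3e11,
                                           blood_count = 1e10) {
  stopifnot(blood_count > 0, exit_spleen >= 0, exit_lymph_node >= 0)
  (exit_spleen + exit_lymph_node) / blood_count
}

#' Lymphocyte recirculation rate from blood transit time
#'
#' If a lymphocyte takes `transit_min` minutes to transit the blood and a
#' fraction `fraction_exit` of transits end in lymphoid tissue, the exit
#' rate is `fraction_exit / transit time`. Defaults (30 min, 87%) give
#' about 42 per day.
#'
#' @param transit_min Blood transit time, minutes.
#' @param fraction_exit Fraction of transits that exit to lymphoid tissue.
#' @return Recirculation rate, day^-1.
#' @export
recirculation_rate_from_transit <- function(transit_min = 30,
                                            fraction_exit = 0.87) {
  stopifnot(transit_min > 0, fraction_exit > 0, fraction_exit <= 1)
  fraction_exit / (transit_min / (24 * 60))
}

#' @export
print.discrepancy_result <- function(x, ...) {
  cat(sprintf("<discrepancy: D = %.4g (p = %g, f = %g /d, grid %g..%g d)>\n",
              x$D, x$params$p, x$params$f_recirc,
              min(x$times), max(x$times)))
  invisible(x)
}
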