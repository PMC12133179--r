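#' One-compartment labelling model parameters
#'
#' The closed-population model `dF/dt = p * b_w * U(t) - d_star * F`, in
#' which a single rate `p` describes proliferation, production by division
#' and turnover, and `d_star` is the disappearance rate of *labelled* cells.
#' `d_star = p` recovers the kinetically homogeneous model; `d_star > p`
#' represents kinetic heterogeneity implicitly.
#'
#' @param p Production rate by division, day^-1 (non-negative).
#' @param d_star Disappearance rate of labelled cells, day^-1
#'   (non-negative). Defaults to `p` (homogeneous case).
#' @return Object of class `one_compartment_params`.
#' @export
one_compartment_params <- function(p, d_star = p) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0,
            is.numeric(d_star), length(d_star) == 1L, d_star >= 0)
  structure(list(p = p, d_star = d_star), class = "one_compartment_params")
}

#' Precursor/target two-compartment model parameters
#'
#' Precursor cells C proliferate at rate `p_C`, die at rate `d_C` and
#' differentiate at rate `r`, undergoing `k` divisions upon differentiation.
#' Target cells E proliferate at `p_E` and disappear at `d_E`. Both
#' populations are independently at equilibrium, which fixes
#' `d_C = p_C - r` and the precursor/target size ratio
#' `ratio_CE = (d_E - p_E) / (r * 2^k)`. Kinetic heterogeneity within each
#' compartment is represented implicitly by disappearance rates of labelled
#' cells `d_C_star >= d_C` and `d_E_star >= d_E`, which replace `d_C` and
#' `d_E` in the label equations when solving with `heterogeneous = TRUE`.
#'
#' `k` is treated as a real number; `2^k` is evaluated for real `k`
#' (`k = 0` means differentiation without division).
#'
#' @param p_C,r,k,p_E,d_E Model rates (day^-1) and divisions per
#'   differentiation event.
#' @param d_C_star Disappearance rate of labelled precursor cells; defaults
#'   to the homogeneous value `p_C - r`.
#' @param d_E_star Disappearance rate of labelled target cells; defaults to
#'   `d_E`.
#' @return Object of class `precursor_target_params`; the derived fields
#'   `d_C` and `ratio_CE` are included.
#' @export
precursor_target_params <- function(p_C, r, k, p_E, d_E,
                                    d_C_star = p_C - r, d_E_star = d_E) {
  base <- c(p_C = p_C, r = r, k = k, p_E = p_E, d_E = d_E)
  stopifnot(is.numeric(base), all(is.finite(base)), all(base >= 0))
  if (r > p_C) stop("equilibrium requires r <= p_C")
  vals <- c(d_C_star = d_C_star, d_E_star = d_E_star)
  stopifnot(is.numeric(vals), all(is.finite(vals)), all(vals >= 0))
  d_C <- unname(p_C - r)
  if (d_C_star < d_C - 1e-12) stop("expected d_C_star >= d_C")
  if (d_E_star < d_E - 1e-12) stop("expected d_E_star >= d_E")
  if (d_E < p_E - 1e-12) stop("equilibrium requires d_E >= p_E")
  if (r == 0) {
    if (d_E > p_E + 1e-12) {
      stop("r = 0 with d_E > p_E leaves the precursor/target size ratio undefined")
    }
    ratio_CE <- 0
  } else {
    ratio_CE <- (d_E - p_E) / (r * 2^k)
  }
  structure(
    list(p_C = p_C, d_C = d_C, d_C_star = d_C_star, r = r, k = k,
         p_E = p_E, d_E = d_E, d_E_star = d_E_star, ratio_CE = ratio_CE),
    class = "precursor_target_params"
  )
}

#' Explicit kinetic heterogeneity model parameters
#'
#' `N` unconnected subpopulations, each independently at equilibrium
#' (so each subpopulation's disappearance rate equals its proliferation
#' rate `p_i`), with relative sizes `alpha_i` summing to one. The observed
#' labelled fraction is the alpha-weighted sum of the subpopulation curves.
#' Subpopulations are stored sorted by increasing `alpha` (the conventional
#' ordering that removes label-switching ambiguity).
#'
#' @param p Vector of subpopulation proliferation rates, day^-1.
#' @param alpha Vector of subpopulation size fractions; must sum to 1.
#' @return Object of class `explicit_heterogeneity_params` with fields
#'   `N`, `p`, `alpha`.
#' @export
explicit_heterogeneity_params <- function(p, alpha = rep(1 / length(p), length(p))) {
  stopifnot(is.numeric(p), length(p) >= 1L, all(is.finite(p)), all(p >= 0),
            is.numeric(alpha), length(alpha) == length(p),
            all(alpha > 0), all(alpha <= 1))
  if (abs(sum(alpha) - 1) > 1e-8) stop("subpopulation weights must sum to 1")
  ord <- order(alpha)
  structure(
    list(N = length(p), p = p[ord], alpha = alpha[ord] / sum(alpha)),
    class = "explicit_heterogeneity_params"
  )
}

#' Precursor plus heterogeneous-target model parameters
#'
#' As [precursor_target_params()], but the target compartment consists of
#' two subpopulations E1 and E2, each independently at equilibrium.
#' Differentiating precursor cells are routed to E1 with probability
#' `gamma` and to E2 otherwise. Equilibrium of each fed subpopulation fixes
#' its size relative to the precursor pool:
#' `ratio_CE1 = (d1 - p1) / (gamma * r * 2^k)` (and analogously for E2).
#' The observed labelled fraction of the target population is the
#' size-weighted average of the two subpopulation curves. When `gamma` is
#' 0 or 1 the unfed subpopulation is absent and the model reduces to the
#' single-target precursor/target model.
#'
#' @param p_C,r,k Upstream rates as in [precursor_target_params()].
#' @param d_C_star Disappearance rate of labelled precursor cells.
#' @param gamma Fraction of differentiating cells entering E1, in [0, 1].
#' @param p1,d1,p2,d2 Proliferation and disappearance rates of the two
#'   target subpopulations (day^-1); each fed subpopulation needs
#'   `d_i > p_i` for a finite equilibrium size.
#' @return Object of class `realistic_target_params` with derived size
#'   ratios and observation weights.
#' @export
realistic_target_params <- function(p_C, r, k, d_C_star, gamma,
                                    p1, d1, p2, d2) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L)
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  vals <- c(p_C, r, k, d_C_star, p1, d1, p2, d2)
  stopifnot(is.numeric(vals), all(is.finite(vals)), all(vals >= 0))
  if (r > p_C) stop("equilibrium requires r <= p_C")
  if (r <= 0) stop("the heterogeneous-target model requires precursor inflow (r > 0)")
  ratio <- function(g, pp, dd, lab) {
    if (g == 0) return(NA_real_)
    if (dd <= pp) {
      stop(sprintf("subpopulation %s receives inflow but has d <= p: no finite equilibrium size", lab))
    }
    (dd - pp) / (g * r * 2^k)
  }
  ratio_CE1 <- ratio(gamma, p1, d1, "E1")
  ratio_CE2 <- ratio(1 - gamma, p2, d2, "E2")
  sizes <- c(
    if (gamma > 0) 1 / ratio_CE1 else 0,   # E1 size in units of C-bar
    if (gamma < 1) 1 / ratio_CE2 else 0
  )
  wts <- sizes / sum(sizes)
  structure(
    list(p_C = p_C, r = r, k = k, d_C_star = d_C_star, gamma = gamma,
         p1 = p1, d1 = d1, p2 = p2, d2 = d2,
         ratio_CE1 = ratio_CE1, ratio_CE2 = ratio_CE2,
         obs_weights = wts,
         # precursor-to-whole-target size ratio and size-weighted mean
         # proliferation of the observed target population
         ratio_CE = 1 / sum(sizes),
         p_E_mean = sum(wts * c(p1, p2))),
    class = "realistic_target_params"
  )
}

#' Blood/lymphoid-tissue recirculation model parameters
#'
#' Cells of the population of interest proliferate (rate `p`) and disappear
#' (rate `d`) in lymphoid tissue (compartment A), enter the blood
#' (compartment B) at rate `g` and return to tissue at rate `f_recirc`.
#' Only blood is sampled. Equilibrium of the tissue compartment requires
#' `d = p`, and equilibrium of the blood compartment together with the
#' blood-to-tissue size ratio `ratio_BA` fixes `g = f_recirc * ratio_BA`.
#'
#' @param p Tissue proliferation rate, day^-1.
#' @param f_recirc Blood-to-tissue return rate, day^-1 (must be > 0).
#'   Named `f_recirc` to avoid clashing with the plateau enrichment of the
#'   body-water curve.
#' @param ratio_BA Blood-to-tissue population size ratio; about 2/98 for
#'   lymphocytes.
#' @return Object of class `blood_lymph_params` with derived `d` and `g`.
#' @export
blood_lymph_params <- function(p, f_recirc, ratio_BA = 2 / 98) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, is.finite(p),
            is.numeric(f_recirc), length(f_recirc) == 1L, is.finite(f_recirc),
            is.numeric(ratio_BA), length(ratio_BA) == 1L, ratio_BA > 0)
  if (f_recirc <= 0) stop("f_recirc must be positive")
  structure(
    list(p = p, d = p, g = f_recirc * ratio_BA, f_recirc = f_recirc,
         ratio_BA = ratio_BA),
    class = "blood_lymph_params"
  )
}

#' @export
print.precursor_target_params <- function(x, ...) {
  cat(sprintf(
    paste0("<precursor/target params: p_C = %.4g, d_C = %.4g (d_C* = %.4g), ",
           "r = %.4g, k = %.3g,\n  p_E = %.4g, d_E = %.4g (d_E* = %.4g), ",
           "C/E ratio = %.4g>\n"),
    x$p_C, x$d_C, x$d_C_star, x$r, x$k, x$p_E, x$d_E, x$d_E_star, x$ratio_CE))
  invisible(x)
}

#' @export
print.explicit_heterogeneity_params <- function(x, ...) {
  cat(sprintf("<explicit kinetic heterogeneity: N = %d>\n", x$N))
  print(data.frame(p = x$p, alpha = x$alpha), row.names = FALSE)
  invisible(x)
}
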