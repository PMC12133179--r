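# Forward solvers for all labelling models.
#
# Each model is a cascade of linear compartments forced by the body-water
# curve U(t), so closed-form solutions are assembled from the .edif/.resp2
# kernels phase by phase (labelling, then washout). Every solver also has a
# numerical path through deSolve::lsoda for cross-validation.

.check_times <- function(times) {
  stopifnot(is.numeric(times), length(times) >= 1L, all(is.finite(times)))
  if (any(times < 0)) stop("time points must be non-negative")
  if (is.unsorted(times, strictly = TRUE)) {
    stop("time points must be strictly increasing")
  }
  invisible(times)
}

# -- closed-form building blocks ---------------------------------------------

# labelled fraction of a single compartment with production rate p and
# labelled-cell disappearance rate a, forced by `curve`
.onecomp_label <- function(p, a, curve, times) {
  tau <- curve$tau
  b_w <- curve$b_w
  in1 <- times <= tau
  t1 <- times[in1]
  s2 <- times[!in1] - tau
  out <- numeric(length(times))
  if (curve$perfect) {
    out[in1] <- p * b_w * .edif(0, a, t1)
    if (any(!in1)) {
      f_tau <- p * b_w * .edif(0, a, tau)
      out[!in1] <- f_tau * exp(-a * s2)
    }
    return(out)
  }
  f <- curve$f_plateau
  delta <- curve$delta
  A <- p * b_w * f
  out[in1] <- A * (.edif(0, a, t1) - .edif(delta, a, t1))
  if (any(!in1)) {
    f_tau <- A * (.edif(0, a, tau) - .edif(delta, a, tau))
    u_tau <- f * (-expm1(-delta * tau))
    out[!in1] <- f_tau * exp(-a * s2) + p * b_w * u_tau * .edif(delta, a, s2)
  }
  out
}

# precursor/target cascade: precursor labelled fraction F_C (production p_C,
# decay a_C) feeding a target compartment with decay a_E, influx coefficient
# w = r * C/E ratio and direct forcing coefficient q = b_w ((2^k - 1) w + p_E)
.cascade_label <- function(p_C, a_C, w, q, a_E, curve, times) {
  tau <- curve$tau
  b_w <- curve$b_w
  in1 <- times <= tau
  t1 <- times[in1]
  s2 <- times[!in1] - tau
  F_C <- numeric(length(times))
  F_E <- numeric(length(times))
  if (curve$perfect) {
    F_C[in1] <- p_C * b_w * .edif(0, a_C, t1)
    F_E[in1] <- q * .edif(0, a_E, t1) +
      w * p_C * b_w * .resp2(0, a_C, a_E, t1)
    if (any(!in1)) {
      fc_tau <- p_C * b_w * .edif(0, a_C, tau)
      fe_tau <- q * .edif(0, a_E, tau) +
        w * p_C * b_w * .resp2(0, a_C, a_E, tau)
      F_C[!in1] <- fc_tau * exp(-a_C * s2)
      F_E[!in1] <- fe_tau * exp(-a_E * s2) +
        w * fc_tau * .edif(a_C, a_E, s2)
    }
    return(list(F_C = F_C, F_E = F_E))
  }
  f <- curve$f_plateau
  delta <- curve$delta
  P_C <- p_C * b_w * f
  F_C[in1] <- P_C * (.edif(0, a_C, t1) - .edif(delta, a_C, t1))
  F_E[in1] <- q * f * (.edif(0, a_E, t1) - .edif(delta, a_E, t1)) +
    w * P_C * (.resp2(0, a_C, a_E, t1) - .resp2(delta, a_C, a_E, t1))
  if (any(!in1)) {
    fc_tau <- P_C * (.edif(0, a_C, tau) - .edif(delta, a_C, tau))
    fe_tau <- q * f * (.edif(0, a_E, tau) - .edif(delta, a_E, tau)) +
      w * P_C * (.resp2(0, a_C, a_E, tau) - .resp2(delta, a_C, a_E, tau))
    u_tau <- f * (-expm1(-delta * tau))
    F_C[!in1] <- fc_tau * exp(-a_C * s2) +
      p_C * b_w * u_tau * .edif(delta, a_C, s2)
    F_E[!in1] <- fe_tau * exp(-a_E * s2) +
      q * u_tau * .edif(delta, a_E, s2) +
      w * (fc_tau * .edif(a_C, a_E, s2) +
             p_C * b_w * u_tau * .resp2(delta, a_C, a_E, s2))
  }
  list(F_C = F_C, F_E = F_E)
}

# -- numerical (ODE) path ----------------------------------------------------

# integrate a linear label system piecewise over the labelling and washout
# phases so the kink in U(t) at tau never crosses an integrator step
.ode_label <- function(rhs, y0, times, curve, parms,
                       rtol = 1e-11, atol = 1e-13) {
  tau <- curve$tau
  grid <- sort(unique(c(0, times, if (max(times) > tau) tau)))
  g1 <- grid[grid <= tau]
  g2 <- grid[grid >= tau]
  out <- NULL
  y <- y0
  if (length(g1) >= 2L) {
    sol1 <- deSolve::lsoda(y, g1, rhs, parms = parms, curve = curve,
                           rtol = rtol, atol = atol)
    out <- sol1
    y <- as.numeric(sol1[nrow(sol1), -1L])
  }
  if (length(g2) >= 2L) {
    sol2 <- deSolve::lsoda(y, g2, rhs, parms = parms, curve = curve,
                           rtol = rtol, atol = atol)
    out <- if (is.null(out)) sol2 else rbind(out, sol2[-1L, , drop = FALSE])
  }
  if (is.null(out)) out <- matrix(c(0, y0), nrow = 1L)
  idx <- match(times, out[, 1L])
  out[idx, -1L, drop = FALSE]
}

# -- label_curve container ---------------------------------------------------

#' Labelled-fraction time course
#'
#' A thin data-frame container for solver output: one row per time point and
#' compartment, columns `time_days`, `compartment`, `fraction_labelled`.
#'
#' @param times Strictly increasing non-negative times, days.
#' @param fractions Named list of labelled-fraction vectors, one per
#'   compartment, each the same length as `times`.
#' @return Object of classes `label_curve` and `data.frame`.
#' @export
label_curve <- function(times, fractions) {
  .check_times(times)
  stopifnot(is.list(fractions), length(fractions) >= 1L,
            !is.null(names(fractions)))
  for (f in fractions) {
    stopifnot(length(f) == length(times), all(is.finite(f)), all(f >= -1e-12))
  }
  out <- do.call(rbind, lapply(names(fractions), function(nm) {
    data.frame(time_days = times, compartment = nm,
               fraction_labelled = pmax(fractions[[nm]], 0))
  }))
  class(out) <- c("label_curve", "data.frame")
  out
}

#' Extract one compartment's fractions from a label curve
#'
#' @param x A [label_curve()].
#' @param compartment Compartment name; defaults to the first present.
#' @return Numeric vector of labelled fractions in time order.
#' @export
label_fractions <- function(x, compartment = NULL) {
  stopifnot(inherits(x, "label_curve"))
  if (is.null(compartment)) compartment <- x$compartment[1L]
  sub <- x[x$compartment == compartment, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no such compartment: ", compartment)
  sub$fraction_labelled[order(sub$time_days)]
}

#' Write a label curve to CSV
#'
#' @param x A [label_curve()].
#' @param path Output file path.
#' @export
write_label_curve <- function(x, path) {
  stopifnot(inherits(x, "label_curve"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

# -- public solvers ----------------------------------------------------------

#' Solve the one-compartment labelling model
#'
#' `dF/dt = p * b_w * U(t) - d_star * F`, with `F(0) = 0`.
#'
#' @param params A [one_compartment_params()].
#' @param curve A [body_water_curve()].
#' @param times Strictly increasing non-negative times, days.
#' @param method `"analytic"` (piecewise closed form, resonance-safe) or
#'   `"ode"` (adaptive numerical integration).
#' @return A [label_curve()] with compartment `"E"`.
#' @export
solve_one_compartment <- function(params, curve, times,
                                  method = c("analytic", "ode")) {
  stopifnot(inherits(params, "one_compartment_params"),
            inherits(curve, "body_water_curve"))
  .check_times(times)
  method <- match.arg(method)
  if (method == "analytic") {
    fr <- .onecomp_label(params$p, params$d_star, curve, times)
  } else {
    rhs <- function(t, y, parms, curve) {
      u <- body_water_fraction(curve, t)
      list(parms$p * curve$b_w * u - parms$d_star * y)
    }
    fr <- as.numeric(.ode_label(rhs, c(F = 0), times, curve, params))
  }
  label_curve(times, list(E = fr))
}

#' Solve the precursor/target labelling model
#'
#' Two-compartment cascade in which labelled precursor cells (fraction
#' `F_C`) feed the target compartment (fraction `F_E`) through
#' division-linked differentiation. With `heterogeneous = TRUE` (default)
#' the disappearance rates of labelled cells `d_C_star`, `d_E_star` replace
#' `d_C`, `d_E` in the label equations, representing kinetic heterogeneity
#' within each compartment implicitly.
#'
#' @param params A [precursor_target_params()].
#' @inheritParams solve_one_compartment
#' @param heterogeneous Use `d_C_star`/`d_E_star` (TRUE) or the homogeneous
#'   rates `d_C`/`d_E` (FALSE) in the label equations.
#' @return A [label_curve()] with compartments `"C"` and `"E"`.
#' @export
solve_precursor_target <- function(params, curve, times,
                                   heterogeneous = TRUE,
                                   method = c("analytic", "ode")) {
  stopifnot(inherits(params, "precursor_target_params"),
            inherits(curve, "body_water_curve"))
  .check_times(times)
  method <- match.arg(method)
  a_C <- (if (heterogeneous) params$d_C_star else params$d_C) + params$r
  a_E <- if (heterogeneous) params$d_E_star else params$d_E
  w <- params$r * params$ratio_CE
  q <- curve$b_w * ((2^params$k - 1) * w + params$p_E)
  if (method == "analytic") {
    sol <- .cascade_label(params$p_C, a_C, w, q, a_E, curve, times)
  } else {
    rhs <- function(t, y, parms, curve) {
      u <- body_water_fraction(curve, t)
      dC <- parms$p_C * curve$b_w * u - parms$a_C * y[1L]
      dE <- parms$q * u + parms$w * y[1L] - parms$a_E * y[2L]
      list(c(dC, dE))
    }
    m <- .ode_label(rhs, c(F_C = 0, F_E = 0), times, curve,
                    list(p_C = params$p_C, a_C = a_C, w = w, q = q, a_E = a_E))
    sol <- list(F_C = m[, 1L], F_E = m[, 2L])
  }
  label_curve(times, list(C = sol$F_C, E = sol$F_E))
}

#' Solve the explicit kinetic heterogeneity model
#'
#' Each of the `N` unconnected subpopulations is a one-compartment system
#' with disappearance rate equal to its proliferation rate; the total
#' labelled fraction is the alpha-weighted sum.
#'
#' @param params An [explicit_heterogeneity_params()].
#' @inheritParams solve_one_compartment
#' @param keep_subpopulations Also return per-subpopulation curves.
#' @return A [label_curve()] with compartment `"total"` (and `"sub1"`, ...
#'   if requested).
#' @export
solve_explicit_heterogeneity <- function(params, curve, times,
                                         method = c("analytic", "ode"),
                                         keep_subpopulations = FALSE) {
  stopifnot(inherits(params, "explicit_heterogeneity_params"),
            inherits(curve, "body_water_curve"))
  .check_times(times)
  method <- match.arg(method)
  subs <- vector("list", params$N)
  for (i in seq_len(params$N)) {
    if (method == "analytic") {
      subs[[i]] <- .onecomp_label(params$p[i], params$p[i], curve, times)
    } else {
      oc <- one_compartment_params(params$p[i], params$p[i])
      subs[[i]] <- label_fractions(
        solve_one_compartment(oc, curve, times, method = "ode"))
    }
  }
  total <- Reduce(`+`, Map(`*`, subs, as.list(params$alpha)))
  out <- list(total = total)
  if (keep_subpopulations) {
    names(subs) <- paste0("sub", seq_len(params$N))
    out <- c(out, subs)
  }
  label_curve(times, out)
}

#' Solve the precursor plus heterogeneous-target model
#'
#' The precursor compartment feeds two target subpopulations E1, E2 (routed
#' with probability `gamma` / `1 - gamma`), each independently at
#' equilibrium. The observed target label is the size-weighted average of
#' the subpopulation curves.
#'
#' @param params A [realistic_target_params()].
#' @inheritParams solve_one_compartment
#' @param keep_subpopulations Also return `C`, `E1`, `E2` curves.
#' @return A [label_curve()] with compartment `"E"` (and components if
#'   requested).
#' @export
solve_realistic_target <- function(params, curve, times,
                                   method = c("analytic", "ode"),
                                   keep_subpopulations = FALSE) {
  stopifnot(inherits(params, "realistic_target_params"),
            inherits(curve, "body_water_curve"))
  .check_times(times)
  method <- match.arg(method)
  a_C <- params$d_C_star + params$r
  two_k <- 2^params$k
  sub_cfg <- list(
    list(g = params$gamma, p = params$p1, d = params$d1),
    list(g = 1 - params$gamma, p = params$p2, d = params$d2)
  )
  F_C <- NULL
  F_sub <- list()
  for (i in 1:2) {
    cfg <- sub_cfg[[i]]
    if (cfg$g == 0) { F_sub[[i]] <- rep(0, length(times)); next }
    w <- (cfg$d - cfg$p) / two_k          # = g * r * ratio_CEi
    q <- curve$b_w * ((two_k - 1) * w + cfg$p)
    if (method == "analytic") {
      sol <- .cascade_label(params$p_C, a_C, w, q, cfg$d, curve, times)
      F_C <- sol$F_C
      F_sub[[i]] <- sol$F_E
    } else {
      rhs <- function(t, y, parms, curve) {
        u <- body_water_fraction(curve, t)
        dC <- parms$p_C * curve$b_w * u - parms$a_C * y[1L]
        dE <- parms$q * u + parms$w * y[1L] - parms$a_E * y[2L]
        list(c(dC, dE))
      }
      m <- .ode_label(rhs, c(F_C = 0, F_E = 0), times, curve,
                      list(p_C = params$p_C, a_C = a_C, w = w, q = q,
                           a_E = cfg$d))
      F_C <- m[, 1L]
      F_sub[[i]] <- m[, 2L]
    }
  }
  wts <- params$obs_weights
  F_E <- wts[1L] * F_sub[[1L]] + wts[2L] * F_sub[[2L]]
  out <- list(E = F_E)
  if (keep_subpopulations) {
    out <- c(out, list(C = F_C, E1 = F_sub[[1L]], E2 = F_sub[[2L]]))
  }
  label_curve(times, out)
}

#' Solve the blood/lymphoid-tissue recirculation model
#'
#' Coupled two-compartment exchange between lymphoid tissue (A, where
#' proliferation occurs) and blood (B, where cells are sampled). Solved in
#' closed form through the eigendecomposition of the exchange matrix, which
#' remains accurate for recirculation rates spanning many orders of
#' magnitude (the system is stiff for fast exchange).
#'
#' @param params A [blood_lymph_params()].
#' @inheritParams solve_one_compartment
#' @return A [label_curve()] with compartments `"A"` (tissue) and `"B"`
#'   (blood).
#' @export
solve_blood_lymph <- function(params, curve, times,
                              method = c("analytic", "ode")) {
  stopifnot(inherits(params, "blood_lymph_params"),
            inherits(curve, "body_water_curve"))
  .check_times(times)
  method <- match.arg(method)
  d <- params$d
  g <- params$g
  f <- params$f_recirc
  rho <- params$ratio_BA
  M <- matrix(c(-(d + g), g / rho, f * rho, -f), 2L, 2L)
  if (method == "ode") {
    rhs <- function(t, y, parms, curve) {
      u <- body_water_fraction(curve, t)
      list(as.numeric(parms$M %*% y) + c(parms$p * curve$b_w * u, 0))
    }
    m <- .ode_label(rhs, c(F_A = 0, F_B = 0), times, curve,
                    list(M = M, p = params$p))
    return(label_curve(times, list(A = m[, 1L], B = m[, 2L])))
  }
  eg <- eigen(M)
  V <- eg$vectors
  lam <- eg$values            # real and distinct: discriminant >= 4 f^2 rho
  v <- solve(V, c(1, 0))
  tau <- curve$tau
  in1 <- times <= tau
  t1 <- times[in1]
  s2 <- times[!in1] - tau
  Z <- matrix(0, 2L, length(times))
  pbw <- params$p * curve$b_w
  if (curve$perfect) {
    for (i in 1:2) {
      Z[i, in1] <- pbw * v[i] * .edif(0, -lam[i], t1)
    }
    if (any(!in1)) {
      z_tau <- vapply(1:2, function(i) pbw * v[i] * .edif(0, -lam[i], tau),
                      numeric(1L))
      for (i in 1:2) Z[i, !in1] <- z_tau[i] * exp(lam[i] * s2)
    }
  } else {
    fpl <- curve$f_plateau
    delta <- curve$delta
    for (i in 1:2) {
      Z[i, in1] <- pbw * fpl * v[i] *
        (.edif(0, -lam[i], t1) - .edif(delta, -lam[i], t1))
    }
    if (any(!in1)) {
      u_tau <- fpl * (-expm1(-delta * tau))
      z_tau <- vapply(1:2, function(i) {
        pbw * fpl * v[i] * (.edif(0, -lam[i], tau) - .edif(delta, -lam[i], tau))
      }, numeric(1L))
      for (i in 1:2) {
        Z[i, !in1] <- z_tau[i] * exp(lam[i] * s2) +
          pbw * u_tau * v[i] * .edif(delta, -lam[i], s2)
      }
    }
  }
  Fmat <- V %*% Z
  label_curve(times, list(A = Fmat[1L, ], B = Fmat[2L, ]))
}
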