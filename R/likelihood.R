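# Likelihood machinery shared by the maximum-likelihood and Bayesian fits.
#
# The noise family and scale always match the dataset's generating noise
# specification and the scale is treated as known, so the lognormal
# likelihood reduces to least squares on the log scale and the Gaussian
# likelihood to ordinary least squares.

# known noise sd for fitting: the realised value recorded at generation
# time if present, else the nominal scale
.known_sd <- function(noise, observations) {
  if (!is.null(noise$sd_realised)) return(noise$sd_realised)
  if (noise$reference == "fraction_of_max") noise$sd * max(observations)
  else noise$sd
}

# pointwise log-likelihood of predictions `pred` for observations `obs`;
# zero observations with zero predictions (the t = 0 anchor under
# lognormal noise) contribute exactly 0
.loglik_pointwise <- function(pred, obs, noise, sd) {
  if (noise$family == "lognormal") {
    out <- rep(-Inf, length(obs))
    anchor <- obs <= 0 & pred <= 1e-300
    ok <- obs > 0 & pred > 0
    out[anchor] <- 0
    out[ok] <- stats::dlnorm(obs[ok], log(pred[ok]), sd, log = TRUE)
    out
  } else {
    stats::dnorm(obs, pred, sd, log = TRUE)
  }
}

# -- model registry ----------------------------------------------------------
#
# A model spec bundles the parameter vector (on the scale the optimiser /
# sampler works on), its box, a predictor at arbitrary times, and
# accessors for the natural-scale estimates.

# predictor for the precursor/target model on the transformed (Table-style)
# scale; ratio_fixed freezes the precursor/target size ratio (the
# "with-ratio" variant drops the d_E coordinate)
.pt_predict <- function(theta, curve, times, ratio_fixed = NULL) {
  delta <- curve$delta
  p_C <- 10^theta[1L]
  lp_E <- theta[2L]
  p_E <- 10^lp_E
  r <- p_C * 10^theta[3L]
  k <- theta[4L]
  d_C_star <- (p_C - r) * 10^theta[5L]
  span <- log10(delta) - lp_E
  if (is.null(ratio_fixed)) {
    d_E <- 10^(lp_E + theta[6L] * span)
    d_E_star <- 10^(lp_E + theta[7L] * span)
    ratio <- (d_E - p_E) / (r * 2^k)
  } else {
    d_E_star <- 10^(lp_E + theta[6L] * span)
    ratio <- ratio_fixed
  }
  a_C <- d_C_star + r
  w <- r * ratio
  q <- curve$b_w * ((2^k - 1) * w + p_E)
  .cascade_label(p_C, a_C, w, q, d_E_star, curve, times)$F_E
}

.pt_natural <- function(theta, curve, ratio_fixed = NULL) {
  delta <- curve$delta
  p_C <- 10^theta[1L]
  p_E <- 10^theta[2L]
  r <- p_C * 10^theta[3L]
  k <- theta[4L]
  span <- log10(delta) - theta[2L]
  if (is.null(ratio_fixed)) {
    d_E <- 10^(theta[2L] + theta[6L] * span)
    d_E_star <- 10^(theta[2L] + theta[7L] * span)
    ratio <- (d_E - p_E) / (r * 2^k)
  } else {
    d_E_star <- 10^(theta[2L] + theta[6L] * span)
    ratio <- ratio_fixed
    d_E <- r * 2^k * ratio + p_E
  }
  list(p_C = p_C, d_C = p_C - r, d_C_star = (p_C - r) * 10^theta[5L],
       r = r, k = k, p_E = p_E, d_E = d_E, d_E_star = d_E_star,
       ratio_CE = ratio)
}

# Build the model spec. `model` is one of:
#   "one_compartment"  p, d* (broad p box, 5/b_w)
#   "implicit"         p, d* (unit boxes; the kinetic-heterogeneity context)
#   "homogeneous"      p only, d* = p
#   "explicit"         N-subpopulation mixture, parameters p_1..p_N and
#                      alpha_1..alpha_{N-1} (ordered ascending)
#   "precursor_target"        transformed 7-parameter cascade
#   "precursor_target_ratio"  as above with the size ratio frozen
.model_spec <- function(model, curve, N = 2L, ratio_CE = NULL,
                        p_upper = NULL, d_star_upper = NULL,
                        bounds = sampling_bounds(delta = curve$delta)) {
  switch(model,
    one_compartment = {
      pu <- if (is.null(p_upper)) 5 / curve$b_w else p_upper
      du <- if (is.null(d_star_upper)) 1 else d_star_upper
      list(id = model, par_names = c("p", "d_star"),
           lower = c(0, 0), upper = c(pu, du),
           # rates span decades: the ML multi-start searches log10 space
           search = list(lower = log10(c(1e-5, 1e-5)),
                         upper = log10(c(pu, du)),
                         map = function(s) 10^s),
           predict = function(theta, times)
             .onecomp_label(theta[1L], theta[2L], curve, times),
           natural = function(theta) list(p = theta[1L], d_star = theta[2L]),
           mean_p = function(theta) theta[1L])
    },
    implicit = {
      pu <- if (is.null(p_upper)) 1 else p_upper
      du <- if (is.null(d_star_upper)) pu else d_star_upper
      list(id = model, par_names = c("p", "d_star"),
           lower = c(0, 0), upper = c(pu, du),
           search = list(lower = log10(c(1e-5, 1e-5)),
                         upper = log10(c(pu, du)),
                         map = function(s) 10^s),
           predict = function(theta, times)
             .onecomp_label(theta[1L], theta[2L], curve, times),
           natural = function(theta) list(p = theta[1L], d_star = theta[2L]),
           mean_p = function(theta) theta[1L])
    },
    homogeneous = {
      pu <- if (is.null(p_upper)) 1 else p_upper
      list(id = model, par_names = "p",
           lower = 0, upper = pu,
           search = list(lower = log10(1e-5), upper = log10(pu),
                         map = function(s) 10^s),
           predict = function(theta, times)
             .onecomp_label(theta[1L], theta[1L], curve, times),
           natural = function(theta) list(p = theta[1L], d_star = theta[1L]),
           mean_p = function(theta) theta[1L])
    },
    explicit = {
      N <- as.integer(N)
      stopifnot(N >= 1L)
      pu <- if (is.null(p_upper)) 1 else p_upper
      pn <- c(paste0("p", seq_len(N)),
              if (N > 1L) paste0("alpha", seq_len(N - 1L)))
      list(id = model, N = N, par_names = pn,
           lower = rep(0, 2L * N - 1L),
           # an ascending weight vector forces every free weight below 1/2
           upper = c(rep(pu, N), rep(0.5, N - 1L)),
           search = list(
             lower = c(rep(log10(1e-5), N), rep(1e-3, N - 1L)),
             upper = c(rep(log10(pu), N), rep(0.5, N - 1L)),
             map = function(s) c(10^s[seq_len(N)],
                                 if (N > 1L) s[(N + 1L):(2L * N - 1L)])),
           # support: weights positive, summing to < 1, ordered ascending
           # with the implied last weight
           support = function(theta) {
             if (N == 1L) return(TRUE)
             a <- theta[(N + 1L):(2L * N - 1L)]
             aN <- 1 - sum(a)
             all(a > 0) && aN > 0 && !is.unsorted(c(a, aN))
           },
           predict = function(theta, times) {
             p <- theta[seq_len(N)]
             a <- if (N == 1L) 1 else {
               aa <- theta[(N + 1L):(2L * N - 1L)]
               c(aa, 1 - sum(aa))
             }
             out <- 0
             for (i in seq_len(N)) {
               out <- out + a[i] * .onecomp_label(p[i], p[i], curve, times)
             }
             out
           },
           natural = function(theta) {
             p <- theta[seq_len(N)]
             a <- if (N == 1L) 1 else {
               aa <- theta[(N + 1L):(2L * N - 1L)]
               c(aa, 1 - sum(aa))
             }
             list(p = p, alpha = a)
           },
           mean_p = function(theta) {
             p <- theta[seq_len(N)]
             a <- if (N == 1L) 1 else {
               aa <- theta[(N + 1L):(2L * N - 1L)]
               c(aa, 1 - sum(aa))
             }
             sum(a * p)
           })
    },
    precursor_target = {
      list(id = model, par_names = names(bounds$lower),
           lower = unname(bounds$lower), upper = unname(bounds$upper),
           predict = function(theta, times) .pt_predict(theta, curve, times),
           natural = function(theta) .pt_natural(theta, curve),
           mean_p = function(theta) 10^theta[2L])
    },
    precursor_target_ratio = {
      stopifnot(!is.null(ratio_CE), ratio_CE >= 0)
      keep <- c(1L, 2L, 3L, 4L, 5L, 7L)
      list(id = model, ratio_CE = ratio_CE,
           par_names = names(bounds$lower)[keep],
           lower = unname(bounds$lower[keep]),
           upper = unname(bounds$upper[keep]),
           predict = function(theta, times)
             .pt_predict(theta, curve, times, ratio_fixed = ratio_CE),
           natural = function(theta)
             .pt_natural(theta, curve, ratio_fixed = ratio_CE),
           mean_p = function(theta) 10^theta[2L])
    },
    stop("unknown model id: ", model)
  )
}

# negative log-likelihood closure for a model spec on (times, obs)
.negloglik_fn <- function(spec, times, obs, noise, sd) {
  function(theta) {
    if (!is.null(spec$support) && !spec$support(theta)) return(Inf)
    pred <- spec$predict(theta, times)
    ll <- sum(.loglik_pointwise(pred, obs, noise, sd))
    if (!is.finite(ll)) Inf else -ll
  }
}
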