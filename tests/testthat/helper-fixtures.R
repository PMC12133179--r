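# Shared fixtures: default curves and a few representative parameter sets.

std_curve <- function() body_water_curve()

# a moderately heterogeneous precursor/target parameter set
pt_fixture <- function() {
  precursor_target_params(p_C = 0.005, r = 0.002, k = 3, p_E = 0.001,
                          d_E = 0.03, d_C_star = 0.01, d_E_star = 0.05)
}

# dense grid crossing the labelling/washout boundary
dense_times <- function() sort(unique(c(0, seq(0.5, 100, by = 0.5))))

# classic strongly heterogeneous two-subpopulation benchmark
strong_heterogeneity_params <- function() {
  explicit_heterogeneity_params(p = c(0.72, 0.016), alpha = c(0.1, 0.9))
}

max_abs_diff <- function(a, b) max(abs(a - b))

# quick Bayesian settings used where the posterior is simple
quick_bayes <- function(model, ds, curve, ...) {
  fit_bayes(model, ds, curve, n_iter = 3000L, n_warmup = 1000L,
            n_chains = 2L, ...)
}
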