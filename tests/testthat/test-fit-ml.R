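# Maximum-likelihood fitting: self-consistency, the production-by-division
# interpretation of the one-compartment estimate, and diagnostics.

test_that("one-compartment fit recovers its own noiseless parameters", {
  curve <- std_curve()
  truth <- label_fractions(solve_one_compartment(
    one_compartment_params(0.02, 0.06), curve, 0:100))
  ds <- labelling_dataset(0:100, truth, noise_spec("lognormal", 0.005),
                          model_id = "one_compartment")
  fit <- fit_ml("one_compartment", ds, curve, seed = 1)
  expect_lt(abs(fit$estimates$p - 0.02) / 0.02, 1e-3)
  expect_lt(abs(fit$estimates$d_star - 0.06) / 0.06, 1e-3)
  expect_length(fit$pointwise, 101L)
  # deterministic under seed
  fit2 <- fit_ml("one_compartment", ds, curve, seed = 1)
  expect_identical(fit$theta, fit2$theta)
})

test_that("one-compartment estimate tracks production by division for k >= 1", {
  curve <- std_curve()
  pars <- Filter(function(p) p$k >= 1,
                 sample_precursor_target_params(10, seed = 42))
  errs <- vapply(seq_along(pars), function(i) {
    ds <- generate_optimal_dataset(pars[[i]], curve, seed = 300 + i)
    fit <- fit_ml("one_compartment", ds, curve, seed = 1)
    d <- target_descriptors(pars[[i]])
    abs(percentage_error(fit$mean_p, d$production_by_division))
  }, numeric(1L))
  expect_lt(stats::median(errs), 5)
})

test_that("nested capacity: the cascade model never fits worse than one compartment", {
  curve <- std_curve()
  for (i in 1:3) {
    pr <- sample_precursor_target_params(1, seed = 40 + i)[[1L]]
    ds <- generate_optimal_dataset(pr, curve, seed = 50 + i)
    f1 <- fit_ml("one_compartment", ds, curve, seed = 1)
    f2 <- fit_ml("precursor_target", ds, curve, seed = 1)
    expect_gte(f2$logLik, f1$logLik - 1e-6)
  }
})

test_that("freezing the size ratio at zero decouples the target compartment", {
  curve <- std_curve()
  truth <- label_fractions(solve_one_compartment(
    one_compartment_params(0.001, 0.04), curve, 0:100))
  ds <- labelling_dataset(0:100, truth, noise_spec("lognormal", 0.005),
                          model_id = "one_compartment")
  fit <- fit_ml_with_ratio(ds, ratio_CE = 0, curve, seed = 2)
  # with no influx the cascade collapses: p_E and d_E* recover the truth
  expect_lt(abs(fit$estimates$p_E - 0.001) / 0.001, 0.02)
  expect_lt(abs(fit$estimates$d_E_star - 0.04) / 0.04, 0.02)
})

test_that("collinear cascade fits are flagged, not failed", {
  curve <- std_curve()
  pr <- sample_precursor_target_params(1, seed = 11)[[1L]]
  ds <- generate_optimal_dataset(pr, curve, seed = 2)
  fit <- fit_ml("precursor_target", ds, curve, seed = 1)
  expect_false(fit$diagnostics$failed)
  expect_true(is.finite(fit$logLik))
  expect_type(fit$diagnostics$identifiable, "logical")
})
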