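test_that("optimal design: 101 daily points, exact curve at zero noise", {
  curve <- std_curve()
  pr <- pt_fixture()
  ds <- generate_optimal_dataset(pr, curve, seed = 4)
  expect_length(ds$times, 101L)
  expect_identical(ds$times, 0:100)
  expect_true(all(ds$observations >= 0))
  exact <- generate_optimal_dataset(pr, curve, seed = 4, sigma = 0)
  expect_identical(exact$observations, exact$truth_curve)
})

test_that("optimal-design noise is lognormal with the stated log-sd", {
  curve <- std_curve()
  pr <- pt_fixture()
  resid <- unlist(lapply(1:30, function(i) {
    ds <- generate_optimal_dataset(pr, curve, seed = i)
    log(ds$observations[-1L] / ds$truth_curve[-1L])
  }))
  expect_equal(stats::sd(resid), 0.005, tolerance = 0.05)
  expect_lt(abs(mean(resid)), 0.0005)
})

test_that("realistic design: weekly 15-point grid with curve-scaled Gaussian noise", {
  curve <- std_curve()
  rt <- sample_realistic_target_params(1, seed = 3)[[1L]]
  ds <- generate_realistic_dataset(rt, curve, seed = 8)
  expect_length(ds$times, 15L)
  expect_identical(ds$times, seq(0, 98, by = 7))
  expect_equal(ds$noise$sd_realised, 0.1 * max(ds$truth_curve),
               tolerance = 1e-12)
  exact <- generate_realistic_dataset(rt, curve, seed = 8, noise_frac = 0)
  expect_identical(exact$observations, exact$truth_curve)
  resid <- unlist(lapply(1:40, function(i) {
    d <- generate_realistic_dataset(rt, curve, seed = 100 + i)
    (d$observations - d$truth_curve) / d$noise$sd_realised
  }))
  expect_equal(stats::sd(resid), 1, tolerance = 0.08)
})

test_that("heterogeneity datasets reproduce the mixture curve at zero noise", {
  curve <- std_curve()
  pars <- strong_heterogeneity_params()
  ds <- generate_heterogeneity_dataset(pars, curve, seed = 2, sigma = 0)
  expect_length(ds$times, 15L)
  ref <- label_fractions(solve_explicit_heterogeneity(
    pars, curve, seq(0, 98, by = 7)), "total")
  expect_identical(ds$observations, ref)
})

test_that("datasets round-trip through CSV plus JSON sidecar", {
  curve <- std_curve()
  ds <- generate_heterogeneity_dataset(strong_heterogeneity_params(), curve, seed = 6)
  path <- tempfile(fileext = ".csv")
  write_labelling_dataset(ds, path)
  back <- read_labelling_dataset(path)
  expect_equal(back$times, ds$times)
  expect_equal(back$observations, ds$observations, tolerance = 1e-12)
  expect_identical(back$noise$family, "lognormal")
  expect_equal(back$noise$sd_realised, ds$noise$sd_realised)
  expect_identical(back$model_id, ds$model_id)
  expect_equal(back$truth$p, ds$truth$p)
  unlink(c(path, paste0(path, ".json")))
})
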