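test_that("precursor/target constructor enforces equilibrium and heterogeneity", {
  p <- pt_fixture()
  expect_equal(p$d_C, p$p_C - p$r)
  expect_equal(p$ratio_CE, (p$d_E - p$p_E) / (p$r * 2^p$k))
  expect_error(precursor_target_params(p_C = 0.01, r = 0.02, k = 0,
                                       p_E = 0.001, d_E = 0.002), "r <= p_C")
  expect_error(precursor_target_params(p_C = 0.01, r = 0.005, k = 0,
                                       p_E = 0.001, d_E = 0.002,
                                       d_E_star = 0.001), "d_E_star")
  # r = 0 only admissible in the fully decoupled case d_E = p_E
  expect_error(precursor_target_params(p_C = 0.01, r = 0, k = 0,
                                       p_E = 0.001, d_E = 0.002),
               "undefined")
  dec <- precursor_target_params(p_C = 0.01, r = 0, k = 0,
                                 p_E = 0.001, d_E = 0.001)
  expect_identical(dec$ratio_CE, 0)
})

test_that("explicit heterogeneity weights are validated and stored ascending", {
  pars <- explicit_heterogeneity_params(p = c(0.7, 0.01), alpha = c(0.2, 0.8))
  expect_identical(pars$alpha, c(0.2, 0.8))
  expect_identical(pars$p, c(0.7, 0.01))
  flipped <- explicit_heterogeneity_params(p = c(0.01, 0.7),
                                           alpha = c(0.8, 0.2))
  expect_identical(flipped$p, c(0.7, 0.01))  # reordered with its weight
  expect_error(explicit_heterogeneity_params(p = numeric(0)))
  expect_error(explicit_heterogeneity_params(p = c(0.1, 0.2),
                                             alpha = c(0.3, 0.3)), "sum")
})

test_that("heterogeneous-target constructor derives sizes and rejects bad routing", {
  pars <- realistic_target_params(p_C = 0.005, r = 0.002, k = 2,
                                  d_C_star = 0.01, gamma = 0.3,
                                  p1 = 0.001, d1 = 0.02,
                                  p2 = 0.002, d2 = 0.01)
  expect_equal(pars$ratio_CE1, (0.02 - 0.001) / (0.3 * 0.002 * 4))
  expect_equal(sum(pars$obs_weights), 1)
  expect_equal(pars$p_E_mean,
               sum(pars$obs_weights * c(0.001, 0.002)))
  expect_error(realistic_target_params(p_C = 0.005, r = 0.002, k = 2,
                                       d_C_star = 0.01, gamma = 1.5,
                                       p1 = 0.001, d1 = 0.02,
                                       p2 = 0.002, d2 = 0.01), "gamma")
  # a fed subpopulation must shrink relative to its inflow (d > p)
  expect_error(realistic_target_params(p_C = 0.005, r = 0.002, k = 2,
                                       d_C_star = 0.01, gamma = 0.5,
                                       p1 = 0.02, d1 = 0.001,
                                       p2 = 0.002, d2 = 0.01), "E1")
})

test_that("blood/lymph constructor applies both equilibrium constraints", {
  pars <- blood_lymph_params(p = 0.01, f_recirc = 28)
  expect_identical(pars$d, pars$p)
  expect_equal(pars$g, 28 * 2 / 98)
  expect_error(blood_lymph_params(p = 0.01, f_recirc = 0), "positive")
  expect_error(blood_lymph_params(p = 0.01, f_recirc = -3), "positive")
})
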