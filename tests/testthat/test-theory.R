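# Analytic descriptors of the target compartment and the error formulas
# that relate the one-compartment estimate to proliferation and turnover.

test_that("descriptors obey their defining identities on random draws", {
  pars <- sample_precursor_target_params(25, seed = 99)
  for (p in pars) {
    d <- target_descriptors(p)
    # turnover equals the steady-state outflow d_E
    expect_equal(d$turnover, p$d_E, tolerance = 1e-12)
    # at equilibrium X = (d_E - p_E) / d_E
    expect_equal(d$influx_ratio, (p$d_E - p$p_E) / p$d_E, tolerance = 1e-12)
    expect_true(d$proliferation <= d$production_by_division + 1e-15)
    expect_true(d$production_by_division <= d$turnover + 1e-15)
    # the error formulas re-derive the descriptor gaps exactly
    expect_equal(100 * (d$production_by_division - p$p_E) / p$p_E,
                 proliferation_error_theory(d$influx_ratio, p$k),
                 tolerance = 1e-10)
    expect_equal(100 * (d$turnover - d$production_by_division) / d$turnover,
                 turnover_error_theory(d$influx_ratio, p$k),
                 tolerance = 1e-10)
  }
})

test_that("limits: no influx or no division-linked expansion", {
  dec <- precursor_target_params(p_C = 0.01, r = 0, k = 0, p_E = 0.002,
                                 d_E = 0.002)
  d <- target_descriptors(dec)
  expect_equal(d$turnover, 0.002)
  expect_equal(d$production_by_division, 0.002)
  expect_identical(d$influx_ratio, 0)
  k0 <- precursor_target_params(p_C = 0.01, r = 0.005, k = 0, p_E = 0.002,
                                d_E = 0.004)
  expect_equal(target_descriptors(k0)$production_by_division, 0.002)
  expect_equal(proliferation_error_theory(0.7, 0), 0)
  expect_equal(proliferation_error_theory(0, 5), 0)
  expect_equal(turnover_error_theory(0, 3), 0)
})

test_that("error formulas: worked values and monotonicity", {
  expect_equal(proliferation_error_theory(0.5, 1), 50)
  expect_equal(turnover_error_theory(0.5, 1), 25)
  expect_equal(turnover_error_theory(0.25, 0), 25)
  x <- seq(0, 0.95, by = 0.05)
  for (k in c(0.5, 1, 3, 10)) {
    expect_true(all(diff(proliferation_error_theory(x, k)) >= 0))
    expect_true(all(diff(turnover_error_theory(x, k)) >= 0))
  }
  ks <- seq(0, 12, by = 0.5)
  expect_true(all(diff(proliferation_error_theory(0.4, ks)) >= 0))
  expect_true(all(diff(turnover_error_theory(0.4, ks)) <= 0))
  expect_error(proliferation_error_theory(1, 2), "X")
  expect_error(turnover_error_theory(-0.1, 2), "X")
})

test_that("case classification follows the k and influx-ratio quadrants", {
  expect_identical(classify_case(0.5, 5), "A")
  expect_identical(classify_case(0.01, 3), "B")
  expect_identical(classify_case(0.5, 0), "C")
  expect_identical(classify_case(0.01, 0), "D")
  # threshold is configurable
  expect_identical(classify_case(0.05, 2, threshold = 0.01), "A")
})

test_that("precursor knowledge bounds the turnover/production gap", {
  expect_identical(upstream_bound(0.01, 0), 0)
  pars <- sample_precursor_target_params(20, seed = 7)
  for (p in pars) {
    d <- target_descriptors(p)
    bound <- upstream_bound(p$p_C, p$ratio_CE)
    expect_true(d$turnover - d$production_by_division <= bound + 1e-15)
  }
  # bound attained exactly when every precursor division feeds differentiation
  eq <- precursor_target_params(p_C = 0.004, r = 0.004, k = 1, p_E = 0.001,
                                d_E = 0.02, d_C_star = 0.001)
  d <- target_descriptors(eq)
  expect_equal(d$turnover - d$production_by_division,
               upstream_bound(eq$p_C, eq$ratio_CE), tolerance = 1e-14)
})
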