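test_that("hypercube draws respect every transformed bound and the rejection rule", {
  pars <- sample_precursor_target_params(100, seed = 123)
  for (p in pars) {
    expect_true(p$p_C >= 1e-4 && p$p_C <= 1e-2)
    expect_true(p$p_E >= 1e-4 && p$p_E <= 1e-2)
    expect_true(p$r >= 0.01 * p$p_C - 1e-15 && p$r <= p$p_C + 1e-15)
    expect_true(p$k >= 0 && p$k <= 20)
    expect_true(p$d_C_star >= p$d_C - 1e-15 &&
                  p$d_C_star <= 100 * p$d_C + 1e-12)
    expect_true(p$d_E >= p$p_E - 1e-15 && p$d_E <= 0.07 + 1e-12)
    expect_true(p$d_E_star > p$d_E)   # the kept-sample rule
    expect_true(p$d_E_star <= 0.07 + 1e-12)
  }
})

test_that("k_mode zero pins the divisions-per-differentiation at zero", {
  pars <- sample_precursor_target_params(20, k_mode = "zero", seed = 5)
  expect_true(all(vapply(pars, function(p) p$k, numeric(1L)) == 0))
})

test_that("sampling is reproducible bit-for-bit under a fixed seed", {
  a <- sample_precursor_target_params(30, seed = 77)
  b <- sample_precursor_target_params(30, seed = 77)
  expect_identical(attr(a, "transformed"), attr(b, "transformed"))
  expect_equal(length(a), 30L)
})

test_that("accepted transformed marginals stay uniform over their bounds", {
  # the d_E* > d_E rejection acts on coordinates 6 and 7 only; the
  # unconstrained marginals should pass a KS test against uniform
  th <- attr(sample_precursor_target_params(400, seed = 31), "transformed")
  bounds <- sampling_bounds()
  for (j in c(1L, 2L, 3L, 4L, 5L)) {
    u <- (th[, j] - bounds$lower[j]) / (bounds$upper[j] - bounds$lower[j])
    expect_gt(suppressWarnings(stats::ks.test(u, "punif"))$p.value, 0.01)
  }
})

test_that("the explicit-heterogeneity grid enumerates 125 admissible combinations", {
  grid <- heterogeneity_grid()
  tab <- attr(grid, "grid")
  expect_length(grid, 125L)
  expect_true(all(tab$p1 > tab$p2))
  expect_true(any(tab$p1 == 0.0072 & tab$p2 == 0.0036 & tab$alpha1 == 0.1))
  expect_false(any(tab$p1 == tab$p2))
  # spot-check one entry carries its parameters (sorted by weight)
  i <- which(tab$p1 == 0.72 & tab$p2 == 0.016 & tab$alpha1 == 0.1)[1L]
  expect_equal(sort(grid[[i]]$p), sort(c(0.72, 0.016)))
  expect_equal(sum(grid[[i]]$alpha), 1)
})

test_that("heterogeneous-target draws are valid equilibrium configurations", {
  pars <- sample_realistic_target_params(15, seed = 9)
  for (p in pars) {
    expect_true(p$gamma > 0 && p$gamma < 1)
    expect_true(p$d1 > p$p1 && p$d2 > p$p2)
    expect_true(p$d1 <= 0.07 + 1e-12 && p$d2 <= 0.07 + 1e-12)
    expect_equal(sum(p$obs_weights), 1)
  }
})
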