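# Forward solvers: degenerate limits, qualitative shape, and closed-form /
# numerical-integrator equivalence on randomly sampled parameter sets.

test_that("one-compartment solver: trivial limits and labelling-phase shape", {
  curve <- std_curve()
  times <- dense_times()
  # no production, no label
  z <- label_fractions(solve_one_compartment(one_compartment_params(0, 0.05),
                                             curve, times))
  expect_true(all(z == 0))
  # non-decreasing during labelling, decreasing after the label peak
  f <- label_fractions(solve_one_compartment(
    one_compartment_params(0.01, 0.05), curve, times))
  expect_identical(f[1L], 0)
  expect_true(all(f >= 0))
  expect_true(all(diff(f[times <= 49]) > 0))
  # strictly decreasing once past the (post-labelling) label peak
  pk <- which.max(f)
  expect_true(all(diff(f[seq(pk, length(f))]) <= 0))
  expect_true(all(diff(f[times >= times[pk] + 2]) < 0))
})

test_that("resonant disappearance rate (d* = delta) stays exact", {
  curve <- std_curve()
  times <- dense_times()
  oc <- one_compartment_params(0.01, curve$delta)
  a1 <- label_fractions(solve_one_compartment(oc, curve, times))
  a2 <- label_fractions(solve_one_compartment(oc, curve, times,
                                              method = "ode"))
  expect_lt(max_abs_diff(a1, a2), 1e-8)
})

test_that("precursor/target solver: decoupled and k = 0 limits", {
  curve <- std_curve()
  times <- dense_times()
  # r = 0 with d_E = p_E: target reduces to a one-compartment system
  dec <- precursor_target_params(p_C = 0.005, r = 0, k = 0, p_E = 0.002,
                                 d_E = 0.002, d_E_star = 0.04)
  fE <- label_fractions(solve_precursor_target(dec, curve, times), "E")
  oc <- label_fractions(solve_one_compartment(
    one_compartment_params(0.002, 0.04), curve, times))
  expect_lt(max_abs_diff(fE, oc), 1e-12)
  # k = 0: the clonal-expansion source vanishes; label still enters via F_C
  k0 <- precursor_target_params(p_C = 0.005, r = 0.002, k = 0, p_E = 0.001,
                                d_E = 0.003, d_E_star = 0.05)
  sol <- solve_precursor_target(k0, curve, times)
  fE0 <- label_fractions(sol, "E")
  ode <- label_fractions(solve_precursor_target(k0, curve, times,
                                                method = "ode"), "E")
  expect_lt(max_abs_diff(fE0, ode), 1e-8)
  expect_true(any(fE0 > label_fractions(solve_one_compartment(
    one_compartment_params(0.001, 0.05), curve, times))))
})

test_that("explicit mixture: single and degenerate subpopulations", {
  curve <- std_curve()
  times <- dense_times()
  one <- label_fractions(solve_explicit_heterogeneity(
    explicit_heterogeneity_params(p = 0.02), curve, times), "total")
  oc <- label_fractions(solve_one_compartment(
    one_compartment_params(0.02, 0.02), curve, times))
  expect_lt(max_abs_diff(one, oc), 1e-14)
  # equal rates: the mixture collapses regardless of the weights
  mix <- label_fractions(solve_explicit_heterogeneity(
    explicit_heterogeneity_params(p = c(0.02, 0.02), alpha = c(0.3, 0.7)),
    curve, times), "total")
  expect_lt(max_abs_diff(mix, oc), 1e-14)
})

test_that("heterogeneous-target model reduces to the single-target cascade", {
  curve <- std_curve()
  times <- dense_times()
  # gamma = 1: all differentiating cells enter E1
  rt <- realistic_target_params(p_C = 0.005, r = 0.002, k = 2,
                                d_C_star = 0.01, gamma = 1,
                                p1 = 0.001, d1 = 0.02,
                                p2 = 0.002, d2 = 0.002)
  pt <- precursor_target_params(p_C = 0.005, r = 0.002, k = 2, p_E = 0.001,
                                d_E = 0.02, d_C_star = 0.01, d_E_star = 0.02)
  a <- label_fractions(solve_realistic_target(rt, curve, times), "E")
  b <- label_fractions(solve_precursor_target(pt, curve, times), "E")
  expect_lt(max_abs_diff(a, b), 1e-12)
  # identical subpopulations with routing proportional to size: homogeneous
  rt2 <- realistic_target_params(p_C = 0.005, r = 0.002, k = 2,
                                 d_C_star = 0.01, gamma = 0.5,
                                 p1 = 0.001, d1 = 0.02,
                                 p2 = 0.001, d2 = 0.02)
  a2 <- label_fractions(solve_realistic_target(rt2, curve, times), "E")
  expect_lt(max_abs_diff(a2, b), 1e-12)
})

test_that("blood/lymph solver: exchange limits and source ordering", {
  curve <- std_curve()
  times <- dense_times()[-1L]
  # fast exchange: blood tracks tissue pointwise
  fast <- solve_blood_lymph(blood_lymph_params(0.01, 1e8), curve, times)
  expect_lt(max_abs_diff(label_fractions(fast, "A"),
                         label_fractions(fast, "B")), 1e-6)
  # label originates in tissue: F_B <= F_A throughout labelling
  mid <- solve_blood_lymph(blood_lymph_params(0.01, 28), curve, times)
  lab <- times <= 49
  expect_true(all(label_fractions(mid, "B")[lab] <=
                    label_fractions(mid, "A")[lab] + 1e-12))
  # the equilibrium constraint is the algebraic identity g * A/B = f
  pars <- blood_lymph_params(0.01, 28, ratio_BA = 2 / 98)
  expect_equal(pars$g / pars$ratio_BA, pars$f_recirc, tolerance = 1e-12)
})

test_that("closed forms agree with the adaptive ODE integrator across random draws", {
  curve <- std_curve()
  times <- sort(unique(c(0, seq(1, 100, by = 3), 49)))
  set.seed(42)
  worst <- 0
  for (rep in 1:8) {
    pt <- sample_precursor_target_params(1, seed = 500 + rep)[[1L]]
    s1 <- solve_precursor_target(pt, curve, times)
    s2 <- solve_precursor_target(pt, curve, times, method = "ode")
    worst <- max(worst,
                 max_abs_diff(label_fractions(s1, "C"), label_fractions(s2, "C")),
                 max_abs_diff(label_fractions(s1, "E"), label_fractions(s2, "E")))
    eh <- explicit_heterogeneity_params(p = 10^stats::runif(2, -3, 0),
                                        alpha = c(a1 <- stats::runif(1, 0.05, 0.5), 1 - a1))
    h1 <- label_fractions(solve_explicit_heterogeneity(eh, curve, times), "total")
    h2 <- label_fractions(solve_explicit_heterogeneity(eh, curve, times,
                                                       method = "ode"), "total")
    worst <- max(worst, max_abs_diff(h1, h2))
    bl <- blood_lymph_params(10^stats::runif(1, -4, -1), 10^stats::runif(1, -2, 3))
    b1 <- solve_blood_lymph(bl, curve, times)
    b2 <- solve_blood_lymph(bl, curve, times, method = "ode")
    worst <- max(worst, max_abs_diff(label_fractions(b1, "B"),
                                     label_fractions(b2, "B")))
    rt <- sample_realistic_target_params(1, seed = 700 + rep)[[1L]]
    r1 <- label_fractions(solve_realistic_target(rt, curve, times), "E")
    r2 <- label_fractions(solve_realistic_target(rt, curve, times,
                                                 method = "ode"), "E")
    worst <- max(worst, max_abs_diff(r1, r2))
  }
  expect_lt(worst, 1e-8)
})

test_that("label curves serialise to the standard CSV layout", {
  curve <- std_curve()
  lc <- solve_precursor_target(pt_fixture(), curve, c(0, 7, 14))
  path <- tempfile(fileext = ".csv")
  write_label_curve(lc, path)
  back <- utils::read.csv(path)
  expect_identical(names(back),
                   c("time_days", "compartment", "fraction_labelled"))
  expect_equal(nrow(back), 6L)
  expect_equal(back$fraction_labelled,
               lc$fraction_labelled, tolerance = 1e-12)
  unlink(path)
})
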