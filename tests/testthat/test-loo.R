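# PSIS-LOO estimates and the decision rule, checked against synthetic
# likelihood matrices and a brute-force exact leave-one-out oracle.

# minimal fit-like object carrying a pointwise log-likelihood matrix
fake_fit <- function(ll) {
  structure(list(model_id = "synthetic", loglik_draws = ll,
                 n_obs = ncol(ll)),
            class = "fit_result")
}

test_that("a model compared with itself is an exact tie", {
  set.seed(1)
  ll <- matrix(stats::rnorm(2000 * 10, -1, 0.2), 2000, 10)
  cmp <- compare_elpd(fake_fit(ll), fake_fit(ll))
  expect_identical(cmp$delta, 0)
  expect_identical(cmp$decision, "tie")
})

test_that("pointwise dominance yields a positive, supported difference", {
  set.seed(2)
  ll <- matrix(stats::rnorm(2000 * 12, -1, 0.1), 2000, 12)
  better <- ll + 1   # strictly higher predictive density everywhere
  cmp <- compare_elpd(fake_fit(better), fake_fit(ll))
  expect_gt(cmp$delta, 0)
  expect_identical(cmp$decision, "select_i")
})

test_that("the tie rule takes precedence when the SE swamps the difference", {
  set.seed(3)
  base <- matrix(stats::rnorm(500 * 8, -1, 0.1), 500, 8)
  # large alternating pointwise differences, near-zero net difference
  shift <- rep(c(2, -2), length.out = 8)
  other <- sweep(base, 2L, shift, `+`)
  cmp <- compare_elpd(fake_fit(other), fake_fit(base))
  expect_gt(cmp$se, abs(cmp$delta))
  expect_identical(cmp$decision, "tie")
  # stringency scales the support threshold
  set.seed(4)
  ll <- matrix(stats::rnorm(1000 * 10, -1, 0.1), 1000, 10)
  near <- ll + 0.05 + matrix(stats::rnorm(1000 * 10, 0, 0.05), 1000, 10)
  c1 <- compare_elpd(fake_fit(near), fake_fit(ll), stringency = 1)
  c2 <- compare_elpd(fake_fit(near), fake_fit(ll), stringency = 1e6)
  expect_identical(c2$decision, "tie")
  expect_true(c1$delta == c2$delta)
})

test_that("missing pointwise likelihood draws raise an error", {
  f <- structure(list(model_id = "ml", loglik_draws = NULL),
                 class = "fit_result")
  expect_error(elpd_loo(f), "draws")
})

test_that("PSIS-LOO agrees with brute-force exact leave-one-out refits", {
  curve <- std_curve()
  pars <- explicit_heterogeneity_params(p = c(0.2, 0.01),
                                        alpha = c(0.3, 0.7))
  ds <- generate_heterogeneity_dataset(pars, curve, seed = 17)
  fit <- fit_bayes("implicit", ds, curve, seed = 5,
                   n_iter = 4000, n_warmup = 1500)
  psis <- elpd_loo(fit)
  # exact LOO: refit without observation i, evaluate its predictive density
  exact <- vapply(seq_along(ds$times)[-1L], function(i) {
    sub <- labelling_dataset(ds$times[-i], ds$observations[-i], ds$noise,
                             model_id = ds$model_id)
    f_i <- fit_bayes("implicit", sub, curve, seed = 5,
                     n_iter = 4000, n_warmup = 1500)
    sd <- isokin:::.known_sd(ds$noise, ds$observations)
    spec <- isokin:::.model_spec("implicit", curve)
    lls <- apply(f_i$draws, 1L, function(th) {
      isokin:::.loglik_pointwise(spec$predict(th, ds$times[i]),
                                 ds$observations[i], ds$noise, sd)
    })
    isokin:::.logsumexp(lls) - log(length(lls))
  }, numeric(1L))
  expect_lt(abs(sum(exact) - psis$elpd), 2 * psis$se + 0.5)
})
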