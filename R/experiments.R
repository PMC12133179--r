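# End-to-end simulation experiments: closed-population bias (upstream
# compartment), kinetic heterogeneity, and prior sensitivity, plus the
# paired significance tests used to summarise them.

#' Experiment configuration
#'
#' Bundles replicate counts, seeds and fitting effort for the experiment
#' runners, and can be written to a manifest for bit-identical re-runs.
#'
#' @param experiment Identifier (free text).
#' @param n_replicates Number of simulated datasets.
#' @param seed Master seed; per-dataset seeds are derived as
#'   `seed + replicate index`.
#' @param n_boot Bootstrap resamples per fit (0 disables bootstrap
#'   coverage); reduced-scale default 100, full scale 500.
#' @param n_starts Global start points per maximum-likelihood fit.
#' @param n_iter,n_warmup,n_chains Bayesian sampling effort.
#' @param output_dir Optional directory for CSV/JSON outputs.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = "experiment", n_replicates = 30L,
                              seed = 1L, n_boot = 100L, n_starts = 50L,
                              n_iter = 4000L, n_warmup = 1500L,
                              n_chains = 2L, output_dir = NULL) {
  stopifnot(n_replicates >= 1L, seed == round(seed))
  structure(
    list(experiment = experiment, n_replicates = as.integer(n_replicates),
         seed = as.integer(seed), n_boot = as.integer(n_boot),
         n_starts = as.integer(n_starts), n_iter = as.integer(n_iter),
         n_warmup = as.integer(n_warmup), n_chains = as.integer(n_chains),
         output_dir = output_dir),
    class = "experiment_config")
}

#' Write an experiment manifest
#'
#' Records the full configuration, package version and an MD5 digest of
#' the serialised configuration, sufficient to re-run the experiment
#' bit-identically.
#'
#' @param config An [experiment_config()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(config)[order(names(unclass(config)))], tmp)
  manifest <- list(
    config = unclass(config),
    config_md5 = unname(tools::md5sum(tmp)),
    package_version = as.character(utils::packageVersion("isokin")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Closed-population bias experiment
#'
#' Samples precursor/target parameter sets, simulates target-compartment
#' datasets (optimal dense/low-noise design, or the realistic weekly
#' design with an explicitly heterogeneous target), fits the
#' one-compartment model, the precursor/target model and the
#' precursor/target model with the size ratio fixed at truth, and
#' summarises percentage errors of the estimated proliferation rate
#' against the true proliferation, turnover and production by division
#' (plus bootstrap coverage when `n_boot > 0`).
#'
#' @param config An [experiment_config()].
#' @param data `"optimal"` or `"realistic"` design.
#' @param curve Body-water curve (defaults to the standard enrichment
#'   curve).
#' @param k_mode Passed to the parameter sampler (`"sampled"` or
#'   `"zero"`).
#' @return A list with `results` (one row per dataset and model:
#'   errors, coverage flags, CI width, influx ratio and k) and `summary`
#'   (median |error| per model plus paired Wilcoxon comparisons).
#' @export
run_upstream_experiment <- function(config = experiment_config(),
                                    data = c("optimal", "realistic"),
                                    curve = body_water_curve(),
                                    k_mode = "sampled") {
  data <- match.arg(data)
  n <- config$n_replicates
  if (data == "optimal") {
    params <- sample_precursor_target_params(n, k_mode = k_mode,
                                             seed = config$seed)
  } else {
    params <- sample_realistic_target_params(n, seed = config$seed)
  }
  models <- c("one_compartment", "precursor_target", "precursor_target_ratio")
  rows <- list()
  failures <- 0L
  for (i in seq_len(n)) {
    pr <- params[[i]]
    ds_seed <- config$seed + i
    if (data == "optimal") {
      ds <- generate_optimal_dataset(pr, curve, seed = ds_seed)
      p_true <- pr$p_E
      ratio_true <- pr$ratio_CE
      desc <- target_descriptors(pr)
    } else {
      ds <- generate_realistic_dataset(pr, curve, seed = ds_seed)
      p_true <- pr$p_E_mean
      ratio_true <- pr$ratio_CE
      desc <- NULL
    }
    for (m in models) {
      fit <- tryCatch(
        fit_ml(m, ds, curve, n_starts = config$n_starts, seed = ds_seed,
               ratio_CE = if (m == "precursor_target_ratio") ratio_true),
        error = function(e) NULL)
      if (is.null(fit) || fit$diagnostics$failed) {
        failures <- failures + 1L
        next
      }
      covered <- NA
      ci_width <- NA_real_
      if (config$n_boot > 0L) {
        bs <- bootstrap_ci(m, ds, curve, n_boot = config$n_boot,
                           seed = ds_seed, fit = fit,
                           ratio_CE = if (m == "precursor_target_ratio") ratio_true)
        ci <- bs$ci["mean_p", ]
        covered <- is.finite(ci[1L]) && p_true >= ci[1L] && p_true <= ci[2L]
        ci_width <- unname(ci[2L] - ci[1L])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = i, model = m, p_hat = fit$mean_p,
        error_p = percentage_error(fit$mean_p, p_true),
        error_T = if (!is.null(desc))
          percentage_error(fit$mean_p, desc$turnover) else NA_real_,
        error_P = if (!is.null(desc))
          percentage_error(fit$mean_p, desc$production_by_division)
          else NA_real_,
        influx_ratio = if (!is.null(desc)) desc$influx_ratio else NA_real_,
        k = if (data == "optimal") pr$k else pr$k,
        covered = covered, ci_width = ci_width,
        identifiable = fit$diagnostics$identifiable)
    }
  }
  results <- do.call(rbind, rows)
  abs_err <- function(m) {
    x <- results[results$model == m, ]
    x <- x[order(x$dataset), ]
    stats::setNames(abs(x$error_p), x$dataset)
  }
  e1 <- abs_err("one_compartment")
  e2 <- abs_err("precursor_target")
  e3 <- abs_err("precursor_target_ratio")
  common <- Reduce(intersect, list(names(e1), names(e2), names(e3)))
  summary <- list(
    median_abs_error = c(
      one_compartment = stats::median(e1[common]),
      precursor_target = stats::median(e2[common]),
      precursor_target_ratio = stats::median(e3[common])),
    wilcoxon_onecomp_vs_pt =
      wilcoxon_signed_rank(e1[common], e2[common]),
    wilcoxon_ratio_vs_pt =
      wilcoxon_signed_rank(e3[common], e2[common]),
    n_failed_fits = failures)
  if (config$n_boot > 0L) {
    summary$coverage <- vapply(models, function(m) {
      x <- results[results$model == m & !is.na(results$covered), ]
      mean(x$covered)
    }, numeric(1L))
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results,
                     file.path(config$output_dir, "upstream_results.csv"),
                     row.names = FALSE)
    write_manifest(config, file.path(config$output_dir, "manifest.json"))
  }
  list(results = results, summary = summary, config = config)
}

#' Kinetic-heterogeneity model-comparison experiment
#'
#' For each scenario of the explicit two-subpopulation grid (optionally a
#' subset), simulates a weekly labelling dataset and fits the homogeneous,
#' implicit and explicit two-subpopulation models by posterior sampling
#' (optionally also running sequential model selection), recording the
#' percentage error, credible-interval width and coverage of the mean
#' proliferation rate.
#'
#' @param config An [experiment_config()].
#' @param grid_subset Indices into [heterogeneity_grid()] (default: all
#'   125 scenarios).
#' @param curve Body-water curve; the grid scenarios use the standard
#'   enrichment parameters.
#' @param models Which of `"homogeneous"`, `"implicit"`, `"explicit"` to
#'   fit.
#' @param selection Also run [sequential_selection()] per dataset.
#' @param priors Shared [prior_spec()].
#' @return A list with `results` (one row per scenario and model),
#'   `summary` (medians overall and stratified by `p1 <= 10 p2` versus
#'   `p1 > 10 p2` and by `alpha1`) and the configuration.
#' @export
run_heterogeneity_experiment <- function(config = experiment_config(),
                                         grid_subset = NULL,
                                         curve = body_water_curve(),
                                         models = c("homogeneous",
                                                    "implicit", "explicit"),
                                         selection = FALSE,
                                         priors = prior_spec()) {
  grid <- heterogeneity_grid()
  tab <- attr(grid, "grid")
  idx <- if (is.null(grid_subset)) seq_along(grid) else grid_subset
  rows <- list()
  for (ii in seq_along(idx)) {
    g <- idx[ii]
    pars <- grid[[g]]
    truth <- sum(pars$alpha * pars$p)
    ds <- generate_heterogeneity_dataset(pars, curve,
                                         seed = config$seed + g)
    for (m in models) {
      fit <- fit_bayes(m, ds, curve, priors = priors,
                       n_iter = config$n_iter, n_warmup = config$n_warmup,
                       n_chains = config$n_chains, seed = config$seed + g,
                       N = 2L)
      ci <- fit$interval["mean_p", ]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = g, p1 = tab$p1[g], p2 = tab$p2[g], alpha1 = tab$alpha1[g],
        model = m, mean_p_true = truth, mean_p_hat = fit$mean_p,
        error = percentage_error(fit$mean_p, truth),
        ci_lower = unname(ci["lower"]), ci_upper = unname(ci["upper"]),
        ci_width = unname(ci["upper"] - ci["lower"]),
        covered = truth >= ci["lower"] && truth <= ci["upper"],
        rhat_max = max(fit$diagnostics$rhat))
    }
    if (selection) {
      sel <- sequential_selection(ds, curve, priors = priors,
                                  n_iter = config$n_iter,
                                  n_warmup = config$n_warmup,
                                  n_chains = config$n_chains,
                                  seed = config$seed + g)
      fit <- sel$fit
      ci <- fit$interval["mean_p", ]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = g, p1 = tab$p1[g], p2 = tab$p2[g], alpha1 = tab$alpha1[g],
        model = "model_selection", mean_p_true = truth,
        mean_p_hat = fit$mean_p,
        error = percentage_error(fit$mean_p, truth),
        ci_lower = unname(ci["lower"]), ci_upper = unname(ci["upper"]),
        ci_width = unname(ci["upper"] - ci["lower"]),
        covered = truth >= ci["lower"] && truth <= ci["upper"],
        rhat_max = max(fit$diagnostics$rhat))
    }
  }
  results <- do.call(rbind, rows)
  results$stratum <- ifelse(results$p1 <= 10 * results$p2,
                            "p1<=10p2", "p1>10p2")
  med <- function(df) stats::aggregate(
    cbind(abs_error = abs(df$error), ci_width = df$ci_width),
    by = list(model = df$model), FUN = stats::median)
  summary <- list(
    overall = med(results),
    by_stratum = stats::aggregate(
      cbind(abs_error = abs(results$error)),
      by = list(model = results$model, stratum = results$stratum),
      FUN = stats::median),
    by_stratum_alpha = stats::aggregate(
      cbind(abs_error = abs(results$error)),
      by = list(model = results$model, stratum = results$stratum,
                alpha1 = results$alpha1),
      FUN = stats::median),
    coverage = stats::aggregate(
      cbind(coverage = results$covered),
      by = list(model = results$model), FUN = mean))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results,
                     file.path(config$output_dir, "heterogeneity_results.csv"),
                     row.names = FALSE)
    write_manifest(config, file.path(config$output_dir, "manifest.json"))
  }
  list(results = results, summary = summary, config = config)
}

#' Prior-sensitivity experiment
#'
#' Fits the implicit and explicit two-subpopulation models to a dataset
#' generated from a strongly heterogeneous mixture (by default the
#' classic benchmark: p1 = 0.72, p2 = 0.016, alpha1 = 0.1, perfect
#' labelling) under uniform priors of different widths, and reports how
#' point estimates and credible-interval widths of the mean proliferation
#' rate respond.
#'
#' @param config An [experiment_config()].
#' @param params Generating [explicit_heterogeneity_params()].
#' @param curve Labelling curve; defaults to [perfect_label_curve()].
#' @param p_uppers Prior upper bounds to sweep.
#' @param models Models to fit.
#' @return A list with `results` (model x prior width: point estimate, CI
#'   bounds and width) and derived `ci_width_ratio` (explicit model, widest
#'   versus narrowest prior) and `implicit_shift_pct` (relative movement
#'   of the implicit point estimate).
#' @export
run_prior_sensitivity <- function(config = experiment_config(),
                                  params = explicit_heterogeneity_params(
                                    p = c(0.72, 0.016),
                                    alpha = c(0.1, 0.9)),
                                  curve = perfect_label_curve(),
                                  p_uppers = c(1, 10),
                                  models = c("implicit", "explicit")) {
  ds <- generate_heterogeneity_dataset(params, curve, seed = config$seed)
  rows <- list()
  for (m in models) {
    for (pu in p_uppers) {
      fit <- fit_bayes(m, ds, curve,
                       priors = prior_spec(p_upper = pu, d_star_upper = pu),
                       n_iter = config$n_iter, n_warmup = config$n_warmup,
                       n_chains = config$n_chains,
                       seed = config$seed, N = 2L)
      ci <- fit$interval["mean_p", ]
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, p_upper = pu, mean_p_hat = fit$mean_p,
        ci_lower = unname(ci["lower"]), ci_upper = unname(ci["upper"]),
        ci_width = unname(ci["upper"] - ci["lower"]),
        rhat_max = max(fit$diagnostics$rhat))
    }
  }
  results <- do.call(rbind, rows)
  wid <- function(m, pu) results$ci_width[results$model == m &
                                            results$p_upper == pu]
  pt <- function(m, pu) results$mean_p_hat[results$model == m &
                                             results$p_upper == pu]
  out <- list(results = results, config = config,
              truth = sum(params$alpha * params$p))
  if ("explicit" %in% models && length(p_uppers) >= 2L) {
    out$ci_width_ratio <- wid("explicit", max(p_uppers)) /
      wid("explicit", min(p_uppers))
  }
  if ("implicit" %in% models && length(p_uppers) >= 2L) {
    out$implicit_shift_pct <- 100 * abs(pt("implicit", max(p_uppers)) -
                                          pt("implicit", min(p_uppers))) /
      pt("implicit", min(p_uppers))
  }
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired test on matched error vectors. Ties at zero
#' difference are dropped (the degenerate all-zero case is flagged and
#' returns p = 1).
#'
#' @param a,b Paired numeric vectors of equal length (>= 6 informative
#'   pairs recommended).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List with `p_value`, `statistic`, `n_effective`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(a, b, alternative = "two.sided") {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b))
  d <- a - b
  n_eff <- sum(d != 0)
  if (n_eff == 0L) {
    return(list(p_value = 1, statistic = NA_real_, n_effective = 0L,
                degenerate = TRUE))
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                            alternative = alternative))
  list(p_value = ht$p.value, statistic = unname(ht$statistic),
       n_effective = n_eff, degenerate = FALSE)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test via the hypergeometric distribution.
#'
#' @param counts 2x2 matrix of non-negative integer counts with no empty
#'   margin.
#' @return List with `p_value` and `odds_ratio`.
#' @export
fishers_exact <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2L, 2L)), all(counts >= 0),
            all(counts == round(counts)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("fishers_exact: table has an empty margin")
  }
  ht <- stats::fisher.test(counts)
  list(p_value = ht$p.value, odds_ratio = unname(ht$estimate))
}
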