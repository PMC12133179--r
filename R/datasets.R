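# Simulated labelling datasets: truth curves plus measurement noise, with
# CSV + JSON-sidecar serialisation.

#' Measurement-noise specification
#'
#' @param family `"lognormal"` (each observation is lognormal with
#'   log-mean `log(truth)` and log-sd `sd`) or `"gaussian"` (additive
#'   normal noise).
#' @param sd Noise scale. For `reference = "absolute"` it is used as is;
#'   for `"fraction_of_max"` the actual standard deviation is
#'   `sd * max(truth curve)` of the dataset it is applied to.
#' @param reference How `sd` is interpreted.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(family = c("lognormal", "gaussian"), sd,
                       reference = c("absolute", "fraction_of_max")) {
  family <- match.arg(family)
  reference <- match.arg(reference)
  stopifnot(is.numeric(sd), length(sd) == 1L, sd >= 0)
  structure(list(family = family, sd = sd, reference = reference),
            class = "noise_spec")
}

# realised standard deviation for a given truth curve
.noise_sd <- function(noise, truth) {
  if (noise$reference == "fraction_of_max") noise$sd * max(truth) else noise$sd
}

#' Labelling dataset
#'
#' Bundles observation times, measured labelled fractions, the noise
#' specification, the generating truth (parameters, model id and noiseless
#' curve) and the seed used.
#'
#' @param times Observation times, days (strictly increasing, >= 0).
#' @param observations Measured labelled fractions (same length as times).
#' @param noise A [noise_spec()].
#' @param truth Generating parameter object (or NULL for real data).
#' @param model_id Identifier of the generating model.
#' @param truth_curve Noiseless labelled fractions at `times` (or NULL).
#' @param seed Seed used to generate the noise (or NULL).
#' @return Object of class `labelling_dataset`.
#' @export
labelling_dataset <- function(times, observations, noise, truth = NULL,
                              model_id = NA_character_, truth_curve = NULL,
                              seed = NULL) {
  .check_times(times)
  stopifnot(length(observations) == length(times), is.numeric(observations),
            all(is.finite(observations)), inherits(noise, "noise_spec"))
  if (noise$family == "lognormal" && noise$sd > 0 &&
      any(observations < 0)) {
    stop("lognormal observations must be non-negative")
  }
  structure(
    list(times = times, observations = observations, noise = noise,
         truth = truth, model_id = model_id, truth_curve = truth_curve,
         seed = seed),
    class = "labelling_dataset"
  )
}

#' @export
print.labelling_dataset <- function(x, ...) {
  cat(sprintf("<labelling dataset: %d points over [%g, %g] d, %s noise (sd %g), model %s>\n",
              length(x$times), min(x$times), max(x$times),
              x$noise$family, x$noise$sd, x$model_id))
  invisible(x)
}

.apply_noise <- function(truth, noise, seed) {
  if (!is.null(seed)) set.seed(seed)
  if (noise$sd == 0) return(truth)
  sd <- .noise_sd(noise, truth)
  if (noise$family == "lognormal") {
    # mu = log(truth); a zero truth value (t = 0) stays exactly zero
    obs <- truth
    pos <- truth > 0
    obs[pos] <- truth[pos] * exp(stats::rnorm(sum(pos), 0, sd))
    obs
  } else {
    truth + stats::rnorm(length(truth), 0, sd)
  }
}

#' Generate an optimal-design dataset from the precursor/target model
#'
#' Dense daily sampling (days 0-100, 101 points) of the target-compartment
#' labelled fraction with small lognormal noise (log-sd 0.005 by default):
#' the idealised design used to isolate the effect of an unsampled
#' upstream compartment from the effect of measurement error.
#'
#' @param params A [precursor_target_params()].
#' @param curve A [body_water_curve()].
#' @param seed Integer seed for the noise draw.
#' @param sigma Lognormal log-sd; 0 returns the exact model curve.
#' @param times Sampling days.
#' @return A [labelling_dataset()] with `model_id = "precursor_target"`.
#' @export
generate_optimal_dataset <- function(params, curve, seed = NULL,
                                     sigma = 0.005, times = 0:100) {
  truth <- label_fractions(
    solve_precursor_target(params, curve, times, heterogeneous = TRUE), "E")
  noise <- noise_spec("lognormal", sigma, "absolute")
  noise$sd_realised <- .noise_sd(noise, truth)
  labelling_dataset(times, .apply_noise(truth, noise, seed), noise,
                    truth = params, model_id = "precursor_target",
                    truth_curve = truth, seed = seed)
}

#' Generate a realistic-design dataset from the heterogeneous-target model
#'
#' Weekly sampling (days 0, 7, ..., 98: 15 points over the 100-day
#' experiment) of the observed target label from the two-subpopulation
#' target model, with additive Gaussian noise of standard deviation
#' `noise_frac` times the maximum of that dataset's true curve.
#'
#' @param params A [realistic_target_params()].
#' @inheritParams generate_optimal_dataset
#' @param noise_frac Noise sd as a fraction of the curve maximum; 0 returns
#'   the exact model curve.
#' @return A [labelling_dataset()] with `model_id = "realistic_target"`.
#' @export
generate_realistic_dataset <- function(params, curve, seed = NULL,
                                       noise_frac = 0.1,
                                       times = seq(0, 98, by = 7)) {
  truth <- label_fractions(
    solve_realistic_target(params, curve, times), "E")
  noise <- noise_spec("gaussian", noise_frac, "fraction_of_max")
  noise$sd_realised <- .noise_sd(noise, truth)
  labelling_dataset(times, .apply_noise(truth, noise, seed), noise,
                    truth = params, model_id = "realistic_target",
                    truth_curve = truth, seed = seed)
}

#' Generate a dataset from the explicit kinetic heterogeneity model
#'
#' Weekly sampling (days 0, 7, ..., 98) of the total labelled fraction of
#' an `N`-subpopulation mixture with lognormal noise (log-sd 0.005 by
#' default).
#'
#' @param params An [explicit_heterogeneity_params()].
#' @inheritParams generate_optimal_dataset
#' @return A [labelling_dataset()] with `model_id = "explicit_heterogeneity"`.
#' @export
generate_heterogeneity_dataset <- function(params, curve, seed = NULL,
                                           sigma = 0.005,
                                           times = seq(0, 98, by = 7)) {
  truth <- label_fractions(
    solve_explicit_heterogeneity(params, curve, times), "total")
  noise <- noise_spec("lognormal", sigma, "absolute")
  noise$sd_realised <- .noise_sd(noise, truth)
  labelling_dataset(times, .apply_noise(truth, noise, seed), noise,
                    truth = params, model_id = "explicit_heterogeneity",
                    truth_curve = truth, seed = seed)
}

#' Write a labelling dataset to CSV with a JSON sidecar
#'
#' The CSV holds `time_days, fraction_labelled`; the sidecar
#' (`<path>.json`) records the noise specification, the generating
#' parameters, the model id and the seed, so the dataset can be audited and
#' regenerated.
#'
#' @param ds A [labelling_dataset()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_labelling_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "labelling_dataset"))
  utils::write.csv(
    data.frame(time_days = ds$times, fraction_labelled = ds$observations),
    path, row.names = FALSE)
  side <- list(
    model_id = ds$model_id,
    noise = unclass(ds$noise),
    seed = ds$seed,
    truth = if (!is.null(ds$truth)) unclass(ds$truth) else NULL,
    truth_curve = ds$truth_curve
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a labelling dataset written by [write_labelling_dataset()]
#'
#' @param path CSV path (the `<path>.json` sidecar must sit alongside).
#' @return A [labelling_dataset()]. The truth parameters are returned as a
#'   plain list (class information is not preserved through JSON).
#' @export
read_labelling_dataset <- function(path) {
  tab <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  noise <- noise_spec(side$noise$family, side$noise$sd, side$noise$reference)
  if (!is.null(side$noise$sd_realised)) noise$sd_realised <- side$noise$sd_realised
  labelling_dataset(tab$time_days, tab$fraction_labelled, noise,
                    truth = side$truth, model_id = side$model_id,
                    truth_curve = side$truth_curve, seed = side$seed)
}
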