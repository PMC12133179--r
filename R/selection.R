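# Sequential complexity-growing model selection over a ladder of
# explicit kinetic heterogeneity models.

#' Sequential selection over a ladder of heterogeneity models
#'
#' Starts from the two simplest models in the ladder and compares them by
#' [compare_elpd()]. While the more complex model is supported, the next
#' model is added and the comparison repeated; as soon as the most complex
#' model under consideration is no longer favoured (tie or worse), the
#' previously supported model is selected. Where there is insufficient
#' evidence for the more complex model, the simpler one wins.
#'
#' The default ladder is the homogeneous model (a single subpopulation)
#' followed by explicit mixtures with 2, 3 and 4 subpopulations.
#'
#' @param dataset A [labelling_dataset()].
#' @param curve The [body_water_curve()] the data were generated under.
#' @param ladder Integer vector of subpopulation counts, increasing;
#'   1 denotes the homogeneous model.
#' @param priors A [prior_spec()] shared by all fits.
#' @param stringency Multiplier on the standard error in the support rule.
#' @inheritParams fit_bayes
#' @return A list of class `selection_result`: `selected` (subpopulation
#'   count), `fit` (the selected model's `fit_result`), `trace` (data
#'   frame: comparison per step with elpd, se, delta and decision) and
#'   `fits` (all fitted models, named by ladder position).
#' @export
sequential_selection <- function(dataset, curve, ladder = c(1L, 2L, 3L, 4L),
                                 priors = prior_spec(), stringency = 1,
                                 n_iter = 6000L, n_warmup = 2000L,
                                 n_chains = 2L, seed = 1L) {
  stopifnot(length(ladder) >= 1L, all(ladder >= 1L),
            !is.unsorted(ladder, strictly = TRUE))
  fit_one <- function(N, s) {
    if (N == 1L) {
      fit_bayes("homogeneous", dataset, curve, priors = priors,
                n_iter = n_iter, n_warmup = n_warmup, n_chains = n_chains,
                seed = s)
    } else {
      fit_bayes("explicit", dataset, curve, priors = priors, N = N,
                n_iter = n_iter, n_warmup = n_warmup, n_chains = n_chains,
                seed = s)
    }
  }
  fits <- list()
  loos <- list()
  key <- function(N) paste0("N", N)
  fits[[key(ladder[1L])]] <- fit_one(ladder[1L], seed)
  loos[[key(ladder[1L])]] <- elpd_loo(fits[[key(ladder[1L])]])
  selected <- ladder[1L]
  trace <- data.frame()
  if (length(ladder) > 1L) {
    for (j in 2L:length(ladder)) {
      N <- ladder[j]
      fits[[key(N)]] <- fit_one(N, seed + j - 1L)
      loos[[key(N)]] <- elpd_loo(fits[[key(N)]])
      cmp <- compare_elpd(loos[[key(N)]], loos[[key(selected)]],
                          stringency = stringency)
      trace <- rbind(trace, data.frame(
        candidate = N, incumbent = selected,
        elpd_candidate = loos[[key(N)]]$elpd,
        elpd_incumbent = loos[[key(selected)]]$elpd,
        delta = cmp$delta, se = cmp$se, decision = cmp$decision))
      if (cmp$decision == "select_i") {
        selected <- N
      } else {
        break
      }
    }
  }
  structure(
    list(selected = selected, fit = fits[[key(selected)]],
         trace = trace, fits = fits),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<sequential selection: %s model selected>\n",
              if (x$selected == 1L) "homogeneous"
              else paste0(x$selected, "-subpopulation explicit")))
  if (nrow(x$trace)) print(x$trace, row.names = FALSE)
  invisible(x)
}
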