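#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(S - k - 1)`, with the number of species
#' `S` as the sample size.  Undefined (returns `NA` with a warning in the
#' selection functions) when `S - k - 1 <= 0`.
#'
#' @param logL Maximised log-likelihood.
#' @param k Number of estimated parameters.
#' @param S Sample size (species count).
#' @return The AICc value.
#' @examples
#' aicc(0, 1, 7)  # 2 + 4/5 = 2.8
#' @export
aicc <- function(logL, k, S) {
  if (S - k - 1 <= 0) return(NA_real_)
  -2 * logL + 2 * k + 2 * k * (k + 1) / (S - k - 1)
}

#' Select among fitted SAD models by AICc
#'
#' Ranks a set of fitted models by AICc and marks the best model and the
#' equal-support set (models whose AICc lies within `delta_support` of the
#' minimum).
#'
#' @param fits Named list of fitted model objects (each with `logL` and
#'   `k`, e.g. from [fit_logseries()] / [fit_pln()]), or a named list of
#'   `list(logL =, k =)` pairs.
#' @param S Number of species the models were fitted to.
#' @param delta_support Support threshold on the AICc difference
#'   (default 2).
#' @return A tibble with one row per model: `model`, `logL`, `k`, `AICc`,
#'   `delta`, `best`, `supported`, sorted by AICc.  Models for which the
#'   AICc correction is undefined are dropped with a warning.
#' @examples
#' fits <- list(logseries = fit_logseries(c(1, 1, 1, 2, 186, 306, 436)))
#' select_sad_models(fits, S = 7)
#' @export
select_sad_models <- function(fits, S, delta_support = 2) {
  stopifnot(length(fits) > 0, !is.null(names(fits)))
  out <- purrr::map_dfr(names(fits), function(nm) {
    f <- fits[[nm]]
    tibble::tibble(model = nm, logL = f$logL, k = as.integer(f$k),
                   AICc = aicc(f$logL, f$k, S))
  })
  if (any(is.na(out$AICc))) {
    warn(paste0("AICc undefined for model(s) ",
                paste(out$model[is.na(out$AICc)], collapse = ", "),
                " (S too small); excluded from selection"))
    out <- out[!is.na(out$AICc), ]
  }
  out <- dplyr::arrange(out, .data$AICc)
  out$delta <- out$AICc - out$AICc[1]
  out$best <- out$delta == 0
  out$supported <- out$delta < delta_support
  out
}

#' Fit and compare SAD models across the assemblages of a table
#'
#' For each island-by-taxon-group assemblage, fits the requested models to
#' the abundance vector and runs AICc selection.  The gambin model is
#' fitted on a different data representation (octave counts, not raw
#' abundances), so its likelihood is not comparable with the logseries and
#' PLN and it is reported through [gambin_alpha()] instead of entering the
#' selection.
#'
#' @param x An assemblage tibble.
#' @param models Character subset of `c("logseries", "pln")`.
#' @param delta_support AICc support threshold.
#' @return A tibble: one row per assemblage and model, with the columns of
#'   [select_sad_models()].
#' @examples
#' \donttest{
#' compare_sad_models(laurisilva_assemblage())
#' }
#' @export
compare_sad_models <- function(x, models = c("logseries", "pln"),
                               delta_support = 2) {
  models <- match.arg(models, several.ok = TRUE)
  fitters <- list(logseries = fit_logseries, pln = fit_pln)[models]
  x |>
    dplyr::group_by(.data$island, .data$taxon_group) |>
    dplyr::group_modify(function(g, key) {
      fits <- purrr::map(fitters, function(f) f(g$abundance))
      select_sad_models(fits, S = nrow(g), delta_support = delta_support)
    }) |>
    dplyr::ungroup()
}

#' Gambin shape parameter per assemblage
#'
#' @param x An assemblage tibble.
#' @param method Probability rule, see [gambin_probs()].
#' @param standardise_to,reps,seed Optional subsample standardisation,
#'   see [fit_gambin()].
#' @return A tibble with one row per assemblage: `S`, `N`, `max_octave`,
#'   `alpha`, `alpha_standardised`.
#' @examples
#' gambin_alpha(laurisilva_assemblage())
#' @export
gambin_alpha <- function(x, method = "classic", standardise_to = NULL,
                         reps = 100, seed = 1) {
  x |>
    dplyr::group_by(.data$island, .data$taxon_group) |>
    dplyr::group_modify(function(g, key) {
      f <- fit_gambin(g$abundance, method = method,
                      standardise_to = standardise_to, reps = reps,
                      seed = seed)
      tibble::tibble(S = f$S, N = f$N, max_octave = f$max_octave,
                     alpha = f$alpha,
                     alpha_standardised = f$alpha_standardised)
    }) |>
    dplyr::ungroup()
}
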