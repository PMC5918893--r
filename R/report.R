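#' Reference values for the bundled laurel-forest dataset
#'
#' The originally reported summary values for the bundled Terceira/Madeira
#' dataset, used by [assemblage_report()] to flag agreement cell by cell.
#' Each row names a quantity, the assemblage it belongs to, the reference
#' value and the tolerance at which agreement is judged (matching the
#' precision at which the value was reported).
#'
#' Two reference cells are known not to be recoverable from the bundled
#' occupancy-summary table and are therefore marked `targeted = FALSE`:
#' the inverse-Simpson values (whose reported values are inconsistent
#' with `1/sum(p_i^2)` on the bundled abundances) and the right-tail
#' probability of the Terceira spider occupancy distribution (reported
#' from a spreadsheet variant of the test whose exact form is not
#' recoverable).  The Terceira ground-beetle PLN AICc is likewise
#' non-targeted: the truncated-PLN likelihood for that vector has no
#' interior maximum and the reported value reflects the original
#' software's stopping point (see the package vignette).
#'
#' @return A tibble with columns `quantity`, `island`, `taxon_group`,
#'   `reference`, `tolerance`, `targeted`.
#' @export
laurisilva_reference <- function() {
  tribble_ <- function(...) tibble::tribble(...)
  tribble_(
    ~quantity, ~island, ~taxon_group, ~reference, ~tolerance, ~targeted,
    "S", "Terceira", "ground_beetles", 7, 0, TRUE,
    "S", "Madeira", "ground_beetles", 34, 0, TRUE,
    "S", "Terceira", "spiders", 21, 0, TRUE,
    "S", "Madeira", "spiders", 40, 0, TRUE,
    "N", "Terceira", "ground_beetles", 933, 0, TRUE,
    "N", "Madeira", "ground_beetles", 3915, 0, TRUE,
    "N", "Terceira", "spiders", 866, 0, TRUE,
    "N", "Madeira", "spiders", 1056, 0, TRUE,
    "jackknife1", "Terceira", "ground_beetles", 10.9, 0.05, TRUE,
    "jackknife1", "Madeira", "ground_beetles", 44.8, 0.05, TRUE,
    "jackknife1", "Terceira", "spiders", 23.9, 0.05, TRUE,
    "jackknife1", "Madeira", "spiders", 51.7, 0.05, TRUE,
    "q1_exp_shannon", "Terceira", "ground_beetles", 2.94, 0.005, TRUE,
    "q1_exp_shannon", "Madeira", "ground_beetles", 7.61, 0.01, TRUE,
    "q1_exp_shannon", "Terceira", "spiders", 8.17, 0.05, TRUE,
    "q1_exp_shannon", "Madeira", "spiders", 11.13, 0.05, TRUE,
    "q2_inv_simpson", "Terceira", "ground_beetles", 2.77, 0.005, FALSE,
    "q2_inv_simpson", "Madeira", "ground_beetles", 4.55, 0.005, FALSE,
    "q2_inv_simpson", "Terceira", "spiders", 2.78, 0.005, FALSE,
    "q2_inv_simpson", "Madeira", "spiders", 4.54, 0.005, FALSE,
    "q3_berger_parker", "Terceira", "ground_beetles", 0.47, 0.005, TRUE,
    "q3_berger_parker", "Madeira", "ground_beetles", 0.32, 0.005, TRUE,
    "q3_berger_parker", "Terceira", "spiders", 0.30, 0.005, TRUE,
    "q3_berger_parker", "Madeira", "spiders", 0.40, 0.005, TRUE,
    "AICc_logseries", "Terceira", "ground_beetles", 67.16, 0.005, TRUE,
    "AICc_logseries", "Madeira", "ground_beetles", 324.67, 0.005, TRUE,
    "AICc_logseries", "Terceira", "spiders", 187.69, 0.005, TRUE,
    "AICc_logseries", "Madeira", "spiders", 299.58, 0.005, TRUE,
    "AICc_pln", "Terceira", "ground_beetles", 72.56, 0.05, FALSE,
    "AICc_pln", "Madeira", "ground_beetles", 328.48, 0.05, TRUE,
    "AICc_pln", "Terceira", "spiders", 188.62, 0.05, TRUE,
    "AICc_pln", "Madeira", "spiders", 302.42, 0.05, TRUE,
    "gambin_alpha", "Terceira", "ground_beetles", 0.64, 0.005, TRUE,
    "gambin_alpha", "Terceira", "spiders", 3.98, 0.005, TRUE,
    "true_rare", "Terceira", "ground_beetles", 0, 0, TRUE,
    "true_rare", "Madeira", "ground_beetles", 5, 0, TRUE,
    "true_rare", "Terceira", "spiders", 0, 0, TRUE,
    "true_rare", "Madeira", "spiders", 9, 0, TRUE
  )
}

#' Full community-structure report for an assemblage table
#'
#' Runs every stage of the pipeline on a table — diversity profiles and
#' richness estimation, logseries/PLN fitting with AICc selection, gambin
#' alpha, occupancy modality, and the rarity screen with optional triage —
#' and, when a reference table is supplied, compares each computed value
#' against its reference cell.  Every number in the report is recomputed
#' from the input table; the reference column is annotation, never a
#' substitute for computation.
#'
#' @param x An assemblage tibble.
#' @param annotations Optional rarity annotations for the triage stage.
#' @param reference Optional reference tibble in the shape of
#'   [laurisilva_reference()]; pass `NULL` to skip comparisons.
#' @param k Occupancy classes for the modality and screening stages.
#' @return An object of class `assemblage_report`: a list of tibbles
#'   `diversity`, `sad_selection`, `gambin`, `ofd_modality`, `rarity`,
#'   and `comparison` (present when a reference was given, with columns
#'   `value`, `reference`, `targeted` and `pass`).
#' @examples
#' \donttest{
#' rep <- assemblage_report(laurisilva_assemblage(),
#'                          annotations = laurisilva_annotations(),
#'                          reference = laurisilva_reference())
#' rep$comparison
#' }
#' @export
assemblage_report <- function(x, annotations = NULL, reference = NULL,
                              k = 10) {
  div <- diversity_profile(x)
  sad <- compare_sad_models(x)
  gam <- gambin_alpha(x)
  ofd <- ofd_modality(x, k = k)
  rar <- if (!is.null(annotations)) {
    triage_rarity(screen_rarity(x, k = k), annotations)
  } else {
    dplyr::count(screen_rarity(x, k = k), .data$island, .data$taxon_group,
                 name = "n_potential")
  }
  out <- list(diversity = div, sad_selection = sad, gambin = gam,
              ofd_modality = ofd, rarity = rar)
  if (!is.null(reference)) {
    long <- dplyr::bind_rows(
      tidyr::pivot_longer(div, c("S", "N", "jackknife1", "q1_exp_shannon",
                                 "q2_inv_simpson", "q3_berger_parker"),
                          names_to = "quantity", values_to = "value"),
      sad |>
        dplyr::mutate(quantity = paste0("AICc_", .data$model),
                      value = .data$AICc),
      gam |> dplyr::mutate(quantity = "gambin_alpha", value = .data$alpha),
      if ("true_rare" %in% names(rar)) {
        rar |> dplyr::mutate(quantity = "true_rare",
                             value = as.numeric(.data$true_rare))
      }
    )
    comparison <- reference |>
      dplyr::left_join(
        long[c("island", "taxon_group", "quantity", "value")],
        by = c("island", "taxon_group", "quantity")) |>
      dplyr::mutate(
        pass = !is.na(.data$value) &
          abs(.data$value - .data$reference) <= .data$tolerance + 1e-9)
    out$comparison <- comparison
  }
  structure(out, class = "assemblage_report")
}

#' @export
print.assemblage_report <- function(x, ...) {
  cat("== Diversity profiles ==\n"); print(x$diversity)
  cat("\n== SAD model selection (AICc) ==\n"); print(x$sad_selection)
  cat("\n== Gambin alpha ==\n"); print(x$gambin)
  cat("\n== Occupancy modality (Tokeshi) ==\n"); print(x$ofd_modality)
  cat("\n== Rarity ==\n"); print(x$rarity)
  if (!is.null(x$comparison)) {
    targeted <- x$comparison[x$comparison$targeted, ]
    cat(sprintf("\n== Reference comparison: %d/%d targeted cells agree ==\n",
                sum(targeted$pass), nrow(targeted)))
    show <- targeted[!targeted$pass, ]
    if (nrow(show) > 0) {
      cat("disagreeing cells:\n")
      print(show)
    }
  }
  invisible(x)
}

#' Export a report as JSON
#'
#' @param report An [assemblage_report()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("report_to_json needs the jsonlite package")
  }
  jsonlite::write_json(unclass(report), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
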