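#' Screen an assemblage for potentially rare species
#'
#' Rarity screening restricts attention to the species in the first
#' quartile of the species abundance distribution and of the occupancy
#' frequency distribution — the low-abundance, range-restricted corner of
#' the abundance-occupancy plane.  Three readings of "first quartile" are
#' implemented:
#'
#' * `"class"` (default): first quartile of the distributions' class axes
#'   — species whose octave index is at most `floor(max_octave / 4)` *and*
#'   whose occupancy class (see [occupancy_class()]) is at most
#'   `floor(k / 4)`.  This is the reading under which the bundled
#'   dataset's annotated rare species are all recovered.
#' * `"intersection"`: species at or below the empirical 25th-percentile
#'   value of both abundance and occupancy (threshold = value at rank
#'   `ceiling(S/4)`, ties included).
#' * `"union"`: at or below either value threshold.
#'
#' Thresholds are computed per island-by-taxon-group assemblage.
#'
#' @param x An assemblage tibble.
#' @param mode `"class"`, `"intersection"` or `"union"`.
#' @param k Number of occupancy classes for `"class"` mode.
#' @return An object of class `rarity_screen`: a tibble of the
#'   potential-rare species (columns of `x` plus `abundance_threshold`,
#'   `occupancy_threshold`, `mode`), with the screened table retained in
#'   attribute `"assemblage"`.
#' @examples
#' scr <- screen_rarity(laurisilva_assemblage())
#' dplyr::count(scr, island, taxon_group)
#' @export
screen_rarity <- function(x, mode = c("class", "intersection", "union"),
                          k = 10) {
  mode <- match.arg(mode)
  out <- x |>
    dplyr::group_by(.data$island, .data$taxon_group) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 4) {
        abort("rarity screening needs at least 4 species per assemblage",
              class = "rarecomm_value_error")
      }
      if (mode == "class") {
        oc <- octave_index(g$abundance)
        oct_cut <- floor(max(oc) / 4)
        cls <- occupancy_class(g$occupancy, g$n_sites[1], k)
        cls_cut <- floor(k / 4)
        keep <- oc <= oct_cut & cls <= cls_cut
        ab_thr <- 2^(oct_cut + 1) - 1
        oc_thr <- g$n_sites[1] * cls_cut / k
      } else {
        q25 <- function(v) sort(v)[ceiling(length(v) / 4)]
        ab_thr <- q25(g$abundance)
        oc_thr <- q25(g$occupancy)
        low_ab <- g$abundance <= ab_thr
        low_oc <- g$occupancy <= oc_thr
        keep <- if (mode == "intersection") low_ab & low_oc else low_ab | low_oc
      }
      g$abundance_threshold <- ab_thr
      g$occupancy_threshold <- oc_thr
      g[keep, ]
    }) |>
    dplyr::ungroup()
  out$mode <- mode
  attr(out, "assemblage") <- x
  class(out) <- c("rarity_screen", class(out))
  out
}

#' Triage potentially rare species with expert annotations
#'
#' The quartile screen is deliberately over-inclusive: some of the species
#' it selects are "tourists" (common in habitats surrounding the sampled
#' one) or microhabitat specialists that the sampling method undersamples
#' — pseudo-rare, not rare.  Separating them from the truly rare species
#' requires biological knowledge, so this step consumes an annotation
#' table rather than inferring categories from counts.
#'
#' @param screen A [screen_rarity()] result.
#' @param annotations An annotation tibble (see
#'   [read_rarity_annotations()]); annotations for species outside the
#'   potential-rare set are ignored with a warning.
#' @return A tibble with one row per assemblage: `n_potential`,
#'   `n_evaluated`, `tourist`, `microhabitat_specialist`, `true_rare`,
#'   `unevaluated`, `prop_true_rare` (of the evaluated species).
#' @examples
#' triage_rarity(screen_rarity(laurisilva_assemblage()),
#'               laurisilva_annotations())
#' @export
triage_rarity <- function(screen, annotations) {
  ann <- annotations[c("island", "species", "category")]
  joined <- dplyr::left_join(tibble::as_tibble(screen), ann,
                             by = c("island", "species"))
  extra <- dplyr::anti_join(ann, tibble::as_tibble(screen),
                            by = c("island", "species"))
  if (nrow(extra) > 0) {
    warn(paste0(nrow(extra), " annotation(s) for species outside the ",
                "potential-rare set were ignored: ",
                paste(head(extra$species, 5), collapse = ", "),
                if (nrow(extra) > 5) ", ..." else ""))
  }
  joined |>
    dplyr::group_by(.data$island, .data$taxon_group) |>
    dplyr::summarise(
      n_potential = dplyr::n(),
      n_evaluated = sum(!is.na(.data$category)),
      tourist = sum(.data$category == "tourist", na.rm = TRUE),
      microhabitat_specialist =
        sum(.data$category == "microhabitat_specialist", na.rm = TRUE),
      true_rare = sum(.data$category == "true_rare", na.rm = TRUE),
      unevaluated = sum(is.na(.data$category)),
      prop_true_rare = ifelse(.data$n_evaluated > 0,
                              .data$true_rare / .data$n_evaluated, NA_real_),
      .groups = "drop"
    )
}
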