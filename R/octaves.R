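#' Octave index of an abundance
#'
#' The log2 abundance class: octave 0 holds abundance 1, octave 1 holds
#' 2–3, octave 2 holds 4–7, and so on (`floor(log2 n)`).  Computed in
#' integer arithmetic (repeated halving, i.e. the bit length minus one),
#' so powers of two land in the right octave with no floating-point
#' rounding.
#'
#' @param abundance Vector of positive integers.
#' @return Integer vector of octave indices.
#' @examples
#' octave_index(c(1, 2, 3, 4, 7, 8, 1024))
#' @export
octave_index <- function(abundance) {
  abundance <- check_abundance(abundance)
  vapply(abundance, function(x) {
    x <- as.integer(x)
    j <- 0L
    while (x > 1L) {
      x <- x %/% 2L
      j <- j + 1L
    }
    j
  }, integer(1))
}

#' Bin abundances into octaves
#'
#' @param abundance Vector of positive integer abundances.
#' @return A tibble with one row per octave from 0 to the highest occupied
#'   octave: `octave`, `lower`, `upper` (the abundance range of the class)
#'   and `count` (species in it; empty interior octaves appear with
#'   count 0).
#' @examples
#' bin_octaves(c(1, 1, 1, 2, 186, 306, 436))
#' @export
bin_octaves <- function(abundance) {
  oc <- octave_index(abundance)
  m <- max(oc)
  tibble::tibble(
    octave = 0:m,
    lower = 2^(0:m),
    upper = 2^(1:(m + 1)) - 1,
    count = tabulate(oc + 1L, nbins = m + 1L)
  )
}

#' Octave-binned SAD deconstructed by distributional status
#'
#' Splits each octave's species count into an indigenous layer (endemic
#' plus native non-endemic) and an introduced layer, per assemblage.  The
#' layer totals are conserved: summed over layers they equal the pooled
#' [bin_octaves()] counts.
#'
#' @param x An assemblage tibble.
#' @return A tibble with one row per island, taxon group and octave:
#'   `count`, `n_indigenous`, `n_introduced`.
#' @examples
#' deconstruct_sad(laurisilva_assemblage())
#' @export
deconstruct_sad <- function(x) {
  x |>
    dplyr::group_by(.data$island, .data$taxon_group) |>
    dplyr::group_modify(function(g, key) {
      oc <- octave_index(g$abundance)
      m <- max(oc)
      tibble::tibble(
        octave = 0:m,
        count = tabulate(oc + 1L, nbins = m + 1L),
        n_indigenous = tabulate(oc[g$status != "INT"] + 1L, nbins = m + 1L),
        n_introduced = tabulate(oc[g$status == "INT"] + 1L, nbins = m + 1L)
      )
    }) |>
    dplyr::ungroup()
}
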