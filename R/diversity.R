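#' Hill-number diversity profile of an abundance vector
#'
#' Computes the four orders used throughout the package: species richness
#' (q = 0), the exponential of the Shannon–Wiener index exp(H') with
#' natural logarithms (q = 1), the inverse of Simpson's concentration
#' index 1/D = 1/sum(p_i^2) (q = 2), and the Berger–Parker index
#' (labelled q = 3).  The first three are effective numbers of species;
#' the Berger–Parker index is reported as the dominance proportion
#' d = max(n_i)/N, the form in which survey tables conventionally print
#' it, rather than as its Hill-number reciprocal.
#'
#' @param abundance Vector of positive integer species abundances.
#' @return A one-row tibble with columns `S`, `N`, `q0_richness`,
#'   `q1_exp_shannon`, `q2_inv_simpson`, `q3_berger_parker`.
#' @examples
#' hill_profile(c(1, 1, 1, 2, 186, 306, 436))
#' @export
hill_profile <- function(abundance) {
  abundance <- check_abundance(abundance)
  N <- sum(abundance)
  p <- abundance / N
  tibble::tibble(
    S = length(abundance),
    N = N,
    q0_richness = length(abundance),
    q1_exp_shannon = exp(-sum(p * log(p))),
    q2_inv_simpson = 1 / sum(p^2),
    q3_berger_parker = max(p)
  )
}

check_abundance <- function(abundance) {
  if (length(abundance) == 0 || any(is.na(abundance)) ||
      any(abundance < 1) || any(abundance != floor(abundance))) {
    abort("abundance must be a non-empty vector of positive integers",
          class = "rarecomm_value_error")
  }
  as.numeric(abundance)
}

#' Diversity profiles for every assemblage in a table
#'
#' Applies [hill_profile()] to each island-by-taxon-group assemblage and
#' appends the first-order jackknife richness estimate and sampling
#' completeness from [jackknife1()].
#'
#' @param x An assemblage tibble (see [read_assemblage()]).
#' @return A tibble with one row per island and taxonomic group.
#' @examples
#' diversity_profile(laurisilva_assemblage())
#' @export
diversity_profile <- function(x) {
  x |>
    dplyr::group_by(.data$island, .data$taxon_group) |>
    dplyr::group_modify(function(g, key) {
      prof <- hill_profile(g$abundance)
      jk <- jackknife1(S_obs = nrow(g), Q1 = sum(g$occupancy == 1),
                       n_sites = g$n_sites[1])
      dplyr::bind_cols(prof, jk[c("jackknife1", "completeness")])
    }) |>
    dplyr::ungroup()
}

#' First-order jackknife richness estimate from occupancy summaries
#'
#' The first-order jackknife estimator corrects observed richness for
#' species likely missed by the sampling: `S_obs + Q1 * (n - 1)/n`, where
#' `Q1` is the number of "uniques" (species found at exactly one site) and
#' `n` the number of sampled sites.  Sampling completeness is the ratio of
#' observed to estimated richness.  A standard error needs site-level
#' incidence data (see [jackknife1_from_incidence()]); from occupancy
#' summaries alone it is reported as `NA` rather than approximated.
#'
#' @param S_obs Observed species richness.
#' @param Q1 Number of species with occupancy exactly 1.
#' @param n_sites Number of sampled sites (at least 2).
#' @return A one-row tibble: `S_obs`, `Q1`, `n_sites`, `jackknife1`,
#'   `jackknife1_se` (`NA` here), `completeness`.
#' @examples
#' jackknife1(S_obs = 34, Q1 = 11, n_sites = 47)  # 44.8 species
#' @export
jackknife1 <- function(S_obs, Q1, n_sites) {
  if (n_sites < 2) {
    abort("jackknife1 needs at least 2 sites", class = "rarecomm_value_error")
  }
  if (Q1 < 0 || Q1 > S_obs) {
    abort("Q1 must lie in [0, S_obs]", class = "rarecomm_value_error")
  }
  est <- S_obs + Q1 * (n_sites - 1) / n_sites
  tibble::tibble(S_obs = S_obs, Q1 = Q1, n_sites = n_sites,
                 jackknife1 = est, jackknife1_se = NA_real_,
                 completeness = S_obs / est)
}

#' First-order jackknife estimate from an incidence matrix
#'
#' Derives `S_obs` and `Q1` from a site-by-species matrix and adds the
#' Heltshe–Forrester variance-based standard error, which needs to know in
#' which sites the uniques co-occur:
#' `var = (n-1)/n * (sum_j j^2 f_j - Q1^2 / n)` with `f_j` the number of
#' sites holding exactly `j` uniques.
#'
#' @param incidence A tibble from [read_incidence()] or [allocate_sites()]
#'   (first column `site`).
#' @return As [jackknife1()], with `jackknife1_se` filled in.
#' @export
jackknife1_from_incidence <- function(incidence) {
  m <- as.matrix(incidence[-1]) > 0
  n <- nrow(m)
  if (n < 2) {
    abort("jackknife1 needs at least 2 sites", class = "rarecomm_value_error")
  }
  occ <- colSums(m)
  present <- occ > 0
  S_obs <- sum(present)
  uniques <- occ == 1
  Q1 <- sum(uniques)
  per_site_uniques <- rowSums(m[, uniques, drop = FALSE])
  f <- tabulate(per_site_uniques, nbins = max(per_site_uniques, 1))
  v <- (n - 1) / n * (sum(seq_along(f)^2 * f) - Q1^2 / n)
  out <- jackknife1(S_obs, Q1, n)
  out$jackknife1_se <- sqrt(max(v, 0))
  out
}

#' Per-site richness and abundance summaries
#'
#' Mean and range of per-site species richness and per-site total
#' abundance from a site-by-species count matrix.
#'
#' @param incidence A tibble with first column `site` and species counts.
#' @return A one-row tibble with `n_sites`, `mean_richness`,
#'   `min_richness`, `max_richness`, `mean_abundance`, `min_abundance`,
#'   `max_abundance`.
#' @export
per_site_summary <- function(incidence) {
  m <- as.matrix(incidence[-1])
  rich <- rowSums(m > 0)
  ab <- rowSums(m)
  tibble::tibble(
    n_sites = nrow(m),
    mean_richness = mean(rich), min_richness = min(rich),
    max_richness = max(rich),
    mean_abundance = mean(ab), min_abundance = min(ab),
    max_abundance = max(ab)
  )
}
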