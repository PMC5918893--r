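#' Proportional occupancy class of a species
#'
#' The occupancy range `1..n_sites` is divided into `k` proportional
#' classes, each covering 10% of the sites when `k = 10`: class `j` covers
#' occupancies in `((j-1) * n/k, j * n/k]` (half-open on the left, closed
#' on the right), so a species occupying every site falls in class `k` and
#' boundaries need not be integers.
#'
#' @param occupancy Integer occupancies, between 1 and `n_sites`.
#' @param n_sites Number of sampled sites.
#' @param k Number of classes (default 10).
#' @return Integer vector of class indices in `1:k`.
#' @examples
#' occupancy_class(c(4, 5, 47), n_sites = 47)  # 1, 2, 10
#' @export
occupancy_class <- function(occupancy, n_sites, k = 10) {
  stopifnot(k >= 2)
  if (any(occupancy < 1) || any(occupancy > n_sites)) {
    abort("occupancy must lie in [1, n_sites]", class = "rarecomm_value_error")
  }
  as.integer(ceiling(occupancy * k / n_sites))
}

#' Occupancy frequency distribution of an assemblage table
#'
#' Counts species per proportional occupancy class for each
#' island-by-taxon-group assemblage, optionally layered by distributional
#' status (indigenous = endemic + native versus introduced).  Mean and
#' standard deviation of occupancy accompany each distribution.
#'
#' @param x An assemblage tibble.
#' @param k Number of occupancy classes.
#' @param by_status Add `n_indigenous` / `n_introduced` layers?
#' @return A tibble with one row per assemblage and class: `class`,
#'   `count`, `S`, `mean_occupancy`, `sd_occupancy` (and the status
#'   layers when requested).
#' @examples
#' build_ofd(laurisilva_assemblage())
#' @export
build_ofd <- function(x, k = 10, by_status = FALSE) {
  if (nrow(x) == 0) abort("empty assemblage", class = "rarecomm_value_error")
  x |>
    dplyr::group_by(.data$island, .data$taxon_group) |>
    dplyr::group_modify(function(g, key) {
      cls <- occupancy_class(g$occupancy, g$n_sites[1], k)
      out <- tibble::tibble(
        class = seq_len(k),
        count = tabulate(cls, nbins = k),
        S = nrow(g),
        mean_occupancy = mean(g$occupancy),
        sd_occupancy = sd(g$occupancy)
      )
      if (by_status) {
        out$n_indigenous <- tabulate(cls[g$status != "INT"], nbins = k)
        out$n_introduced <- tabulate(cls[g$status == "INT"], nbins = k)
      }
      out
    }) |>
    dplyr::ungroup()
}

#' Tokeshi modality test of an occupancy frequency distribution
#'
#' Two-step test against the null that each of `S` species falls into any
#' of the `k` classes with equal probability `1/k`, under which every
#' class count is marginally `Binomial(S, 1/k)`.  First the overall shape:
#' `Pc` is the upper-tail probability of the modal (largest) class count.
#' If the shape deviates (`Pc < alpha_level`), the terminal peaks are
#' tested: `Pl` and `Pr` are the upper-tail probabilities of the counts in
#' the left-most and right-most *occupied* classes.  Both peaks
#' significant gives a bimodal classification, exactly one gives unimodal.
#' The occupied-class convention matters: with a strictly terminal class
#' that happens to be empty, the right-tail test would be vacuous
#' (`Pr = 1`) for nearly any empirical distribution.
#'
#' @param counts Integer vector of species counts per occupancy class
#'   (length `k`), e.g. one assemblage's `count` column from
#'   [build_ofd()].
#' @param alpha_level Significance level of the two-step procedure.
#' @return An object of class `tokeshi_test`: `Pc`, `Pl`, `Pr`,
#'   `classification` (one of `"uniform-consistent"`, `"unimodal"`,
#'   `"bimodal"`, `"indeterminate"`), `alpha_level`, `S`, `k`, the tested
#'   class indices, and the input counts.
#' @examples
#' ofd <- build_ofd(laurisilva_assemblage())
#' cnt <- ofd$count[ofd$island == "Madeira" & ofd$taxon_group == "spiders"]
#' tokeshi_test(cnt)
#' @export
tokeshi_test <- function(counts, alpha_level = 0.05) {
  stopifnot(all(counts >= 0), all(counts == floor(counts)))
  S <- sum(counts)
  k <- length(counts)
  if (S < 2) abort("Tokeshi test needs at least 2 species",
                   class = "rarecomm_value_error")
  occupied <- which(counts > 0)
  modal <- max(counts)
  left <- min(occupied)
  right <- max(occupied)
  tail_p <- function(n_obs) pbinom(n_obs - 1, S, 1 / k, lower.tail = FALSE)
  Pc <- tail_p(modal)
  Pl <- tail_p(counts[left])
  Pr <- tail_p(counts[right])
  classification <- if (Pc >= alpha_level) {
    "uniform-consistent"
  } else if (Pl < alpha_level && Pr < alpha_level) {
    "bimodal"
  } else if (Pl < alpha_level || Pr < alpha_level) {
    "unimodal"
  } else {
    "indeterminate"
  }
  structure(
    list(Pc = Pc, Pl = Pl, Pr = Pr, classification = classification,
         alpha_level = alpha_level, S = S, k = k,
         left_class = left, right_class = right, counts = counts),
    class = "tokeshi_test"
  )
}

#' Monte-Carlo multinomial check of the Tokeshi tail probabilities
#'
#' Draws `R` multinomial allocations of `S` species into `k`
#' equiprobable classes and estimates `Pc`, `Pl` and `Pr` as the fraction
#' of draws in which the corresponding class count reaches the observed
#' one.  The class positions (modal, left-most occupied, right-most
#' occupied) are fixed at the observed distribution's, so each estimate
#' converges on the binomial marginal tail that [tokeshi_test()] computes.
#'
#' @param counts Observed class counts.
#' @param R Number of multinomial draws.
#' @param seed Seed.
#' @return Named numeric vector `c(Pc =, Pl =, Pr =)`.
#' @export
tokeshi_mc_null <- function(counts, R = 1e5, seed = 1) {
  S <- sum(counts)
  k <- length(counts)
  occupied <- which(counts > 0)
  modal_class <- which.max(counts)
  left <- min(occupied)
  right <- max(occupied)
  withr::with_seed(seed, {
    draws <- rmultinom(R, S, rep(1 / k, k))
    c(Pc = mean(draws[modal_class, ] >= counts[modal_class]),
      Pl = mean(draws[left, ] >= counts[left]),
      Pr = mean(draws[right, ] >= counts[right]))
  })
}

#' Tokeshi modality tests for every assemblage of a table
#'
#' @param x An assemblage tibble.
#' @param k Number of occupancy classes.
#' @param alpha_level Significance level.
#' @return A tibble with one row per assemblage: `S`, `Pc`, `Pl`, `Pr`,
#'   `classification`.
#' @examples
#' ofd_modality(laurisilva_assemblage())
#' @export
ofd_modality <- function(x, k = 10, alpha_level = 0.05) {
  ofd <- build_ofd(x, k = k)
  ofd |>
    dplyr::group_by(.data$island, .data$taxon_group) |>
    dplyr::group_modify(function(g, key) {
      tt <- tokeshi_test(g$count, alpha_level = alpha_level)
      tibble::tibble(S = tt$S, Pc = tt$Pc, Pl = tt$Pl, Pr = tt$Pr,
                     classification = tt$classification)
    }) |>
    dplyr::ungroup()
}

#' @export
print.tokeshi_test <- function(x, ...) {
  cat("Tokeshi occupancy-modality test (k =", x$k, ", S =", x$S, ")\n")
  cat(sprintf("  Pc = %.4g  Pl = %.4g  Pr = %.4g  (alpha = %g)\n",
              x$Pc, x$Pl, x$Pr, x$alpha_level))
  cat("  classification:", x$classification, "\n")
  invisible(x)
}
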