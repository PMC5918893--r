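#' Specify a synthetic community
#'
#' Bundles the parameters of the community generator: an abundance model
#' (logseries, zero-truncated Poisson lognormal, or gambin), a number of
#' species to draw, a number of sites, a Dirichlet clumping parameter for
#' the site-allocation stage, and a fraction of introduced species.
#'
#' @param sad_model `"logseries"`, `"pln"` or `"gambin"`.
#' @param params Named list of model parameters: `x` (logseries), `mu` and
#'   `sigma` (pln), or `alpha` and `max_octave` (gambin).
#' @param S_target Number of species to draw.
#' @param n_sites Number of sites for allocation.
#' @param theta Dirichlet concentration (> 0); small values clump
#'   individuals into few sites, large values spread them evenly.
#' @param introduced_fraction Probability that a species is labelled
#'   introduced.
#' @param seed Master seed; each stage derives its own sub-stream so that
#'   stages can be rerun independently.
#' @return A `community_spec` list.
#' @export
community_spec <- function(sad_model = c("logseries", "pln", "gambin"),
                           params, S_target, n_sites = 40, theta = 1,
                           introduced_fraction = 0.25, seed = 1) {
  sad_model <- match.arg(sad_model)
  stopifnot(theta > 0, S_target >= 1,
            introduced_fraction >= 0, introduced_fraction <= 1)
  needed <- switch(sad_model, logseries = "x", pln = c("mu", "sigma"),
                   gambin = c("alpha", "max_octave"))
  missing <- setdiff(needed, names(params))
  if (length(missing) > 0) {
    abort(paste0("missing ", sad_model, " parameter(s): ",
                 paste(missing, collapse = ", ")),
          class = "rarecomm_value_error")
  }
  structure(list(sad_model = sad_model, params = params,
                 S_target = S_target, n_sites = n_sites, theta = theta,
                 introduced_fraction = introduced_fraction, seed = seed),
            class = "community_spec")
}

# deterministic sub-stream seeds, kept below 2^31
stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + stage * 9973) %% 2147483629
}

#' Sample species abundances from a community specification
#'
#' Logseries abundances are i.i.d. `dlogseries(n, x)` draws; PLN
#' abundances are Poisson counts of lognormal means with zeros rejected;
#' gambin abundances come from the latent-suitability sampler
#' [rgambin()].  Reproducible under the spec's seed.
#'
#' @param spec A [community_spec()].
#' @return Integer vector of `S_target` positive abundances.
#' @export
sample_abundances <- function(spec) {
  withr::with_seed(stage_seed(spec$seed, 1L), {
    p <- spec$params
    switch(spec$sad_model,
      logseries = rlogseries(spec$S_target, p$x),
      pln = rpln(spec$S_target, p$mu, p$sigma),
      gambin = rgambin(spec$S_target, p$alpha, p$max_octave)
    )
  })
}

#' Allocate individuals of each species to sites
#'
#' Each species receives site weights from a symmetric Dirichlet with
#' concentration `theta` and its individuals are placed multinomially, so
#' occupancy emerges from abundance and clumping: `theta` near zero packs
#' a species into few sites, large `theta` approaches an even spread.
#'
#' @param abundance Vector of positive integer abundances.
#' @param n_sites Number of sites (at least 2).
#' @param theta Dirichlet concentration, positive.
#' @param seed Seed.
#' @return An incidence tibble (first column `site`, one count column per
#'   species, named `sp001`, `sp002`, ... unless `abundance` is named).
#' @export
allocate_sites <- function(abundance, n_sites, theta, seed = 1) {
  nms <- names(abundance)
  abundance <- check_abundance(abundance)
  if (n_sites < 2) abort("need at least 2 sites", class = "rarecomm_value_error")
  stopifnot(theta > 0)
  S <- length(abundance)
  if (is.null(nms)) nms <- sprintf("sp%03d", seq_len(S))
  m <- withr::with_seed(stage_seed(seed, 2L), {
    vapply(seq_len(S), function(i) {
      w <- rgamma(n_sites, shape = theta)
      if (all(w == 0)) w <- rep(1, n_sites)  # theta tiny: all mass underflows
      drop(rmultinom(1, abundance[i], w / sum(w)))
    }, numeric(n_sites))
  })
  colnames(m) <- nms
  dplyr::bind_cols(tibble::tibble(site = sprintf("site%03d", seq_len(n_sites))),
                   tibble::as_tibble(m))
}

#' Label simulated species with a distributional status
#'
#' Each species is independently introduced (`INT`) with the given
#' probability; the remainder are endemic (`END`) or native non-endemic
#' (`NAT`) in an 80/20 split.
#'
#' @param x A tibble with one row per species.
#' @param introduced_fraction Probability of `INT`.
#' @param seed Seed.
#' @return `x` with a `status` column added (or replaced).
#' @export
label_status <- function(x, introduced_fraction, seed = 1) {
  stopifnot(introduced_fraction >= 0, introduced_fraction <= 1)
  x$status <- withr::with_seed(stage_seed(seed, 3L), {
    int <- runif(nrow(x)) < introduced_fraction
    ifelse(int, "INT", ifelse(runif(nrow(x)) < 0.8, "END", "NAT"))
  })
  x
}

#' Simulate a full assemblage table with its incidence matrix
#'
#' Chains [sample_abundances()], [allocate_sites()] and [label_status()]
#' and derives occupancy from the incidence matrix, producing a table in
#' the same shape as [laurisilva_assemblage()] so that every analysis
#' stage can be exercised on data with known generating parameters.
#'
#' @param spec A [community_spec()].
#' @param island,taxon_group Labels to stamp on the table.
#' @return A list with elements `assemblage` (validated tibble) and
#'   `incidence`.
#' @examples
#' sim <- simulate_assemblage(
#'   community_spec("logseries", list(x = 0.995), S_target = 30,
#'                  n_sites = 20, theta = 1, seed = 42))
#' diversity_profile(sim$assemblage)
#' @export
simulate_assemblage <- function(spec, island = "SimIsland",
                                taxon_group = "sim_taxon") {
  abundance <- sample_abundances(spec)
  names(abundance) <- sprintf("sp%03d", seq_along(abundance))
  incidence <- allocate_sites(abundance, spec$n_sites, spec$theta,
                              seed = spec$seed)
  occ <- colSums(as.matrix(incidence[-1]) > 0)
  tab <- tibble::tibble(
    island = island, taxon_group = taxon_group,
    species = names(abundance), status = NA_character_,
    occupancy = as.integer(occ), abundance = as.integer(abundance),
    n_sites = as.integer(spec$n_sites)
  )
  tab <- label_status(tab, spec$introduced_fraction, seed = spec$seed)
  list(assemblage = validate_assemblage(tab), incidence = incidence)
}
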