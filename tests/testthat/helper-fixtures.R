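# Small in-code fixtures shared across test files.

toy_assemblage <- function() {
  tibble::tibble(
    island = "Toy",
    taxon_group = "bugs",
    species = paste("sp", 1:6),
    status = c("END", "END", "NAT", "INT", "INT", "END"),
    occupancy = c(1L, 2L, 5L, 1L, 8L, 10L),
    abundance = c(1L, 4L, 9L, 2L, 30L, 55L),
    n_sites = 10L
  )
}

# deterministic random assemblage generator for property-style loops
random_assemblage <- function(seed, S = 25, n_sites = 20) {
  withr::with_seed(seed, {
    ab <- pmax(1L, as.integer(round(rlnorm(S, 1.5, 1.3))))
    occ <- pmin(pmax(1L, as.integer(ceiling(runif(S) * pmin(ab, n_sites)))),
                n_sites)
    tibble::tibble(
      island = "Rnd", taxon_group = "rnd",
      species = sprintf("sp%03d", seq_len(S)),
      status = sample(c("END", "NAT", "INT"), S, replace = TRUE),
      occupancy = occ, abundance = ab, n_sites = as.integer(n_sites)
    )
  })
}

terceira_beetle_abundances <- function() c(1, 1, 1, 2, 186, 306, 436)
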