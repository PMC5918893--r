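test_that("hill profile matches hand values and degenerate cases", {
  prof <- hill_profile(terceira_beetle_abundances())
  expect_equal(round(prof$q1_exp_shannon, 2), 2.94)
  expect_equal(round(prof$q3_berger_parker, 2), 0.47)
  # single species: everything collapses to 1
  one <- hill_profile(17)
  expect_equal(unlist(one[c("q0_richness", "q1_exp_shannon",
                            "q2_inv_simpson", "q3_berger_parker")]),
               c(q0_richness = 1, q1_exp_shannon = 1, q2_inv_simpson = 1,
                 q3_berger_parker = 1))
  # uniform community: q1 = q2 = S, dominance 1/S
  unif <- hill_profile(rep(5, 4))
  expect_equal(unif$q1_exp_shannon, 4)
  expect_equal(unif$q2_inv_simpson, 4)
  expect_equal(unif$q3_berger_parker, 0.25)
  expect_error(hill_profile(numeric(0)), class = "rarecomm_value_error")
})

test_that("Hill ordering q0 >= q1 >= q2 and dominance bounds hold on random vectors", {
  withr::with_seed(99, {
    for (i in 1:1000) {
      S <- sample(2:40, 1)
      ab <- pmax(1, round(rlnorm(S, 1, 1.5)))
      p <- hill_profile(ab)
      expect_true(p$q0_richness >= p$q1_exp_shannon - 1e-9)
      expect_true(p$q1_exp_shannon >= p$q2_inv_simpson - 1e-9)
      expect_true(p$q2_inv_simpson >= 1 - 1e-9)
      expect_true(p$q3_berger_parker >= 1 / p$S - 1e-12 &&
                    p$q3_berger_parker <= 1)
    }
  })
})

test_that("jackknife1 reproduces fixture estimates and respects its invariants", {
  asm <- laurisilva_assemblage()
  jk <- function(isl, grp) {
    g <- asm[asm$island == isl & asm$taxon_group == grp, ]
    jackknife1(nrow(g), sum(g$occupancy == 1), g$n_sites[1])
  }
  expect_equal(round(jk("Madeira", "ground_beetles")$jackknife1, 1), 44.8)
  expect_equal(round(jk("Terceira", "spiders")$jackknife1, 1), 23.9)
  # no uniques: estimate equals observed richness, completeness 1
  none <- jackknife1(12, 0, 40)
  expect_equal(none$jackknife1, 12)
  expect_equal(none$completeness, 1)
  expect_error(jackknife1(5, 1, 1), class = "rarecomm_value_error")
  # monotone non-decreasing in Q1 at fixed S, n
  ests <- vapply(0:10, function(q) jackknife1(10, q, 20)$jackknife1,
                 numeric(1))
  expect_true(all(diff(ests) >= 0))
})

test_that("incidence-based jackknife agrees with the summary path and adds an SE", {
  # 2 sites, species A only in site 1, B in both: S=2, Q1=1, estimate 2.5
  inc <- tibble::tibble(site = c("s1", "s2"), A = c(3L, 0L), B = c(1L, 2L))
  est <- jackknife1_from_incidence(inc)
  expect_equal(est$jackknife1, 2.5)
  expect_equal(est$Q1, 1)
  # every species in >= 2 sites: estimate collapses to S_obs with zero SE
  inc2 <- tibble::tibble(site = c("s1", "s2", "s3"),
                         A = c(1L, 1L, 0L), B = c(2L, 0L, 1L))
  est2 <- jackknife1_from_incidence(inc2)
  expect_equal(est2$jackknife1, 2)
  expect_equal(est2$jackknife1_se, 0)
  # simulated matrix: incidence path equals summary path on derived S, Q1
  sim <- simulate_assemblage(
    community_spec("logseries", list(x = 0.995), S_target = 35,
                   n_sites = 15, theta = 0.5, seed = 5))
  a <- jackknife1_from_incidence(sim$incidence)
  b <- jackknife1(a$S_obs, a$Q1, a$n_sites)
  expect_equal(a$jackknife1, b$jackknife1)
  expect_false(is.na(a$jackknife1_se))
})

test_that("per-site summaries satisfy the grand-total identity and count empty sites", {
  inc <- tibble::tibble(site = c("s1", "s2", "s3"),
                        A = c(4L, 0L, 0L), B = c(2L, 3L, 0L))
  s <- per_site_summary(inc)
  expect_equal(s$mean_abundance, 9 / 3)
  expect_equal(s$min_richness, 0)
  expect_equal(s$max_richness, 2)
})

test_that("diversity_profile reports per-assemblage completeness for the fixture", {
  div <- diversity_profile(laurisilva_assemblage())
  key <- paste(div$island, div$taxon_group)
  comp <- setNames(round(div$completeness, 2), key)
  expect_equal(unname(comp["Terceira ground_beetles"]), 0.64)
  expect_equal(unname(comp["Terceira spiders"]), 0.88)
  expect_true(all(abs(comp[c("Madeira ground_beetles", "Madeira spiders")]
                      - c(0.76, 0.77)) <= 0.015))
})
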