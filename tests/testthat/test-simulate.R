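test_that("community_spec validates its inputs", {
  expect_error(community_spec("pln", list(mu = 1), S_target = 10),
               "missing pln parameter", class = "rarecomm_value_error")
  spec <- community_spec("logseries", list(x = 0.9), S_target = 10)
  expect_s3_class(spec, "community_spec")
})

test_that("abundance sampling is deterministic under a seed and hits degenerate limits", {
  spec <- community_spec("logseries", list(x = 0.99), S_target = 40, seed = 3)
  expect_identical(sample_abundances(spec), sample_abundances(spec))
  # PLN with tiny sigma concentrates near exp(mu)
  spec2 <- community_spec("pln", list(mu = log(5), sigma = 1e-3),
                          S_target = 200, seed = 9)
  ab <- sample_abundances(spec2)
  expect_lt(abs(mean(ab) - 5 / (1 - exp(-5))), 0.5)
  expect_true(all(ab >= 1))
})

test_that("site allocation forces occupancy 1 for singletons and spreads with large theta", {
  inc <- allocate_sites(c(a = 1), n_sites = 12, theta = 0.2, seed = 5)
  expect_equal(sum(inc$a > 0), 1)
  # near-uniform weights: 1000 individuals cover all 10 sites almost surely
  inc2 <- allocate_sites(c(b = 1000), n_sites = 10, theta = 1e6, seed = 5)
  expect_equal(sum(inc2$b > 0), 10)
})

test_that("mean occupancy is non-decreasing in the clumping parameter", {
  mean_occ <- function(theta) {
    occ <- vapply(1:200, function(i) {
      inc <- allocate_sites(c(x = 50), n_sites = 20, theta = theta, seed = i)
      sum(inc$x > 0)
    }, numeric(1))
    mean(occ)
  }
  ms <- vapply(c(0.05, 0.5, 5, 50), mean_occ, numeric(1))
  expect_true(all(diff(ms) > 0))
})

test_that("status labelling respects the introduced fraction", {
  tab <- tibble::tibble(species = sprintf("s%d", 1:10000))
  expect_true(all(label_status(tab, 0, seed = 1)$status != "INT"))
  expect_true(all(label_status(tab, 1, seed = 1)$status == "INT"))
  half <- label_status(tab, 0.5, seed = 2)
  expect_lt(abs(mean(half$status == "INT") - 0.5), 0.02)
  # non-introduced species split END/NAT roughly 80/20
  nat <- half$status[half$status != "INT"]
  expect_lt(abs(mean(nat == "END") - 0.8), 0.05)
})

test_that("end-to-end: logseries communities are recovered through the full pipeline", {
  alpha_true <- 8
  N_target <- 1000
  x <- N_target / (N_target + alpha_true)
  S_draw <- round(alpha_true * log(1 + N_target / alpha_true))
  res <- vapply(1:200, function(seed) {
    spec <- community_spec("logseries", list(x = x), S_target = S_draw,
                           n_sites = 47, theta = 1, seed = seed)
    sim <- simulate_assemblage(spec)
    jk <- jackknife1_from_incidence(sim$incidence)
    c(alpha = fit_logseries(sim$assemblage$abundance)$fisher_alpha,
      cover = jk$jackknife1 >= 0.8 * S_draw)
  }, numeric(2))
  expect_lt(abs(median(res["alpha", ]) - alpha_true) / alpha_true, 0.10)
  expect_gte(mean(res["cover", ]), 0.9)
})

test_that("small-theta simulations reproduce the left-skewed occupancy pattern", {
  spec <- community_spec("logseries", list(x = 0.995), S_target = 45,
                         n_sites = 40, theta = 0.15, seed = 17)
  sim <- simulate_assemblage(spec)
  ofd <- build_ofd(sim$assemblage)
  expect_equal(which.max(ofd$count), 1L)  # class 1 modal
  tt <- tokeshi_test(ofd$count)
  expect_lt(tt$Pl, 0.05)
})
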