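test_that("proportional occupancy classes follow the half-open boundary rule", {
  expect_equal(occupancy_class(5, 47), 2L)    # 5 > 4.7
  expect_equal(occupancy_class(4, 40), 1L)    # 4 <= 4.0 exactly
  expect_equal(occupancy_class(47, 47), 10L)  # full occupancy -> top class
  expect_error(occupancy_class(48, 47), class = "rarecomm_value_error")
})

test_that("OFD histograms and status layers conserve species totals", {
  asm <- laurisilva_assemblage()
  ofd <- build_ofd(asm, by_status = TRUE)
  # Madeira spiders: 22 species occupy at most 4 of 47 sites (class 1):
  # 12 with occupancy 1, 6 with occupancy 2, 4 with occupancy 3
  ms <- ofd[ofd$island == "Madeira" & ofd$taxon_group == "spiders", ]
  expect_equal(ms$count[ms$class == 1], 22)
  expect_equal(sum(ms$count), 40)
  expect_true(all(ofd$n_indigenous + ofd$n_introduced == ofd$count))
  # single-species table: one class holds the one species
  single <- toy_assemblage()[5, ]
  o1 <- build_ofd(single)
  expect_equal(sum(o1$count), 1)
  expect_equal(sum(o1$count > 0), 1)
  # conservation on random tables
  for (seed in 1:100) {
    tab <- random_assemblage(seed)
    o <- build_ofd(tab, by_status = TRUE)
    expect_equal(sum(o$count), nrow(tab))
    expect_true(all(o$n_indigenous + o$n_introduced == o$count))
  }
})

test_that("Tokeshi test classifies the fixtures unimodal with a left-most peak", {
  res <- ofd_modality(laurisilva_assemblage())
  expect_equal(nrow(res), 4)
  expect_true(all(res$classification == "unimodal"))
  expect_true(all(res$Pl < 0.05))
  expect_true(all(res$Pr > 0.05))
  # right-most occupied class with one species, S = 34: Pr = 1 - 0.9^34 ~ 0.97
  mb <- res[res$island == "Madeira" & res$taxon_group == "ground_beetles", ]
  expect_equal(mb$Pr, 1 - 0.9^34)
  expect_lt(abs(mb$Pr - 0.97), 0.005)
})

test_that("uniform class counts are consistent with the null", {
  tt <- tokeshi_test(rep(4, 10))
  expect_equal(tt$classification, "uniform-consistent")
  expect_gt(tt$Pc, 0.05)
})

test_that("tail probabilities are monotone in the observed count", {
  S <- 30
  k <- 10
  tails <- vapply(1:15, function(n) {
    cnt <- numeric(k)
    cnt[1] <- n
    cnt[5] <- S - n
    tokeshi_test(cnt)$Pl
  }, numeric(1))
  expect_true(all(diff(tails) <= 1e-12))
})

test_that("binomial tails agree with the Monte-Carlo multinomial null", {
  withr::with_seed(12, {
    for (i in 1:20) {
      S <- sample(10:60, 1)
      k <- 10
      probs <- rgamma(k, 0.6) + 1e-3
      counts <- drop(rmultinom(1, S, probs / sum(probs)))
      tt <- tokeshi_test(counts)
      mc <- tokeshi_mc_null(counts, R = 1e5, seed = 1000 + i)
      expect_lt(abs(mc["Pc"] - tt$Pc), 0.01)
      expect_lt(abs(mc["Pl"] - tt$Pl), 0.01)
      expect_lt(abs(mc["Pr"] - tt$Pr), 0.01)
    }
  })
})
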