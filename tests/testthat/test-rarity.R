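test_that("clear quartile splits are screened in every mode", {
  tab <- tibble::tibble(
    island = "Toy", taxon_group = "bugs",
    species = c("a", "b", "c", "d"),
    status = "END",
    occupancy = c(1L, 1L, 5L, 20L),
    abundance = c(1L, 1L, 10L, 100L),
    n_sites = 20L
  )
  for (mode in c("class", "intersection", "union")) {
    scr <- screen_rarity(tab, mode = mode)
    expect_setequal(scr$species, c("a", "b"))
  }
})

test_that("union always contains intersection", {
  for (seed in 1:25) {
    tab <- random_assemblage(seed)
    uni <- screen_rarity(tab, mode = "union")$species
    int <- screen_rarity(tab, mode = "intersection")$species
    expect_true(all(int %in% uni))
  }
})

test_that("value-threshold screening is scale-free in abundance", {
  for (mode in c("intersection", "union")) {
    tab <- random_assemblage(7)
    base <- screen_rarity(tab, mode = mode)$species
    scaled <- tab
    scaled$abundance <- scaled$abundance * 16L
    expect_setequal(screen_rarity(scaled, mode = mode)$species, base)
  }
})

test_that("fixture screen recovers every annotated rare species", {
  asm <- laurisilva_assemblage()
  scr <- screen_rarity(asm)
  bold <- asm[asm$annotated_rare, ]
  found <- paste(scr$island, scr$species)
  expect_true(all(paste(bold$island, bold$species) %in% found))
  # Madeira evaluated set: 21 spiders + 14 beetles
  n_pot <- dplyr::count(tibble::as_tibble(scr), island, taxon_group)
  expect_equal(n_pot$n[n_pot$island == "Madeira" & n_pot$taxon_group == "spiders"], 21L)
  expect_equal(n_pot$n[n_pot$island == "Madeira" & n_pot$taxon_group == "ground_beetles"], 14L)
})

test_that("triage splits potential rares by annotation and flags strays", {
  asm <- laurisilva_assemblage()
  scr <- screen_rarity(asm)
  tri <- triage_rarity(scr, laurisilva_annotations())
  md <- tri[tri$island == "Madeira", ]
  expect_equal(md$true_rare[md$taxon_group == "spiders"], 9L)
  expect_equal(md$true_rare[md$taxon_group == "ground_beetles"], 5L)
  expect_true(all(tri$true_rare[tri$island == "Terceira"] == 0L))
  # empty annotations: everything unevaluated
  none <- triage_rarity(scr, laurisilva_annotations()[0, ])
  expect_true(all(none$n_evaluated == 0))
  expect_equal(none$unevaluated, none$n_potential)
  # annotation for a non-screened species is ignored with a warning
  stray <- tibble::tibble(island = "Madeira", taxon_group = "spiders",
                          species = "Tenuiphantes tenuis",
                          category = "tourist")
  expect_warning(tri2 <- triage_rarity(scr, stray), "ignored")
  expect_true(all(tri2$tourist[tri2$island == "Madeira"] == 0L))
})
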