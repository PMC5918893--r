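test_that("bundled laurel-forest dataset has the expected structure and totals", {
  asm <- laurisilva_assemblage()
  expect_equal(nrow(asm), 102)
  counts <- dplyr::count(asm, island, taxon_group)
  expect_equal(
    counts$n[match(c("Madeira.ground_beetles", "Madeira.spiders",
                     "Terceira.ground_beetles", "Terceira.spiders"),
                   paste(counts$island, counts$taxon_group, sep = "."))],
    c(34L, 40L, 7L, 21L))
  island_tot <- tapply(asm$abundance, asm$island, sum)
  expect_equal(as.vector(island_tot[c("Terceira", "Madeira")]),
               c(1799L, 4971L))
  group_tot <- tapply(asm$abundance, paste(asm$island, asm$taxon_group), sum)
  expect_equal(as.vector(group_tot[c("Terceira ground_beetles",
                                     "Madeira ground_beetles",
                                     "Terceira spiders", "Madeira spiders")]),
               c(933L, 3915L, 866L, 1056L))
  # 14 species annotated rare, all on Madeira: 9 spiders + 5 beetles
  rare <- asm[asm$annotated_rare, ]
  expect_equal(nrow(rare), 14)
  expect_true(all(rare$island == "Madeira"))
  expect_equal(sum(rare$taxon_group == "spiders"), 9)
  expect_equal(sum(rare$taxon_group == "ground_beetles"), 5)
  expect_equal(unique(asm$n_sites[asm$island == "Terceira"]), 40L)
  expect_equal(unique(asm$n_sites[asm$island == "Madeira"]), 47L)
})

test_that("write/read round-trip reproduces the table for both delimiters", {
  asm <- laurisilva_assemblage()
  for (delim in c("\t", ",")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_assemblage(asm, path, delim = delim)
    back <- read_assemblage(path)  # delimiter sniffed from header
    expect_equal(as.data.frame(back), as.data.frame(asm))
  }
})

test_that("validation rejects malformed rows with row numbers", {
  bad <- toy_assemblage()
  bad$status[3] <- "X"
  expect_error(validate_assemblage(bad), "row 3.*unknown status",
               class = "rarecomm_value_error")
  bad <- toy_assemblage()
  bad$abundance[2] <- 0L
  expect_error(validate_assemblage(bad), "row 2.*abundance")
  bad <- toy_assemblage()
  bad$occupancy[6] <- 99L
  expect_error(validate_assemblage(bad), "n_sites")
  bad <- toy_assemblage()
  bad$occupancy[2] <- 5L  # occupancy 5 > abundance 4
  expect_error(validate_assemblage(bad), "exceeds abundance")
  bad <- toy_assemblage()
  bad$species[2] <- bad$species[1]
  expect_error(validate_assemblage(bad), "duplicated")
})

test_that("reader enforces the schema and tolerates an empty body", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("island\ttaxon_group\tspecies\toccupancy\tabundance", path)
  expect_error(read_assemblage(path, n_sites = c(Toy = 5)),
               "missing required column", class = "rarecomm_schema_error")
  writeLines("island\ttaxon_group\tspecies\tstatus\toccupancy\tabundance",
             path)
  empty <- read_assemblage(path, n_sites = c(Toy = 5))
  expect_equal(nrow(empty), 0)
})

test_that("status/island/taxon filters reproduce hand counts from the fixture", {
  asm <- laurisilva_assemblage()
  tb_int <- filter_assemblage(asm, island = "Terceira",
                              taxon_group = "ground_beetles", status = "INT")
  expect_equal(nrow(tb_int), 4)
  # introduced Madeira spiders hold 575 of 1056 individuals (> 54%)
  ms_int <- filter_assemblage(asm, island = "Madeira",
                              taxon_group = "spiders", status = "INT")
  expect_equal(sum(ms_int$abundance), 575)
  expect_gt(575 / 1056, 0.54)
  # no filters = identity; impossible filter warns and returns empty
  expect_equal(filter_assemblage(asm), asm)
  expect_warning(none <- filter_assemblage(asm, island = "Atlantis"),
                 "no assemblage records")
  expect_equal(nrow(none), 0)
})

test_that("incidence consistency check accepts matching and rejects broken matrices", {
  spec <- community_spec("logseries", list(x = 0.99), S_target = 12,
                         n_sites = 6, theta = 1, seed = 11)
  sim <- simulate_assemblage(spec)
  expect_true(check_incidence(sim$assemblage, sim$incidence))
  broken <- sim$incidence
  broken[[2]][1] <- broken[[2]][1] + 5L
  expect_error(check_incidence(sim$assemblage, broken),
               class = "rarecomm_value_error")
})

test_that("annotation reader validates categories and uniqueness", {
  ann <- laurisilva_annotations()
  expect_true(all(ann$category %in%
                    c("tourist", "microhabitat_specialist", "true_rare")))
  expect_equal(anyDuplicated(ann[c("species", "island")]), 0L)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tisland\tcategory", "A\tX\tnot_a_category"), path)
  expect_error(read_rarity_annotations(path), "unknown rarity category")
})
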