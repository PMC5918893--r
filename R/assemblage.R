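#' Read a species-level assemblage table
#'
#' An assemblage table has one row per species per island and taxonomic
#' group, with the species' total abundance (individuals), occupancy
#' (number of occupied sampling sites), distributional status and the
#' number of sites sampled on that island.  This is the unit of data that
#' every analysis stage in the package consumes.
#'
#' The required columns are `island`, `taxon_group`, `species`, `status`,
#' `occupancy` and `abundance`; `functional_group`, `family`,
#' `annotated_rare` and `n_sites` are optional.  `n_sites` may instead be
#' supplied via the `n_sites` argument as a named vector (one entry per
#' island).  Column matching is case-insensitive.  The delimiter is sniffed
#' from the header line: tab wins over comma when both occur.
#'
#' @param path Path to a delimited text file (UTF-8, header row).
#' @param n_sites Optional named integer vector giving the number of
#'   sampled sites per island, e.g. `c(Terceira = 40, Madeira = 47)`.
#'   Ignored when the file carries an `n_sites` column.
#' @param delim Field delimiter; `NULL` (default) sniffs the header,
#'   preferring tab over comma.
#' @return A validated assemblage tibble.
#' @examples
#' path <- system.file("extdata", "laurisilva_assemblage.tsv",
#'                     package = "rarecomm")
#' asm <- read_assemblage(path)
#' dplyr::count(asm, island, taxon_group)
#' @export
read_assemblage <- function(path, n_sites = NULL, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("assemblage file not found: ", path), class = "rarecomm_io_error")
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  x <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                         progress = FALSE, show_col_types = FALSE)
  names(x) <- tolower(names(x))
  required <- c("island", "taxon_group", "species", "status",
                "occupancy", "abundance")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "rarecomm_schema_error")
  }
  if (!("n_sites" %in% names(x))) {
    if (is.null(n_sites)) {
      abort("no `n_sites` column in file and no `n_sites` argument supplied",
            class = "rarecomm_schema_error")
    }
    x$n_sites <- unname(n_sites[x$island])
  }
  validate_assemblage(x)
}

#' Validate an assemblage table
#'
#' Checks column types and the row-level invariants: integer positive
#' abundance and occupancy, occupancy no larger than abundance or than the
#' island's number of sites, status one of `END`/`NAT`/`INT`, and species
#' names unique within island and taxonomic group.  Species names are
#' normalised (whitespace trimmed, internal runs collapsed) before the
#' uniqueness check.  Errors name the offending rows.
#'
#' @param x A data frame with assemblage columns (see [read_assemblage()]).
#' @return The validated table as a tibble, invisibly unchanged apart from
#'   name normalisation and status upper-casing.
#' @export
validate_assemblage <- function(x) {
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) {
    x$abundance <- integer(0)
    x$occupancy <- integer(0)
    x$n_sites <- integer(0)
    return(x)
  }
  x$species <- normalise_name(x$species)
  x$island <- normalise_name(x$island)
  x$status <- toupper(trimws(x$status))

  bad_int <- function(v) !is.numeric(v) | is.na(v) | v != floor(v)
  problems <- character()
  row_msg <- function(rows, what) {
    sprintf("row %s: %s", paste(rows, collapse = ", "), what)
  }
  if (any(is.na(x$n_sites))) {
    problems <- c(problems, row_msg(which(is.na(x$n_sites)),
                                    "island has no n_sites entry"))
  }
  bad <- which(bad_int(x$abundance) | x$abundance < 1)
  if (length(bad)) problems <- c(problems, row_msg(bad, "abundance must be a positive integer"))
  bad <- which(bad_int(x$occupancy) | x$occupancy < 1)
  if (length(bad)) problems <- c(problems, row_msg(bad, "occupancy must be a positive integer"))
  if (length(problems) == 0) {
    bad <- which(x$occupancy > x$abundance)
    if (length(bad)) problems <- c(problems, row_msg(bad, "occupancy exceeds abundance"))
    bad <- which(x$occupancy > x$n_sites)
    if (length(bad)) problems <- c(problems, row_msg(bad, "occupancy exceeds the island's n_sites"))
  }
  bad <- which(!(x$status %in% c("END", "NAT", "INT")))
  if (length(bad)) {
    problems <- c(problems, row_msg(bad, paste0(
      "unknown status code (", paste(unique(x$status[bad]), collapse = ", "),
      "); expected END, NAT or INT")))
  }
  dup <- duplicated(x[c("island", "taxon_group", "species")])
  if (any(dup)) {
    problems <- c(problems, row_msg(which(dup), "duplicated species within island and taxon_group"))
  }
  if (length(problems) > 0) {
    abort(paste0("invalid assemblage table:\n",
                 paste0("  ", problems, collapse = "\n")),
          class = "rarecomm_value_error")
  }
  x$abundance <- as.integer(x$abundance)
  x$occupancy <- as.integer(x$occupancy)
  x$n_sites <- as.integer(x$n_sites)
  x
}

normalise_name <- function(s) gsub("[[:space:]]+", " ", trimws(s))

#' Write an assemblage table to delimited text
#'
#' @param x An assemblage tibble.
#' @param path Output path.
#' @param delim Delimiter, tab by default.
#' @return `path`, invisibly.
#' @export
write_assemblage <- function(x, path, delim = "\t") {
  readr::write_delim(x, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Subset an assemblage by island, taxonomic group, or status
#'
#' Deconstruction of an assemblage into subsets (for example native versus
#' introduced species) is the basis of the comparative analyses; this is a
#' convenience filter that keeps the table's structure intact.
#'
#' @param x An assemblage tibble.
#' @param island,taxon_group Optional value(s) to keep.
#' @param status Optional subset of `c("END", "NAT", "INT")`.
#' @return The filtered assemblage tibble.  An empty result triggers a
#'   warning, not an error.
#' @examples
#' asm <- laurisilva_assemblage()
#' filter_assemblage(asm, island = "Terceira", taxon_group = "ground_beetles",
#'                   status = "INT")
#' @export
filter_assemblage <- function(x, island = NULL, taxon_group = NULL,
                              status = NULL) {
  out <- x
  if (!is.null(island)) out <- dplyr::filter(out, .data$island %in% .env$island)
  if (!is.null(taxon_group)) out <- dplyr::filter(out, .data$taxon_group %in% .env$taxon_group)
  if (!is.null(status)) out <- dplyr::filter(out, .data$status %in% .env$status)
  if (nrow(out) == 0) warn("filter matched no assemblage records")
  out
}

#' Laurel-forest spider and ground-beetle assemblages of Terceira and Madeira
#'
#' The bundled reference dataset: epigean spiders (Araneae) and ground
#' beetles (Carabidae) sampled with standardised pitfall-trap transects in
#' the native laurel forest (Laurisilva) of two Macaronesian islands —
#' Terceira (Azores, 40 sites) and Madeira (47 sites).  One row per species
#' with total abundance, occupancy, distributional status (`END` endemic,
#' `NAT` native non-endemic, `INT` introduced), family and functional
#' group.  `annotated_rare` flags the species judged truly rare in the
#' original survey (14 Madeira species: 9 spiders, 5 ground beetles).
#'
#' @return An assemblage tibble with 102 rows.
#' @examples
#' asm <- laurisilva_assemblage()
#' sum(asm$abundance[asm$island == "Terceira"])  # 1799 specimens
#' @export
laurisilva_assemblage <- function() {
  path <- system.file("extdata", "laurisilva_assemblage.tsv",
                      package = "rarecomm", mustWork = TRUE)
  read_assemblage(path)
}

#' Bundled rarity annotations for the laurel-forest dataset
#'
#' Expert triage labels for every species selected by the first-quartile
#' rarity screen of the bundled dataset: `tourist` (rare in the laurel
#' forest but common in surrounding habitats), `microhabitat_specialist`
#' (characteristic of the forest but concentrated in microhabitats that
#' ground-level pitfall trapping undersamples, e.g. bark or canopy), or
#' `true_rare`.  The `true_rare` labels reproduce the dataset's
#' `annotated_rare` flags; the tourist/specialist split is a synthetic
#' reconstruction consistent with the original survey's published
#' summary (all Terceira potential rares pseudo-rare; about a third of the
#' evaluated Madeira spiders microhabitat specialists), hence the fixture
#' file's `_synthetic` suffix.
#'
#' @return A tibble with columns `island`, `taxon_group`, `species`,
#'   `category`, `evidence`.
#' @export
laurisilva_annotations <- function() {
  path <- system.file("extdata", "rarity_annotations_synthetic.tsv",
                      package = "rarecomm", mustWork = TRUE)
  read_rarity_annotations(path)
}

#' Read a rarity-annotation table
#'
#' @param path Delimited text with columns `species`, `island`, `category`
#'   (one of `tourist`, `microhabitat_specialist`, `true_rare`) and
#'   optionally `taxon_group` and `evidence`.
#' @param delim Delimiter; sniffed from the header when `NULL`.
#' @return A validated tibble.
#' @export
read_rarity_annotations <- function(path, delim = NULL) {
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  x <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                         progress = FALSE, show_col_types = FALSE)
  names(x) <- tolower(names(x))
  required <- c("species", "island", "category")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("missing annotation column(s): ",
                 paste(missing, collapse = ", ")),
          class = "rarecomm_schema_error")
  }
  ok <- c("tourist", "microhabitat_specialist", "true_rare")
  bad <- setdiff(unique(x$category), ok)
  if (length(bad) > 0) {
    abort(paste0("unknown rarity category: ", paste(bad, collapse = ", ")),
          class = "rarecomm_value_error")
  }
  x$species <- normalise_name(x$species)
  if (anyDuplicated(x[c("species", "island")])) {
    abort("duplicated (species, island) in annotations",
          class = "rarecomm_value_error")
  }
  tibble::as_tibble(x)
}

#' Read a site-by-species incidence or count matrix
#'
#' First column identifies the site; remaining columns are species counts
#' (or 0/1 presences).  Site-level matrices support the jackknife variance
#' and per-site summaries that an occupancy-summary table cannot provide.
#'
#' @param path Delimited text file.
#' @param delim Delimiter; sniffed when `NULL`.
#' @return A tibble with the site identifier in column `site`.
#' @export
read_incidence <- function(path, delim = NULL) {
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  x <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                         progress = FALSE, show_col_types = FALSE)
  names(x)[1] <- "site"
  vals <- as.matrix(x[-1])
  if (any(is.na(vals)) || any(vals < 0) || any(vals != floor(vals))) {
    abort("incidence values must be non-negative integers",
          class = "rarecomm_value_error")
  }
  tibble::as_tibble(x)
}

#' Check an incidence matrix against an assemblage table
#'
#' Verifies that per-species occupancy derived from the matrix (columns
#' with a positive count) matches the assemblage's `occupancy` column, and,
#' when the matrix holds counts, that per-species totals match `abundance`.
#'
#' @param assemblage An assemblage tibble restricted to one island and
#'   taxonomic group.
#' @param incidence An incidence tibble from [read_incidence()] or
#'   [allocate_sites()].
#' @param counts Should abundance totals be checked too? Default `TRUE`
#'   when the matrix contains values greater than 1.
#' @return `TRUE` invisibly; mismatches raise an error naming the species.
#' @export
check_incidence <- function(assemblage, incidence, counts = NULL) {
  m <- as.matrix(incidence[-1])
  if (is.null(counts)) counts <- any(m > 1)
  species <- colnames(m)
  missing <- setdiff(assemblage$species, species)
  if (length(missing) > 0) {
    abort(paste0("species absent from incidence matrix: ",
                 paste(missing, collapse = ", ")),
          class = "rarecomm_value_error")
  }
  occ <- colSums(m[, assemblage$species, drop = FALSE] > 0)
  bad <- assemblage$species[occ != assemblage$occupancy]
  if (length(bad) > 0) {
    abort(paste0("occupancy mismatch for: ", paste(bad, collapse = ", ")),
          class = "rarecomm_value_error")
  }
  if (counts) {
    tot <- colSums(m[, assemblage$species, drop = FALSE])
    bad <- assemblage$species[tot != assemblage$abundance]
    if (length(bad) > 0) {
      abort(paste0("abundance mismatch for: ", paste(bad, collapse = ", ")),
            class = "rarecomm_value_error")
    }
  }
  invisible(TRUE)
}
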