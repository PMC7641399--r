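#' Read a multilocus HLA genotype table
#'
#' The genotype file is a plain tab-separated table with one row per
#' individual: a `population` column, an `id` column, then two columns per
#' locus named `<locus>_1` and `<locus>_2` (e.g. `A_1`, `A_2`, ...,
#' `DRB1_2`). Allele names may be at any resolution; they are reduced to
#' two-field resolution on read. Empty cells mean the individual is untyped
#' at that locus; such individuals contribute zero chromosomes at that
#' locus but are retained at the others. Allele order within a genotype
#' carries no meaning and is canonicalized by sorting.
#'
#' @param path path to the genotype TSV.
#' @param region_map optional tibble as returned by [read_region_map()];
#'   when given, every population in the file must appear in it.
#' @return A tibble in long genotype form: one row per individual x locus,
#'   with columns `population`, `id`, `locus`, `allele_1`, `allele_2`
#'   (two-field names, sorted, `NA` when untyped).
#' @export
read_cohort <- function(path, region_map = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  if (!all(c("population", "id") %in% names(raw))) {
    abort("Genotype file must have 'population' and 'id' columns.")
  }
  allele_cols <- setdiff(names(raw), c("population", "id"))
  if (length(allele_cols) %% 2L != 0L) {
    abort("Odd number of allele columns: each locus needs a '<locus>_1' and '<locus>_2' pair.")
  }
  loci <- unique(sub("_[12]$", "", allele_cols))
  missing_pairs <- loci[!(paste0(loci, "_1") %in% allele_cols &
                            paste0(loci, "_2") %in% allele_cols)]
  if (length(missing_pairs)) {
    abort(paste0("Locus column pair incomplete for: ", paste(missing_pairs, collapse = ", ")))
  }
  long <- tidyr::pivot_longer(raw,
    cols = dplyr::all_of(allele_cols),
    names_to = c("locus", ".value"),
    names_pattern = "^(.*)_([12])$"
  )
  names(long)[names(long) == "1"] <- "allele_1"
  names(long)[names(long) == "2"] <- "allele_2"
  half <- xor(is.na(long$allele_1), is.na(long$allele_2))
  if (any(half)) {
    abort(paste0(
      "Half-typed genotypes (one allele blank) for individual(s): ",
      paste(unique(long$id[half]), collapse = ", ")
    ))
  }
  long$allele_1 <- reduce_to_two_field(long$allele_1)
  long$allele_2 <- reduce_to_two_field(long$allele_2)
  cohort <- canonicalize_genotypes(long[, c("population", "id", "locus", "allele_1", "allele_2")])
  if (!is.null(region_map)) {
    unknown <- setdiff(unique(cohort$population), region_map$population)
    if (length(unknown)) {
      abort(paste0("Population(s) absent from region map: ", paste(unknown, collapse = ", ")))
    }
  }
  cohort
}

# Sort the two alleles of each genotype lexicographically.
canonicalize_genotypes <- function(cohort) {
  a1 <- pmin(cohort$allele_1, cohort$allele_2)
  a2 <- pmax(cohort$allele_1, cohort$allele_2)
  cohort$allele_1 <- a1
  cohort$allele_2 <- a2
  cohort
}

#' Write a cohort back to the genotype TSV dialect
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, f))` reproduces
#' `x` exactly.
#'
#' @param cohort long genotype tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  wide <- tidyr::pivot_wider(cohort,
    names_from = "locus",
    values_from = c("allele_1", "allele_2"),
    names_glue = "{locus}_{sub('allele_', '', .value)}"
  )
  loci <- unique(cohort$locus)
  ord <- c("population", "id", as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2"))))
  readr::write_tsv(wide[, ord], path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a population-to-region map
#'
#' A CSV with columns `population`, `region` and optionally
#' `ordering_rank`, the rank of each population along the inferred
#' colonization route (distance from the Siberian source along a
#' least-cost path), used as a proxy for cumulative drift.
#'
#' @param path path to the CSV.
#' @return tibble with `population`, `region`, `ordering` (rank or `NA`).
#' @export
read_region_map <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("population", "region") %in% names(raw))) {
    abort("Region map needs 'population' and 'region' columns.")
  }
  bad <- setdiff(unique(raw$region), region_labels())
  if (length(bad)) {
    abort(paste0(
      "Unknown region label(s): ", paste(bad, collapse = ", "),
      ". Expected one of ", paste(region_labels(), collapse = ", "), "."
    ))
  }
  tibble::tibble(
    population = as.character(raw$population),
    region = as.character(raw$region),
    ordering = if ("ordering_rank" %in% names(raw)) as.numeric(raw$ordering_rank) else NA_real_
  )
}

#' Read a worldwide reference allele-frequency panel
#'
#' A CSV with columns `population`, `allele`, `frequency`, `n` (sample
#' size, chromosomes) and the logical flags `migrant` and
#' `uncertain_origin`. Flagged populations are retained in the table but
#' excluded from mean-frequency computations downstream (allele
#' classification), mirroring the practice of omitting migrant populations
#' and populations of uncertain continental origin from meta-analysis
#' means.
#'
#' @param path path to the CSV.
#' @return tibble `population`, `allele`, `frequency`, `n`, `migrant`,
#'   `uncertain_origin`.
#' @export
read_reference_panel <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("population", "allele", "frequency", "n")
  if (!all(need %in% names(raw))) {
    abort(paste0("Reference panel needs columns: ", paste(need, collapse = ", ")))
  }
  tibble::tibble(
    population = as.character(raw$population),
    allele = reduce_to_two_field(as.character(raw$allele)),
    frequency = as.numeric(raw$frequency),
    n = as.numeric(raw$n),
    migrant = if ("migrant" %in% names(raw)) as.logical(raw$migrant) else FALSE,
    uncertain_origin = if ("uncertain_origin" %in% names(raw)) {
      as.logical(raw$uncertain_origin)
    } else {
      FALSE
    }
  )
}

#' Read an aligned allele-sequence map from FASTA
#'
#' FASTA headers carry allele names (any resolution; reduced to two-field).
#' All sequences for a locus must be aligned to equal length over the
#' alphabet A, C, G, T, -.
#'
#' @param path FASTA path.
#' @param locus locus label attached to the returned map.
#' @return tibble `locus`, `allele`, `sequence`.
#' @export
read_sequence_map <- function(path, locus) {
  seqs <- Biostrings::readBStringSet(path)
  alleles <- reduce_to_two_field(names(seqs))
  if (anyDuplicated(alleles)) {
    abort(paste0(
      "Duplicate allele header(s) in FASTA: ",
      paste(unique(alleles[duplicated(alleles)]), collapse = ", ")
    ))
  }
  strings <- toupper(as.character(seqs))
  lens <- nchar(strings)
  if (length(unique(lens)) > 1L) {
    abort(paste0(
      "Ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "),
      " differ; alleles of one locus must be aligned to equal length."
    ))
  }
  bad <- grepl("[^ACGT-]", strings)
  if (any(bad)) {
    abort(paste0(
      "Sequence alphabet must be {A,C,G,T,-}; offending allele(s): ",
      paste(alleles[bad], collapse = ", ")
    ))
  }
  tibble::tibble(locus = locus, allele = alleles, sequence = unname(strings))
}

#' Write an allele-sequence map to FASTA
#'
#' @param seqmap tibble with `allele` and `sequence` columns (one locus).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_sequence_map <- function(seqmap, path) {
  x <- Biostrings::BStringSet(setNames(seqmap$sequence, seqmap$allele))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a microsatellite genotype panel
#'
#' TSV with one row per individual (`population`, `id`) and two columns
#' per marker (`<marker>_1`, `<marker>_2`) holding integer allele sizes.
#'
#' @param path path to the TSV.
#' @return long tibble `population`, `id`, `marker`, `size_1`, `size_2`.
#' @export
read_msat_panel <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    population = readr::col_character(), id = readr::col_character(),
    .default = readr::col_integer()
  ), na = c("", "NA"), progress = FALSE)
  size_cols <- setdiff(names(raw), c("population", "id"))
  long <- tidyr::pivot_longer(raw,
    cols = dplyr::all_of(size_cols),
    names_to = c("marker", ".value"),
    names_pattern = "^(.*)_([12])$"
  )
  names(long)[names(long) == "1"] <- "size_1"
  names(long)[names(long) == "2"] <- "size_2"
  if (any(long$size_1 <= 0 | long$size_2 <= 0, na.rm = TRUE)) {
    abort("Microsatellite allele sizes must be positive integers.")
  }
  long[, c("population", "id", "marker", "size_1", "size_2")]
}

#' Write a microsatellite panel to its TSV dialect
#' @param msat long microsatellite tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msat_panel <- function(msat, path) {
  wide <- tidyr::pivot_wider(msat,
    names_from = "marker",
    values_from = c("size_1", "size_2"),
    names_glue = "{marker}_{sub('size_', '', .value)}"
  )
  markers <- unique(msat$marker)
  ord <- c("population", "id", as.vector(rbind(paste0(markers, "_1"), paste0(markers, "_2"))))
  readr::write_tsv(wide[, ord], path, na = "", progress = FALSE)
  invisible(path)
}
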