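#' Per-population allele counts and frequencies
#'
#' Tallies allele copies over the two chromosomes of every typed
#' individual. Untyped individuals contribute nothing at that locus, so
#' the chromosome count `n` can differ across loci within one population.
#'
#' @param cohort long genotype tibble (see [read_cohort()]).
#' @param loci optional character vector restricting the loci tallied.
#' @return tibble with one row per population x locus x allele:
#'   `population`, `locus`, `allele`, `count`, `n` (chromosomes),
#'   `frequency` = `count / n`. Frequencies sum to one within each
#'   population x locus.
#' @export
allele_frequencies <- function(cohort, loci = NULL) {
  x <- cohort
  if (!is.null(loci)) x <- dplyr::filter(x, .data$locus %in% loci)
  x <- dplyr::filter(x, !is.na(.data$allele_1) & !is.na(.data$allele_2))
  if (nrow(x) == 0L) {
    abort("No typed genotypes at the requested loci (n = 0).")
  }
  long <- tidyr::pivot_longer(x,
    cols = c("allele_1", "allele_2"),
    values_to = "allele", names_to = NULL
  )
  out <- dplyr::count(long, .data$population, .data$locus, .data$allele, name = "count")
  out <- dplyr::mutate(dplyr::group_by(out, .data$population, .data$locus),
    n = sum(.data$count),
    frequency = .data$count / .data$n
  )
  dplyr::ungroup(out)
}

#' Distinct two-field alleles pooled over all populations
#'
#' @param cohort long genotype tibble.
#' @return tibble `locus`, `k`: the number of distinct alleles observed
#'   anywhere in the cohort at each locus.
#' @export
cohort_allele_count <- function(cohort) {
  x <- dplyr::filter(cohort, !is.na(.data$allele_1))
  long <- tidyr::pivot_longer(x,
    cols = c("allele_1", "allele_2"),
    values_to = "allele", names_to = NULL
  )
  dplyr::summarise(dplyr::group_by(long, .data$locus),
    k = dplyr::n_distinct(.data$allele), .groups = "drop"
  )
}

#' Chromosome counts per population and locus
#'
#' @param cohort long genotype tibble.
#' @return tibble `population`, `locus`, `n` where `n` is twice the number
#'   of individuals typed at that locus.
#' @export
chromosome_counts <- function(cohort) {
  dplyr::summarise(dplyr::group_by(cohort, .data$population, .data$locus),
    n = 2L * sum(!is.na(.data$allele_1)), .groups = "drop"
  )
}
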