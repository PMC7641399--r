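# Bundled summary tables from a published survey of HLA variation in 23
# Native American populations and one Siberian population. These are
# printed summary statistics (not individual genotypes), re-typed as
# plain-text data so that regional aggregation and plotting can be
# demonstrated and checked against published values.

hlapop_extdata <- function(file) {
  system.file("extdata", file, package = "hlapop", mustWork = TRUE)
}

#' Published per-population endemic/LFD frequency sums
#'
#' Per-population, per-locus sums of allele frequencies in the endemic
#' and LFD categories for 23 Native American populations and one
#' Siberian-derived survey, in the shape produced by
#' [category_frequency_sums()] (the `other_sum` column is not published
#' and is reported as `NA`).
#'
#' @return tibble `population`, `locus`, `endemic_sum`, `lfd_sum`,
#'   `other_sum`.
#' @export
published_category_sums <- function() {
  raw <- readr::read_tsv(hlapop_extdata("native_american_category_sums.tsv"),
                         col_types = readr::cols(), progress = FALSE)
  long <- tidyr::pivot_longer(raw, cols = -c("population", "region"),
                              names_to = c("category", "locus"),
                              names_pattern = "^(endemic|lfd)_(.*)$",
                              values_to = "sum")
  wide <- tidyr::pivot_wider(long, names_from = "category", values_from = "sum")
  tibble::tibble(
    population = wide$population, locus = wide$locus,
    endemic_sum = wide$endemic, lfd_sum = wide$lfd, other_sum = NA_real_
  )
}

#' Published per-population heterozygosities and sample sizes
#'
#' @return tibble `population`, `region`, `locus`, `n` (chromosomes),
#'   `H`.
#' @export
published_heterozygosity <- function() {
  raw <- readr::read_tsv(hlapop_extdata("native_american_heterozygosity.tsv"),
                         col_types = readr::cols(), progress = FALSE)
  long <- tidyr::pivot_longer(raw, cols = -c("population", "region"),
                              names_to = c("what", "locus"),
                              names_pattern = "^(n|H)_(.*)$")
  tidyr::pivot_wider(long, names_from = "what", values_from = "value")
}

#' Region map of the published survey populations
#'
#' Populations with their region labels and their rank along the
#' colonization route.
#'
#' @return tibble `population`, `region`, `ordering`.
#' @export
published_region_map <- function() {
  read_region_map(hlapop_extdata("native_american_regions.csv"))
}
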