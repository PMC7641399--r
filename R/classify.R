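# Classification of alleles as endemic / LFD / other relative to a
# worldwide reference panel.

# Unweighted mean frequency of each allele across a set of populations,
# counting populations where the allele is absent as frequency zero.
mean_over_populations <- function(freq_tbl, n_pops) {
  dplyr::summarise(
    dplyr::group_by(freq_tbl, .data$locus, .data$allele),
    mean_frequency = sum(.data$frequency) / n_pops, .groups = "drop"
  )
}

#' Classify alleles as endemic, LFD or other
#'
#' Compares each allele's unweighted mean frequency across the Native
#' American populations of the cohort with its mean across the unflagged
#' populations of a worldwide reference panel (migrant and
#' uncertain-origin populations are excluded from the reference mean).
#' Categories: *endemic* — present in the cohort, completely absent from
#' the reference; *LFD* (large frequency difference) — present in both
#' but at least `ratio_threshold`-fold (default 3, inclusive) more common
#' in the Americas; *other* — everything else. Endemic or LFD calls
#' backed by `copies_threshold` (default 3) or fewer allele copies in the
#' Americas are flagged *poorly supported*: such ratios are often
#' artifacts of small samples. When a secondary native/non-native
#' comparison is supplied, an LFD allele poorly supported in **both**
#' datasets is removed from the final list; without it the removal filter
#' degrades to the primary-only flag, with a warning.
#'
#' @param cohort long genotype tibble (Native American populations; use
#'   `regions` to drop others).
#' @param reference reference panel tibble (see [read_reference_panel()]).
#' @param regions optional region map; when given, only populations in
#'   `include_regions` enter the native means.
#' @param include_regions regions counted as Native American.
#' @param secondary optional tibble `allele`, `native_mean`, `ref_mean`,
#'   `copies` giving the same comparison in an independent dataset.
#'   Alleles absent from it count as poorly supported there.
#' @param ratio_threshold LFD fold-change threshold (inclusive).
#' @param copies_threshold maximum copy count considered poorly supported.
#' @return tibble `locus`, `allele`, `native_mean`, `ref_mean`, `ratio`,
#'   `copies`, `category` (`"endemic"`, `"LFD"`, `"other"`),
#'   `poorly_supported`, `removed`.
#' @export
classify_alleles <- function(cohort, reference, regions = NULL,
                             include_regions = native_regions(),
                             secondary = NULL, ratio_threshold = 3,
                             copies_threshold = 3) {
  if (!is.null(regions)) {
    keep <- regions$population[regions$region %in% include_regions]
    cohort <- dplyr::filter(cohort, .data$population %in% keep)
  }
  freqs <- allele_frequencies(cohort)
  n_native <- dplyr::n_distinct(freqs$population)
  native <- mean_over_populations(freqs, n_native)
  copies <- dplyr::summarise(dplyr::group_by(freqs, .data$locus, .data$allele),
                             copies = sum(.data$count), .groups = "drop")
  if (any(freqs$frequency > 0 & freqs$count == 0)) {
    abort("Inconsistent input: positive frequency with zero copies.")
  }

  ref_ok <- dplyr::filter(reference, !.data$migrant, !.data$uncertain_origin)
  n_ref <- dplyr::n_distinct(ref_ok$population)
  if (n_ref == 0) abort("Reference panel has no unflagged populations.")
  ref_ok$locus <- sub("\\*.*$", "", ref_ok$allele)
  ref_mean <- mean_over_populations(ref_ok, n_ref)
  names(ref_mean)[names(ref_mean) == "mean_frequency"] <- "ref_mean"

  out <- dplyr::left_join(native, copies, by = c("locus", "allele"))
  out <- dplyr::left_join(out, ref_mean, by = c("locus", "allele"))
  out$ref_mean[is.na(out$ref_mean)] <- 0
  names(out)[names(out) == "mean_frequency"] <- "native_mean"
  out$ratio <- ifelse(out$ref_mean > 0, out$native_mean / out$ref_mean, Inf)
  out$category <- dplyr::case_when(
    out$ref_mean == 0 ~ "endemic",
    out$ratio >= ratio_threshold ~ "LFD",
    TRUE ~ "other"
  )
  out$poorly_supported <- out$category != "other" & out$copies <= copies_threshold

  if (is.null(secondary)) {
    if (any(out$poorly_supported & out$category == "LFD")) {
      warn(paste0(
        "No secondary dataset: the both-datasets removal filter degrades ",
        "to the primary poorly-supported flag; no allele is removed."
      ))
    }
    out$removed <- FALSE
  } else {
    sec <- secondary
    sec$poorly_secondary <- sec$copies <= copies_threshold
    out <- dplyr::left_join(out, sec[, c("allele", "poorly_secondary")],
                            by = "allele")
    out$poorly_secondary[is.na(out$poorly_secondary)] <- TRUE
    out$removed <- out$category == "LFD" & out$poorly_supported &
      out$poorly_secondary
    out$poorly_secondary <- NULL
  }
  dplyr::arrange(out, .data$locus, .data$allele)
}

#' Per-population sums of endemic and LFD allele frequencies
#'
#' For every population and locus, the total frequency carried by alleles
#' in each category (alleles removed by the both-datasets filter are
#' excluded). The three sums partition the allele set, so
#' `endemic + LFD + other = 1` at every typed locus.
#'
#' @param freqs allele-frequency tibble from [allele_frequencies()].
#' @param classification tibble from [classify_alleles()].
#' @return tibble `population`, `locus`, `endemic_sum`, `lfd_sum`,
#'   `other_sum`, `n_endemic` (count of distinct endemic alleles present).
#' @export
category_frequency_sums <- function(freqs, classification) {
  cls <- dplyr::filter(classification, !.data$removed)
  d <- dplyr::left_join(freqs,
                        cls[, c("locus", "allele", "category")],
                        by = c("locus", "allele"))
  # alleles removed from the classification fall back to "other"
  d$category[is.na(d$category)] <- "other"
  dplyr::summarise(
    dplyr::group_by(d, .data$population, .data$locus),
    endemic_sum = sum(.data$frequency[.data$category == "endemic"]),
    lfd_sum = sum(.data$frequency[.data$category == "LFD"]),
    other_sum = sum(.data$frequency[.data$category == "other"]),
    n_endemic = sum(.data$category == "endemic"),
    .groups = "drop"
  )
}

#' Regional mean frequencies of endemic and LFD alleles
#'
#' Unweighted arithmetic mean of the per-population category sums over
#' the populations of each geographic region, plus an all-regions
#' (continental) mean over every included population. The Aché
#' population, a diversity outlier, is excluded by default.
#'
#' @param sums tibble from [category_frequency_sums()].
#' @param regions region map tibble.
#' @param exclude populations excluded from every mean.
#' @param include_regions regions summarized (default the four Native
#'   American regions).
#' @return tibble `region` (region label or `"All"`), `locus`,
#'   `endemic_mean`, `lfd_mean`, `n_pops`.
#' @export
region_category_means <- function(sums, regions, exclude = "Ache",
                                  include_regions = native_regions()) {
  d <- dplyr::inner_join(sums, regions[, c("population", "region")],
                         by = "population")
  d <- dplyr::filter(d, !(.data$population %in% exclude),
                     .data$region %in% include_regions)
  if (nrow(d) == 0) abort("No populations left after exclusions.")
  by_region <- dplyr::summarise(
    dplyr::group_by(d, .data$region, .data$locus),
    endemic_mean = mean(.data$endemic_sum),
    lfd_mean = mean(.data$lfd_sum),
    n_pops = dplyr::n(), .groups = "drop"
  )
  overall <- dplyr::summarise(
    dplyr::group_by(d, .data$locus),
    region = "All",
    endemic_mean = mean(.data$endemic_sum),
    lfd_mean = mean(.data$lfd_sum),
    n_pops = dplyr::n(), .groups = "drop"
  )
  dplyr::bind_rows(overall, by_region)[, c("region", "locus", "endemic_mean",
                                           "lfd_mean", "n_pops")]
}

#' Correlation of endemic/LFD burden with microsatellite heterozygosity
#'
#' Pearson correlation, per locus, between each population's total
#' frequency of endemic-plus-LFD alleles and its mean microsatellite
#' heterozygosity. A negative correlation indicates that populations
#' having experienced more drift (lower neutral diversity) carry a larger
#' burden of geographically restricted alleles.
#'
#' @param sums tibble from [category_frequency_sums()].
#' @param msat_h tibble from [msat_heterozygosity()].
#' @param exclude populations to exclude.
#' @return tibble `locus`, `estimate`, `p.value`, `n`; loci with zero
#'   variance in either vector are reported with `NA` estimates.
#' @export
category_msat_correlation <- function(sums, msat_h, exclude = character()) {
  d <- dplyr::inner_join(sums, msat_h, by = "population")
  d <- dplyr::filter(d, !(.data$population %in% exclude))
  d$burden <- d$endemic_sum + d$lfd_sum
  out <- dplyr::group_modify(
    dplyr::group_by(d, .data$locus),
    function(g, key) {
      if (nrow(g) < 3 || var(g$burden) == 0 || var(g$H_msat) == 0) {
        return(tibble::tibble(estimate = NA_real_, p.value = NA_real_,
                              n = nrow(g)))
      }
      ct <- cor.test(g$burden, g$H_msat)
      tibble::tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
                     n = nrow(g))
    }
  )
  dplyr::ungroup(out)
}
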