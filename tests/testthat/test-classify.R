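make_reference <- function(allele_freqs, n_pops = 4, flagged = logical(n_pops)) {
  dplyr::bind_rows(purrr::map(seq_len(n_pops), function(j) {
    tibble::tibble(
      population = paste0("ref_", j),
      allele = names(allele_freqs),
      frequency = unname(allele_freqs),
      n = 100,
      migrant = flagged[j],
      uncertain_origin = FALSE
    )
  }))
}

test_that("the 3-fold ratio boundary is inclusive: ratio 3.0 is LFD", {
  # native mean 0.09 (one population), reference mean 0.03
  g <- make_genotypes(c(
    replicate(9, c("A*01:01", "A*02:01"), simplify = FALSE),
    replicate(41, c("A*02:01", "A*02:01"), simplify = FALSE)
  ))
  ref <- make_reference(c("A*01:01" = 0.03, "A*02:01" = 0.97))
  cls <- classify_alleles(g, ref)
  row <- cls[cls$allele == "A*01:01", ]
  expect_equal(row$native_mean, 0.09, tolerance = 1e-12)
  expect_equal(row$ratio, 3, tolerance = 1e-12)
  expect_equal(row$category, "LFD")
  # just under 3-fold is "other"
  ref2 <- make_reference(c("A*01:01" = 0.031, "A*02:01" = 0.969))
  cls2 <- classify_alleles(g, ref2)
  expect_equal(cls2$category[cls2$allele == "A*01:01"], "other")
})

test_that("alleles absent from the unflagged reference are endemic; flags matter", {
  g <- make_genotypes(c(
    replicate(4, c("A*31:15", "A*02:01"), simplify = FALSE),
    replicate(16, c("A*02:01", "A*02:01"), simplify = FALSE)
  ))
  # allele present ONLY in a migrant-flagged reference population
  ref <- dplyr::bind_rows(
    make_reference(c("A*02:01" = 1), n_pops = 3),
    make_reference(c("A*31:15" = 0.1, "A*02:01" = 0.9), n_pops = 1,
                   flagged = TRUE)
  )
  cls <- classify_alleles(g, ref)
  row <- cls[cls$allele == "A*31:15", ]
  expect_equal(row$category, "endemic")
  expect_false(row$poorly_supported) # 4 copies
  expect_equal(row$copies, 4L)
})

test_that("endemic or LFD calls on <= 3 copies are poorly supported", {
  g <- make_genotypes(c(
    replicate(3, c("A*68:05", "A*02:01"), simplify = FALSE),
    replicate(27, c("A*02:01", "A*02:01"), simplify = FALSE)
  ))
  ref <- make_reference(c("A*02:01" = 1))
  cls <- classify_alleles(g, ref)
  expect_true(cls$poorly_supported[cls$allele == "A*68:05"])
})

test_that("the both-datasets removal filter only ever shrinks the LFD list", {
  g <- make_genotypes(c(
    replicate(2, c("A*35:43", "A*02:01"), simplify = FALSE),
    replicate(48, c("A*02:01", "A*02:01"), simplify = FALSE)
  ))
  ref <- make_reference(c("A*35:43" = 0.005, "A*02:01" = 0.995))
  expect_warning(cls_primary <- classify_alleles(g, ref), "secondary")
  expect_equal(cls_primary$category[cls_primary$allele == "A*35:43"], "LFD")
  expect_false(any(cls_primary$removed))

  secondary <- tibble::tibble(allele = "A*35:43", native_mean = 0.01,
                              ref_mean = 0.001, copies = 2)
  cls_both <- classify_alleles(g, ref, secondary = secondary)
  expect_true(cls_both$removed[cls_both$allele == "A*35:43"])
  # secondary support rescues the allele
  secondary_ok <- dplyr::mutate(secondary, copies = 10)
  cls_ok <- classify_alleles(g, ref, secondary = secondary_ok)
  expect_false(any(cls_ok$removed))
  # removal is monotone: the filtered LFD set is a subset of the unfiltered
  lfd_filtered <- cls_both$allele[cls_both$category == "LFD" & !cls_both$removed]
  lfd_all <- cls_primary$allele[cls_primary$category == "LFD"]
  expect_true(all(lfd_filtered %in% lfd_all))
})

test_that("category frequency sums partition each population-locus to one", {
  sim <- sim_cohort(small_sim_params(seed = 21))
  cls <- suppressWarnings(
    classify_alleles(sim$cohort, sim$reference, regions = sim$regions)
  )
  freqs <- allele_frequencies(sim$cohort)
  sums <- category_frequency_sums(freqs, cls)
  total <- sums$endemic_sum + sums$lfd_sum + sums$other_sum
  expect_true(all(abs(total - 1) < 1e-9))
  # populations without endemic alleles have an endemic sum of exactly 0
  expect_true(any(sums$endemic_sum == 0))
})

test_that("regional means average per-population sums, excluding the outlier", {
  sums <- published_category_sums()
  regions <- published_region_map()
  means <- region_category_means(sums, regions, exclude = "Ache")
  # single-population check against a direct average of the SAL rows
  sal_pops <- regions$population[regions$region == "SAL" &
                                   regions$population != "Ache"]
  direct <- mean(sums$lfd_sum[sums$population %in% sal_pops &
                                sums$locus == "B"])
  expect_equal(means$lfd_mean[means$region == "SAL" & means$locus == "B"],
               direct, tolerance = 1e-12)
  # a single-population region mean equals that population's sum
  one <- region_category_means(
    dplyr::filter(sums, population == "Guarani"),
    regions, exclude = character()
  )
  expect_equal(one$endemic_mean[one$locus == "B" & one$region == "SAL"],
               sums$endemic_sum[sums$population == "Guarani" & sums$locus == "B"])
})

test_that("category burden correlates negatively with drift on simulated cohorts", {
  neg <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    sim <- sim_cohort(small_sim_params(seed = 400 + r))
    cls <- suppressWarnings(
      classify_alleles(sim$cohort, sim$reference, regions = sim$regions)
    )
    truth <- sim$truth$planted
    cls_truth <- dplyr::filter(cls, allele %in% truth$allele)
    freqs <- allele_frequencies(sim$cohort)
    sums <- category_frequency_sums(freqs, cls_truth)
    mh <- msat_heterozygosity(sim$msat)
    cc <- category_msat_correlation(sums, mh)
    if (mean(cc$estimate, na.rm = TRUE) < 0) neg <- neg + 1
  }
  expect_gte(neg, round(0.9 * reps))
})
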