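test_that("theta = 0 gives a monomorphic neutral sample", {
  p <- sim_neutral_population(theta = 0, n = 20, seed = 1)
  f <- allele_frequencies(p)
  expect_equal(nrow(f), 1)
})

test_that("mean allele number under the Ewens draw matches its closed form", {
  theta <- 2
  n <- 50
  n_rep <- 3000
  e_k <- sum(theta / (theta + 0:(n - 1)))
  ks <- withr::with_seed(11, replicate(n_rep, {
    length(unique(hlapop:::crp_labels(theta, n)))
  }))
  se <- sd(ks) / sqrt(n_rep)
  expect_lt(abs(mean(ks) - e_k), 3 * se)
})

test_that("neutral samples sit at Hardy-Weinberg proportions", {
  ps <- withr::with_seed(5, replicate(150, {
    g <- sim_neutral_population(theta = 3, n = 50)
    hwp_exact(g, mc_steps = 400, seed = 1)$p.value
  }))
  # exact-test p-values are conservative but roughly uniform
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("identical seeds give byte-identical cohorts", {
  s1 <- sim_cohort(small_sim_params(seed = 9))
  s2 <- sim_cohort(small_sim_params(seed = 9))
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$msat, s2$msat)
  expect_identical(s1$reference, s2$reference)
  s3 <- sim_cohort(small_sim_params(seed = 10))
  expect_false(identical(s1$cohort, s3$cohort))
})

test_that("simulated tables satisfy the data-model invariants", {
  sim <- sim_cohort(small_sim_params(seed = 3))
  f <- allele_frequencies(sim$cohort)
  sums <- dplyr::summarise(dplyr::group_by(f, population, locus),
                           s = sum(frequency), n = n[1], cn = sum(count),
                           .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  expect_true(all(sums$cn == sums$n))
  expect_true(all(chromosome_counts(sim$cohort)$n %% 2 == 0))
  expect_true(all(sim$regions$region %in% region_labels()))
  expect_true(all(sim$msat$size_1 >= 1))
})

test_that("a huge bottleneck barely moves heterozygosity in one generation", {
  params <- sim_params(
    founder_chain = tibble::tibble(region = "NAM", n_b = 1e6, g = 1L,
                                   n_pops = 1L),
    individuals_per_pop = 10L, n_msat = 2L, n_ref_pops = 3L,
    g_pop = 0L, seed = 2,
    planted_endemics = NULL, planted_lfd = NULL
  )
  sim <- sim_cohort(params)
  for (lc in c("A", "B", "C", "DRB1")) {
    h_src <- 1 - sum(sim$truth$source_frequencies[[lc]]^2)
    f_pop <- sim$truth$population_frequencies[[lc]][[1]]
    h_pop <- 1 - sum(f_pop^2)
    expect_lt(abs(h_src - h_pop), 0.01)
  }
})

test_that("expected heterozygosity declines along the founder chain", {
  # 4-population chain at a tight bottleneck: the rank correlation between
  # chain position and expected heterozygosity should be negative in
  # nearly every replicate
  n_neg <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    params <- sim_params(
      founder_chain = tibble::tibble(
        region = c("NAM", "MEA", "SAA", "SAL"),
        n_b = 25, g = 6L, n_pops = 1L
      ),
      individuals_per_pop = 5L, n_msat = 2L, n_ref_pops = 3L,
      g_pop = 0L, seed = 1000 + r,
      planted_endemics = NULL, planted_lfd = NULL
    )
    sim <- sim_cohort(params)
    h <- vapply(seq_len(4), function(i) {
      mean(vapply(c("A", "B", "C", "DRB1"), function(lc) {
        f <- sim$truth$population_frequencies[[lc]][[i]]
        1 - sum(f^2)
      }, numeric(1)))
    }, numeric(1))
    if (cor(seq_len(4), h, method = "spearman") <= 0) n_neg <- n_neg + 1
  }
  expect_gte(n_neg, round(0.95 * n_rep))
})

test_that("planted endemic alleles are absent from unflagged reference populations", {
  sim <- sim_cohort(small_sim_params(seed = 4))
  endemics <- dplyr::filter(sim$truth$planted, category == "endemic")$allele
  ref_ok <- dplyr::filter(sim$reference, !migrant, !uncertain_origin)
  expect_equal(sum(ref_ok$allele %in% endemics & ref_ok$frequency > 0), 0)
  # LFD alleles are present in the reference but several-fold rarer
  lfd <- dplyr::filter(sim$truth$planted, category == "LFD")
  for (i in seq_len(nrow(lfd))) {
    ref_mean <- mean(ref_ok$frequency[ref_ok$allele == lfd$allele[i]])
    expect_lt(ref_mean * 3, lfd$target_frequency[i])
  }
})

test_that("sequence modes produce the intended clade structure", {
  sm <- sim_sequences(6, length = 60, mode = "balanced_clades", seed = 8,
                      n_clade_diffs = 10)
  mat <- do.call(rbind, strsplit(sm$sequence, ""))
  # sites separating the two clades exist and are shared, not singleton
  d_within1 <- sum(mat[1, ] != mat[2, ])
  d_across <- sum(mat[1, ] != mat[6, ])
  expect_gt(d_across, d_within1 + 5)

  sm2 <- sim_sequences(c("A*01:01", "A*02:01"), length = 10, mode = "star",
                       seed = 1, n_private = 1)
  m2 <- do.call(rbind, strsplit(sm2$sequence, ""))
  expect_equal(sum(m2[1, ] != m2[2, ]), 2) # one private site per allele
})

test_that("two-locus simulation honors D' at its extremes", {
  # D' = 1 with equal biallelic margins: only coupling haplotypes survive
  s <- sim_two_locus(c(0.6, 0.4), c(0.6, 0.4), d_prime = 1, n = 200, seed = 3)
  h <- s$haplotypes
  coupling <- (h$allele_a == "A*01:01") == (h$allele_b == "B*01:01")
  expect_true(all(coupling))
  expect_equal(sum(h$frequency), 1, tolerance = 1e-12)

  # D' = 0: haplotype frequencies are the products of the margins
  s0 <- sim_two_locus(c(0.5, 0.3, 0.2), c(0.7, 0.3), d_prime = 0, n = 10, seed = 1)
  expect_equal(s0$haplotypes$frequency,
               as.vector(outer(c(0.5, 0.3, 0.2), c(0.7, 0.3))),
               tolerance = 1e-12)

  expect_error(sim_two_locus(c(0.5, 0.5), c(0.5, 0.5), d_prime = 1.2),
               "d_prime")
})
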