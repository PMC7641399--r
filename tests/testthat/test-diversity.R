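test_that("heterozygosity uses the unbiased n/(n-1) estimator", {
  g <- make_genotypes(list(c("A*01:01", "A*01:01"), c("A*02:01", "A*02:01")))
  h <- heterozygosity(allele_frequencies(g))
  expect_equal(h$H, (4 / 3) * (1 - 0.5), tolerance = 1e-12) # counts (2,2), n = 4
  h0 <- heterozygosity(allele_frequencies(g), unbiased = FALSE)
  expect_equal(h0$H, 0.5, tolerance = 1e-12)
})

test_that("monomorphic samples have zero heterozygosity", {
  g <- make_genotypes(replicate(5, c("A*01:01", "A*01:01"), simplify = FALSE))
  h <- heterozygosity(allele_frequencies(g))
  expect_identical(h$H, 0)
  expect_identical(h$k, 1L)
})

test_that("heterozygosity is relabeling-invariant and maximal at uniform frequencies", {
  g1 <- make_genotypes(list(c("A*01:01", "A*02:01"), c("A*01:01", "A*01:01")))
  g2 <- make_genotypes(list(c("A*07:07", "A*09:09"), c("A*07:07", "A*07:07")))
  expect_equal(heterozygosity(allele_frequencies(g1))$H,
               heterozygosity(allele_frequencies(g2))$H)
  # flattening frequencies raises H at fixed k and n
  skew <- make_genotypes(list(c("A*01:01", "A*01:01"), c("A*01:01", "A*01:01"),
                              c("A*01:01", "A*02:01")))
  flat <- make_genotypes(list(c("A*01:01", "A*01:01"), c("A*01:01", "A*02:01"),
                              c("A*02:01", "A*02:01")))
  expect_gt(heterozygosity(allele_frequencies(flat))$H,
            heterozygosity(allele_frequencies(skew))$H)
})

test_that("population-level correlation matches a hand-rolled covariance formula", {
  set.seed(21)
  x <- runif(12)
  y <- 0.5 * x + rnorm(12, sd = 0.1)
  res <- population_level_correlation(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$estimate, r_hand, tolerance = 1e-12)
  expect_equal(population_level_correlation(x, x)$estimate, 1)
  expect_error(population_level_correlation(rep(1, 5), runif(5)), "variance")
})

test_that("regional contrasts: equal values give p = 1, separated regions tiny p", {
  regions <- tibble::tibble(
    population = paste0("p", 1:8),
    region = rep(c("NAM", "SAL"), each = 4),
    ordering = 1:8
  )
  h_equal <- tibble::tibble(population = paste0("p", 1:8), H = 0.5)
  rc <- regional_contrasts(h_equal, regions)
  expect_true(all(rc$p.adj == 1))

  set.seed(2)
  h_sep <- tibble::tibble(
    population = paste0("p", 1:8),
    H = c(rnorm(4, 0.8, 0.01), rnorm(4, 0.3, 0.01)) # ~50 SD apart
  )
  rc2 <- regional_contrasts(h_sep, regions)
  expect_lt(rc2$p.adj, 1e-4)
})

test_that("Tukey-adjusted p-values are conservative relative to raw t-tests", {
  set.seed(31)
  regions <- tibble::tibble(
    population = paste0("p", 1:12),
    region = rep(c("NAM", "MEA", "SAL"), each = 4),
    ordering = 1:12
  )
  h <- tibble::tibble(population = paste0("p", 1:12),
                      H = runif(12, 0.4, 0.8))
  rc <- regional_contrasts(h, regions)
  for (i in seq_len(nrow(rc))) {
    gg <- strsplit(rc$contrast[i], "-")[[1]]
    raw <- stats::t.test(
      h$H[regions$region == gg[1]], h$H[regions$region == gg[2]],
      var.equal = TRUE
    )$p.value
    expect_gte(rc$p.adj[i] + 1e-10, raw * 0.5) # adjusted never far below raw
  }
  expect_true(all(rc$p.adj >= 0 & rc$p.adj <= 1))
})

test_that("individual-level association agrees with a least-squares oracle", {
  set.seed(7)
  zyg <- tibble::tibble(
    population = "p1",
    id = paste0("i", 1:30),
    hla_hom_count = sample(0:3, 30, replace = TRUE),
    hla_typed = 4L,
    msat_hom_prop = runif(30, 0.2, 0.4)
  )
  zyg$class <- factor(ifelse(zyg$hla_hom_count >= 2, "2+",
                             as.character(zyg$hla_hom_count)),
                      levels = c("0", "1", "2+"))
  res <- individual_level_association(zyg)
  x <- zyg$hla_hom_count
  y <- zyg$msat_hom_prop
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(res$slope, beta, tolerance = 1e-10)
  fit <- summary(lm(y ~ x))
  expect_equal(res$p.value, fit$coefficients[2, 4], tolerance = 1e-10)
})

test_that("a perfectly increasing class trend is strongly significant", {
  set.seed(9)
  zyg <- tibble::tibble(
    population = "p1",
    id = paste0("i", 1:300),
    hla_hom_count = rep(0:2, each = 100),
    hla_typed = 4L,
    msat_hom_prop = rep(c(0.2, 0.3, 0.4), each = 100) + rnorm(300, sd = 0.01)
  )
  zyg$class <- factor(ifelse(zyg$hla_hom_count >= 2, "2+",
                             as.character(zyg$hla_hom_count)),
                      levels = c("0", "1", "2+"))
  regions <- tibble::tibble(population = "p1", region = "SAL", ordering = 1)
  tr <- homozygosity_class_trend(zyg, regions)
  expect_lt(tr$p.value, 0.001)
  expect_gt(tr$slope, 0)
  expect_lt(tr$mean_0, tr$mean_2plus)
})

test_that("independent HLA and msat homozygosity rejects near the nominal rate", {
  set.seed(17)
  n_rep <- 150
  pvals <- replicate(n_rep, {
    zyg <- tibble::tibble(
      population = "p1", id = paste0("i", 1:40),
      hla_hom_count = stats::rbinom(40, 4, 0.3), hla_typed = 4L,
      msat_hom_prop = runif(40, 0.2, 0.5)
    )
    zyg$class <- factor(ifelse(zyg$hla_hom_count >= 2, "2+",
                               as.character(zyg$hla_hom_count)),
                        levels = c("0", "1", "2+"))
    individual_level_association(zyg, threshold = 0.05)$p.value
  })
  rate <- mean(pvals < 0.05, na.rm = TRUE)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
})
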