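# Independent AMOVA oracle: build the explicit chromosome-level distance
# matrix and compute the variance components from their definitions.
fst_oracle <- function(alleles1, alleles2, d_fun = function(x, y) as.numeric(x != y)) {
  all_units <- c(alleles1, alleles2)
  N <- length(all_units)
  sizes <- c(length(alleles1), length(alleles2))
  D <- outer(all_units, all_units, Vectorize(d_fun))
  ssd_tot <- sum(D[lower.tri(D)]) / N
  idx1 <- seq_along(alleles1)
  D1 <- D[idx1, idx1]
  D2 <- D[-idx1, -idx1]
  ssd_wp <- sum(D1[lower.tri(D1)]) / sizes[1] + sum(D2[lower.tri(D2)]) / sizes[2]
  ssd_ap <- ssd_tot - ssd_wp
  msd_wp <- ssd_wp / (N - 2)
  n_c <- N - sum(sizes^2) / N
  sigma_a <- (ssd_ap / 1 - msd_wp) / n_c
  sigma_a / (sigma_a + msd_wp)
}

two_pop_cohort <- function(pairs1, pairs2, locus = "A") {
  dplyr::bind_rows(
    make_genotypes(pairs1, locus = locus, population = "p1"),
    make_genotypes(pairs2, locus = locus, population = "p2")
  )
}

test_that("fixed allele differences give F_ST = 1", {
  cohort <- two_pop_cohort(
    replicate(10, c("A*01:01", "A*01:01"), simplify = FALSE),
    replicate(10, c("A*02:01", "A*02:01"), simplify = FALSE)
  )
  res <- pairwise_fst(cohort)
  expect_equal(res$fst, 1, tolerance = 1e-12)
})

test_that("identical monomorphic populations are degenerate with F_ST = 0", {
  cohort <- two_pop_cohort(
    replicate(5, c("A*01:01", "A*01:01"), simplify = FALSE),
    replicate(5, c("A*01:01", "A*01:01"), simplify = FALSE)
  )
  res <- pairwise_fst(cohort)
  expect_equal(res$fst, 0)
  expect_true(res$degenerate)
})

test_that("AMOVA F_ST equals the explicit sums-of-squares oracle on toys", {
  cohort <- two_pop_cohort(
    c(replicate(6, c("A*01:01", "A*01:01"), simplify = FALSE),
      replicate(4, c("A*01:01", "A*02:01"), simplify = FALSE)),
    c(replicate(3, c("A*01:01", "A*02:01"), simplify = FALSE),
      replicate(7, c("A*02:01", "A*02:01"), simplify = FALSE))
  )
  res <- pairwise_fst(cohort)
  a1 <- c(rep("x", 16), rep("y", 4))
  a2 <- c(rep("x", 3), rep("y", 17))
  expect_equal(res$fst, fst_oracle(a1, a2), tolerance = 1e-12)
})

test_that("F_ST is symmetric and relabeling-invariant; no-differentiation limit is near 0", {
  f1 <- c("A*01:01" = 30, "A*02:01" = 50, "A*03:01" = 20)
  f2 <- c("A*01:01" = 28, "A*02:01" = 52, "A*03:01" = 20)
  r12 <- hlapop:::fst_from_counts(f1, f2)
  r21 <- hlapop:::fst_from_counts(f2, f1)
  expect_equal(r12$fst, r21$fst, tolerance = 1e-12)
  relab <- setNames(f2, c("A*09:09", "A*08:08", "A*07:07"))
  relab1 <- setNames(f1, c("A*09:09", "A*08:08", "A*07:07"))
  expect_equal(hlapop:::fst_from_counts(relab1, relab)$fst, r12$fst)
  expect_lt(abs(r12$fst), 0.02)
})

test_that("R_ST: fixed size difference gives 1, identical distributions near 0, oracle agrees", {
  r_fixed <- hlapop:::rst_from_counts(c(20, 0), c(0, 20), sizes = c(10, 12))
  expect_equal(r_fixed$fst, 1, tolerance = 1e-12)
  r_same <- hlapop:::rst_from_counts(c(10, 10), c(10, 10), sizes = c(10, 12))
  # identical samples sit at the estimator's small negative bias
  expect_lt(abs(r_same$fst), 0.06)
  # toy against the explicit squared-difference oracle
  c1 <- c(5, 3, 2)
  c2 <- c(1, 4, 5)
  sizes <- c(10, 11, 14)
  a1 <- rep(sizes, c1)
  a2 <- rep(sizes, c2)
  oracle <- fst_oracle(a1, a2, d_fun = function(x, y) (x - y)^2)
  expect_equal(hlapop:::rst_from_counts(c1, c2, sizes)$fst, oracle,
               tolerance = 1e-12)
})

test_that("the per-marker microsatellite F_ST sweep matches the single-pair kernel", {
  sim <- sim_cohort(small_sim_params(seed = 6))
  msat <- dplyr::filter(sim$msat, marker %in% paste0("ms", 1:5),
                        population %in% c("NAM_1", "SAL_1"))
  sweep <- msat_pairwise_fst(msat)
  for (mk in unique(sweep$marker)) {
    d <- dplyr::filter(msat, marker == mk)
    long <- tidyr::pivot_longer(d, cols = c("size_1", "size_2"),
                                values_to = "size", names_to = NULL)
    tab <- table(long$population, long$size)
    r <- hlapop:::fst_from_counts(
      setNames(as.numeric(tab["NAM_1", ]), colnames(tab)),
      setNames(as.numeric(tab["SAL_1", ]), colnames(tab))
    )
    expect_equal(unname(sweep$fst[sweep$marker == mk]), r$fst,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("region summary means equal direct averages of the listed pairs", {
  fst_tbl <- tibble::tibble(
    locus = "A",
    pop1 = c("p1", "p1", "p2", "p1", "p2", "p3"),
    pop2 = c("p2", "p3", "p3", "p4", "p4", "p4"),
    fst = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  )
  regions <- tibble::tibble(
    population = paste0("p", 1:4),
    region = c("NAM", "NAM", "NAM", "MEA"),
    ordering = 1:4
  )
  rs <- region_summary(fst_tbl, regions)
  expect_equal(rs$mean_fst[rs$comparison == "within" & rs$locus == "A"],
               mean(c(0.1, 0.2, 0.3)))
  expect_equal(rs$mean_fst[rs$comparison == "between" & rs$locus == "A"],
               mean(c(0.4, 0.5, 0.6)))
})

test_that("Z_ST identities: zero at the background mean, counting p-value", {
  msat_fst <- tibble::tibble(
    pop1 = "p1", pop2 = "p2", marker = paste0("ms", 1:678),
    fst = seq(0, 0.2, length.out = 678)
  )
  hla_at_mean <- tibble::tibble(locus = "A", pop1 = "p1", pop2 = "p2",
                                fst = mean(msat_fst$fst))
  z0 <- zst(hla_at_mean, msat_fst)
  expect_equal(z0$zst[z0$locus == "A"], 0, tolerance = 1e-12)

  # place HLA F_ST so that exactly 8 of the 678 markers exceed it
  cut <- sort(msat_fst$fst, decreasing = TRUE)[8:9]
  hla8 <- tibble::tibble(locus = "A", pop1 = "p1", pop2 = "p2",
                         fst = mean(cut))
  z8 <- zst(hla8, msat_fst)
  expect_equal(z8$p_empirical[z8$locus == "A"], 8 / 678, tolerance = 1e-12)
})

test_that("Z_ST of a normal background matches normal-tail expectations", {
  set.seed(99)
  reps <- 60
  zs <- numeric(reps)
  ps <- numeric(reps)
  for (r in seq_len(reps)) {
    v <- rnorm(678, mean = 0.05, sd = 0.01)
    msat_fst <- tibble::tibble(pop1 = "a", pop2 = "b",
                               marker = paste0("ms", 1:678), fst = v)
    hla <- tibble::tibble(locus = "A", pop1 = "a", pop2 = "b",
                          fst = mean(v) + 2 * sd(v))
    z <- zst(hla, msat_fst)
    zs[r] <- z$zst[z$locus == "A"]
    ps[r] <- z$p_empirical[z$locus == "A"]
  }
  expect_equal(mean(zs), 2, tolerance = 0.05)
  expect_equal(mean(ps), pnorm(-2), tolerance = 0.01)
})

test_that("zero-SD microsatellite background is an error", {
  msat_fst <- tibble::tibble(pop1 = "a", pop2 = "b",
                             marker = c("m1", "m2"), fst = c(0.1, 0.1))
  hla <- tibble::tibble(locus = "A", pop1 = "a", pop2 = "b", fst = 0.2)
  expect_error(zst(hla, msat_fst), "SD")
})
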