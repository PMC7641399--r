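# Independent oracle for the Ewens-Watterson conditional distribution:
# enumerate all set partitions of n labeled gametes into exactly k
# unlabeled blocks; under the Ewens sampling formula conditional on k,
# each labeled partition has probability proportional to
# prod((block size - 1)!).
ew_oracle <- function(n, k) {
  # enumerate assignments recursively in restricted-growth form
  results <- list()
  rec <- function(assign, next_block) {
    pos <- length(assign) + 1
    if (pos > n) {
      if (next_block - 1 == k) results[[length(results) + 1]] <<- assign
      return(invisible(NULL))
    }
    for (b in seq_len(min(next_block, k))) {
      rec(c(assign, b), max(next_block, b + 1))
    }
    invisible(NULL)
  }
  rec(integer(0), 1)
  sizes <- lapply(results, function(a) as.integer(table(a)))
  w <- vapply(sizes, function(s) prod(factorial(s - 1)), numeric(1))
  Fs <- vapply(sizes, function(s) sum((s / n)^2), numeric(1))
  list(F = Fs, prob = w / sum(w))
}

test_that("the n = 2, k = 2 configuration is unique: F = 0.5, p = 1", {
  res <- ewens_watterson(c(1, 1))
  expect_equal(res$F_obs, 0.5)
  expect_equal(res$F_exp, 0.5)
  expect_equal(res$p.value, 1)
})

test_that("EW expectation and p-value match a labeled set-partition oracle", {
  for (cfg in list(c(5, 1), c(4, 2), c(3, 3), c(4, 3, 1), c(2, 2, 2, 2))) {
    n <- sum(cfg)
    k <- length(cfg)
    orc <- ew_oracle(n, k)
    f_exp_oracle <- sum(orc$F * orc$prob)
    f_obs <- sum((cfg / n)^2)
    p_oracle <- sum(orc$prob[orc$F <= f_obs + 1e-9])
    res <- ewens_watterson(cfg)
    expect_equal(res$F_exp, f_exp_oracle, tolerance = 1e-10)
    expect_equal(res$p.value, p_oracle, tolerance = 1e-10)
  }
})

test_that("EW enumeration and Monte-Carlo agree within Monte-Carlo error", {
  for (cfg in list(c(10, 5, 3, 2), c(15, 3, 2), c(9, 9))) {
    enum <- ewens_watterson(cfg)
    mc <- ewens_watterson(cfg, max_partitions = 1, mc_draws = 8000, seed = 5)
    expect_equal(mc$method, "monte_carlo")
    se_p <- sqrt(enum$p.value * (1 - enum$p.value) / 8000)
    expect_lt(abs(mc$p.value - enum$p.value), 3 * se_p + 0.01)
    expect_lt(abs(mc$F_exp - enum$F_exp), 0.02)
  }
})

test_that("a monomorphic configuration is degenerate", {
  res <- ewens_watterson(c(20))
  expect_equal(res$F_obs, 1)
  expect_true(is.na(res$p.value))
})

test_that("sequence recoding expands alleles by their copy counts", {
  g <- make_genotypes(list(c("A*01:01", "A*01:01"), c("A*01:01", "A*02:01")))
  sm <- tibble::tibble(locus = "A", allele = c("A*01:01", "A*02:01"),
                       sequence = c("AAAA", "AAAT"))
  seqs <- recode_to_sequences(g, "pop1", "A", sm)
  expect_length(seqs, 4)
  expect_equal(sum(seqs == "AAAA"), 3)
  sm_missing <- sm[1, ]
  expect_error(recode_to_sequences(g, "pop1", "A", sm_missing), "A\\*02:01")
})

test_that("Tajima's D matches a hand evaluation on a 4-sequence singleton toy", {
  seqs <- c("AAAA", "AAAA", "AAAA", "AAAT")
  res <- tajimas_d(seqs, n_sims = 0)
  n <- 4
  a1 <- 1 + 1 / 2 + 1 / 3
  a2 <- 1 + 1 / 4 + 1 / 9
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  pi_hand <- (1 * 3) / choose(4, 2) # singleton: 3 of 6 pairs differ
  d_hand <- (pi_hand - 1 / a1) / sqrt(e1 * 1 + e2 * 1 * 0)
  expect_equal(res$S, 1L, ignore_attr = TRUE)
  expect_equal(res$pi, pi_hand, tolerance = 1e-12)
  expect_equal(res$D, d_hand, tolerance = 1e-12)
})

test_that("identical sequences (S = 0) are an error, and gaps are deleted", {
  expect_error(tajimas_d(rep("ACGT", 5), n_sims = 0), "S = 0")
  # the only variable column also carries a gap: complete deletion removes it
  seqs <- c("AC-A", "ACTA", "ACTA", "ACTA")
  expect_error(tajimas_d(seqs, n_sims = 0), "S = 0")
})

test_that("pi counts identical sequences with multiplicity", {
  seqs <- c("AAAA", "AAAA", "TTAA", "TTAA")
  res <- tajimas_d(seqs, n_sims = 0)
  # 2 segregating sites; 4 of 6 pairs differ at both sites
  expect_equal(res$S, 2L, ignore_attr = TRUE)
  expect_equal(res$pi, 2 * 4 / 6, tolerance = 1e-12)
})

test_that("deep balanced clades push D positive, star-like skew pushes it negative", {
  n_pos <- 0
  n_neg <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    sm <- sim_sequences(8, length = 120, mode = "balanced_clades",
                        seed = 300 + r)
    # equal clade frequencies: sample both clades at intermediate frequency
    counts <- c(10, 2, 2, 2, 10, 2, 2, 2)
    seqs <- rep(sm$sequence, counts)
    if (tajimas_d(seqs, n_sims = 0)$D > 0) n_pos <- n_pos + 1

    sm2 <- sim_sequences(8, length = 120, mode = "star", seed = 600 + r,
                         n_private = 2)
    # one common ancestral allele, the rest rare: excess singletons
    counts2 <- c(25, 1, 1, 1, 1, 1, 1, 1)
    seqs2 <- rep(sm2$sequence, counts2)
    if (tajimas_d(seqs2, n_sims = 0)$D < 0) n_neg <- n_neg + 1
  }
  expect_gte(n_pos, round(0.95 * n_rep))
  expect_gte(n_neg, round(0.95 * n_rep))
})

test_that("the coalescent p-value convention maps +D to small p and -D to large p", {
  sm <- sim_sequences(8, length = 120, mode = "balanced_clades", seed = 12)
  seqs_pos <- rep(sm$sequence, c(10, 2, 2, 2, 10, 2, 2, 2))
  res_pos <- tajimas_d(seqs_pos, n_sims = 1500, seed = 3)
  expect_gt(res_pos$D, 0)
  expect_lt(res_pos$p.value, 0.2)

  sm2 <- sim_sequences(8, length = 120, mode = "star", seed = 13, n_private = 2)
  seqs_neg <- rep(sm2$sequence, c(25, 1, 1, 1, 1, 1, 1, 1))
  res_neg <- tajimas_d(seqs_neg, n_sims = 1500, seed = 3)
  expect_lt(res_neg$D, 0)
  expect_gt(res_neg$p.value, 0.8)
})
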