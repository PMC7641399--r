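# Ewens-Watterson homozygosity test and Tajima's D.

.ew_cache <- new.env(parent = emptyenv())

# Number of partitions of n into exactly k parts.
count_partitions <- function(n, k) {
  if (k <= 0 || k > n) return(0)
  P <- matrix(0, n + 1, k + 1)
  P[, 1] <- 0
  P[1, ] <- 0
  P[1, 1] <- 1 # p(0,0)
  for (nn in 1:n) {
    for (kk in 1:k) {
      P[nn + 1, kk + 1] <- P[nn, kk] + if (nn - kk >= 0) P[nn - kk + 1, kk + 1] else 0
    }
  }
  P[n + 1, k + 1]
}

# Enumerate partitions of n into exactly k non-increasing parts.
enumerate_partitions <- function(n, k, fn) {
  parts <- integer(k)
  rec <- function(pos, rem, maxpart) {
    left <- k - pos + 1L
    if (pos == k) {
      if (rem <= maxpart && rem >= 1) {
        parts[k] <<- rem
        fn(parts)
      }
      return(invisible(NULL))
    }
    # each remaining part >= 1; current part bounded by rem - (left - 1)
    hi <- min(maxpart, rem - (left - 1L))
    lo <- ceiling(rem / left)
    if (hi < lo) return(invisible(NULL))
    for (v in hi:lo) {
      parts[pos] <<- v
      rec(pos + 1L, rem - v, v)
    }
    invisible(NULL)
  }
  rec(1L, n, n)
  invisible(NULL)
}

# The distribution of the allele configuration (partition of n) under the
# Ewens sampling formula, conditional on observing k alleles, is free of
# theta: P(config) is proportional to 1 / (prod(parts) * prod(mult_j!)),
# where mult_j is the number of parts equal to j. Returns the exact
# conditional distribution of F = sum((parts / n)^2), memoized on (n, k).
ew_conditional <- function(n, k, max_partitions = 1e5) {
  if (count_partitions(n, k) > max_partitions) return(NULL)
  key <- paste(n, k, sep = "_")
  if (!is.null(.ew_cache[[key]])) return(.ew_cache[[key]])
  Fs <- numeric(0)
  ws <- numeric(0)
  enumerate_partitions(n, k, function(parts) {
    mult <- tabulate(parts)
    w <- exp(-sum(log(parts)) - sum(lgamma(mult[mult > 0] + 1)))
    Fs[length(Fs) + 1L] <<- sum((parts / n)^2)
    ws[length(ws) + 1L] <<- w
  })
  out <- list(F = Fs, prob = ws / sum(ws))
  .ew_cache[[key]] <- out
  out
}

# Monte-Carlo fallback: sample configurations by the sequential (Chinese
# restaurant) construction at a theta matched to E[k | n, theta] = k, and
# reject draws whose allele count differs from k. Conditional on k the
# configuration distribution does not depend on theta, so the accepted
# draws follow the exact conditional distribution.
ew_conditional_mc <- function(n, k, draws = 1e5, seed = NULL) {
  ek <- function(theta) sum(theta / (theta + 0:(n - 1)))
  theta <- stats::uniroot(function(t) ek(t) - k, c(1e-6, 1e6))$root
  with_seed(seed, {
    Fs <- numeric(0)
    got <- 0L
    batch <- max(1000L, draws %/% 50L)
    while (got < draws) {
      for (b in seq_len(batch)) {
        counts <- tabulate(crp_labels(theta, n))
        if (length(counts) == k) {
          got <- got + 1L
          Fs[got] <- sum((counts / n)^2)
        }
      }
      if (got == 0L && length(Fs) == 0L && batch > 1e6) break
    }
    Fs
  })
}

#' Ewens-Watterson homozygosity test of neutrality
#'
#' Compares the observed homozygosity statistic `F = sum(p_i^2)` of an
#' allele configuration with its expectation under the Ewens sampling
#' distribution conditional on the sample size `n` and number of alleles
#' `k`. The p-value is the lower-tail probability `Pr(F <= F_obs | n, k)`:
#' small p (below 0.025 under the customary two-tailed convention) points
#' to balancing selection (too-even frequencies), p close to one (above
#' 0.975) to directional selection.
#'
#' The exact conditional distribution is enumerated over partitions of
#' `n` into `k` parts when there are at most `max_partitions` of them,
#' otherwise it is sampled by a sequential-construction Monte-Carlo with
#' rejection on `k`.
#'
#' @param x allele counts: a numeric vector of copy counts, or an
#'   [allele_frequencies()] tibble for a single population x locus (its
#'   `count` column is used).
#' @param max_partitions enumeration threshold.
#' @param mc_draws Monte-Carlo draws used beyond it.
#' @param seed optional integer seed (Monte-Carlo path only).
#' @return one-row tibble `n`, `k`, `F_obs`, `F_exp`, `p.value`, `method`.
#'   For a monomorphic sample (`k = 1`) the test is degenerate: `F_obs =
#'   1` and `p.value = NA`.
#' @export
ewens_watterson <- function(x, max_partitions = 1e5, mc_draws = 1e5,
                            seed = NULL) {
  counts <- if (is.data.frame(x)) x$count else x
  counts <- counts[counts > 0]
  n <- sum(counts)
  k <- length(counts)
  f_obs <- sum((counts / n)^2)
  if (k == 1L) {
    return(tibble::tibble(n = n, k = k, F_obs = 1, F_exp = NA_real_,
                          p.value = NA_real_, method = "degenerate"))
  }
  cond <- ew_conditional(n, k, max_partitions)
  if (!is.null(cond)) {
    f_exp <- sum(cond$F * cond$prob)
    p <- sum(cond$prob[cond$F <= f_obs + 1e-9])
    method <- "enumeration"
  } else {
    Fs <- ew_conditional_mc(n, k, draws = mc_draws, seed = seed)
    f_exp <- mean(Fs)
    p <- mean(Fs <= f_obs + 1e-9)
    method <- "monte_carlo"
  }
  tibble::tibble(n = n, k = k, F_obs = f_obs, F_exp = f_exp, p.value = p,
                 method = method)
}

#' Ewens-Watterson tests for every population x locus of a cohort
#'
#' @param cohort long genotype tibble.
#' @param ... passed to [ewens_watterson()].
#' @return tibble `population`, `locus`, `n`, `k`, `F_obs`, `F_exp`,
#'   `p.value`, `method`, `significant` (two-tailed at 0.05: p below
#'   0.025 or above 0.975).
#' @export
ewens_watterson_test <- function(cohort, ...) {
  freqs <- allele_frequencies(cohort)
  out <- dplyr::group_modify(
    dplyr::group_by(freqs, .data$population, .data$locus),
    function(d, key) ewens_watterson(d$count, ...)
  )
  out <- dplyr::ungroup(out)
  out$significant <- !is.na(out$p.value) &
    (out$p.value < 0.025 | out$p.value > 0.975)
  out
}

#' Expand a population sample into sequence-recoded chromosomes
#'
#' Transforms each allele call into its DNA sequence, yielding one aligned
#' sequence per chromosome (multiplicity equal to the allele's copy
#' count). This recoding exposes molecular-level variation to
#' site-frequency-spectrum tests such as Tajima's D. Every sampled allele
#' must have a sequence; otherwise an error names the absentees (loci
#' whose typing resolution does not map alleles uniquely to sequences
#' cannot be recoded).
#'
#' @param cohort long genotype tibble.
#' @param population,locus which sample to recode.
#' @param seqmap sequence map tibble (see [read_sequence_map()]).
#' @return character vector of aligned sequences, one per chromosome.
#' @export
recode_to_sequences <- function(cohort, population, locus, seqmap) {
  pop <- population
  lc <- locus
  freqs <- allele_frequencies(
    dplyr::filter(cohort, .data$population == pop), loci = lc
  )
  sm <- dplyr::filter(seqmap, .data$locus == lc)
  missing <- setdiff(freqs$allele, sm$allele)
  if (length(missing)) {
    abort(paste0("No sequence for allele(s): ", paste(missing, collapse = ", ")))
  }
  rep(sm$sequence[match(freqs$allele, sm$allele)], freqs$count)
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

tajima_d_value <- function(S, pi, n) {
  cst <- tajima_constants(n)
  (pi - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

# Simulate the neutral-coalescent null distribution of Tajima's D for a
# sample of n sequences. Each replicate draws a Kingman genealogy; with
# fixed_s, exactly S mutations are placed on branches with probability
# proportional to branch length (conditioning on the observed number of
# segregating sites); otherwise a Poisson number with Watterson's
# theta-hat as rate. A mutation on a branch subtending i tips yields a
# derived-allele count of i, from which pi and D follow.
tajima_null_sims <- function(n, S, n_sims = 1e4, fixed_s = TRUE) {
  n_branch <- 2L * (n - 1L)
  theta_w <- S / sum(1 / seq_len(n - 1))
  npairs <- n * (n - 1) / 2
  D <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    sz <- rep.int(1L, n)
    birth <- numeric(n)
    bsize <- integer(n_branch)
    blen <- numeric(n_branch)
    nb <- 0L
    t <- 0
    j <- n
    while (j > 1L) {
      t <- t + rexp(1, j * (j - 1) / 2)
      pair <- sample.int(j, 2L)
      i1 <- pair[1]
      i2 <- pair[2]
      bsize[nb + 1L] <- sz[i1]
      blen[nb + 1L] <- t - birth[i1]
      bsize[nb + 2L] <- sz[i2]
      blen[nb + 2L] <- t - birth[i2]
      nb <- nb + 2L
      sz[i1] <- sz[i1] + sz[i2]
      birth[i1] <- t
      sz[i2] <- sz[j]
      birth[i2] <- birth[j]
      j <- j - 1L
    }
    total_len <- sum(blen)
    n_mut <- if (fixed_s) S else stats::rpois(1, theta_w * total_len / 2)
    if (n_mut == 0) {
      D[s] <- NA_real_
      next
    }
    xi <- bsize[sample.int(n_branch, n_mut, replace = TRUE, prob = blen)]
    pi_sim <- sum(xi * (n - xi)) / npairs
    D[s] <- tajima_d_value(n_mut, pi_sim, n)
  }
  D[!is.na(D)]
}

#' Tajima's D on an aligned sequence sample
#'
#' Computes the normalized difference between the mean pairwise
#' difference estimator (pi) and the segregating-sites estimator (S/a1)
#' of the scaled mutation rate:
#' \deqn{D = \frac{\pi - S/a_1}{\sqrt{e_1 S + e_2 S (S-1)}}}
#' with the standard constants. Positive D (excess of
#' intermediate-frequency variants) is the signature of long-term
#' balancing selection; negative D (excess of rare variants) of
#' expansion, purifying selection or selective sweeps. Alignment columns
#' containing any gap are excluded entirely (complete deletion); pi
#' averages over all `choose(n, 2)` sequence pairs, counting identical
#' sequences with their multiplicity.
#'
#' The p-value is `Pr(D_sim >= D_obs)` under a neutral coalescent null
#' (so, as for the Ewens-Watterson test, large positive D gives small p
#' and strongly negative D gives p near 1; two-tailed significance at
#' 0.05 corresponds to p below 0.025 or above 0.975). By default the null
#' conditions on the observed number of segregating sites; set `fixed_s =
#' FALSE` for a Poisson number of mutations at Watterson's theta-hat.
#'
#' @param sequences character vector of aligned sequences (one per
#'   chromosome), `n >= 4`.
#' @param n_sims coalescent replicates for the p-value (0 skips it).
#' @param fixed_s condition the null on the observed S.
#' @param seed optional integer seed for the null simulation.
#' @return one-row tibble `n`, `S`, `pi`, `D`, `p.value`, `n_sims`.
#' @export
tajimas_d <- function(sequences, n_sims = 1e4, fixed_s = TRUE, seed = NULL) {
  n <- length(sequences)
  if (n < 4) abort("Tajima's D needs at least 4 sequences.")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) abort("Sequences must be aligned to equal length.")
  mat <- matrix(unlist(strsplit(sequences, "")), nrow = n, byrow = TRUE)
  gap_col <- apply(mat == "-", 2, any)
  mat <- mat[, !gap_col, drop = FALSE]
  poly <- vapply(seq_len(ncol(mat)), function(jj) {
    length(unique(mat[, jj])) > 1
  }, logical(1))
  S <- sum(poly)
  if (S == 0) abort("No segregating sites (S = 0): Tajima's D is undefined.")
  npairs <- n * (n - 1) / 2
  pi <- sum(vapply(which(poly), function(jj) {
    cc <- tabulate(factor(mat[, jj]))
    (n^2 - sum(cc^2)) / 2 / npairs
  }, numeric(1)))
  D <- tajima_d_value(S, pi, n)
  p <- NA_real_
  if (n_sims > 0) {
    sims <- with_seed(seed, tajima_null_sims(n, S, n_sims, fixed_s))
    p <- mean(sims >= D - 1e-12)
  }
  tibble::tibble(n = n, S = S, pi = pi, D = D, p.value = p, n_sims = n_sims)
}

#' Tajima's D for every population at sequence-recodable loci
#'
#' @param cohort long genotype tibble.
#' @param seqmap sequence map covering every sampled allele at the chosen
#'   loci.
#' @param loci loci to test (class I by default; class II typing often
#'   cannot be uniquely sequence-recoded).
#' @param n_sims,fixed_s,seed passed to [tajimas_d()] (per-test seeds are
#'   derived from `seed`).
#' @return tibble `population`, `locus`, `n`, `S`, `pi`, `D`, `p.value`,
#'   `significant` (two-tailed at 0.05).
#' @export
tajima_test <- function(cohort, seqmap, loci = c("A", "B", "C"),
                        n_sims = 1e4, fixed_s = TRUE, seed = NULL) {
  groups <- dplyr::distinct(
    dplyr::filter(cohort, .data$locus %in% loci, !is.na(.data$allele_1)),
    .data$population, .data$locus
  )
  seeds <- derive_seeds(seed, nrow(groups))
  out <- purrr::map(seq_len(nrow(groups)), function(i) {
    seqs <- recode_to_sequences(cohort, groups$population[i], groups$locus[i], seqmap)
    res <- tajimas_d(seqs, n_sims = n_sims, fixed_s = fixed_s, seed = seeds[[i]])
    dplyr::bind_cols(groups[i, ], res)
  })
  out <- dplyr::bind_rows(out)
  out$significant <- !is.na(out$p.value) &
    (out$p.value < 0.025 | out$p.value > 0.975)
  out
}
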