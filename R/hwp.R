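# Exact test of Hardy-Weinberg proportions for multiallelic loci.
#
# Conditional on the observed allele counts m_1..m_k (2n gametes), the
# probability of a genotype array {n_ij} under random union of gametes is
#   P = n! 2^H prod_i m_i! / ( (2n)! prod_{i<=j} n_ij! ),
# with H the number of heterozygous individuals. The exact p-value is the
# total conditional probability of arrays no more probable than the one
# observed. Small array spaces are enumerated exhaustively; larger ones
# are sampled by Monte-Carlo permutation of the gamete vector.

log_array_prob <- function(counts_ij, het, n_ind, m) {
  lgamma(n_ind + 1) + het * log(2) + sum(lgamma(m + 1)) -
    lgamma(2 * n_ind + 1) - sum(lgamma(counts_ij + 1))
}

# Enumerate all genotype arrays consistent with allele-count margins m
# (k alleles). Calls fn(array_matrix) for each array. Margins are consumed
# row by row; the last off-diagonal cell of each row is forced.
enumerate_arrays <- function(m, fn) {
  k <- length(m)
  arr <- matrix(0L, k, k)
  rec <- function(i, j, rem) {
    if (i > k) {
      fn(arr)
      return(invisible(NULL))
    }
    if (j > k) {
      if (rem[i] != 0L) return(invisible(NULL))
      return(rec(i + 1L, i + 1L, rem))
    }
    if (i == j) {
      for (c in 0:(rem[i] %/% 2L)) {
        arr[i, i] <<- c
        rem2 <- rem
        rem2[i] <- rem2[i] - 2L * c
        rec(i, j + 1L, rem2)
      }
      arr[i, i] <<- 0L
    } else if (j == k && i < k) {
      c <- rem[i]
      if (c <= rem[k]) {
        arr[i, k] <<- c
        rem2 <- rem
        rem2[i] <- 0L
        rem2[k] <- rem2[k] - c
        rec(i, j + 1L, rem2)
        arr[i, k] <<- 0L
      }
    } else {
      for (c in 0:min(rem[i], rem[j])) {
        arr[i, j] <<- c
        rem2 <- rem
        rem2[i] <- rem2[i] - c
        rem2[j] <- rem2[j] - c
        rec(i, j + 1L, rem2)
      }
      arr[i, j] <<- 0L
    }
    invisible(NULL)
  }
  rec(1L, 1L, as.integer(m))
  invisible(NULL)
}

# Cheap upper bound on the array-space size, used to decide between
# exhaustive enumeration and Monte-Carlo.
array_space_bound <- function(m) {
  k <- length(m)
  b <- 1
  for (i in seq_len(k)) {
    b <- b * (m[i] %/% 2 + 1)
    if (i < k) {
      for (j in (i + 1):k) if (j < k) b <- b * (min(m[i], m[j]) + 1)
    }
    if (b > 1e12) return(b)
  }
  b
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Tests a single population x locus genotype sample against
#' Hardy-Weinberg proportions, conditional on the observed allele counts.
#' When the space of genotype arrays is small (at most `max_arrays` by a
#' cheap bound) the conditional distribution is enumerated exactly;
#' otherwise the null is sampled by shuffling the 2n observed gametes into
#' random genotype pairings (`mc_steps` draws). Arrays are ordered by
#' conditional probability, so the p-value is the probability of an array
#' at most as probable as the observed one.
#'
#' @param genotypes tibble with columns `allele_1`, `allele_2` for one
#'   population and locus (untyped rows dropped), or a two-column
#'   character matrix.
#' @param mc_steps Monte-Carlo permutations when enumeration is not
#'   feasible.
#' @param seed optional integer seed for the Monte-Carlo path.
#' @param max_arrays enumeration threshold on the array-space bound.
#' @return list of class `hwp_result`: `p.value`, `method`
#'   (`"enumeration"`, `"monte_carlo"` or `"degenerate"`), `k`, `n_ind`,
#'   and `genotype_table`, a tibble of observed and HWP-expected genotype
#'   counts with standardized residuals (see [genotype_residuals()]).
#' @export
hwp_exact <- function(genotypes, mc_steps = 1e5, seed = NULL,
                      max_arrays = 1e6) {
  if (is.matrix(genotypes)) {
    genotypes <- tibble::tibble(allele_1 = genotypes[, 1], allele_2 = genotypes[, 2])
  }
  g <- dplyr::filter(genotypes, !is.na(.data$allele_1), !is.na(.data$allele_2))
  n_ind <- nrow(g)
  if (n_ind < 2) abort("Need at least 2 typed individuals.")
  alleles <- sort(unique(c(g$allele_1, g$allele_2)))
  k <- length(alleles)
  i1 <- match(g$allele_1, alleles)
  i2 <- match(g$allele_2, alleles)
  lo <- pmin(i1, i2)
  hi <- pmax(i1, i2)
  obs <- matrix(0L, k, k)
  for (r in seq_len(n_ind)) obs[lo[r], hi[r]] <- obs[lo[r], hi[r]] + 1L
  m <- tabulate(c(i1, i2), nbins = k)

  geno_table <- hwp_genotype_table(obs, m, alleles, n_ind)

  if (k == 1L) {
    return(structure(list(p.value = 1, method = "degenerate", k = k,
                          n_ind = n_ind, genotype_table = geno_table),
                     class = "hwp_result"))
  }

  upper <- upper.tri(obs, diag = TRUE)
  het_obs <- sum(obs[upper.tri(obs)])
  logp_obs <- log_array_prob(obs[upper], het_obs, n_ind, m)

  if (array_space_bound(m) <= max_arrays) {
    total <- 0
    le <- 0
    enumerate_arrays(m, function(arr) {
      lp <- log_array_prob(arr[upper], sum(arr[upper.tri(arr)]), n_ind, m)
      p <- exp(lp)
      total <<- total + p
      if (lp <= logp_obs + 1e-9) le <<- le + p
    })
    p_value <- le / total
    method <- "enumeration"
  } else {
    gametes <- c(i1, i2)
    lfac <- lgamma(seq_len(n_ind + 2)) # lfac[c + 1] = log(c!)
    const <- lgamma(n_ind + 1) + sum(lgamma(m + 1)) - lgamma(2 * n_ind + 1)
    hits <- 0L
    p_value <- with_seed(seed, {
      for (b in seq_len(mc_steps)) {
        perm <- sample(gametes)
        a <- perm[seq(1, 2 * n_ind, by = 2)]
        bb <- perm[seq(2, 2 * n_ind, by = 2)]
        lo2 <- pmin(a, bb)
        hi2 <- pmax(a, bb)
        cell <- lo2 + (hi2 - 1L) * k
        cnt <- tabulate(cell, nbins = k * k)
        cnt <- cnt[cnt > 0L]
        lp <- const + sum(a != bb) * log(2) - sum(lfac[cnt + 1L])
        if (lp <= logp_obs + 1e-9) hits <- hits + 1L
      }
      (hits + 1) / (mc_steps + 1)
    })
    method <- "monte_carlo"
  }
  structure(list(p.value = p_value, method = method, k = k, n_ind = n_ind,
                 genotype_table = geno_table),
            class = "hwp_result")
}

hwp_genotype_table <- function(obs, m, alleles, n_ind) {
  k <- length(alleles)
  p <- m / (2 * n_ind)
  rows <- list()
  for (i in seq_len(k)) {
    for (j in i:k) {
      expd <- if (i == j) n_ind * p[i]^2 else 2 * n_ind * p[i] * p[j]
      o <- obs[i, j]
      if (o == 0 && expd < 1e-12) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        allele_1 = alleles[i], allele_2 = alleles[j],
        observed = o, expected = expd,
        residual = if (expd > 0) (o - expd) / sqrt(expd) else NA_real_
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$flagged <- !is.na(out$residual) & abs(out$residual) > 1.96
  out
}

#' Per-genotype deviation diagnostics from an HWP test
#'
#' Standardized residuals `(observed - expected) / sqrt(expected)` for
#' each genotype class, flagged two-sided at `|residual| > 1.96`. This
#' pinpoints which genotype classes (typically specific heterozygotes)
#' drive an overall locus-level deviation. Residuals are undefined
#' (reported `NA`) when the expected count is zero.
#'
#' @param result an `hwp_result` from [hwp_exact()].
#' @param flagged_only return only the flagged genotype classes.
#' @return tibble `allele_1`, `allele_2`, `observed`, `expected`,
#'   `residual`, `flagged`.
#' @export
genotype_residuals <- function(result, flagged_only = FALSE) {
  stopifnot(inherits(result, "hwp_result"))
  out <- result$genotype_table
  if (flagged_only) out <- dplyr::filter(out, .data$flagged)
  out
}

#' HWP exact tests for every population x locus of a cohort
#'
#' @param cohort long genotype tibble.
#' @param mc_steps,seed,max_arrays passed to [hwp_exact()] (per-test seeds
#'   are derived from `seed`).
#' @return tibble `population`, `locus`, `k`, `n_ind`, `p.value`,
#'   `method`, `significant` (at `alpha`), plus a list-column `result`
#'   holding each `hwp_result`.
#' @param alpha significance level for the `significant` flag.
#' @export
hwp_test <- function(cohort, mc_steps = 1e5, seed = NULL, max_arrays = 1e6,
                     alpha = 0.05) {
  groups <- dplyr::distinct(dplyr::filter(cohort, !is.na(.data$allele_1)),
                            .data$population, .data$locus)
  seeds <- derive_seeds(seed, nrow(groups))
  res <- purrr::map(seq_len(nrow(groups)), function(i) {
    g <- dplyr::filter(cohort, .data$population == groups$population[i],
                       .data$locus == groups$locus[i])
    hwp_exact(g, mc_steps = mc_steps, seed = seeds[[i]], max_arrays = max_arrays)
  })
  tibble::tibble(
    population = groups$population,
    locus = groups$locus,
    k = purrr::map_int(res, "k"),
    n_ind = purrr::map_int(res, "n_ind"),
    p.value = purrr::map_dbl(res, "p.value"),
    method = purrr::map_chr(res, "method"),
    significant = purrr::map_dbl(res, "p.value") < alpha &
      purrr::map_chr(res, "method") != "degenerate",
    result = res
  )
}
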