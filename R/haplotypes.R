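# EM (gene-counting) estimation of two-locus haplotype frequencies and
# allele-specific heterozygosity (ASH).

#' Extract unphased two-locus genotypes from a cohort
#'
#' @param cohort long genotype tibble.
#' @param population population to extract.
#' @param loci length-2 character vector: first the "a" locus, then "b".
#' @return tibble `id`, `a_1`, `a_2`, `b_1`, `b_2` for individuals typed
#'   at both loci.
#' @export
two_locus_genotypes <- function(cohort, population, loci) {
  pop <- population
  d <- dplyr::filter(cohort, .data$population == pop,
                     .data$locus %in% loci, !is.na(.data$allele_1))
  a <- dplyr::filter(d, .data$locus == loci[1])
  b <- dplyr::filter(d, .data$locus == loci[2])
  out <- dplyr::inner_join(
    setNames(a[, c("id", "allele_1", "allele_2")], c("id", "a_1", "a_2")),
    setNames(b[, c("id", "allele_1", "allele_2")], c("id", "b_1", "b_2")),
    by = "id"
  )
  out
}

#' EM estimation of two-locus haplotype frequencies
#'
#' Standard gene-counting EM on unphased two-locus genotypes: individuals
#' heterozygous at both loci have two possible phase resolutions, whose
#' posterior weights under the current haplotype frequencies drive the
#' expected haplotype counts. The log-likelihood is non-decreasing at
#' every iteration (asserted); convergence is declared when its change
#' falls below `tol`. The best solution over one linkage-equilibrium
#' initialization plus `restarts` random initializations is returned.
#'
#' @param genotypes tibble with columns `a_1`, `a_2`, `b_1`, `b_2` (see
#'   [two_locus_genotypes()] or [sim_two_locus()]).
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations per start.
#' @param restarts number of random restarts.
#' @param seed optional integer seed for the random restarts.
#' @param loci length-2 character vector of locus labels carried into the
#'   result.
#' @return object of class `hla_em`: a list with `haplotypes` (tibble
#'   `allele_a`, `allele_b`, `frequency`), `loglik`, `iterations`,
#'   `converged`, `n` (individuals), `loci` and `ll_trace` (the
#'   log-likelihood path of the winning start). Haplotype frequencies are
#'   non-negative, sum to one, and their margins reproduce the sample
#'   allele frequencies.
#' @export
em_haplotypes <- function(genotypes, tol = 1e-8, max_iter = 1e4,
                          restarts = 10, seed = NULL, loci = c("a", "b")) {
  g <- dplyr::filter(genotypes, !is.na(.data$a_1), !is.na(.data$b_1))
  n <- nrow(g)
  if (n < 2) abort("EM needs at least 2 individuals typed at both loci.")
  cls <- dplyr::count(g, .data$a_1, .data$a_2, .data$b_1, .data$b_2,
                      name = "count")

  hap_key <- function(a, b) paste(a, b, sep = "\r")
  # phase options per genotype class
  phase1 <- cbind(hap_key(cls$a_1, cls$b_1), hap_key(cls$a_2, cls$b_2))
  phase2 <- cbind(hap_key(cls$a_1, cls$b_2), hap_key(cls$a_2, cls$b_1))
  double_het <- cls$a_1 != cls$a_2 & cls$b_1 != cls$b_2
  haps <- unique(c(phase1, phase2[double_het, ]))
  H <- length(haps)
  p1a <- match(phase1[, 1], haps)
  p1b <- match(phase1[, 2], haps)
  p2a <- match(phase2[, 1], haps)
  p2b <- match(phase2[, 2], haps)
  mult1 <- ifelse(p1a == p1b, 1, 2)
  mult2 <- ifelse(p2a == p2b, 1, 2)

  run_em <- function(h) {
    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      w1 <- mult1 * h[p1a] * h[p1b]
      w2 <- ifelse(double_het, mult2 * h[p2a] * h[p2b], 0)
      tot <- w1 + w2
      if (any(tot <= 0)) {
        # a genotype class with zero likelihood under h: dead start
        return(list(h = h, loglik = -Inf, iterations = iter,
                    converged = FALSE, ll_trace = ll_trace))
      }
      ll <- sum(cls$count * log(tot))
      if (ll < ll_old - 1e-7) {
        abort("EM log-likelihood decreased; this should be impossible.")
      }
      ll_trace[iter] <- ll
      # expected haplotype counts
      e <- numeric(H)
      r1 <- cls$count * w1 / tot
      r2 <- cls$count * w2 / tot
      for (i in seq_len(nrow(cls))) {
        e[p1a[i]] <- e[p1a[i]] + r1[i]
        e[p1b[i]] <- e[p1b[i]] + r1[i]
        if (double_het[i]) {
          e[p2a[i]] <- e[p2a[i]] + r2[i]
          e[p2b[i]] <- e[p2b[i]] + r2[i]
        }
      }
      h_new <- e / (2 * n)
      if (abs(ll - ll_old) < tol) {
        converged <- TRUE
        h <- h_new
        break
      }
      if (iter >= max_iter) break
      h <- h_new
      ll_old <- ll
    }
    list(h = h, loglik = ll, iterations = iter, converged = converged,
         ll_trace = ll_trace)
  }

  # linkage-equilibrium initialization from the marginal allele counts
  split_key <- function(k) do.call(rbind, strsplit(k, "\r", fixed = TRUE))
  hk <- split_key(haps)
  fa <- table(c(cls$a_1[rep(seq_len(nrow(cls)), cls$count)],
                cls$a_2[rep(seq_len(nrow(cls)), cls$count)]))
  fb <- table(c(cls$b_1[rep(seq_len(nrow(cls)), cls$count)],
                cls$b_2[rep(seq_len(nrow(cls)), cls$count)]))
  h_le <- as.numeric(fa[hk[, 1]] / sum(fa)) * as.numeric(fb[hk[, 2]] / sum(fb))
  h_le <- h_le / sum(h_le)

  inits <- c(list(h_le), with_seed(seed, purrr::map(seq_len(restarts), function(i) {
    x <- rgamma(H, shape = 1)
    x / sum(x)
  })))
  runs <- purrr::map(inits, run_em)
  best <- runs[[which.max(purrr::map_dbl(runs, "loglik"))]]
  if (!best$converged) {
    warn("EM did not converge within max_iter; best estimate returned.")
  }
  structure(list(
    haplotypes = tibble::tibble(allele_a = hk[, 1], allele_b = hk[, 2],
                                frequency = best$h),
    loglik = best$loglik, iterations = best$iterations,
    converged = best$converged, n = n, loci = loci,
    ll_trace = best$ll_trace
  ), class = "hla_em")
}

#' @export
print.hla_em <- function(x, ...) {
  cat("Two-locus EM haplotype fit (", x$loci[1], " x ", x$loci[2], ")\n",
      "  individuals: ", x$n, ", haplotypes: ", nrow(x$haplotypes),
      ", logLik: ", format(x$loglik, digits = 6),
      ", iterations: ", x$iterations,
      if (x$converged) " (converged)" else " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Tidy a two-locus EM haplotype fit
#'
#' @param x an `hla_em` object.
#' @param ... unused.
#' @return the haplotype tibble `allele_a`, `allele_b`, `frequency`,
#'   sorted by decreasing frequency.
#' @export
tidy.hla_em <- function(x, ...) {
  dplyr::arrange(x$haplotypes, dplyr::desc(.data$frequency))
}

#' One-row summary of a two-locus EM haplotype fit
#'
#' @param x an `hla_em` object.
#' @param ... unused.
#' @return tibble `loglik`, `iterations`, `converged`, `n_haplotypes`,
#'   `n_ind`.
#' @export
glance.hla_em <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, iterations = x$iterations,
                 converged = x$converged, n_haplotypes = nrow(x$haplotypes),
                 n_ind = x$n)
}

#' Allele-specific heterozygosity (ASH)
#'
#' The heterozygosity of the partner-locus alleles found on haplotypes
#' carrying a conditioned allele `a`:
#' \deqn{ASH(a) = 1 - \sum_b \left(\frac{h_{ab}}{p_a}\right)^2,}
#' the plug-in heterozygosity of the conditional partner-allele
#' distribution. ASH is 0 exactly when the allele rides a single
#' haplotype background — the signature of a young (or recently selected)
#' allele — and approaches `1 - 1/m` for an allele equally spread over
#' `m` partner haplotypes.
#'
#' @param haps an `hla_em` object or a haplotype tibble (`allele_a`,
#'   `allele_b`, `frequency`).
#' @param allele the conditioned allele.
#' @param conditioned which side the conditioned allele is on: `"a"` or
#'   `"b"`.
#' @return one-row tibble `allele`, `frequency` (of the conditioned
#'   allele), `ash`, `n_partners`.
#' @export
ash <- function(haps, allele, conditioned = c("a", "b")) {
  conditioned <- match.arg(conditioned)
  h <- if (inherits(haps, "hla_em")) haps$haplotypes else haps
  own <- if (conditioned == "a") h$allele_a else h$allele_b
  hh <- h$frequency[own == allele]
  p <- sum(hh)
  if (p <= 0) abort(paste0("Conditioned allele ", allele, " has frequency 0."))
  tibble::tibble(
    allele = allele, frequency = p,
    ash = 1 - sum((hh / p)^2),
    n_partners = sum(hh > 0)
  )
}

#' ASH summarized by allele category and frequency stratum
#'
#' Runs the two-locus EM in every population and locus pair, computes
#' ASH for each conditioned allele, attaches its classification category
#' and its frequency in that population, and averages ASH with equal
#' allele weight: per conditioned locus and category (pooled over partner
#' loci and populations), and per frequency stratum and category pooled
#' over all loci. Strata follow the conventional bounds: (0.05, 0.10] and
#' above 0.10; the per-locus rows include alleles above the lower bound.
#'
#' @param cohort long genotype tibble.
#' @param classification tibble from [classify_alleles()].
#' @param loci loci to pair (default all four).
#' @param strata numeric lower bounds of the frequency strata (the first
#'   is also the inclusion floor).
#' @param em_args list of arguments passed on to [em_haplotypes()].
#' @param seed optional integer seed for the EM restarts.
#' @return list with `alleles` (one row per conditioned allele x
#'   population x partner locus: `population`, `conditioned_locus`,
#'   `partner_locus`, `allele`, `frequency`, `category`, `ash`),
#'   `by_locus` (mean ASH per conditioned locus x category) and
#'   `by_stratum` (mean ASH per stratum x category over all loci).
#' @export
ash_by_category <- function(cohort, classification, loci = hla_loci(),
                            strata = c(0.05, 0.10),
                            em_args = list(restarts = 2), seed = NULL) {
  pops <- unique(cohort$population)
  pairs <- utils::combn(intersect(loci, unique(cohort$locus)), 2)
  seeds <- derive_seeds(seed, length(pops) * ncol(pairs))
  rows <- list()
  si <- 0
  for (pop in pops) {
    for (pc in seq_len(ncol(pairs))) {
      si <- si + 1
      l1 <- pairs[1, pc]
      l2 <- pairs[2, pc]
      g <- two_locus_genotypes(cohort, pop, c(l1, l2))
      if (nrow(g) < 2) next
      fit <- do.call(em_haplotypes,
                     c(list(genotypes = g, seed = seeds[[si]], loci = c(l1, l2)),
                       em_args))
      h <- fit$haplotypes
      for (side in c("a", "b")) {
        cond_locus <- if (side == "a") l1 else l2
        part_locus <- if (side == "a") l2 else l1
        own <- if (side == "a") h$allele_a else h$allele_b
        for (al in unique(own)) {
          a <- ash(h, al, conditioned = side)
          rows[[length(rows) + 1]] <- tibble::tibble(
            population = pop, conditioned_locus = cond_locus,
            partner_locus = part_locus, allele = al,
            frequency = a$frequency, ash = a$ash
          )
        }
      }
    }
  }
  alleles <- dplyr::bind_rows(rows)
  alleles <- dplyr::left_join(
    alleles, classification[, c("allele", "category")], by = "allele"
  )
  alleles$category[is.na(alleles$category)] <- "other"
  floor1 <- strata[1]
  alleles$stratum <- cut(alleles$frequency,
                         breaks = c(strata, 1),
                         labels = c(paste0("(", strata[1], ",", strata[2], "]"),
                                    paste0(">", strata[2])),
                         include.lowest = FALSE)
  eligible <- dplyr::filter(alleles, .data$frequency > floor1)
  by_locus <- dplyr::summarise(
    dplyr::group_by(eligible, locus = .data$conditioned_locus, .data$category),
    mean_ash = mean(.data$ash), n_alleles = dplyr::n(), .groups = "drop"
  )
  by_stratum <- dplyr::summarise(
    dplyr::group_by(eligible, .data$stratum, .data$category),
    mean_ash = mean(.data$ash), n_alleles = dplyr::n(), .groups = "drop"
  )
  list(alleles = alleles, by_locus = by_locus, by_stratum = by_stratum)
}
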