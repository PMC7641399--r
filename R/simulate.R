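#' Simulation parameters for a serial-founder cohort
#'
#' Bundles the knobs of [sim_cohort()]. The defaults emulate the study
#' design that motivates the package: one Siberian source population and
#' 23 Native American populations in four regions (NAM, MEA, SAA, SAL)
#' founded serially along a colonization route, typed at four HLA-like
#' loci and a panel of 678 genome-wide microsatellites, with a worldwide
#' reference panel, planted endemic and large-frequency-difference (LFD)
#' alleles, and linkage disequilibrium between the first two HLA loci.
#'
#' @param theta named numeric: scaled mutation rate per HLA locus for the
#'   infinite-alleles (Ewens) draw that creates the source allele pool.
#'   Higher values of theta give more alleles; the default makes B the
#'   most polymorphic locus, as in real HLA data.
#' @param founder_chain tibble with columns `region`, `n_b` (bottleneck
#'   size, diploid individuals), `g` (generations of drift at that size)
#'   and `n_pops` (populations founded in the region). Regions are founded
#'   serially in row order, each from the previous region's allele pool.
#' @param individuals_per_pop diploid sample size per population.
#' @param n_msat number of microsatellite markers (study panel: 678).
#' @param mu_msat per-copy per-generation stepwise mutation rate.
#' @param planted_endemics tibble of alleles created by mutation after the
#'   split from the reference world: columns `locus`, `target_frequency`,
#'   `regions` (list-column of region labels carrying the allele). These
#'   alleles are absent from every unflagged reference population.
#' @param planted_lfd tibble of planted LFD alleles: columns `locus`,
#'   `native_frequency`, `ref_frequency` (present in the reference panel
#'   at least 3-fold rarer), `regions`.
#' @param ld_dprime association weight in `[0, 1]` coupling haplotypes at
#'   the first two loci; 0 gives linkage equilibrium.
#' @param n_ref_pops number of reference-panel populations (a scaled-down
#'   stand-in for a worldwide meta-analysis; configurable).
#' @param n_ref_flagged how many reference populations are flagged as
#'   migrant/uncertain-origin (these carry planted endemic alleles, so the
#'   exclusion of flagged populations is exercised).
#' @param ref_concentration Dirichlet concentration scaling for
#'   reference-population frequencies around the source frequencies.
#' @param g_pop generations of extra drift when each population is founded
#'   from its predecessor within the region chain.
#' @param seq_length length of simulated allele sequences.
#' @param seq_mode `"balanced_clades"` or `"star"` (see [sim_sequences()]).
#' @param seed integer seed; identical parameters and seed give identical
#'   output.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(theta = c(A = 6, B = 14, C = 6, DRB1 = 7),
                       founder_chain = tibble::tibble(
                         region = c("SIB", "NAM", "MEA", "SAA", "SAL"),
                         n_b = c(400, 150, 90, 60, 35),
                         g = c(4L, 8L, 8L, 8L, 8L),
                         n_pops = c(1L, 3L, 6L, 4L, 10L)
                       ),
                       individuals_per_pop = 20L,
                       n_msat = 678L,
                       mu_msat = 1e-3,
                       planted_endemics = tibble::tibble(
                         locus = c("B", "B", "A", "C"),
                         target_frequency = c(0.15, 0.06, 0.05, 0.03),
                         regions = list(c("MEA", "SAA", "SAL"), "SAL", "SAA", "MEA")
                       ),
                       planted_lfd = tibble::tibble(
                         locus = c("A", "B", "DRB1"),
                         native_frequency = c(0.20, 0.25, 0.30),
                         ref_frequency = c(0.03, 0.04, 0.05),
                         regions = list(
                           c("NAM", "MEA", "SAA", "SAL"),
                           c("NAM", "MEA", "SAA", "SAL"),
                           c("NAM", "MEA", "SAA", "SAL")
                         )
                       ),
                       ld_dprime = 0.5,
                       n_ref_pops = 50L,
                       n_ref_flagged = 3L,
                       ref_concentration = 60,
                       g_pop = 3L,
                       seq_length = 400L,
                       seq_mode = c("balanced_clades", "star"),
                       seed = NULL) {
  stopifnot(all(theta >= 0), nrow(founder_chain) >= 1, all(founder_chain$n_b >= 1))
  stopifnot(ld_dprime >= -1, ld_dprime <= 1)
  bad_region <- setdiff(founder_chain$region, region_labels())
  if (length(bad_region)) {
    abort(paste0("founder_chain regions must come from ",
                 paste(region_labels(), collapse = ", ")))
  }
  params <- list(
    theta = theta, founder_chain = founder_chain,
    individuals_per_pop = as.integer(individuals_per_pop),
    n_msat = as.integer(n_msat), mu_msat = mu_msat,
    planted_endemics = planted_endemics, planted_lfd = planted_lfd,
    ld_dprime = ld_dprime, n_ref_pops = as.integer(n_ref_pops),
    n_ref_flagged = as.integer(n_ref_flagged),
    ref_concentration = ref_concentration, g_pop = as.integer(g_pop),
    seq_length = as.integer(seq_length), seq_mode = match.arg(seq_mode),
    seed = seed
  )
  structure(params, class = "sim_params")
}

# --- infinite-alleles (Chinese restaurant) draw ------------------------------

# Sequential Ewens-sampling-formula construction: gamete j starts a new
# allele with probability theta / (theta + j - 1).
crp_labels <- function(theta, n) {
  labels <- integer(n)
  counts <- integer(n)
  labels[1] <- 1L
  counts[1] <- 1L
  k <- 1L
  if (n >= 2) {
    for (j in 2:n) {
      if (theta > 0 && runif(1) < theta / (theta + j - 1)) {
        k <- k + 1L
        labels[j] <- k
      } else {
        labels[j] <- sample.int(k, 1L, prob = counts[seq_len(k)])
      }
      counts[labels[j]] <- counts[labels[j]] + 1L
    }
  }
  labels
}

hla_allele_names <- function(locus, k) {
  sprintf("%s*%02d:%02d", locus, (seq_len(k) - 1L) %/% 99L + 1L,
          (seq_len(k) - 1L) %% 99L + 1L)
}

#' Simulate one neutral population under the infinite-alleles model
#'
#' Draws an allele configuration of `n` gametes from the Ewens sampling
#' formula (sequential construction) and forms genotypes by random pairing
#' of gametes without replacement, so the sample is at Hardy-Weinberg
#' proportions by construction. This is the null model of the
#' Ewens-Watterson neutrality test.
#'
#' @param theta scaled mutation rate (`theta = 0` gives a monomorphic
#'   sample).
#' @param n even number of gametes (chromosomes), at least 2.
#' @param seed optional integer seed.
#' @param locus,population labels attached to the output.
#' @return long genotype tibble (`population`, `id`, `locus`, `allele_1`,
#'   `allele_2`) with `n / 2` individuals.
#' @export
sim_neutral_population <- function(theta, n, seed = NULL, locus = "A",
                                   population = "pop1") {
  stopifnot(n >= 2, n %% 2 == 0, theta >= 0)
  with_seed(seed, {
    labels <- crp_labels(theta, n)
    alleles <- hla_allele_names(locus, max(labels))[labels]
    perm <- sample.int(n)
    a1 <- alleles[perm[seq(1, n, by = 2)]]
    a2 <- alleles[perm[seq(2, n, by = 2)]]
    canonicalize_genotypes(tibble::tibble(
      population = population,
      id = paste0(population, "_", seq_len(n / 2)),
      locus = locus,
      allele_1 = a1, allele_2 = a2
    ))
  })
}

# --- Wright-Fisher drift on frequency matrices -------------------------------

# One multinomial Wright-Fisher generation applied column-wise to an
# S x M frequency matrix (M loci sharing one population size), via
# sequential conditional binomials so that all M loci are drawn in S
# vectorized rbinom calls.
wf_step <- function(freq, n2) {
  S <- nrow(freq)
  M <- ncol(freq)
  counts <- matrix(0L, S, M)
  rem <- rep.int(n2, M)
  remp <- rep(1, M)
  for (s in seq_len(S)) {
    p <- ifelse(remp > 1e-12, pmin(freq[s, ] / remp, 1), 0)
    cs <- rbinom(M, rem, p)
    counts[s, ] <- cs
    rem <- rem - cs
    remp <- remp - freq[s, ]
  }
  sweep(counts, 2, n2, "/")
}

wf_drift <- function(freq, n2, generations) {
  for (g in seq_len(generations)) freq <- wf_step(freq, n2)
  freq
}

# Deterministic stepwise-mutation flow on a size grid: a fraction mu of
# copies moves to an adjacent size class (half up, half down; reflected at
# the grid boundary).
msat_mutation_step <- function(freq, mu) {
  S <- nrow(freq)
  up <- rbind(0, freq[-S, , drop = FALSE])
  down <- rbind(freq[-1, , drop = FALSE], 0)
  out <- (1 - mu) * freq + mu / 2 * (up + down)
  out[1, ] <- out[1, ] + mu / 2 * freq[1, ]
  out[S, ] <- out[S, ] + mu / 2 * freq[S, ]
  out
}

# --- allele sequences --------------------------------------------------------

#' Simulate aligned allele sequences for one locus
#'
#' Two regimes of genealogical depth are available. `"star"` hangs every
#' allele off a common ancestor with a few private substitutions each, so
#' sampled variation is dominated by rare variants (the negative Tajima's D
#' regime when allele frequencies are skewed). `"balanced_clades"` splits
#' the alleles into two deep clades separated by many substitutions, so a
#' sample containing both clades at appreciable frequency carries many
#' intermediate-frequency variants (the positive-D regime characteristic
#' of long-term balancing selection).
#'
#' @param alleles character vector of allele names (`k >= 2`), or a single
#'   integer k (names are generated).
#' @param length alignment length `L >= k`.
#' @param mode `"star"` or `"balanced_clades"`.
#' @param seed optional integer seed.
#' @param n_private private substitutions per allele.
#' @param n_clade_diffs substitutions separating the two clades
#'   (balanced_clades mode).
#' @param locus locus label.
#' @return tibble `locus`, `allele`, `sequence` (aligned, equal lengths).
#' @export
sim_sequences <- function(alleles, length = 400L,
                          mode = c("balanced_clades", "star"), seed = NULL,
                          n_private = 2L, n_clade_diffs = 24L, locus = "A") {
  mode <- match.arg(mode)
  if (is.numeric(alleles) && length(alleles) == 1L) {
    alleles <- hla_allele_names(locus, alleles)
  }
  k <- base::length(alleles)
  stopifnot(k >= 2, length >= k)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    root <- sample(bases, length, replace = TRUE)
    n_fixed <- if (mode == "balanced_clades") min(n_clade_diffs, length) else 0L
    need <- n_fixed + k * n_private
    pos_pool <- sample.int(length, min(need, length))
    clade_pos <- if (n_fixed > 0) pos_pool[seq_len(n_fixed)] else integer(0)
    priv_pool <- if (n_fixed > 0) pos_pool[-seq_len(n_fixed)] else pos_pool
    seqs <- matrix(root, nrow = k, ncol = length, byrow = TRUE)
    if (mode == "balanced_clades") {
      clade2 <- seq_len(k) > ceiling(k / 2)
      for (p in clade_pos) {
        seqs[clade2, p] <- sample(setdiff(bases, root[p]), 1)
      }
    }
    # private substitutions, disjoint positions across alleles where possible
    pp <- split(
      priv_pool[seq_len(min(base::length(priv_pool), k * n_private))],
      rep(seq_len(k), each = n_private)[seq_len(min(base::length(priv_pool), k * n_private))]
    )
    for (i in seq_along(pp)) {
      for (p in pp[[i]]) {
        seqs[as.integer(names(pp)[i]), p] <- sample(setdiff(bases, seqs[as.integer(names(pp)[i]), p]), 1)
      }
    }
    tibble::tibble(
      locus = locus, allele = alleles,
      sequence = apply(seqs, 1, paste, collapse = "")
    )
  })
}

# --- two-locus haplotype structure -------------------------------------------

# Comonotone coupling of two discrete margins (mass matched along sorted
# cumulative distributions).
comonotone_coupling <- function(p, q) {
  K <- length(p)
  L <- length(q)
  M <- matrix(0, K, L)
  i <- 1L
  j <- 1L
  pi <- p[1]
  qj <- q[1]
  while (i <= K && j <= L) {
    m <- min(pi, qj)
    M[i, j] <- M[i, j] + m
    pi <- pi - m
    qj <- qj - m
    if (pi <= 1e-12) {
      i <- i + 1L
      if (i <= K) pi <- p[i]
    }
    if (qj <= 1e-12) {
      j <- j + 1L
      if (j <= L) qj <- q[j]
    }
  }
  M
}

# Haplotype frequency matrix with a controlled level of association.
# For two biallelic loci this is exactly Lewontin's D': h = p q' + D with
# D = d_prime * D_max. For more alleles, |d_prime| mixes the independence
# coupling with a comonotone (or antitone, for negative d_prime) coupling.
two_locus_haplotype_matrix <- function(p_a, p_b, d_prime) {
  stopifnot(abs(sum(p_a) - 1) < 1e-8, abs(sum(p_b) - 1) < 1e-8,
            abs(d_prime) <= 1)
  if (length(p_a) == 2L && length(p_b) == 2L) {
    d_max <- if (d_prime >= 0) {
      min(p_a[1] * p_b[2], p_a[2] * p_b[1])
    } else {
      min(p_a[1] * p_b[1], p_a[2] * p_b[2])
    }
    d <- d_prime * d_max
    h <- outer(p_a, p_b)
    h[1, 1] <- h[1, 1] + d
    h[2, 2] <- h[2, 2] + d
    h[1, 2] <- h[1, 2] - d
    h[2, 1] <- h[2, 1] - d
    if (any(h < -1e-12)) abort("Infeasible d_prime for the given margins.")
    h[h < 0] <- 0
    return(h)
  }
  lam <- abs(d_prime)
  M <- if (d_prime >= 0) {
    comonotone_coupling(p_a, p_b)
  } else {
    comonotone_coupling(p_a, rev(p_b))[, rev(seq_along(p_b)), drop = FALSE]
  }
  (1 - lam) * outer(p_a, p_b) + lam * M
}

#' Simulate an unphased two-locus genotype sample with known haplotypes
#'
#' Haplotype frequencies are `h = p_a p_b' + D`, with the disequilibrium
#' scaled by `d_prime` (exactly Lewontin's D' when both loci are
#' biallelic; an association weight mixing independence with a comonotone
#' coupling otherwise). Genotypes are formed by random union of gametes
#' drawn from `h`, so the truth is fully known for testing EM haplotype
#' estimation and allele-specific heterozygosity.
#'
#' @param p_a,p_b named allele-frequency vectors (names become allele
#'   labels; unnamed vectors get generated HLA-style names).
#' @param d_prime association level in `[-1, 1]`.
#' @param n number of diploid individuals.
#' @param seed optional integer seed.
#' @param loci length-2 character vector of locus labels.
#' @return list with `genotypes` (tibble `id`, `a_1`, `a_2`, `b_1`, `b_2`),
#'   `haplotypes` (tibble `allele_a`, `allele_b`, `frequency` — the truth),
#'   and `loci`.
#' @export
sim_two_locus <- function(p_a, p_b, d_prime = 0, n = 100L, seed = NULL,
                          loci = c("A", "B")) {
  if (is.null(names(p_a))) names(p_a) <- hla_allele_names(loci[1], length(p_a))
  if (is.null(names(p_b))) names(p_b) <- hla_allele_names(loci[2], length(p_b))
  h <- two_locus_haplotype_matrix(p_a, p_b, d_prime)
  hap_tbl <- tibble::tibble(
    allele_a = rep(names(p_a), times = length(p_b)),
    allele_b = rep(names(p_b), each = length(p_a)),
    frequency = as.vector(h)
  )
  with_seed(seed, {
    idx <- sample.int(nrow(hap_tbl), 2L * n, replace = TRUE, prob = hap_tbl$frequency)
    g1 <- idx[seq(1, 2 * n, by = 2)]
    g2 <- idx[seq(2, 2 * n, by = 2)]
    genotypes <- tibble::tibble(
      id = paste0("ind_", seq_len(n)),
      a_1 = pmin(hap_tbl$allele_a[g1], hap_tbl$allele_a[g2]),
      a_2 = pmax(hap_tbl$allele_a[g1], hap_tbl$allele_a[g2]),
      b_1 = pmin(hap_tbl$allele_b[g1], hap_tbl$allele_b[g2]),
      b_2 = pmax(hap_tbl$allele_b[g1], hap_tbl$allele_b[g2])
    )
    list(genotypes = genotypes,
         haplotypes = dplyr::filter(hap_tbl, .data$frequency > 0),
         loci = loci)
  })
}

# --- full cohort -------------------------------------------------------------

rdirichlet_one <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

# Insert a planted allele into a frequency vector at a target frequency.
plant_allele <- function(freq, allele, target) {
  if (sum(target) >= 1) abort("Planted target frequencies exceed 1 at a locus.")
  c(freq * (1 - sum(target)), setNames(target, allele))
}

#' Simulate a serial-founder cohort with planted ground truth
#'
#' Generates, under one seed, everything the analysis pipeline consumes:
#' an HLA-like genotype cohort, a microsatellite panel for the same
#' individuals, a worldwide reference allele-frequency panel, aligned
#' allele sequences, a region map with a route ordering, and a truth
#' record listing every planted allele.
#'
#' Demography is a chain of founder events: each region in
#' `params$founder_chain` is founded from the previous region's allele
#' pool and drifts for `g` generations at bottleneck size `n_b`
#' (Wright-Fisher binomial resampling of frequencies); populations within
#' a region are founded serially from one another with `g_pop` extra
#' generations each. Expected heterozygosity therefore declines along the
#' chain, at both HLA-like and microsatellite loci. Endemic alleles arise
#' by mutation after the split from the reference world and are absent
#' from every unflagged reference population; LFD alleles are present in
#' the reference panel at a several-fold lower frequency. Planted alleles
#' at the second locus are locked onto as few partner haplotypes at the
#' first locus as the margins allow, mimicking the reduced haplotype
#' diversity of young alleles.
#'
#' @param params a [sim_params()] object.
#' @return list of class `hla_sim` with elements `cohort` (long genotype
#'   tibble), `msat` (long microsatellite tibble), `reference` (reference
#'   panel tibble), `regions` (population, region, ordering), `sequences`
#'   (allele sequence map), and `truth` (list: `planted` tibble,
#'   `population_frequencies`, `region_chain`).
#' @export
sim_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, sim_cohort_impl(params))
}

sim_cohort_impl <- function(params) {
  chain <- params$founder_chain
  loci <- hla_loci()
  n_ind <- params$individuals_per_pop

  # population bookkeeping
  pops <- tibble::tibble(
    population = unlist(purrr::map2(chain$region, chain$n_pops, function(r, np) {
      paste0(r, "_", seq_len(np))
    })),
    region = rep(chain$region, chain$n_pops)
  )
  pops$ordering <- seq_len(nrow(pops))

  # --- HLA loci: source pools and reference panel ---
  source_freqs <- purrr::map(setNames(loci, loci), function(lc) {
    labels <- crp_labels(params$theta[[lc]], 1000L)
    counts <- tabulate(labels)
    setNames(counts / sum(counts), hla_allele_names(lc, length(counts)))
  })

  # planted alleles get fresh names beyond the source pool
  planted <- list()
  plant_name <- function(lc, tag, i) sprintf("%s*%d:%02d", lc, 90 + i %% 9, i %% 90 + 1)
  pe <- params$planted_endemics
  if (!is.null(pe) && nrow(pe)) {
    for (i in seq_len(nrow(pe))) {
      planted[[length(planted) + 1]] <- tibble::tibble(
        locus = pe$locus[i],
        allele = sprintf("%s*%02d:%02d", pe$locus[i], 90L, i),
        category = "endemic",
        target_frequency = pe$target_frequency[i],
        ref_frequency = 0,
        regions = list(pe$regions[[i]])
      )
    }
  }
  pl <- params$planted_lfd
  if (!is.null(pl) && nrow(pl)) {
    for (i in seq_len(nrow(pl))) {
      planted[[length(planted) + 1]] <- tibble::tibble(
        locus = pl$locus[i],
        allele = sprintf("%s*%02d:%02d", pl$locus[i], 95L, i),
        category = "LFD",
        target_frequency = pl$native_frequency[i],
        ref_frequency = pl$ref_frequency[i],
        regions = list(pl$regions[[i]])
      )
    }
  }
  planted <- if (length(planted)) dplyr::bind_rows(planted) else
    tibble::tibble(locus = character(), allele = character(),
                   category = character(), target_frequency = numeric(),
                   ref_frequency = numeric(), regions = list())

  # reference panel: Dirichlet scatter around source; LFD alleles included
  # at ref_frequency; endemic alleles only in flagged (migrant) populations
  ref_rows <- list()
  n_flag <- min(params$n_ref_flagged, params$n_ref_pops)
  for (j in seq_len(params$n_ref_pops)) {
    flagged <- j <= n_flag
    for (lc in loci) {
      f <- source_freqs[[lc]]
      pl_lc <- dplyr::filter(planted, .data$locus == lc)
      add <- numeric(0)
      if (nrow(pl_lc)) {
        for (i in seq_len(nrow(pl_lc))) {
          if (pl_lc$category[i] == "LFD") {
            add[pl_lc$allele[i]] <- pl_lc$ref_frequency[i]
          } else if (flagged) {
            # recent migrants carry some endemic copies
            add[pl_lc$allele[i]] <- pl_lc$target_frequency[i] / 2
          }
        }
      }
      if (length(add)) f <- c(f * (1 - sum(add)), add)
      fj <- rdirichlet_one(params$ref_concentration * length(f) * f / sum(f))
      keep <- fj > 0
      ref_rows[[length(ref_rows) + 1]] <- tibble::tibble(
        population = paste0("ref_", j),
        allele = names(f)[keep],
        frequency = fj[keep],
        n = 100,
        migrant = flagged,
        uncertain_origin = FALSE
      )
    }
  }
  reference <- dplyr::bind_rows(ref_rows)

  # --- serial founder drift: region chain then population chain ---
  pop_freqs <- purrr::map(setNames(loci, loci), function(lc) list())
  for (lc in loci) {
    f <- source_freqs[[lc]]
    for (r in seq_len(nrow(chain))) {
      f <- as.vector(wf_drift(matrix(f, ncol = 1), 2L * chain$n_b[r], chain$g[r]))
      names(f) <- names(source_freqs[[lc]])[seq_along(f)]
      region <- chain$region[r]
      # plant alleles whose region set includes this region
      f_region <- f
      pl_here <- dplyr::filter(planted, .data$locus == lc,
                               purrr::map_lgl(.data$regions, ~ region %in% .x))
      if (nrow(pl_here)) {
        f_region <- plant_allele(f_region, pl_here$allele, pl_here$target_frequency)
      }
      fp <- f_region
      for (p in which(pops$region == region)) {
        fp <- as.vector(wf_drift(matrix(fp, ncol = 1), 2L * chain$n_b[r], params$g_pop))
        names(fp) <- names(f_region)
        pop_freqs[[lc]][[pops$population[p]]] <- fp
      }
    }
  }

  # --- genotype sampling; loci 1 and 2 are coupled, the rest independent ---
  cohort_rows <- list()
  for (p in seq_len(nrow(pops))) {
    pop <- pops$population[p]
    ids <- paste0(pop, "_", seq_len(n_ind))
    f_a <- pop_freqs[[loci[1]]][[pop]]
    f_b <- pop_freqs[[loci[2]]][[pop]]
    f_a <- f_a[f_a > 0]
    f_b <- f_b[f_b > 0]
    f_a <- f_a / sum(f_a)
    f_b <- f_b / sum(f_b)
    if (length(f_a) >= 2 && length(f_b) >= 2) {
      # planted alleles at locus 2 ride one (or as few as possible)
      # partner haplotypes; margins at both loci are preserved by building
      # the coupling of the remaining mass on the residual margins
      locked <- intersect(names(f_b), planted$allele)
      h <- matrix(0, length(f_a), length(f_b),
                  dimnames = list(names(f_a), names(f_b)))
      f_a_res <- f_a
      for (b in locked) {
        q <- f_b[b]
        while (q > 1e-12) {
          j <- which.max(f_a_res)
          take <- min(q, f_a_res[j])
          h[j, b] <- h[j, b] + take
          f_a_res[j] <- f_a_res[j] - take
          q <- q - take
        }
      }
      free_b <- setdiff(names(f_b), locked)
      rest <- sum(f_b[free_b])
      if (rest > 1e-12 && sum(f_a_res > 1e-12) >= 1 && length(free_b) >= 1) {
        if (length(free_b) == 1L || sum(f_a_res > 1e-12) == 1L) {
          h[, free_b] <- h[, free_b] + outer(f_a_res / rest, f_b[free_b])
        } else {
          h[, free_b] <- h[, free_b] + rest * two_locus_haplotype_matrix(
            f_a_res / rest, f_b[free_b] / rest, params$ld_dprime
          )
        }
      }
      idx <- sample.int(length(h), 2L * n_ind, replace = TRUE, prob = as.vector(h))
      ia <- (idx - 1L) %% length(f_a) + 1L
      ib <- (idx - 1L) %/% length(f_a) + 1L
      gam_a <- names(f_a)[ia]
      gam_b <- names(f_b)[ib]
    } else {
      gam_a <- sample(names(f_a), 2L * n_ind, replace = TRUE, prob = f_a)
      gam_b <- sample(names(f_b), 2L * n_ind, replace = TRUE, prob = f_b)
    }
    odd <- seq(1, 2 * n_ind, by = 2)
    even <- odd + 1L
    for (lc in loci) {
      gam <- if (lc == loci[1]) gam_a else if (lc == loci[2]) gam_b else NULL
      if (is.null(gam)) {
        f <- pop_freqs[[lc]][[pop]]
        f <- f[f > 0]
        gam <- sample(names(f), 2L * n_ind, replace = TRUE, prob = f / sum(f))
      }
      cohort_rows[[length(cohort_rows) + 1]] <- tibble::tibble(
        population = pop, id = ids, locus = lc,
        allele_1 = pmin(gam[odd], gam[even]),
        allele_2 = pmax(gam[odd], gam[even])
      )
    }
  }
  cohort <- dplyr::arrange(dplyr::bind_rows(cohort_rows),
                           .data$population, .data$id, .data$locus)

  # --- microsatellites: size-grid drift along the same chain ---
  grid <- 10:45
  S <- length(grid)
  M <- params$n_msat
  F0 <- matrix(0, S, M)
  for (m in seq_len(M)) {
    w <- sample(3:8, 1)
    start <- sample.int(S - w, 1)
    a <- rdirichlet_one(rep(2, w))
    F0[start:(start + w - 1), m] <- a
  }
  msat_rows <- list()
  Freg <- F0
  for (r in seq_len(nrow(chain))) {
    for (g in seq_len(chain$g[r])) {
      Freg <- msat_mutation_step(Freg, params$mu_msat)
      Freg <- wf_step(Freg, 2L * chain$n_b[r])
    }
    Fp <- Freg
    for (p in which(pops$region == chain$region[r])) {
      Fp <- wf_drift(Fp, 2L * chain$n_b[r], params$g_pop)
      counts <- wf_step(Fp, 2L * n_ind) * 2L * n_ind  # sample gamete counts
      pop <- pops$population[p]
      sizes <- matrix(0L, 2L * n_ind, M)
      for (m in seq_len(M)) {
        gam <- rep.int(grid, round(counts[, m]))
        sizes[, m] <- gam[sample.int(length(gam))]
      }
      odd <- seq(1, 2 * n_ind, by = 2)
      msat_rows[[length(msat_rows) + 1]] <- tibble::tibble(
        population = pop,
        id = rep(paste0(pop, "_", seq_len(n_ind)), times = M),
        marker = rep(paste0("ms", seq_len(M)), each = n_ind),
        size_1 = as.vector(pmin(sizes[odd, ], sizes[odd + 1L, ])),
        size_2 = as.vector(pmax(sizes[odd, ], sizes[odd + 1L, ]))
      )
    }
  }
  msat <- dplyr::bind_rows(msat_rows)

  # --- allele sequences for every allele seen in the cohort ---
  seq_rows <- purrr::map(setNames(loci, loci), function(lc) {
    alle <- sort(unique(c(cohort$allele_1[cohort$locus == lc],
                          cohort$allele_2[cohort$locus == lc])))
    if (length(alle) < 2L) {
      # locus fixed cohort-wide under strong drift: one constant sequence
      return(tibble::tibble(
        locus = lc, allele = alle,
        sequence = paste(sample(c("A", "C", "G", "T"), params$seq_length,
                                replace = TRUE), collapse = "")
      ))
    }
    sim_sequences(alle, length = max(params$seq_length, length(alle) * 4L),
                  mode = params$seq_mode, locus = lc)
  })
  sequences <- dplyr::bind_rows(seq_rows)

  structure(list(
    cohort = cohort,
    msat = msat,
    reference = reference,
    regions = pops,
    sequences = sequences,
    truth = list(
      planted = planted,
      source_frequencies = source_freqs,
      population_frequencies = pop_freqs,
      region_chain = chain
    )
  ), class = "hla_sim")
}
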