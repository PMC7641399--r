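# Small in-code fixtures shared across tests.

# Build a long-format genotype tibble from a list of c(allele_1, allele_2)
# pairs for one population and locus.
make_genotypes <- function(pairs, locus = "A", population = "pop1",
                           id_prefix = population) {
  tibble::tibble(
    population = population,
    id = paste0(id_prefix, "_", seq_along(pairs)),
    locus = locus,
    allele_1 = pmin(vapply(pairs, `[`, "", 1), vapply(pairs, `[`, "", 2)),
    allele_2 = pmax(vapply(pairs, `[`, "", 1), vapply(pairs, `[`, "", 2))
  )
}

# A tiny two-population, two-locus cohort.
toy_cohort <- function() {
  dplyr::bind_rows(
    make_genotypes(list(c("A*01:01", "A*01:01"), c("A*01:01", "A*02:01")),
                   locus = "A", population = "p1"),
    make_genotypes(list(c("B*39:06", "B*39:06"), c("B*15:04", "B*39:06")),
                   locus = "B", population = "p1"),
    make_genotypes(list(c("A*02:01", "A*02:01"), c("A*02:01", "A*03:01")),
                   locus = "A", population = "p2"),
    make_genotypes(list(c("B*15:04", "B*15:04"), c("B*15:04", "B*15:04")),
                   locus = "B", population = "p2")
  )
}

# Genotype counts for one population where genotype proportions follow
# exact HWP for two alleles at frequency 1/2 (n individuals).
hwp_perfect_pairs <- function(n) {
  n_hom <- round(n / 4)
  n_het <- n - 2 * n_hom
  c(
    replicate(n_hom, c("A*01:01", "A*01:01"), simplify = FALSE),
    replicate(n_het, c("A*01:01", "A*02:01"), simplify = FALSE),
    replicate(n_hom, c("A*02:01", "A*02:01"), simplify = FALSE)
  )
}

# Fast sim parameters for pipeline-level tests.
small_sim_params <- function(seed = 1, ...) {
  sim_params(
    founder_chain = tibble::tibble(
      region = c("SIB", "NAM", "MEA", "SAA", "SAL"),
      n_b = c(400, 150, 90, 60, 35),
      g = c(4L, 6L, 6L, 6L, 6L),
      n_pops = c(1L, 2L, 2L, 2L, 3L)
    ),
    individuals_per_pop = 15L,
    n_msat = 60L,
    n_ref_pops = 25L,
    seed = seed,
    ...
  )
}
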