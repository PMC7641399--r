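# Pairwise AMOVA F_ST / R_ST and the empirical Z_ST standardization.
#
# AMOVA is applied at the haplotype (chromosome) level: the 2n typed
# chromosomes of each population are the units, and the squared distance
# between two chromosomes is 0/1 allele identity for F_ST or the squared
# allele-size difference for R_ST. With two populations the two-level
# variance-component decomposition gives
#   F_ST = sigma2_among / (sigma2_among + sigma2_within).
# All pairwise sums of squared distances reduce to allele-count
# arithmetic, so no distance matrix is ever formed.

# Variance components from within-population and total sums of squares.
amova_fst <- function(ssd_wp, ssd_total, n_sizes) {
  N <- sum(n_sizes)
  P <- length(n_sizes)
  ssd_ap <- ssd_total - ssd_wp
  msd_ap <- ssd_ap / (P - 1)
  msd_wp <- ssd_wp / (N - P)
  n_c <- (N - sum(n_sizes^2) / N) / (P - 1)
  sigma_a <- (msd_ap - msd_wp) / n_c
  sigma_w <- msd_wp
  denom <- sigma_a + sigma_w
  if (abs(denom) < 1e-300) return(list(fst = 0, degenerate = TRUE))
  list(fst = sigma_a / denom, degenerate = FALSE)
}

# F_ST between two populations from allele-copy counts (named vectors).
fst_from_counts <- function(c1, c2) {
  alleles <- union(names(c1), names(c2))
  x1 <- setNames(numeric(length(alleles)), alleles)
  x2 <- x1
  x1[names(c1)] <- c1
  x2[names(c2)] <- c2
  n1 <- sum(x1)
  n2 <- sum(x2)
  stopifnot(n1 >= 2, n2 >= 2)
  ssd_wp <- (n1^2 - sum(x1^2)) / (2 * n1) + (n2^2 - sum(x2^2)) / (2 * n2)
  xt <- x1 + x2
  N <- n1 + n2
  ssd_total <- (N^2 - sum(xt^2)) / (2 * N)
  amova_fst(ssd_wp, ssd_total, c(n1, n2))
}

# R_ST between two populations from copy counts over integer allele sizes.
rst_from_counts <- function(c1, c2, sizes) {
  n1 <- sum(c1)
  n2 <- sum(c2)
  s1 <- sum(sizes * c1)
  s2 <- sum(sizes * c2)
  q1 <- sum(sizes^2 * c1)
  q2 <- sum(sizes^2 * c2)
  ssd_wp <- (n1 * q1 - s1^2) / (2 * n1) + (n2 * q2 - s2^2) / (2 * n2)
  N <- n1 + n2
  ssd_total <- (N * (q1 + q2) - (s1 + s2)^2) / (2 * N)
  amova_fst(ssd_wp, ssd_total, c(n1, n2))
}

#' Pairwise AMOVA F_ST between populations at each HLA locus
#'
#' Haplotype-level AMOVA with allele-identity distance (0 if the two
#' chromosomes carry the same two-field allele, 1 otherwise). Negative
#' estimates are retained as computed (they arise for essentially
#' undifferentiated pairs). A pair in which both populations are
#' monomorphic for the same allele has no variance to partition; it is
#' returned as `fst = 0` with `degenerate = TRUE`.
#'
#' @param cohort long genotype tibble.
#' @param loci loci to include (default: all present).
#' @return tibble `locus`, `pop1`, `pop2`, `fst`, `degenerate`, symmetric
#'   in the two populations (each unordered pair appears once).
#' @export
pairwise_fst <- function(cohort, loci = NULL) {
  freqs <- allele_frequencies(cohort, loci = loci)
  out <- list()
  for (lc in unique(freqs$locus)) {
    fl <- dplyr::filter(freqs, .data$locus == lc)
    counts <- split(setNames(fl$count, fl$allele), fl$population)
    pops <- names(counts)
    if (length(pops) < 2) next
    for (i in seq_len(length(pops) - 1)) {
      for (j in (i + 1):length(pops)) {
        r <- fst_from_counts(counts[[i]], counts[[j]])
        out[[length(out) + 1]] <- tibble::tibble(
          locus = lc, pop1 = pops[i], pop2 = pops[j],
          fst = r$fst, degenerate = r$degenerate
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

# Per-population x marker allele-size count matrices on a common grid.
msat_count_array <- function(msat) {
  sizes <- sort(unique(c(msat$size_1, msat$size_2)))
  markers <- sort(unique(msat$marker))
  pops <- sort(unique(msat$population))
  arr <- array(0L, dim = c(length(pops), length(markers), length(sizes)),
               dimnames = list(pops, markers, sizes))
  long <- tidyr::pivot_longer(msat, cols = c("size_1", "size_2"),
                              values_to = "size", names_to = NULL)
  long <- dplyr::filter(long, !is.na(.data$size))
  tab <- dplyr::count(long, .data$population, .data$marker, .data$size)
  idx <- cbind(match(tab$population, pops), match(tab$marker, markers),
               match(tab$size, sizes))
  arr[idx] <- tab$n
  list(arr = arr, sizes = sizes, markers = markers, pops = pops)
}

#' Per-marker microsatellite F_ST (or R_ST) vectors for every population pair
#'
#' For each unordered population pair, computes the per-marker F_ST
#' (allele-identity distance) or R_ST (squared allele-size distance)
#' across the whole microsatellite panel: the genome-wide background
#' distribution that [zst()] standardizes against. Markers monomorphic
#' within a pair carry no differentiation signal and contribute 0 (flagged
#' via the `degenerate` count), keeping the panel denominator stable.
#'
#' @param msat long microsatellite tibble.
#' @param measure `"fst"` (identity) or `"rst"` (squared size difference).
#' @return tibble `pop1`, `pop2`, `marker`, `fst`.
#' @export
msat_pairwise_fst <- function(msat, measure = c("fst", "rst")) {
  measure <- match.arg(measure)
  ca <- msat_count_array(msat)
  arr <- ca$arr
  sizes <- ca$sizes
  P <- length(ca$pops)
  M <- length(ca$markers)
  out <- vector("list", P * (P - 1) / 2)
  ii <- 0
  for (i in seq_len(P - 1)) {
    for (j in (i + 1):P) {
      C1 <- arr[i, , ]
      C2 <- arr[j, , ]
      n1 <- rowSums(C1)
      n2 <- rowSums(C2)
      if (measure == "fst") {
        ssd_wp <- (n1^2 - rowSums(C1^2)) / (2 * n1) +
          (n2^2 - rowSums(C2^2)) / (2 * n2)
        Ct <- C1 + C2
        N <- n1 + n2
        ssd_total <- (N^2 - rowSums(Ct^2)) / (2 * N)
      } else {
        s1 <- C1 %*% sizes
        s2 <- C2 %*% sizes
        q1 <- C1 %*% sizes^2
        q2 <- C2 %*% sizes^2
        ssd_wp <- as.vector((n1 * q1 - s1^2) / (2 * n1) +
                              (n2 * q2 - s2^2) / (2 * n2))
        N <- n1 + n2
        ssd_total <- as.vector((N * (q1 + q2) - (s1 + s2)^2) / (2 * N))
      }
      N <- n1 + n2
      ssd_ap <- ssd_total - ssd_wp
      msd_wp <- ssd_wp / (N - 2)
      n_c <- (N - (n1^2 + n2^2) / N)
      sigma_a <- (ssd_ap - msd_wp) / n_c
      denom <- sigma_a + msd_wp
      fst <- ifelse(abs(denom) < 1e-300, 0, sigma_a / denom)
      ii <- ii + 1
      out[[ii]] <- tibble::tibble(
        pop1 = ca$pops[i], pop2 = ca$pops[j], marker = ca$markers, fst = fst
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Mean pairwise F_ST within and between regions
#'
#' Averages pairwise F_ST over all population pairs falling within one
#' region or spanning a given pair of regions, per locus; the `mean_HLA`
#' rows average the per-locus means.
#'
#' @param fst_tbl tibble from [pairwise_fst()] (or any tibble with
#'   `locus`, `pop1`, `pop2`, `fst`).
#' @param regions region map tibble.
#' @param exclude populations excluded from the averages (default none).
#' @return tibble `comparison` (`"within"` or `"between"`), `regions`
#'   (e.g. `"MEA"` or `"MEA:NAM"`), `locus`, `mean_fst`, `n_pairs`. Empty
#'   cells are absent from the output.
#' @export
region_summary <- function(fst_tbl, regions, exclude = character()) {
  d <- dplyr::filter(fst_tbl, !(.data$pop1 %in% exclude),
                     !(.data$pop2 %in% exclude))
  d <- dplyr::left_join(d, setNames(regions[, c("population", "region")],
                                    c("pop1", "region1")), by = "pop1")
  d <- dplyr::left_join(d, setNames(regions[, c("population", "region")],
                                    c("pop2", "region2")), by = "pop2")
  ra <- pmin(d$region1, d$region2)
  rb <- pmax(d$region1, d$region2)
  d$comparison <- ifelse(ra == rb, "within", "between")
  d$regions <- ifelse(ra == rb, ra, paste0(ra, ":", rb))
  per_locus <- dplyr::summarise(
    dplyr::group_by(d, .data$comparison, .data$regions, .data$locus),
    mean_fst = mean(.data$fst), n_pairs = dplyr::n(), .groups = "drop"
  )
  hla_mean <- dplyr::summarise(
    dplyr::group_by(per_locus, .data$comparison, .data$regions),
    locus = "mean_HLA", mean_fst = mean(.data$mean_fst),
    n_pairs = .data$n_pairs[1], .groups = "drop"
  )
  dplyr::arrange(dplyr::bind_rows(per_locus, hla_mean),
                 .data$comparison, .data$regions, .data$locus)
}

#' Standardized differentiation Z_ST with an empirical p-value
#'
#' Places each HLA pairwise F_ST in the context of the genome-wide
#' microsatellite background for the same population pair:
#' \deqn{Z_{ST} = \frac{F_{ST}^{HLA} - \overline{F_{ST}^{msat}}}{SD(F_{ST}^{msat})}}
#' The empirical p-value is the proportion of microsatellite markers with
#' an F_ST strictly higher than the HLA value, so its resolution is one
#' over the panel size. A `mean_HLA` row per pair standardizes the mean
#' of the per-locus HLA F_ST values.
#'
#' @param hla_fst tibble from [pairwise_fst()] on the HLA cohort.
#' @param msat_fst tibble from [msat_pairwise_fst()] on the same
#'   populations.
#' @return tibble `pop1`, `pop2`, `locus`, `fst`, `msat_mean`, `msat_sd`,
#'   `zst`, `p_empirical`, `n_msat`.
#' @export
zst <- function(hla_fst, msat_fst) {
  bg <- dplyr::summarise(
    dplyr::group_by(msat_fst, .data$pop1, .data$pop2),
    msat_mean = mean(.data$fst), msat_sd = sd(.data$fst),
    n_msat = dplyr::n(), .groups = "drop"
  )
  if (any(bg$msat_sd == 0)) abort("Zero SD in a microsatellite F_ST vector.")
  if (any(bg$n_msat < 2)) abort("Microsatellite vector needs >= 2 markers.")
  mean_rows <- dplyr::summarise(
    dplyr::group_by(hla_fst, .data$pop1, .data$pop2),
    locus = "mean_HLA", fst = mean(.data$fst), .groups = "drop"
  )
  h <- dplyr::bind_rows(hla_fst[, c("pop1", "pop2", "locus", "fst")], mean_rows)
  h <- dplyr::inner_join(h, bg, by = c("pop1", "pop2"))
  exceed <- purrr::map2_dbl(
    paste(h$pop1, h$pop2, sep = "\r"), h$fst,
    function(key, f) {
      v <- msat_fst$fst[paste(msat_fst$pop1, msat_fst$pop2, sep = "\r") == key]
      mean(v > f)
    }
  )
  h$zst <- (h$fst - h$msat_mean) / h$msat_sd
  h$p_empirical <- exceed
  dplyr::arrange(h, .data$pop1, .data$pop2, .data$locus)
}

#' Aggregate Z_ST empirical p-values by region pair
#'
#' Averages `-log(p)` (natural log) of the per-pair empirical p-values
#' within each region pair and locus; `-log(p) = 3` corresponds
#' approximately to the 0.05 level. Empirical p-values of zero are floored
#' at half the panel resolution before taking logs.
#'
#' @param zst_tbl tibble from [zst()].
#' @param regions region map tibble.
#' @param exclude populations to exclude.
#' @return tibble `regions`, `locus`, `mean_neglog_p`, `mean_zst`,
#'   `n_pairs`.
#' @export
zst_region_summary <- function(zst_tbl, regions, exclude = character()) {
  d <- dplyr::filter(zst_tbl, !(.data$pop1 %in% exclude),
                     !(.data$pop2 %in% exclude))
  d <- dplyr::left_join(d, setNames(regions[, c("population", "region")],
                                    c("pop1", "region1")), by = "pop1")
  d <- dplyr::left_join(d, setNames(regions[, c("population", "region")],
                                    c("pop2", "region2")), by = "pop2")
  ra <- pmin(d$region1, d$region2)
  rb <- pmax(d$region1, d$region2)
  d$region_pair <- ifelse(ra == rb, ra, paste0(ra, ":", rb))
  d$p_floor <- pmax(d$p_empirical, 0.5 / d$n_msat)
  out <- dplyr::summarise(
    dplyr::group_by(d, regions = .data$region_pair, .data$locus),
    mean_neglog_p = mean(-log(.data$p_floor)),
    mean_zst = mean(.data$zst),
    n_pairs = dplyr::n(), .groups = "drop"
  )
  out
}
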