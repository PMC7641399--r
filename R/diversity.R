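#' Sample heterozygosity and allele counts per population and locus
#'
#' Heterozygosity is the unbiased estimator
#' \deqn{H = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right),}
#' where the `n/(n-1)` factor corrects for sampling `n` chromosomes (the
#' convention of standard HLA summary-statistics software). Set
#' `unbiased = FALSE` for the plug-in gene diversity `1 - sum(p^2)`.
#'
#' @param freqs allele-frequency tibble from [allele_frequencies()].
#' @param unbiased apply the `n/(n-1)` small-sample correction (default).
#' @return tibble `population`, `locus`, `n`, `k` (distinct alleles),
#'   `H`. `H = 0` exactly when the sample is monomorphic.
#' @export
heterozygosity <- function(freqs, unbiased = TRUE) {
  if (nrow(freqs) == 0L) abort("Empty frequency table.")
  out <- dplyr::summarise(
    dplyr::group_by(freqs, .data$population, .data$locus),
    n = .data$n[1],
    k = dplyr::n(),
    H = 1 - sum(.data$frequency^2),
    .groups = "drop"
  )
  if (any(out$n < 2)) abort("Heterozygosity needs n >= 2 chromosomes.")
  if (unbiased) out$H <- out$H * out$n / (out$n - 1)
  out
}

#' Mean microsatellite heterozygosity per population
#'
#' Computes per-marker sample heterozygosity (same estimator as
#' [heterozygosity()]) from allele sizes and averages over markers.
#'
#' @param msat long microsatellite tibble (see [read_msat_panel()]).
#' @param unbiased apply the `n/(n-1)` correction per marker.
#' @return tibble `population`, `H_msat`, `n_markers`.
#' @export
msat_heterozygosity <- function(msat, unbiased = TRUE) {
  long <- tidyr::pivot_longer(msat, cols = c("size_1", "size_2"),
                              values_to = "size", names_to = NULL)
  long <- dplyr::filter(long, !is.na(.data$size))
  per_marker <- dplyr::summarise(
    dplyr::group_by(long, .data$population, .data$marker),
    n = dplyr::n(),
    H = 1 - sum((tabulate(factor(.data$size)) / dplyr::n())^2),
    .groups = "drop"
  )
  if (unbiased) per_marker$H <- per_marker$H * per_marker$n / (per_marker$n - 1)
  dplyr::summarise(dplyr::group_by(per_marker, .data$population),
    H_msat = mean(.data$H), n_markers = dplyr::n(), .groups = "drop"
  )
}

#' Correlation between HLA and microsatellite heterozygosity across populations
#'
#' Pearson correlation (with its two-sided p-value) between two
#' per-population diversity vectors, e.g. mean HLA heterozygosity against
#' mean microsatellite heterozygosity. A strong positive correlation
#' indicates that demographic history, rather than locus-specific
#' selection, drives among-population diversity differences.
#'
#' @param x,y numeric vectors over the same populations (length >= 3).
#' @return one-row tibble `estimate`, `statistic`, `p.value`, `n`.
#' @export
population_level_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) abort("Need at least 3 populations.")
  if (var(x) == 0 || var(y) == 0) abort("Zero variance in one of the vectors.")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate),
                 statistic = unname(ct$statistic),
                 p.value = ct$p.value, n = length(x))
}

#' Pairwise regional contrasts in heterozygosity (ANOVA + Tukey HSD)
#'
#' One-way ANOVA of per-population heterozygosity on region, followed by
#' Tukey's honestly-significant-difference intervals over all region
#' pairs. The Aché population is an extreme diversity outlier and is
#' excluded by default from regional summaries (set `exclude = NULL` to
#' keep it).
#'
#' @param h tibble with columns `population` and a diversity column named
#'   by `value`.
#' @param regions region map tibble (`population`, `region`).
#' @param value name of the diversity column in `h`.
#' @param exclude populations dropped before testing (default `"Ache"`).
#' @param include_regions regions entering the ANOVA (default the four
#'   Native American regions).
#' @return tibble `contrast`, `diff`, `lwr`, `upr`, `p.adj` (Tukey
#'   adjusted).
#' @export
regional_contrasts <- function(h, regions, value = "H",
                               exclude = "Ache",
                               include_regions = native_regions()) {
  d <- dplyr::inner_join(h, regions, by = "population")
  d <- dplyr::filter(d, !(.data$population %in% exclude),
                     .data$region %in% include_regions)
  counts <- table(d$region)
  singletons <- names(counts)[counts < 2]
  if (length(singletons)) {
    warn(paste0("Region(s) with a single population skipped: ",
                paste(singletons, collapse = ", ")))
    d <- dplyr::filter(d, !(.data$region %in% singletons))
  }
  if (dplyr::n_distinct(d$region) < 2) abort("Need at least 2 regions with >= 2 populations.")
  d$region <- factor(d$region)
  if (var(d[[value]]) == 0) {
    # no variation at all: every contrast is exactly null
    pairs <- utils::combn(levels(d$region), 2)
    return(tibble::tibble(
      contrast = paste(pairs[2, ], pairs[1, ], sep = "-"),
      diff = 0, lwr = 0, upr = 0, p.adj = 1
    ))
  }
  fit <- aov(stats::reformulate("region", response = value), data = d)
  tk <- TukeyHSD(fit)$region
  tibble::tibble(
    contrast = rownames(tk),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p.adj = tk[, "p adj"]
  )
}

#' Per-individual zygosity at HLA loci and microsatellites
#'
#' For each individual: the number of typed HLA loci at which they are
#' homozygous (0-4), the proportion of microsatellite markers at which
#' they are homozygous, and the class label 0 / 1 / 2+ used for the
#' class-trend analysis.
#'
#' @param cohort long genotype tibble.
#' @param msat long microsatellite tibble (same individual ids).
#' @return tibble `population`, `id`, `hla_hom_count`, `hla_typed`,
#'   `msat_hom_prop`, `class` (factor "0", "1", "2+").
#' @export
individual_zygosity <- function(cohort, msat) {
  hla <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(cohort, !is.na(.data$allele_1)),
                    .data$population, .data$id),
    hla_hom_count = sum(.data$allele_1 == .data$allele_2),
    hla_typed = dplyr::n(), .groups = "drop"
  )
  ms <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(msat, !is.na(.data$size_1)),
                    .data$population, .data$id),
    msat_hom_prop = mean(.data$size_1 == .data$size_2), .groups = "drop"
  )
  out <- dplyr::inner_join(hla, ms, by = c("population", "id"))
  out$class <- factor(ifelse(out$hla_hom_count >= 2, "2+",
                             as.character(out$hla_hom_count)),
                      levels = c("0", "1", "2+"))
  out
}

#' Within-population association of HLA and microsatellite homozygosity
#'
#' Per population, a linear regression of the individual's proportion of
#' homozygous microsatellite markers on the individual's count of
#' homozygous HLA loci. Populations are flagged significant under a
#' Bonferroni threshold of `alpha / (number of populations tested)`;
#' a fixed printed threshold can be supplied instead via `threshold`.
#'
#' @param zygosity tibble from [individual_zygosity()].
#' @param alpha family-wise level for the Bonferroni threshold.
#' @param threshold optional fixed per-test threshold overriding the
#'   Bonferroni computation (e.g. `0.0025`).
#' @return tibble `population`, `slope`, `p.value`, `n`, `bonferroni`,
#'   `significant`.
#' @export
individual_level_association <- function(zygosity, alpha = 0.05,
                                         threshold = NULL) {
  fits <- dplyr::group_modify(
    dplyr::group_by(zygosity, .data$population),
    function(d, key) {
      if (var(d$hla_hom_count) == 0 || nrow(d) < 3) {
        return(tibble::tibble(slope = NA_real_, p.value = NA_real_, n = nrow(d)))
      }
      fit <- summary(lm(msat_hom_prop ~ hla_hom_count, data = d))
      tibble::tibble(slope = fit$coefficients["hla_hom_count", "Estimate"],
                     p.value = fit$coefficients["hla_hom_count", "Pr(>|t|)"],
                     n = nrow(d))
    }
  )
  fits <- dplyr::ungroup(fits)
  n_tested <- sum(!is.na(fits$p.value))
  thr <- if (is.null(threshold)) alpha / n_tested else threshold
  fits$bonferroni <- thr
  fits$significant <- !is.na(fits$p.value) & fits$p.value < thr
  fits
}

#' Regional trend in microsatellite homozygosity across HLA zygosity classes
#'
#' Within each region, tests whether the proportion of homozygous
#' microsatellite markers increases across the classes of individuals
#' with 0, 1, or 2+ homozygous HLA loci, by regressing the proportion on
#' class scores 0, 1, 2 (a linear-contrast trend test). Classes with no
#' individuals are merged upward with a warning.
#'
#' @param zygosity tibble from [individual_zygosity()].
#' @param regions region map tibble.
#' @return tibble `region`, `slope`, `p.value`, `n`, and per-class mean
#'   homozygosity columns `mean_0`, `mean_1`, `mean_2plus`.
#' @export
homozygosity_class_trend <- function(zygosity, regions) {
  d <- dplyr::inner_join(zygosity, regions, by = "population")
  out <- dplyr::group_modify(
    dplyr::group_by(d, .data$region),
    function(g, key) {
      present <- levels(g$class)[table(g$class) > 0]
      if (length(present) < length(levels(g$class))) {
        warn(paste0("Empty zygosity class in region ", key$region,
                    "; classes merged upward."))
      }
      score <- pmin(g$hla_hom_count, 2L)
      if (var(score) == 0) {
        return(tibble::tibble(slope = NA_real_, p.value = NA_real_, n = nrow(g),
                              mean_0 = NA_real_, mean_1 = NA_real_,
                              mean_2plus = NA_real_))
      }
      fit <- summary(lm(g$msat_hom_prop ~ score))
      cls_mean <- function(cl) {
        v <- g$msat_hom_prop[g$class == cl]
        if (length(v)) mean(v) else NA_real_
      }
      tibble::tibble(
        slope = fit$coefficients["score", "Estimate"],
        p.value = fit$coefficients["score", "Pr(>|t|)"],
        n = nrow(g),
        mean_0 = cls_mean("0"), mean_1 = cls_mean("1"), mean_2plus = cls_mean("2+")
      )
    }
  )
  dplyr::ungroup(out)
}
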