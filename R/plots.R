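# ggplot2 views of the main result types.

#' Heterozygosity along the colonization route
#'
#' Plots per-population heterozygosity against the route ordering
#' (least-cost-path rank), colored by region: the serial-founder
#' expectation is a decline with distance from the source.
#'
#' @param h tibble with `population` and a diversity column.
#' @param regions region map tibble with `ordering`.
#' @param value name of the diversity column.
#' @return a ggplot object.
#' @export
plot_heterozygosity_cline <- function(h, regions, value = "H") {
  d <- dplyr::inner_join(h, regions, by = "population")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ordering, y = .data[[value]],
                                  color = .data$region)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(group = 1), color = "grey60",
                       linewidth = 0.3) +
    ggplot2::labs(x = "route ordering (distance from source)",
                  y = "heterozygosity", color = "region") +
    ggplot2::theme_minimal()
}

#' Standardized differentiation by region pair
#'
#' Bar chart of the mean `-log(empirical p)` of Z_ST per region pair and
#' locus, with a reference line at 3 (approximately the 0.05 level).
#'
#' @param zst_region tibble from [zst_region_summary()].
#' @return a ggplot object.
#' @export
plot_zst <- function(zst_region) {
  ggplot2::ggplot(zst_region,
                  ggplot2::aes(x = .data$regions, y = .data$mean_neglog_p,
                               fill = .data$locus)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 3, linetype = "dashed") +
    ggplot2::labs(x = "region pair", y = "mean -log(empirical p)",
                  fill = "locus") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Haplotype frequency heatmap for an EM fit
#'
#' @param object an `hla_em` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.hla_em <- function(object, ...) {
  d <- dplyr::filter(object$haplotypes, .data$frequency > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$allele_b, y = .data$allele_a,
                                  fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = object$loci[2], y = object$loci[1],
                  fill = "frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
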