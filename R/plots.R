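#' Plot per-family variant burden
#'
#' Bars show family members carrying at least one variant; the line/points
#' overlay the size-normalized variant rate (total variants per member gene).
#'
#' @param rollup tibble from [family_rollup()].
#' @return a ggplot object.
#' @export
plot_family_variants <- function(rollup) {
  scale <- max(rollup$genes_with_variants, 1) /
    max(rollup$variants_per_gene, 1)
  ggplot2::ggplot(rollup, ggplot2::aes(x = stats::reorder(.data$family,
                                                          -.data$total_variants))) +
    ggplot2::geom_col(ggplot2::aes(y = .data$genes_with_variants),
                      fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$variants_per_gene * scale),
                        colour = "firebrick") +
    ggplot2::geom_line(ggplot2::aes(y = .data$variants_per_gene * scale,
                                    group = 1), colour = "firebrick") +
    ggplot2::scale_y_continuous(
      "genes with variants",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "variants per gene")
    ) +
    ggplot2::labs(x = "family") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the AAC histogram
#'
#' @param bins tibble from [bin_by_aac()]; tail bins are dropped (they
#'   overlap the closed bins).
#' @return a ggplot object.
#' @export
plot_aac_bins <- function(bins) {
  closed <- dplyr::filter(bins, !.data$tail)
  closed$bin <- factor(closed$bin, levels = closed$bin)
  ggplot2::ggplot(closed, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%.2f%%)", .data$n, .data$pct)),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = "amino acid changes per gene", y = "genes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for strain comparisons
#'
#' @param object a `strain_comparison` from [run_pipeline()].
#' @param type `"aac_bins"` (default) or `"families"`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.strain_comparison <- function(object, type = c("aac_bins", "families"),
                                       ...) {
  type <- match.arg(type)
  if (type == "families") {
    if (is.null(object$family_summary)) stopf("no family annotation in this run")
    plot_family_variants(object$family_summary)
  } else {
    plot_aac_bins(object$aac_bins)
  }
}
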