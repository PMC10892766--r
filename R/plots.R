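# ggplot2 figures for landscape summaries and association scans.

#' Manhattan plot of a CNVR association scan
#'
#' @param results A `cnvr_gwas` tibble.
#' @param cnvrs CNVR tibble with coordinates.
#' @param chroms Optional chromosome table (track order/extents).
#' @param threshold Optional p-value threshold drawn as a horizontal line;
#'   defaults to the Bonferroni threshold attached to `results`, if any.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, cnvrs, chroms = NULL, threshold = NULL) {
  md <- manhattan_qq_data(results, cnvrs, chroms)$manhattan
  threshold <- threshold %||% attr(results, "threshold")
  md$chrom <- factor(md$chrom, levels = unique(md$chrom))
  gg <- ggplot2::ggplot(md, ggplot2::aes(x = .data$pos_cum / 1e6,
                                         y = .data$neg_log10_p,
                                         colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::labs(x = "Cumulative position (Mb)",
                  y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold) && is.finite(threshold)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(threshold),
                                   linetype = "dashed")
  }
  gg
}

#' QQ plot of association p-values
#'
#' @inheritParams plot_manhattan
#' @return A ggplot object (expected vs observed -log10 p, with the identity
#'   line); the genomic inflation factor is shown in the subtitle.
#' @export
plot_qq <- function(results, cnvrs) {
  mq <- manhattan_qq_data(results, cnvrs)
  ggplot2::ggplot(mq$qq, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](italic(p))),
                  y = expression(Observed ~ -log[10](italic(p))),
                  subtitle = paste0("lambda_GC = ",
                                    signif(mq$lambda_gc, 3))) +
    ggplot2::theme_minimal()
}

#' @method autoplot cnvr_gwas
#' @export
autoplot.cnvr_gwas <- function(object, cnvrs, ...) {
  plot_manhattan(object, cnvrs, ...)
}

#' Genome track map of CNVRs by type
#'
#' One horizontal track per chromosome; segments colored loss (grey),
#' gain (red), mixed (blue).
#'
#' @param cnvrs CNVR tibble.
#' @param chroms Chromosome table.
#' @return A ggplot object.
#' @export
plot_cnvr_landscape <- function(cnvrs, chroms) {
  segs <- genome_track(cnvrs, chroms)
  backdrop <- tibble(
    chrom = factor(chroms$chrom, levels = chroms$chrom),
    length_mb = chroms$length / 1e6
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = backdrop,
      ggplot2::aes(x = 0, xend = .data$length_mb,
                   y = .data$chrom, yend = .data$chrom),
      linewidth = 0.3, colour = "grey85") +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$start_mb, xend = .data$end_mb,
                   y = .data$chrom, yend = .data$chrom,
                   colour = .data$type),
      linewidth = 3) +
    ggplot2::scale_colour_manual(
      values = c(loss = "grey40", gain = "red", mixed = "blue")) +
    ggplot2::labs(x = "Position (Mb)", y = "Chromosome", colour = "CNVR type") +
    ggplot2::theme_minimal()
}

#' Bar chart of the CNVR size distribution
#'
#' @param size_bins Output of [size_distribution()].
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(size_bins) {
  size_bins$bin <- factor(size_bins$bin, levels = size_bins$bin)
  ggplot2::ggplot(size_bins, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$percentage, "%")),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = "CNVR size (bp)", y = "Count") +
    ggplot2::theme_minimal()
}

#' Bar chart of the CNVR type distribution
#'
#' @param types Output of [type_distribution()].
#' @return A ggplot object.
#' @export
plot_type_distribution <- function(types) {
  ggplot2::ggplot(types, ggplot2::aes(x = .data$type, y = .data$n,
                                      fill = .data$type)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(
      values = c(loss = "grey40", gain = "red", mixed = "blue")) +
    ggplot2::labs(x = "CNVR type", y = "Count") +
    ggplot2::theme_minimal()
}
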