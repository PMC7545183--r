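#' Manhattan-style plot of a windowed scan
#'
#' One point per window along the genome, faceted by chromosome, with the
#' per-partition candidate thresholds drawn as dashed lines.
#'
#' @param track A window tibble (e.g. [scan_windows()] output).
#' @param stat Statistic column to plot (default `"fst"`).
#' @param quantile Top tail fraction for the threshold lines.
#' @return A ggplot object.
#' @export
plot_fst_scan <- function(track, stat = "fst", quantile = 0.05) {
  cand <- candidate_regions(track, stat = stat, quantile = quantile)
  thr <- dplyr::distinct(cand, .data$partition, .data$threshold)
  track$partition <- subgenome_partition(track$chrom)
  ggplot2::ggplot(track, ggplot2::aes(
    x = (.data$start + .data$end) / 2e6, y = .data[[stat]]
  )) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::geom_hline(
      data = thr |> left_join(
        dplyr::distinct(track, .data$partition), by = "partition"),
      ggplot2::aes(yintercept = .data$threshold),
      linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$partition),
      cols = ggplot2::vars(.data$chrom),
      scales = "free_x", space = "free_x"
    ) +
    ggplot2::labs(x = "position (Mb)", y = stat) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.window_track <- function(object, ...) plot_fst_scan(object, ...)

#' CNV-index track plot
#'
#' @param cnv Output of [cnv_index()].
#' @return A ggplot object.
#' @export
plot_cnv_track <- function(cnv) {
  ggplot2::ggplot(cnv, ggplot2::aes(
    x = (.data$start + .data$end) / 2e6, y = .data$cnv_index
  )) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(
      x = "position (Mb)",
      y = "CNV-index (NCN_DO - NCN_DE)"
    ) +
    ggplot2::theme_minimal()
}

#' Manhattan plot of mixed-model association results
#'
#' @param fit A `feralscan_mlm` from [mlm_association()].
#' @return A ggplot object with the Bonferroni threshold drawn.
#' @export
plot_gwas <- function(fit) {
  d <- tidy(fit)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$pos / 1e6, y = -log10(.data$p_value)
  )) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = -log10(fit$bonferroni),
      linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.feralscan_mlm <- function(object, ...) plot_gwas(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
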