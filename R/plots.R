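#' Volcano plot of haplotype-specific accessibility
#'
#' Absolute difference in percent accessible fibers between haplotypes
#' against -log10 p, with the nominal significance line and the BH
#' significance line (the largest p passing the FDR cut, when any peak
#' does).
#'
#' @param results Tibble from [haplotype_specific_accessibility()].
#' @param nominal_p Nominal significance level to draw.
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, nominal_p = 0.01) {
  df <- results
  df$neglog10p <- -log10(pmax(df$p_value, 1e-300))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$abs_delta,
                                         y = .data$neglog10p)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$fdr_sig),
                        alpha = 0.6, size = 0.9) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::geom_hline(yintercept = -log10(nominal_p),
                        linetype = "dashed", colour = "blue") +
    ggplot2::labs(x = "|Δ % accessible fibers| (H1 vs H2)",
                  y = expression(-log[10] ~ p),
                  colour = "BH significant") +
    ggplot2::theme_minimal()
  if (any(df$fdr_sig)) {
    gg <- gg + ggplot2::geom_hline(
      yintercept = -log10(max(df$p_value[df$fdr_sig])),
      linetype = "dashed", colour = "red")
  }
  gg
}

#' Swarm-style plot of regional accessibility imbalance
#'
#' Per-peak signed haplotype deltas jittered within region groups, the
#' view used to compare a candidate silenced region against the genomic
#' background.
#'
#' @param peak_deltas The `peak_deltas` table from
#'   [genome_imbalance_report()].
#' @return A ggplot object.
#' @export
plot_imbalance <- function(peak_deltas) {
  df <- peak_deltas[!is.na(peak_deltas$region), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$delta)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.5, size = 0.8) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.5, colour = "firebrick",
                          linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = NULL,
                  y = "Δ % accessible fibers (H1 - H2)") +
    ggplot2::theme_minimal()
}
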