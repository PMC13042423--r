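#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of a DEG signature
#'
#' @param object A [call_degs()] result.
#' @param ... Unused.
#' @return A ggplot: log2 fold change vs -log10 adjusted p, colored by call,
#'   with the calling thresholds drawn.
#' @method autoplot deg_signature
#' @export
autoplot.deg_signature <- function(object, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = -log10(pmax(.data$q, 1e-300)),
                                   color = .data$call)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$lfc_threshold, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = 2) +
    ggplot2::scale_color_manual(values = c(up = "#c0392b", down = "#2980b9", ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR", color = NULL) +
    ggplot2::theme_minimal()
}

#' Training-trace plot of a macrogene model
#'
#' @param object A [pretrain_macrogenes()] result.
#' @param ... Unused.
#' @return A ggplot of the reconstruction, similarity and total losses per
#'   step.
#' @method autoplot macrogene_model
#' @export
autoplot.macrogene_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, c("l_rc", "l_s", "total"),
                            names_to = "component", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$loss,
                                   color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = "loss", color = NULL) +
    ggplot2::theme_minimal()
}

#' Up-vs-down GSVA score scatter for a Tom-score result
#'
#' @param object A [compute_tom_scores()] result.
#' @param ... Unused.
#' @return A ggplot scatter of per-cell up vs down scores colored by Tom
#'   group, annotated with the Pearson correlation.
#' @method autoplot tom_result
#' @export
autoplot.tom_result <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$gsva_up, y = .data$gsva_down,
                               color = .data$group)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                      label = sprintf("r = %.2f", object$cor_updown)) +
    ggplot2::labs(x = "GSVA score (up signature)", y = "GSVA score (down signature)",
                  color = "Tom group") +
    ggplot2::theme_minimal()
}

#' QC metric distributions
#'
#' @param qc_table Output of [apply_qc_filter()] (or [compute_cell_qc()]).
#' @return A ggplot of the three QC metric distributions, colored by keep
#'   status when available.
#' @export
plot_qc <- function(qc_table) {
  df <- tidyr::pivot_longer(qc_table,
                            c("detected_genes", "total_umi", "mito_fraction"),
                            names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value))
  p <- if ("keep" %in% names(qc_table))
    p + ggplot2::geom_histogram(ggplot2::aes(fill = .data$keep), bins = 50)
  else p + ggplot2::geom_histogram(bins = 50)
  p + ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::theme_minimal()
}
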