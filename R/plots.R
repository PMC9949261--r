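#' Mean-variance plot with the NB model line
#'
#' Log-log scatter of empirical per-template variance against mean, with
#' the fitted `v = m + d m^2` curve and the Poisson `v = m` reference.
#'
#' @param mv A tibble from [mean_variance_table()].
#' @return A ggplot object.
#' @export
plot_mean_variance <- function(mv) {
  ggplot2::ggplot(mv, ggplot2::aes(x = .data$m_hat, y = .data$v_hat)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$v_model), colour = "red") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "empirical mean (log scale)",
                  y = "empirical variance (log scale)",
                  title = "Template count mean-variance relationship",
                  subtitle = "red: v = m + d m²; dashed: Poisson v = m") +
    ggplot2::theme_minimal()
}

#' Heatmap of signed V x J Pearson residuals
#'
#' Tiles ordered by the stored clustering orders; positive residuals
#' (over-represented primer pairs) in one colour, negative in the other.
#'
#' @param object A `vj_residuals` object (ideally after [cluster_order()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vj_residuals
#' @export
autoplot.vj_residuals <- function(object, ...) {
  long <- tidy(object)
  long$v_name <- factor(long$v_name,
                        levels = rownames(object$values)[object$row_order])
  long$j_name <- factor(long$j_name,
                        levels = colnames(object$values)[object$col_order])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$j_name, y = .data$v_name,
                                     fill = .data$residual)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = "J primer", y = "V primer", fill = "(O-E)/√E",
                  title = "Primer-pair dependence (signed Pearson residuals)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-sample template-count spread before and after normalization
#'
#' Box plots of template counts per sample, raw and normalized, on a log
#' scale -- the visual check that normalization compresses
#' template-to-template spread within each sample.
#'
#' @param x An `st_counts` tibble.
#' @param sf A `scaling_factors` tibble.
#' @return A ggplot object.
#' @export
plot_spread <- function(x, sf) {
  stopifnot(inherits(x, "st_counts"), inherits(sf, "scaling_factors"))
  m <- count_matrix(x)
  f <- sf$factor[match(seq_len(nrow(m)), sf$pair)]
  keep <- !is.na(f)
  raw_long <- tidyr::pivot_longer(
    tibble::as_tibble(m[keep, , drop = FALSE]),
    cols = dplyr::everything(), names_to = "sample", values_to = "count")
  norm_long <- tidyr::pivot_longer(
    tibble::as_tibble(m[keep, , drop = FALSE] / f[keep]),
    cols = dplyr::everything(), names_to = "sample", values_to = "count")
  long <- dplyr::bind_rows(
    dplyr::mutate(raw_long, stage = "raw"),
    dplyr::mutate(norm_long, stage = "normalized"))
  long$stage <- factor(long$stage, levels = c("raw", "normalized"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$count,
                                     fill = .data$stage)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sample", y = "template count (log scale)",
                  title = "Template-count spread before/after normalization") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
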