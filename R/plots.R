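# ggplot2 views of the result objects. These are deliberately plain
# renderings; publication heatmap aesthetics are left to the caller.

#' @method autoplot tss_diff_table
#' @export
autoplot.tss_diff_table <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(-"promoter_id", names_to = "offset",
                        values_to = "diff") |>
    dplyr::mutate(offset = as.integer(.data$offset),
                  promoter_id = factor(.data$promoter_id,
                                       levels = rev(object$promoter_id)))
  ggplot2::ggplot(long, ggplot2::aes(.data$offset, .data$promoter_id,
                                     fill = .data$diff)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "cyan3", mid = "white",
                                  high = "orange", na.value = "grey85") +
    ggplot2::labs(x = "window offset (nt, downstream positive)",
                  y = NULL, fill = "usage\ndifference",
                  title = attr(object, "source_label")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @method autoplot tss_corr
#' @export
autoplot.tss_corr <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(.data$library_a, .data$library_b,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(NA, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' @method autoplot tss_pca
#' @export
autoplot.tss_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2, label = .data$mutant)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * object$var_frac[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * object$var_frac[2])) +
    ggplot2::theme_minimal()
}

#' @method autoplot scan_outcome
#' @export
autoplot.scan_outcome <- function(object, ...) {
  ggplot2::ggplot(object$counts, ggplot2::aes(.data$offset, .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected), colour = "red") +
    ggplot2::labs(x = "window offset (nt)", y = "5' end count") +
    ggplot2::theme_minimal()
}

#' Bar plot of mutant-minus-WT bin differences
#'
#' @param diffs Output of [diff_bins()].
#' @return A ggplot object.
#' @export
plot_bin_differences <- function(diffs) {
  ggplot2::ggplot(diffs, ggplot2::aes(.data$bin_id, .data$diff)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$diff - .data$sd,
                                        ymax = .data$diff + .data$sd),
                           width = 0.25) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "TSS bin (upstream to downstream)",
                  y = "mutant - WT usage fraction") +
    ggplot2::theme_minimal()
}
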