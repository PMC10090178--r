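#' Plot a partition image, optionally with kept/removed segment centroids
#'
#' @param partition A `partition_image` or `rendered_partition`.
#' @param records Optional segment-record tibble; kept and removed segments
#'   are marked at their centroids.
#' @return A ggplot object.
#' @export
plot_partition <- function(partition, records = NULL) {
  img <- partition$image
  df <- tibble(row = rep(seq_len(nrow(img)), times = ncol(img)),
               col = rep(seq_len(ncol(img)), each = nrow(img)),
               gray = as.vector(img))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$gray)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(records) && nrow(records)) {
    p <- p + ggplot2::geom_point(
      data = records,
      ggplot2::aes(x = .data$col, y = .data$row, colour = .data$status),
      shape = 1, size = 2) +
      ggplot2::scale_colour_manual(values = c(kept = "#2ca02c",
                                              removed = "#d62728"))
  }
  p
}

#' Scatter plot of automated estimates against stereology counts
#'
#' One point per partition with the per-partition Spearman rank correlation
#' annotated; axes on a common linear scale.
#'
#' @param table Method table (columns `automated`, `manual`, `subregion`).
#' @return A ggplot object.
#' @export
plot_method_table <- function(table) {
  r <- suppressWarnings(cor.test(table$automated, table$manual,
                                 method = "spearman", exact = FALSE))
  ggplot2::ggplot(table, ggplot2::aes(x = .data$manual, y = .data$automated,
                                      colour = .data$subregion)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::labs(x = "Manual stereology count",
                  y = "Automated estimate",
                  subtitle = sprintf("Spearman r = %.2f", r$estimate)) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_method_table Box plots of Dice score groups.
#' @param object,... `autoplot` arguments.
#' @method autoplot mask_agreement
#' @export
autoplot.mask_agreement <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$comparison, y = .data$dice)) +
    ggplot2::geom_boxplot(width = 0.4) +
    ggplot2::geom_jitter(width = 0.05, alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Dice score") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_method_table Distribution of replicate fractionator
#'   estimates with the true count marked.
#' @method autoplot stereology_run
#' @export
autoplot.stereology_run <- function(object, ...) {
  p <- ggplot2::ggplot(object$replicates, ggplot2::aes(x = .data$N)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "Fractionator estimate N", y = "Replicates") +
    ggplot2::theme_minimal()
  if (!is.null(object$true_count))
    p <- p + ggplot2::geom_vline(xintercept = object$true_count,
                                 colour = "#d62728", linetype = 2)
  p
}
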