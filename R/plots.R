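#' Violin plot of per-cell zero fractions
#'
#' The per-cell distribution of zero fractions (optionally grouped by an
#' a priori cell annotation), the visual used to judge how badly dropout
#' hits RAS values before/after denoising.
#'
#' @param object a `sparsity_report`.
#' @param essential plot the essential-restricted fractions instead
#'   (default `FALSE`).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sparsity_report <- function(object, essential = FALSE, ...) {
  df <- object$per_cell
  ycol <- if (essential) "essential_zero_fraction" else "zero_fraction"
  if (essential && !"essential_zero_fraction" %in% names(df)) {
    stop_scflux("report has no essential-restricted fractions", class = "scflux_validation_error")
  }
  if (!"group" %in% names(df)) df$group <- "all cells"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data[[ycol]])) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.4, size = 0.6) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL,
                  y = if (essential) "zero RAS fraction (essential reactions)" else "zero fraction") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a clustering in PC space
#'
#' @param object a `cluster_result`.
#' @param known optional vector of known group labels to colour by instead
#'   of the cluster labels.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_result <- function(object, known = NULL, ...) {
  df <- tidy(object)
  df$colour <- if (is.null(known)) df$cluster else as.character(known)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2, colour = .data$colour)) +
    ggplot2::geom_point(size = 1.2, alpha = 0.8) +
    ggplot2::labs(x = "PC1", y = "PC2",
                  colour = if (is.null(known)) "cluster" else "group") +
    ggplot2::theme_minimal()
}

#' Histogram of pairwise Spearman correlations
#'
#' Distribution of the off-diagonal pairwise rank correlations of a RAS (or
#' flux) matrix — the diagnostic showing how denoising restores
#' between-reaction correlation structure.
#'
#' @param pairs tibble from [pairwise_spearman()], or a matrix-like object
#'   passed through it.
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_correlation_distribution <- function(pairs, ...) {
  if (!is.data.frame(pairs)) pairs <- pairwise_spearman(pairs)
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$rho)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey30") +
    ggplot2::labs(x = "pairwise Spearman correlation", y = "pairs") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
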