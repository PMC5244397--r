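#' @exportS3Method ggplot2::autoplot
autoplot.antdev_pca <- function(object, x = 1, y = 2, samples = NULL, ...) {
  xs <- paste0("PC", x)
  ys <- paste0("PC", y)
  dat <- object$scores
  if (!is.null(samples)) {
    dat <- dplyr::left_join(dat, samples, by = "sample_id")
  }
  ve <- object$variance$variance_explained
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data[[xs]], .data[[ys]])) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xs, 100 * ve[x]),
      y = sprintf("%s (%.1f%%)", ys, 100 * ve[y])
    ) +
    ggplot2::theme_minimal()
  if ("stage" %in% names(dat)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$stage), size = 3) +
      ggplot2::geom_text(ggplot2::aes(label = .data$sample_id),
                         vjust = -1, size = 3, show.legend = FALSE)
  } else {
    p + ggplot2::geom_point(size = 3) +
      ggplot2::geom_text(ggplot2::aes(label = .data$sample_id),
                         vjust = -1, size = 3)
  }
}

#' MA plot of a pairwise stage comparison
#'
#' @param comparison An `ma_comparison` tibble from [pairwise_ma()].
#' @param ... Unused.
#' @return A ggplot object: M versus A with significant genes
#'   highlighted.
#' @export
plot_ma <- function(comparison, ...) {
  ggplot2::ggplot(comparison, ggplot2::aes(.data$A, .data$M,
                                           colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(
      x = "A (mean log2 normalized expression)",
      y = sprintf("M (log2 %s / %s)", attr(comparison, "stage_b"),
                  attr(comparison, "stage_a")),
      colour = sprintf("p < %g", attr(comparison, "p_threshold"))
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ma_comparison <- function(object, ...) plot_ma(object, ...)

#' @exportS3Method ggplot2::autoplot
autoplot.profile_clusters <- function(object, profiles, ...) {
  stages <- setdiff(names(profiles), "gene_id")
  dat <- dplyr::left_join(profiles, object$assignments, by = "gene_id") |>
    tidyr::pivot_longer(dplyr::all_of(stages), names_to = "stage",
                        values_to = "expression") |>
    dplyr::mutate(stage = factor(.data$stage, levels = stages))
  ggplot2::ggplot(dat, ggplot2::aes(.data$stage, .data$expression,
                                    group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "stage", y = "log2 normalized expression") +
    ggplot2::theme_minimal()
}
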