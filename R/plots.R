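#' Plot a compartment eigenvector track
#'
#' @param object An `eigen_track`.
#' @param ... Unused.
#' @return A ggplot: per-bin eigenvector bars colored by A/B label,
#'   faceted by chromosome.
#' @export
autoplot.eigen_track <- function(object, ...) {
  df <- filter(as_tibble(object), !is.na(.data$e))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1e6, y = .data$e,
                                   fill = .data$label)) +
    ggplot2::geom_col(width = (df$end - df$start)[1] / 1e6) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(A = "#d73027", B = "#4575b4")) +
    ggplot2::labs(x = "position (Mb)", y = "eigenvector",
                  fill = "compartment") +
    ggplot2::theme_minimal()
}

#' Plot an APA aggregate
#'
#' @param apa_result Output of [apa()].
#' @return A ggplot heat map of the aggregate with the score in the title.
#' @export
plot_apa <- function(apa_result) {
  agg <- apa_result$aggregate
  h <- (nrow(agg) - 1) / 2
  df <- expand.grid(dx = -h:h, dy = -h:h)
  df$z <- as.vector(agg)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dx, y = .data$dy, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("APA score %.2f (n = %d)",
                                  apa_result$score, apa_result$n_sites),
                  x = "offset (bins)", y = "offset (bins)", fill = "mean z") +
    ggplot2::theme_minimal()
}

#' Plot replicate clustering
#'
#' @param rep_dist Output of [replicate_distances()].
#' @return A ggplot of the 2-D principal-coordinate embedding, colored by
#'   group when available.
#' @export
plot_replicates <- function(rep_dist) {
  df <- rep_dist$embedding
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::labs(x = "PCo1", y = "PCo2") +
    ggplot2::theme_minimal()
  if (!all(is.na(df$group))) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$group), size = 3)
  } else {
    p + ggplot2::geom_point(size = 3)
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
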