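#' Boxplot of shortest weighted path length by connection subtype
#'
#' Mirrors the subtype path-length comparison on the averaged healthy
#' control network: intramodular connections are topologically shortest,
#' cortico-striatal longest.
#'
#' @param atab An [atrophy_table()] (or any data frame with `subtype` and
#'   `L` columns).
#' @return A ggplot object.
#' @export
plot_subtype_lengths <- function(atab) {
  df <- as.data.frame(atab)
  df <- df[is.finite(df$L), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subtype, y = .data$L,
                                   fill = .data$subtype)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "shortest weighted path length") +
    ggplot2::theme_minimal()
}

#' Scatterplot of atrophy score against path length
#'
#' Per-connection group-averaged transformed atrophy score (cross-sectional
#' or longitudinal) against shortest weighted path length, coloured by
#' connection subtype, with a least-squares line.
#'
#' @param atab An [atrophy_table()].
#' @param score `"cross"` (baseline atrophy) or `"long"` (rate of atrophy).
#' @return A ggplot object.
#' @export
plot_length_atrophy <- function(atab, score = c("cross", "long")) {
  score <- match.arg(score)
  col <- paste0("score_", score)
  df <- as.data.frame(atab)
  df <- df[is.finite(df$L) & is.finite(df[[col]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$L, y = .data[[col]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$subtype), alpha = 0.6,
                        size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "black",
                         se = FALSE, linewidth = 0.5) +
    ggplot2::labs(x = "shortest weighted path length",
                  y = if (score == "cross") "transformed atrophy score"
                      else "transformed rate-of-atrophy score",
                  colour = "subtype") +
    ggplot2::theme_minimal()
}

#' Heatmap of the module co-assignment (agreement) matrix
#'
#' Regions are ordered by consensus module; block structure along the
#' diagonal indicates stable modules across Louvain runs.
#'
#' @param object A [consensus_partition()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.module_partition <- function(object, ...) {
  ord <- order(object$assignment$module)
  A <- object$agreement[ord, ord]
  df <- tidyr::expand_grid(row = seq_len(nrow(A)), col = seq_len(ncol(A)))
  df$agreement <- A[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$agreement)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "co-assignment",
                  title = paste0("consensus agreement (gamma = ",
                                 object$gamma, ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
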