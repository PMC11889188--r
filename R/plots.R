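# ggplot2 views of the analysis surfaces.

#' Plot a binned response curve
#' @param curve A `binned_curve` (or a named list of them to overlay).
#' @param show_excluded Draw excluded bins as hollow points.
#' @return A ggplot object.
#' @export
plot_binned_curve <- function(curve, show_excluded = FALSE) {
  curves <- if (inherits(curve, "binned_curve")) list(curve = curve) else curve
  df <- dplyr::bind_rows(lapply(curves, tibble::as_tibble), .id = "series")
  if (!show_excluded) df <- df[df$included, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$bin_mean,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$included)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(x = paste0(attr(curves[[1]], "condition"), " (",
                             attr(curves[[1]], "space"), ")"),
                  y = "mean score", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a pairwise condition grid
#' @param grid A `pair_grid`.
#' @return A ggplot object.
#' @export
plot_pair_grid <- function(grid) {
  df <- tibble::as_tibble(grid[grid$included, ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mid, y = .data$y_mid,
                                   fill = .data$mean_score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "#f7f7f7",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = paste0("z_", attr(grid, "condition_x")),
                  y = paste0("z_", attr(grid, "condition_y")),
                  fill = "mean score") +
    ggplot2::theme_minimal()
}

#' Plot a word-level severity-vs-sentiment scatter
#' @param scatter Output of [word_scatter()].
#' @param label_n Label the `label_n` most extreme tokens on each axis.
#' @return A ggplot object.
#' @export
plot_word_scatter <- function(scatter, label_n = 10L) {
  ext <- unique(c(order(scatter$severity)[seq_len(label_n)],
                  order(-scatter$severity)[seq_len(label_n)],
                  order(scatter$sentiment)[seq_len(label_n)],
                  order(-scatter$sentiment)[seq_len(label_n)]))
  ggplot2::ggplot(scatter, ggplot2::aes(x = .data$severity,
                                        y = .data$sentiment)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_text(data = scatter[ext, ],
                       ggplot2::aes(label = .data$token),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "weather severity valence", y = "sentiment valence") +
    ggplot2::theme_minimal()
}
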