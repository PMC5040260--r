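#' Conservation-agreement projection plot
#'
#' Plots every reference position in conservation-agreement space (x =
#' group-wise conservation, y = between-group agreement), colored by SDP
#' signal x - y; the bottom-right corner is maximal signal. Both the
#' all-groups and the support-only projections are shown as facets.
#'
#' @param object An `sdp_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sdp_ensemble
#' @export
autoplot.sdp_ensemble <- function(object, ...) {
  pos <- object$positions
  df <- bind_rows(
    tibble(position = pos$position, x = pos$x_all, y = pos$y_all,
           variant = "all groups"),
    tibble(position = pos$position, x = pos$x_support, y = pos$y_support,
           variant = "support only")
  )
  df <- df[!is.na(df$x), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$x - .data$y)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_gradient2(low = "steelblue", mid = "grey85",
                                    high = "darkred", midpoint = 0,
                                    limits = c(-1, 1), name = "SDP signal") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::facet_wrap(~variant) +
    ggplot2::labs(x = "group-wise conservation", y = "between-group agreement") +
    ggplot2::theme_minimal()
}

#' Composition bar chart for one group at one position
#'
#' A simple frequency bar chart of the amino-acid composition matrix — the
#' plot-ready counterpart of a sequence logo column.
#'
#' @param msas List of `sdp_msa` replicates.
#' @param position Reference position.
#' @param group Group name.
#' @return A ggplot object.
#' @export
plot_composition <- function(msas, position, group) {
  cm <- composition_matrix(msas, position, group)
  cm <- cm[cm$count > 0, , drop = FALSE]
  ggplot2::ggplot(cm, ggplot2::aes(x = stats::reorder(.data$residue, -.data$frequency),
                                   y = .data$frequency)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "residue", y = "frequency",
                  title = paste0(group, " @ position ", position)) +
    ggplot2::theme_minimal()
}
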