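#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a point pattern
#'
#' @param object A [point_pattern()] or a `pattern_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.point_pattern <- function(object, ...) {
  d <- pattern_domain(object)
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(size = 0.6, colour = "grey20") +
    ggplot2::coord_fixed(xlim = c(0, d$length_x), ylim = c(0, d$length_y)) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("%s cells (n = %d)",
                                  pattern_cell_type(object), nrow(object))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.point_pattern
#' @export
autoplot.pattern_set <- function(object, ...) {
  pats <- object$patterns
  df <- dplyr::bind_rows(lapply(pats, function(p) {
    tibble::tibble(cell_type = pattern_cell_type(p), x = p$x, y = p$y)
  }))
  d <- pattern_domain(pats[[1]])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$cell_type)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_fixed(xlim = c(0, d$length_x), ylim = c(0, d$length_y)) +
    ggplot2::scale_colour_manual(values = c(
      Xd = "darkorange2", Xl = "gold2", M = "grey15",
      Id = "slategray3", Il = "steelblue3"), na.value = "grey50") +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "cell type") +
    ggplot2::theme_minimal()
}

#' Persistence diagram plot
#'
#' Birth/death scatter per homology dimension with the diagonal; essential
#' features are drawn at the filtration cap with open triangles.
#'
#' @param object A [compute_persistence()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.persistence_diagram <- function(object, ...) {
  cap <- attr(object, "max_radius", exact = TRUE) %||%
    max(object$death[is.finite(object$death)], 0)
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(essential = !is.finite(.data$death),
                  death_plot = ifelse(.data$essential, cap, .data$death),
                  dimension = factor(.data$dim))
  ggplot2::ggplot(df, ggplot2::aes(.data$birth, .data$death_plot,
                                   colour = .data$dimension,
                                   shape = .data$essential)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 2)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "birth radius (µm)", y = "death radius (µm)",
                  shape = "capped") +
    ggplot2::theme_minimal()
}

#' Plot clusters over the pattern
#'
#' @param object A [cluster_pattern()] result.
#' @param ... Unused.
#' @return A ggplot with cells coloured by cluster and centroids marked.
#' @export
autoplot.cluster_set <- function(object, ...) {
  d <- attr(object, "domain", exact = TRUE)
  ggplot2::ggplot(object$assignments,
                  ggplot2::aes(.data$x, .data$y,
                               colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_point(data = object$clusters,
                        ggplot2::aes(.data$centroid_x, .data$centroid_y),
                        colour = "black", shape = 4, size = 3,
                        inherit.aes = FALSE) +
    ggplot2::coord_fixed(xlim = c(0, d$length_x), ylim = c(0, d$length_y)) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "cluster") +
    ggplot2::theme_minimal()
}
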