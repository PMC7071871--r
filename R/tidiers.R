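#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a persistence diagram
#'
#' @param x A [compute_persistence()] result.
#' @param ... Unused.
#' @return A plain tibble with `dim`, `birth`, `death`, `persistence` plus a
#'   `cell_type` column.
#' @export
tidy.persistence_diagram <- function(x, ...) {
  tibble::as_tibble(x)[, c("dim", "birth", "death", "persistence")] |>
    dplyr::mutate(cell_type = attr(x, "cell_type", exact = TRUE) %||% NA_character_)
}

#' One-row summary of a persistence diagram
#'
#' @param x A [compute_persistence()] result.
#' @param ... Unused.
#' @return A one-row tibble: feature counts per dimension and the largest
#'   finite dimension-1 persistence.
#' @export
glance.persistence_diagram <- function(x, ...) {
  d1 <- x[x$dim == 1 & is.finite(x$death), , drop = FALSE]
  tibble::tibble(
    n_points = attr(x, "n_points", exact = TRUE) %||% NA_integer_,
    n_dim0 = sum(x$dim == 0),
    n_dim1 = sum(x$dim == 1),
    n_dim1_essential = sum(x$dim == 1 & !is.finite(x$death)),
    max_dim1_persistence = if (nrow(d1)) max(d1$death - d1$birth) else NA_real_,
    max_radius = attr(x, "max_radius", exact = TRUE) %||% NA_real_)
}

#' Tidy a cluster set
#'
#' @param x A [cluster_pattern()] result.
#' @param ... Unused.
#' @return The per-cluster summary tibble.
#' @export
tidy.cluster_set <- function(x, ...) x$clusters

#' @rdname tidy.cluster_set
#' @export
glance.cluster_set <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$clusters),
                 n_cells = nrow(x$assignments),
                 cell_type = attr(x, "cell_type", exact = TRUE) %||% NA_character_)
}

report_tidy <- function(x) {
  vals <- unclass(x)
  tibble::tibble(metric = names(vals),
                 value = vapply(vals, function(v) as.numeric(v)[1], numeric(1)))
}

#' Tidy quantification reports
#'
#' Long `metric`/`value` tibbles for band, spot and formation reports;
#' `tidy.pattern_report()` adds the mode.
#'
#' @param x A report object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.band_report <- function(x, ...) report_tidy(x)

#' @rdname tidy.band_report
#' @export
tidy.spot_report <- function(x, ...) report_tidy(x)

#' @rdname tidy.band_report
#' @export
tidy.formation_times <- function(x, ...) report_tidy(x)

#' @rdname tidy.band_report
#' @export
tidy.pattern_report <- function(x, ...) {
  dplyr::mutate(tidy(x$results), mode = x$mode, .before = 1)
}
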