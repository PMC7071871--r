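#' Vietoris-Rips persistent homology of a point pattern
#'
#' Computes dimension-0 (connected components) and, optionally, dimension-1
#' (loops) persistence of the Vietoris-Rips filtration built on the cylinder
#' metric of the pattern's domain.
#'
#' Births and deaths are reported on the **ball-radius scale**: growing a
#' ball of radius r around every cell, two cells become connected when r
#' reaches half their pairwise distance. Equivalently, the Rips filtration
#' is computed on halved pairwise distances. On this scale the persistence
#' of a band loop is half the maximum gap between adjacent bands, so twice
#' the persistence estimates the maximum enclosed band width, and the
#' standard cell-spacing thresholds apply literally. Set
#' `scale = "distance"` to report unhalved filtration values instead.
#'
#' The filtration is truncated at `max_radius` for tractability; features
#' still alive there are reported with `death = Inf` (essential). The
#' default cap, `min(length_y/2, length_x/8)`, is chosen to sit above every
#' band-merge scale of interest yet below the radius (about `length_x/6`) at
#' which the Rips complex fills the periodic direction; the 1-cycle that
#' wraps the domain therefore stays essential, as band counting assumes.
#'
#' @param pattern A non-empty [point_pattern()].
#' @param max_dim Maximum homology dimension, 0 or 1.
#' @param max_radius Filtration truncation on the radius scale (um);
#'   `NULL` for the domain-derived default.
#' @param scale `"radius"` (default) or `"distance"`.
#'
#' @return A tibble of class `persistence_diagram` with columns `dim`
#'   (integer), `birth`, `death`, `persistence` (um; `death` and
#'   `persistence` are `Inf` for essential features), sorted by
#'   `(dim, birth, death)`, with attributes `cell_type`, `n_points`,
#'   `max_radius`, `scale`.
#' @export
#'
#' @examples
#' pp <- point_pattern(data.frame(x = c(0, 100), y = c(0, 0)),
#'                     domain(1000, 400), "M")
#' compute_persistence(pp, max_dim = 0)  # one pair dying at radius 50
compute_persistence <- function(pattern, max_dim = 1, max_radius = NULL,
                                scale = c("radius", "distance")) {
  assert_pattern(pattern)
  scale <- match.arg(scale)
  if (!max_dim %in% c(0, 1)) rlang::abort("`max_dim` must be 0 or 1.")
  d <- pattern_domain(pattern)
  if (is.null(max_radius)) {
    max_radius <- min(d$length_y / 2, d$length_x / 8)
  }
  if (!is.numeric(max_radius) || max_radius <= 0) {
    rlang::abort("`max_radius` must be positive.")
  }
  dm <- pattern_dist(pattern)
  raw <- rips_pairs_cpp(dm, cap = 2 * max_radius, maxdim = as.integer(max_dim))
  out <- tibble::as_tibble(raw)
  half <- if (scale == "radius") 0.5 else 1
  out$birth <- out$birth * half
  out$death <- out$death * half
  out <- dplyr::arrange(out, .data$dim, .data$birth, .data$death)
  out$persistence <- out$death - out$birth
  structure(out,
            class = c("persistence_diagram", class(out)),
            cell_type = pattern_cell_type(pattern),
            n_points = nrow(pattern),
            max_radius = max_radius,
            scale = scale)
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf(
    "<persistence_diagram> %s, %d points, cap %g um (%s scale)\n",
    attr(x, "cell_type", exact = TRUE) %||% "?",
    attr(x, "n_points", exact = TRUE) %||% NA_integer_,
    attr(x, "max_radius", exact = TRUE) %||% NA_real_,
    attr(x, "scale", exact = TRUE) %||% "radius"))
  NextMethod()
}

assert_diagram <- function(diagram) {
  if (!inherits(diagram, "persistence_diagram") &&
      !(is.data.frame(diagram) && all(c("dim", "birth", "death") %in% names(diagram)))) {
    rlang::abort("expected a persistence diagram (columns dim, birth, death).")
  }
  invisible(diagram)
}

#' Count significant persistence features
#'
#' Thresholded Betti numbers. Dimension 0 counts features whose persistence
#' strictly exceeds `tp`; essential components (infinite persistence) always
#' qualify. Dimension 1 counts features with persistence at least `tp` and
#' birth radius at most `tb`; features still alive at the filtration cap are
#' treated as infinitely persistent, so they count whenever their birth is
#' small enough (a complete band that wraps the periodic domain stays alive
#' far beyond every threshold and must still be counted). Width measurement,
#' by contrast, uses finite features only; see [max_band_width()].
#'
#' @param diagram A [compute_persistence()] result.
#' @param dim Homology dimension to count, 0 or 1.
#' @param tp Minimum persistence (um; same scale as the diagram).
#' @param tb Maximum birth radius for dimension-1 features (um); ignored for
#'   dimension 0.
#'
#' @return Integer count.
#' @export
count_significant <- function(diagram, dim, tp, tb = Inf) {
  assert_diagram(diagram)
  if (!dim %in% c(0, 1)) rlang::abort("`dim` must be 0 or 1.")
  if (!is.numeric(tp) || tp < 0) rlang::abort("`tp` must be nonnegative.")
  rows <- diagram[diagram$dim == dim, , drop = FALSE]
  if (nrow(rows) == 0) return(0L)
  pers <- rows$death - rows$birth
  if (dim == 0) {
    sum(pers > tp)
  } else {
    sum(pers >= tp & rows$birth <= tb)
  }
}

#' Export / import a persistence diagram as a delimited table
#'
#' Flat CSV with columns `dim`, `birth`, `death` (infinite deaths written as
#' `Inf`), for caching and fixtures.
#'
#' @param diagram A persistence diagram.
#' @param path File path.
#' @return `write_diagram()` returns `path` invisibly; `read_diagram()`
#'   returns a `persistence_diagram` tibble (provenance attributes are not
#'   round-tripped).
#' @export
write_diagram <- function(diagram, path) {
  assert_diagram(diagram)
  readr::write_csv(diagram[, c("dim", "birth", "death")], path)
  invisible(path)
}

#' @rdname write_diagram
#' @export
read_diagram <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           dim = readr::col_integer(),
                           birth = readr::col_double(),
                           death = readr::col_double()))
  out$persistence <- out$death - out$birth
  structure(out, class = c("persistence_diagram", class(out)))
}
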