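#' Rectangular pattern domain, periodic in x
#'
#' Constructs the domain on which agent coordinates live: a rectangle of
#' `length_x` by `length_y` micrometres with periodic boundary conditions in
#' the horizontal (x) direction and wall-like boundaries at the top and
#' bottom. With these boundary conditions a complete stripe wraps around the
#' domain and is a topological loop, while a spot is a plain connected
#' component.
#'
#' @param length_x Horizontal extent in micrometres (periodic direction).
#' @param length_y Vertical extent in micrometres (walled direction).
#'
#' @return An object of class `domain`: a named list with elements
#'   `length_x` and `length_y`.
#' @export
#'
#' @examples
#' domain(3000, 2200)
domain <- function(length_x, length_y) {
  if (!is.numeric(length_x) || length(length_x) != 1 || !is.finite(length_x) ||
      length_x <= 0) {
    rlang::abort("`length_x` must be a single positive number (micrometres).")
  }
  if (!is.numeric(length_y) || length(length_y) != 1 || !is.finite(length_y) ||
      length_y <= 0) {
    rlang::abort("`length_y` must be a single positive number (micrometres).")
  }
  structure(list(length_x = as.numeric(length_x),
                 length_y = as.numeric(length_y)),
            class = "domain")
}

#' @export
print.domain <- function(x, ...) {
  cat(sprintf("<domain> %g x %g um (periodic in x)\n", x$length_x, x$length_y))
  invisible(x)
}

is_domain <- function(x) inherits(x, "domain")

#' Labelled point pattern on a periodic-in-x domain
#'
#' Wraps a table of agent coordinates as a point pattern: one row per cell
#' with positions in micrometres. The x coordinate is canonicalized into
#' `[0, length_x)`; y must lie in `[0, length_y]` (walls). All points of one
#' pattern share a single cell-type label (e.g. `"M"`, `"Xd"`, `"Xl"`,
#' `"Id"`, `"Il"`, or any user label).
#'
#' @param data A data frame with numeric columns `x` and `y` (micrometres).
#' @param domain A [domain()] object.
#' @param cell_type Single character label for the agents in this pattern.
#' @param day Optional integer day (e.g. days post fertilization) for
#'   snapshot series.
#'
#' @return A tibble of class `point_pattern` with columns `x`, `y` and
#'   attributes `domain`, `cell_type`, `day`.
#' @export
#'
#' @examples
#' pp <- point_pattern(data.frame(x = c(10, 2990), y = c(100, 100)),
#'                     domain(3000, 2200), cell_type = "Xd")
#' n_points(pp)
point_pattern <- function(data, domain, cell_type = "cell", day = NULL) {
  if (!is_domain(domain)) rlang::abort("`domain` must be a `domain` object.")
  if (!is.data.frame(data) || !all(c("x", "y") %in% names(data))) {
    rlang::abort("`data` must be a data frame with columns `x` and `y`.")
  }
  x <- as.numeric(data$x)
  y <- as.numeric(data$y)
  if (anyNA(x) || anyNA(y)) rlang::abort("coordinates contain missing values.")
  bad <- which(y < 0 | y > domain$length_y)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "y coordinates outside [0, %g] at rows: %s", domain$length_y,
      paste(utils::head(bad, 5), collapse = ", ")))
  }
  x <- x %% domain$length_x
  out <- tibble::tibble(x = x, y = y)
  structure(out,
            class = c("point_pattern", class(out)),
            domain = domain,
            cell_type = as.character(cell_type)[1],
            day = if (is.null(day)) NULL else as.integer(day)[1])
}

#' @export
print.point_pattern <- function(x, ...) {
  d <- pattern_domain(x)
  cat(sprintf("<point_pattern> %d %s cells on %g x %g um%s\n",
              nrow(x), pattern_cell_type(x), d$length_x, d$length_y,
              if (!is.null(pattern_day(x)))
                sprintf(" (day %d)", pattern_day(x)) else ""))
  NextMethod()
}

#' Pattern metadata accessors
#'
#' @param pattern A [point_pattern()].
#' @return The domain, cell-type label, day, or number of points.
#' @export
pattern_domain <- function(pattern) attr(pattern, "domain", exact = TRUE)

#' @rdname pattern_domain
#' @export
pattern_cell_type <- function(pattern) attr(pattern, "cell_type", exact = TRUE)

#' @rdname pattern_domain
#' @export
pattern_day <- function(pattern) attr(pattern, "day", exact = TRUE)

#' @rdname pattern_domain
#' @export
n_points <- function(pattern) nrow(pattern)

assert_pattern <- function(pattern, nonempty = TRUE) {
  if (!inherits(pattern, "point_pattern")) {
    rlang::abort("expected a `point_pattern` object; see `point_pattern()`.")
  }
  if (nonempty && nrow(pattern) == 0) {
    rlang::abort("point pattern is empty.")
  }
  invisible(pattern)
}

#' Trim the top and bottom margins of a pattern
#'
#' Removes cells in the top and bottom `fraction` of the domain height.
#' Partially formed bands and spots accumulate near the horizontal walls, so
#' analyses are run on trimmed patterns (default trim fraction 0.1). Points
#' exactly on the retention boundary are kept (closed interval).
#'
#' @param pattern A [point_pattern()].
#' @param fraction Fraction of the domain height trimmed from each side;
#'   must satisfy `0 <= fraction < 0.5`.
#'
#' @return A `point_pattern` with only the retained points; the domain is
#'   unchanged.
#' @export
trim_margins <- function(pattern, fraction = 0.1) {
  assert_pattern(pattern, nonempty = FALSE)
  if (!is.numeric(fraction) || length(fraction) != 1 || is.na(fraction) ||
      fraction < 0 || fraction >= 0.5) {
    rlang::abort("`fraction` must be a single number in [0, 0.5).")
  }
  d <- pattern_domain(pattern)
  lo <- fraction * d$length_y
  hi <- (1 - fraction) * d$length_y
  keep <- pattern$y >= lo & pattern$y <= hi
  point_pattern(pattern[keep, , drop = FALSE], d,
                cell_type = pattern_cell_type(pattern),
                day = pattern_day(pattern))
}
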