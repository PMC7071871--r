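#' Cylinder (periodic-in-x) distance between two points
#'
#' Distance on a rectangular domain that is periodic in the horizontal
#' direction: the x separation wraps around the domain while the y
#' separation is plain. This is the metric under which complete stripes are
#' loops.
#'
#' @param p,q Numeric length-2 vectors `c(x, y)` in micrometres.
#' @param domain A [domain()] giving the period `length_x`.
#'
#' @return The distance in micrometres:
#'   `sqrt(min(|dx|, length_x - |dx|)^2 + dy^2)`.
#' @export
#'
#' @examples
#' periodic_distance(c(0, 100), c(2990, 100), domain(3000, 2200)) # 10
periodic_distance <- function(p, q, domain) {
  if (!is_domain(domain)) rlang::abort("`domain` must be a `domain` object.")
  dx <- abs(p[1] - q[1])
  dx <- min(dx, domain$length_x - dx)
  sqrt(dx^2 + (p[2] - q[2])^2)
}

#' Pairwise cylinder distance matrix of a pattern
#'
#' All pairwise distances between the points of a pattern under the cylinder
#' metric, in input order.
#'
#' @param pattern A non-empty [point_pattern()].
#'
#' @return A symmetric numeric matrix (micrometres) with zero diagonal.
#' @export
pattern_dist <- function(pattern) {
  assert_pattern(pattern)
  d <- pattern_domain(pattern)
  cylinder_dist_cpp(pattern$x, pattern$y, d$length_x)
}
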