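#' Count spots of one cell type
#'
#' Thresholded zeroth Betti number: the number of dimension-0 persistence
#' features (connected components) whose persistence strictly exceeds the
#' cell type's `tp0`; the essential component counts. Two cell groups merge
#' at a ball radius of half their separation, so `tp0` set above half the
#' typical cell spacing counts clusters, not cells. Use a clustered cell
#' type: counting a type that also scatters lone cells across the domain
#' (e.g. stray melanophores) inflates the count by one per stray cell.
#'
#' @param pattern A trimmed [point_pattern()] (`Il`, `M`, or any type with a
#'   configured `tp0`).
#' @param config A [quant_config()].
#' @param diagram Optional precomputed dimension-0 diagram for `pattern`.
#'
#' @return Integer spot count (0 with a warning for an empty pattern).
#' @export
count_spots <- function(pattern, config = quant_config(), diagram = NULL) {
  assert_pattern(pattern, nonempty = FALSE)
  assert_config(config)
  if (nrow(pattern) == 0) {
    rlang::warn("empty pattern: spot count is 0.")
    return(0L)
  }
  tp <- threshold_for(config$tp0, pattern_cell_type(pattern), "dimension-0 persistence")
  if (is.null(diagram)) diagram <- compute_persistence(pattern, max_dim = 0)
  count_significant(diagram, dim = 0, tp = tp)
}

#' Spot size: median cells per spot
#'
#' The median cluster cardinality of a [cluster_pattern()] partition. For an
#' even number of spots the lower median is used (spot sizes are integers).
#'
#' @param clusters A [cluster_pattern()] result.
#' @return Integer median number of cells per spot.
#' @export
spot_size <- function(clusters) {
  assert_cluster_set(clusters)
  sizes <- sort(clusters$clusters$n)
  sizes[ceiling(length(sizes) / 2)]
}

#' Spot roundness: median PCA eigenvalue ratio
#'
#' For each spot, the ratio of the first to the second eigenvalue of the PCA
#' of its member coordinates measures elongation; the reported roundness is
#' the median ratio over spots (midpoint interpolation for even counts). A
#' value near 1 means round spots; much larger than 1 means elongated or
#' irregular spots. Degenerate clusters (fewer than 3 members, or collinear
#' members with a zero second eigenvalue) are excluded with a warning.
#'
#' @param clusters A [cluster_pattern()] result.
#' @return Median eigenvalue ratio (>= 1).
#' @export
spot_roundness <- function(clusters) {
  assert_cluster_set(clusters)
  cl <- clusters$clusters
  ok <- cl$n >= 3 & cl$lambda2 > 0
  if (any(!ok)) {
    rlang::warn(sprintf(
      "%d degenerate cluster(s) (collinear or < 3 members) excluded from roundness.",
      sum(!ok)))
  }
  if (!any(ok)) rlang::abort("all clusters are degenerate; roundness undefined.")
  stats::median(cl$lambda1[ok] / cl$lambda2[ok])
}

#' Spot spacing regularity
#'
#' For each spot centroid, the Chebyshev (l-infinity) distance to its
#' nearest other centroid, with the x component wrapped periodically; the
#' reported value is the sample standard deviation (n - 1 denominator) of
#' these nearest-neighbour distances. Zero for perfectly lattice-aligned
#' spots; grows with placement irregularity.
#'
#' @param clusters A [cluster_pattern()] result with at least 2 clusters.
#' @return Standard deviation in micrometres.
#' @export
spot_spacing_sd <- function(clusters) {
  assert_cluster_set(clusters)
  cl <- clusters$clusters
  if (nrow(cl) < 2) {
    rlang::abort("spot spacing needs at least 2 clusters.")
  }
  d <- attr(clusters, "domain", exact = TRUE)
  nn <- vapply(seq_len(nrow(cl)), function(i) {
    dx <- abs(cl$centroid_x[-i] - cl$centroid_x[i])
    dx <- pmin(dx, d$length_x - dx)
    dy <- abs(cl$centroid_y[-i] - cl$centroid_y[i])
    min(pmax(dx, dy))
  }, numeric(1))
  stats::sd(nn)
}

#' Centre width: clearance of the central region
#'
#' Twice the minimum cylinder distance from any spot centroid to the domain
#' midpoint `(length_x/2, length_y/2)`, minus the median spot diameter,
#' floored at zero. For spotted phenotypes with an enlarged light central
#' region this estimates the width of the central interstripe. Set
#' `midline = TRUE` to measure the vertical distance to the horizontal
#' midline instead of the distance to the centre point.
#'
#' @param clusters A [cluster_pattern()] result with at least 1 cluster.
#' @param midline Use the horizontal midline instead of the centre point.
#' @return Width in micrometres.
#' @export
center_width <- function(clusters, midline = FALSE) {
  assert_cluster_set(clusters)
  cl <- clusters$clusters
  if (nrow(cl) < 1) rlang::abort("centre width needs at least 1 cluster.")
  d <- attr(clusters, "domain", exact = TRUE)
  if (midline) {
    dist_mid <- abs(cl$centroid_y - d$length_y / 2)
  } else {
    dx <- abs(cl$centroid_x - d$length_x / 2)
    dx <- pmin(dx, d$length_x - dx)
    dist_mid <- sqrt(dx^2 + (cl$centroid_y - d$length_y / 2)^2)
  }
  diam <- stats::median(cl$diameter)
  max(0, 2 * min(dist_mid) - diam)
}

#' Full spot-pattern report
#'
#' Runs the spot pipeline on a trimmed pattern of a clustered cell type:
#' counts spots by thresholded dimension-0 persistence, partitions the cells
#' into that many single-linkage clusters, and reports spot size, roundness,
#' spacing regularity and centre width.
#'
#' @inheritParams count_spots
#' @param midline Passed to [center_width()].
#'
#' @return A list of class `spot_report`: `n_spots`, `spot_size`,
#'   `roundness`, `spacing_sd` (um), `center_width` (um). Statistics that
#'   need more clusters than found are `NA`.
#' @export
quantify_spots <- function(pattern, config = quant_config(), midline = FALSE) {
  assert_pattern(pattern)
  assert_config(config)
  diagram <- compute_persistence(pattern, max_dim = 0)
  k <- count_spots(pattern, config, diagram = diagram)
  if (k < 1) {
    return(structure(list(n_spots = 0L, spot_size = NA_integer_,
                          roundness = NA_real_, spacing_sd = NA_real_,
                          center_width = NA_real_), class = "spot_report"))
  }
  cl <- spot_clusters(pattern, min(k, nrow(pattern)))
  structure(list(
    n_spots = as.integer(k),
    spot_size = spot_size(cl),
    roundness = tryCatch(suppressWarnings(spot_roundness(cl)),
                         error = function(e) NA_real_),
    spacing_sd = if (k >= 2) spot_spacing_sd(cl) else NA_real_,
    center_width = center_width(cl, midline = midline)
  ), class = "spot_report")
}

#' @export
print.spot_report <- function(x, ...) {
  cat("<spot_report>\n")
  cat(sprintf("  spots: %d, size (median cells): %s\n", x$n_spots, x$spot_size))
  cat(sprintf("  roundness (median eigenvalue ratio): %.2f\n", x$roundness))
  cat(sprintf("  spacing SD: %.1f um, centre width: %.1f um\n",
              x$spacing_sd, x$center_width))
  invisible(x)
}
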