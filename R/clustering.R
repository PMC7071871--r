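#' Single-linkage clustering of a pattern under the cylinder metric
#'
#' Partitions the cells of a pattern into `k` clusters by single-linkage
#' agglomeration (equivalent to cutting the `k - 1` longest edges of the
#' minimum spanning tree). Single linkage is used deliberately: it recovers
#' the elongated, undulating, non-spherical clusters that stripes and mutant
#' spots form, which centroid-based methods split.
#'
#' Per-cluster summaries are computed after unwrapping clusters that
#' straddle the periodic x seam (members are shifted by the period so the
#' cluster is contiguous, by cutting at the largest circular gap in x).
#' The PCA eigenvalues are those of the covariance matrix of the
#' mean-centred member coordinates; the diameter is twice the greatest
#' Euclidean distance from the centroid to a member.
#'
#' @param pattern A non-empty [point_pattern()].
#' @param k Number of clusters, `1 <= k <= n_points(pattern)`.
#'
#' @return A list of class `cluster_set` with
#'   \describe{
#'     \item{assignments}{tibble `x`, `y`, `cluster` (one row per cell)}
#'     \item{clusters}{tibble `cluster`, `n`, `centroid_x`, `centroid_y`,
#'       `lambda1`, `lambda2` (PCA eigenvalues, um^2), `diameter` (um)}
#'   }
#'   plus attributes `domain` and `cell_type`.
#' @export
#'
#' @examples
#' pp <- point_pattern(data.frame(x = c(0, 10, 500, 510),
#'                                y = c(0, 0, 0, 0)),
#'                     domain(2000, 100), "Il")
#' cluster_pattern(pp, 2)$clusters
cluster_pattern <- function(pattern, k) {
  assert_pattern(pattern)
  n <- nrow(pattern)
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 || k != round(k)) {
    rlang::abort("`k` must be a positive integer.")
  }
  if (k > n) {
    rlang::abort(sprintf("`k` (%d) exceeds the number of points (%d).", as.integer(k), n))
  }
  d <- pattern_domain(pattern)
  if (n == 1) {
    member <- 1L
  } else {
    hc <- stats::hclust(stats::as.dist(pattern_dist(pattern)), method = "single")
    member <- stats::cutree(hc, k = as.integer(k))
  }
  assignments <- tibble::tibble(x = pattern$x, y = pattern$y,
                                cluster = as.integer(member))
  clusters <- dplyr::bind_rows(lapply(sort(unique(member)), function(cl) {
    summarize_cluster(pattern$x[member == cl], pattern$y[member == cl],
                      d$length_x, cl)
  }))
  structure(list(assignments = assignments, clusters = clusters),
            class = "cluster_set",
            domain = d,
            cell_type = pattern_cell_type(pattern))
}

#' @rdname cluster_pattern
#' @export
band_clusters <- function(pattern, k) cluster_pattern(pattern, k)

#' @rdname cluster_pattern
#' @export
spot_clusters <- function(pattern, k) cluster_pattern(pattern, k)

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters of %d %s cells\n",
              nrow(x$clusters), nrow(x$assignments),
              attr(x, "cell_type", exact = TRUE) %||% "?"))
  print(x$clusters, ...)
  invisible(x)
}

assert_cluster_set <- function(x) {
  if (!inherits(x, "cluster_set")) {
    rlang::abort("expected a `cluster_set`; see `cluster_pattern()`.")
  }
  invisible(x)
}

# Shift x coordinates by the period so a cluster straddling the seam becomes
# contiguous: cut the circle at its largest empty arc.
unwrap_x <- function(x, length_x) {
  if (length(x) < 2) return(x)
  ord <- order(x)
  xs <- x[ord]
  gaps <- c(diff(xs), xs[1] + length_x - xs[length(xs)])
  cut_at <- which.max(gaps)
  if (cut_at == length(xs)) return(x)  # largest gap is across the seam: contiguous
  cut_x <- xs[cut_at + 1]  # start of the occupied arc
  x + length_x * (x < cut_x)
}

summarize_cluster <- function(x, y, length_x, label) {
  xu <- unwrap_x(x, length_x)
  cx <- mean(xu)
  cy <- mean(y)
  n <- length(x)
  if (n >= 2) {
    cv <- stats::cov(cbind(xu, y))
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0)
  }
  diam <- 2 * max(sqrt((xu - cx)^2 + (y - cy)^2))
  tibble::tibble(cluster = as.integer(label), n = n,
                 centroid_x = cx %% length_x, centroid_y = cy,
                 lambda1 = ev[1], lambda2 = ev[2], diameter = diam)
}
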