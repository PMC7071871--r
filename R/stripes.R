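#' Count complete bands (stripes or interstripes) of one cell type
#'
#' Thresholded first Betti number: the number of dimension-1 persistence
#' features with persistence at least `tp1` and birth radius at most the
#' cell type's `tb1`. On a periodic-in-x domain every complete band wraps
#' the domain and is a loop, so this count estimates the number of
#' stripes (for `Xl` or `M` cells) or interstripes (for `Xd` cells). A
#' broken band only closes into a loop at half its break width, pushing its
#' birth radius above `tb1`, so breaks lower the count.
#'
#' @param pattern A trimmed [point_pattern()] of a single band-forming cell
#'   type (`Xd`, `Xl`, `M`, or any type with a configured `tb1`).
#' @param config A [quant_config()].
#' @param diagram Optionally, a precomputed dimension-1
#'   [compute_persistence()] diagram for `pattern` (avoids recomputation).
#'
#' @return Integer band count.
#' @export
count_bands <- function(pattern, config = quant_config(), diagram = NULL) {
  assert_pattern(pattern)
  assert_config(config)
  tb <- threshold_for(config$tb1, pattern_cell_type(pattern), "dimension-1 birth")
  if (is.null(diagram)) diagram <- compute_persistence(pattern, max_dim = 1)
  count_significant(diagram, dim = 1, tp = config$tp1, tb = tb)
}

#' Flag stripe and interstripe breaks
#'
#' An interstripe break is flagged when the interstripe count from `Xd`
#' cells falls below the expected number of interstripes. A stripe break is
#' flagged only when the stripe counts from **both** `Xl` and `M` cells fall
#' below the expected number of stripes: `Xl` cells appear at low density in
#' stripes, so requiring agreement of the two cell types guards against
#' false positives.
#'
#' @param xd,xl,m Trimmed [point_pattern()]s of `Xd`, `Xl` and `M` cells on
#'   a common domain.
#' @param config A [quant_config()].
#'
#' @return A list with logicals `interstripe_break`, `stripe_break` and the
#'   underlying counts `n_interstripes`, `n_stripes_xl`, `n_stripes_m`.
#' @export
detect_breaks <- function(xd, xl, m, config = quant_config()) {
  assert_config(config)
  doms <- lapply(list(xd, xl, m), pattern_domain)
  if (!all(vapply(doms, identical, logical(1), y = doms[[1]]))) {
    rlang::abort("`xd`, `xl` and `m` must share one domain.")
  }
  b1_xd <- count_bands(xd, config)
  b1_xl <- count_bands(xl, config)
  b1_m <- count_bands(m, config)
  list(interstripe_break = b1_xd < config$expected_interstripes,
       stripe_break = b1_xl < config$expected_stripes &&
         b1_m < config$expected_stripes,
       n_interstripes = b1_xd, n_stripes_xl = b1_xl, n_stripes_m = b1_m)
}

#' Maximum band width from loop persistence
#'
#' Twice the largest persistence among the significant **finite**
#' dimension-1 features of a pattern. A band loop dies when the two bands
#' flanking it merge, at a ball radius of half their maximum separation, so
#' `2 * (death - birth)` approximates the maximum width of the enclosed band
#' (using `death - birth` rather than `death` alone discounts the narrow
#' boundary region where the band itself lives). Features that survive to
#' the filtration cap (notably the one cycle that wraps the periodic domain)
#' are never used.
#'
#' For a `Xl` (stripe) pattern this estimates the maximum interstripe width;
#' for a `Xd` (interstripe) pattern, an upper bound on stripe width.
#'
#' @inheritParams count_bands
#'
#' @return Width in micrometres.
#' @export
max_band_width <- function(pattern, config = quant_config(), diagram = NULL) {
  assert_pattern(pattern)
  assert_config(config)
  tb <- threshold_for(config$tb1, pattern_cell_type(pattern), "dimension-1 birth")
  if (is.null(diagram)) diagram <- compute_persistence(pattern, max_dim = 1)
  rows <- diagram[diagram$dim == 1 & is.finite(diagram$death), , drop = FALSE]
  pers <- rows$death - rows$birth
  keep <- pers >= config$tp1 & rows$birth <= tb
  if (!any(keep)) {
    rlang::abort(paste0(
      "no significant finite band loop for cell type '",
      pattern_cell_type(pattern),
      "': the pattern has no measurable band pair."),
      class = "pigmentr_no_bands")
  }
  2 * max(pers[keep])
}

#' Stripe curviness from cluster boundary arc length
#'
#' Average percentage excess of the arc length of band boundaries over
#' perfectly straight bands:
#' `curviness = mean over bands (true ALD / straight ALD - 1) * 100`,
#' where ALD is the summed arc length of the band's upper and lower boundary
#' polylines and the straight ALD of a band spanning the domain is
#' `2 * length_x`.
#'
#' Boundaries are extracted per cluster by partitioning x into bins, taking
#' the maximum (upper) and minimum (lower) y per bin, and joining
#' consecutive bin representatives into closed periodic polylines. The
#' default bin width is twice the pattern's median nearest-neighbour
#' spacing, the smallest width that guarantees every bin holds a full
#' lattice column of a band, so the extracted envelope follows the band
#' edge rather than sawtoothing between rows. A cluster that does not span
#' the full period (not a band) is excluded from the mean with a warning.
#'
#' @param clusters A [cluster_pattern()] result whose clusters are bands.
#' @param bin_width Bin width in um; `NULL` for twice the median
#'   nearest-neighbour spacing of the clustered cells.
#'
#' @return A list with `curviness` (percent), `bin_width` (um) and
#'   `n_bands_used`.
#' @export
curviness <- function(clusters, bin_width = NULL) {
  assert_cluster_set(clusters)
  d <- attr(clusters, "domain", exact = TRUE)
  asg <- clusters$assignments
  if (is.null(bin_width)) bin_width <- 2 * median_nn_spacing(asg$x, asg$y, d)
  n_bins <- max(4L, as.integer(round(d$length_x / bin_width)))
  edges <- seq(0, d$length_x, length.out = n_bins + 1)
  per_band <- vapply(split(asg, asg$cluster), function(df) {
    bin <- findInterval(df$x, edges, rightmost.closed = TRUE)
    if (length(unique(bin)) < n_bins) return(NA_real_)  # not a spanning band
    upper <- tapply(df$y, bin, max)
    lower <- tapply(df$y, bin, min)
    xc <- (edges[-1] + edges[-length(edges)]) / 2
    (polyline_length(xc, as.numeric(upper), d$length_x) +
        polyline_length(xc, as.numeric(lower), d$length_x)) /
      (2 * d$length_x)
  }, numeric(1))
  if (anyNA(per_band)) {
    rlang::warn(sprintf(
      "%d cluster(s) do not span the full x period and were excluded from curviness.",
      sum(is.na(per_band))))
  }
  used <- per_band[!is.na(per_band)]
  if (length(used) == 0) {
    rlang::abort("no cluster spans the full x period; curviness undefined.")
  }
  list(curviness = mean(used - 1) * 100,
       bin_width = bin_width,
       n_bands_used = length(used))
}

# closed periodic polyline length through (x, y) ordered by x
polyline_length <- function(x, y, length_x) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  dx <- diff(c(x, x[1] + length_x))
  dy <- diff(c(y, y[1]))
  sum(sqrt(dx^2 + dy^2))
}

median_nn_spacing <- function(x, y, domain) {
  dm <- cylinder_dist_cpp(x, y, domain$length_x)
  diag(dm) <- Inf
  stats::median(apply(dm, 1, min))
}

#' Full stripe-pattern report
#'
#' Runs the stripe pipeline on trimmed `Xd`, `Xl` and `M` patterns: band
#' counts, break flags, maximum band widths (interstripe width from `Xl`
#' loops, stripe width upper bound from `Xd` loops) and stripe curviness
#' from single-linkage clusters of `Xd` cells (the number of clusters is the
#' expected interstripe count minus any detected shortfall).
#'
#' @inheritParams detect_breaks
#'
#' @return A list of class `band_report`:
#'   `n_interstripes`, `n_stripes_xl`, `n_stripes_m`, `interstripe_break`,
#'   `stripe_break`, `max_interstripe_width`, `max_stripe_width` (um, `NA`
#'   when no significant finite loop exists), `curviness` (percent),
#'   `curviness_bin_width` (um).
#' @export
quantify_stripes <- function(xd, xl, m, config = quant_config()) {
  assert_config(config)
  dxd <- compute_persistence(xd, max_dim = 1)
  dxl <- compute_persistence(xl, max_dim = 1)
  dm_ <- compute_persistence(m, max_dim = 1)
  b1_xd <- count_bands(xd, config, diagram = dxd)
  b1_xl <- count_bands(xl, config, diagram = dxl)
  b1_m <- count_bands(m, config, diagram = dm_)
  interstripe_break <- b1_xd < config$expected_interstripes
  stripe_break <- b1_xl < config$expected_stripes && b1_m < config$expected_stripes
  width_or_na <- function(pattern, diagram) {
    tryCatch(max_band_width(pattern, config, diagram = diagram),
             pigmentr_no_bands = function(e) NA_real_)
  }
  n_clust <- max(1L, config$expected_interstripes -
                   max(0L, config$expected_interstripes - b1_xd))
  cl <- band_clusters(xd, min(n_clust, nrow(xd)))
  curv <- tryCatch(curviness(cl), error = function(e) {
    list(curviness = NA_real_, bin_width = NA_real_, n_bands_used = 0L)
  })
  structure(list(
    n_interstripes = b1_xd,
    n_stripes_xl = b1_xl,
    n_stripes_m = b1_m,
    interstripe_break = interstripe_break,
    stripe_break = stripe_break,
    max_interstripe_width = width_or_na(xl, dxl),
    max_stripe_width = width_or_na(xd, dxd),
    curviness = curv$curviness,
    curviness_bin_width = curv$bin_width
  ), class = "band_report")
}

#' @export
print.band_report <- function(x, ...) {
  cat("<band_report>\n")
  cat(sprintf("  interstripes (Xd): %d%s\n", x$n_interstripes,
              if (x$interstripe_break) "  [BREAK]" else ""))
  cat(sprintf("  stripes (Xl/M): %d/%d%s\n", x$n_stripes_xl, x$n_stripes_m,
              if (x$stripe_break) "  [BREAK]" else ""))
  cat(sprintf("  max interstripe width: %.1f um\n", x$max_interstripe_width))
  cat(sprintf("  max stripe width (upper bound): %.1f um\n", x$max_stripe_width))
  cat(sprintf("  curviness: %.2f%%\n", x$curviness))
  invisible(x)
}
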