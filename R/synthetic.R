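#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# hexagonal packing of a horizontal strip [y_lo, y_hi] across the full
# (periodic) x extent; spacing is adjusted so columns tile the period exactly
hex_strip <- function(length_x, y_lo, y_hi, spacing, jitter_sd = 0) {
  n_cols <- max(1L, round(length_x / spacing))
  dx <- length_x / n_cols
  dy <- spacing * sqrt(3) / 2
  n_rows <- max(1L, floor((y_hi - y_lo) / dy) + 1L)
  y0 <- (y_lo + y_hi) / 2 - (n_rows - 1) * dy / 2
  rows <- seq_len(n_rows)
  pts <- do.call(rbind, lapply(rows, function(r) {
    off <- if (r %% 2 == 0) dx / 2 else 0
    cbind(x = (seq_len(n_cols) - 1) * dx + off, y = y0 + (r - 1) * dy)
  }))
  if (jitter_sd > 0) {
    pts[, 1] <- pts[, 1] + stats::rnorm(nrow(pts), 0, jitter_sd)
    pts[, 2] <- pts[, 2] + stats::rnorm(nrow(pts), 0, jitter_sd)
  }
  pts
}

#' Specification of a synthetic banded (stripe/interstripe) pattern
#'
#' Describes the ground truth for [generate_bands()]: `n_bands` interstripe
#' bands of width `band_width`, separated edge-to-edge by `gap`; each gap
#' hosts one stripe band inset by `margin` on both sides (so stripes are
#' `gap - 2 * margin` wide and adjacent same-type bands sit
#' `band_width + 2 * margin` apart). Cells are hexagonally packed at
#' `cell_spacing` with Gaussian positional jitter `jitter_sd` (default 15%
#' of the spacing, the near-regular spacing real skins show). Band
#' centrelines can undulate as `amplitude * sin(2*pi*x / wavelength)`, and
#' `breaks` punches cell-free gaps into chosen interstripes.
#'
#' Defaults emulate a wild-type flank at the three-interstripe stage on a
#' 3000 x 2200 um domain with 50 um cell spacing.
#'
#' @param n_bands Number of interstripe bands (stripes in between:
#'   `n_bands - 1`).
#' @param band_width Interstripe band width (um).
#' @param gap Edge-to-edge distance between consecutive interstripes (um).
#' @param margin Cell-free margin between a stripe and its neighbouring
#'   interstripes (um).
#' @param cell_spacing Target nearest-neighbour spacing (um), realistically
#'   30-80.
#' @param jitter_sd Positional jitter SD (um); `NULL` for 15% of
#'   `cell_spacing`.
#' @param amplitude,wavelength Sinusoidal undulation of band centrelines
#'   (um); `amplitude = 0` gives straight bands.
#' @param breaks Data frame with columns `band` (interstripe index, 1-based
#'   from the bottom), `x` (centre of the break, um) and `width` (um), or
#'   `NULL`.
#' @param domain A [domain()].
#' @param seed Integer seed; fixed seed gives byte-identical output.
#'
#' @return A list of class `band_spec`.
#' @export
band_spec <- function(n_bands = 3, band_width = 350, gap = 500, margin = 75,
                      cell_spacing = 50, jitter_sd = NULL,
                      amplitude = 0, wavelength = 3000,
                      breaks = NULL, domain = pigmentr::domain(3000, 2200),
                      seed = 1) {
  if (is.null(jitter_sd)) jitter_sd <- 0.15 * cell_spacing
  stopifnot(n_bands >= 1, band_width > 0, gap > 0, margin >= 0,
            cell_spacing > 0, jitter_sd >= 0, amplitude >= 0, wavelength > 0)
  span <- n_bands * band_width + (n_bands - 1) * gap
  if (span + 2 * amplitude > domain$length_y) {
    rlang::abort("bands (plus undulation) exceed the domain height.")
  }
  if (!is.null(breaks)) {
    stopifnot(is.data.frame(breaks),
              all(c("band", "x", "width") %in% names(breaks)),
              all(breaks$band >= 1 & breaks$band <= n_bands),
              all(breaks$x >= 0 & breaks$x < domain$length_x),
              all(breaks$width > 0))
  }
  structure(list(n_bands = as.integer(n_bands), band_width = band_width,
                 gap = gap, margin = margin, cell_spacing = cell_spacing,
                 jitter_sd = jitter_sd, amplitude = amplitude,
                 wavelength = wavelength, breaks = breaks, domain = domain,
                 seed = as.integer(seed)),
            class = "band_spec")
}

#' Generate a synthetic banded point pattern with known ground truth
#'
#' Builds labelled patterns for the three band-forming cell types:
#' interstripe cells (`Xd`) on the interstripe bands and stripe cells (`Xl`
#' and `M`, independently jittered) on the stripe bands. Deterministic for a
#' fixed spec seed.
#'
#' @param spec A [band_spec()].
#'
#' @return A list of class `pattern_set`: `patterns` (named list of
#'   [point_pattern()]s `Xd`, `Xl`, `M`) and `truth`, the planted ground
#'   truth (`n_interstripes`, `n_stripes`, per-type expected maximum band
#'   widths `width_from_xd` / `width_from_xl`, undulation, breaks).
#' @export
#'
#' @examples
#' bands <- generate_bands(band_spec(seed = 7))
#' count_bands(trim_margins(bands$patterns$Xd))
generate_bands <- function(spec) {
  if (!inherits(spec, "band_spec")) rlang::abort("`spec` must be a `band_spec`.")
  d <- spec$domain
  span <- spec$n_bands * spec$band_width + (spec$n_bands - 1) * spec$gap
  y0 <- (d$length_y - span) / 2
  inter_centers <- y0 + spec$band_width / 2 +
    (seq_len(spec$n_bands) - 1) * (spec$band_width + spec$gap)
  stripe_width <- spec$gap - 2 * spec$margin
  stripe_centers <- if (spec$n_bands > 1) {
    utils::head(inter_centers, -1) + spec$band_width / 2 + spec$gap / 2
  } else numeric(0)

  undulate <- function(pts) {
    pts[, 2] <- pts[, 2] +
      spec$amplitude * sin(2 * pi * pts[, 1] / spec$wavelength)
    pts
  }
  fill_bands <- function(centers, width) {
    do.call(rbind, lapply(seq_along(centers), function(i) {
      pts <- hex_strip(d$length_x, centers[i] - width / 2,
                       centers[i] + width / 2,
                       spec$cell_spacing, spec$jitter_sd)
      cbind(undulate(pts), band = i)
    }))
  }

  with_seed(spec$seed, {
    xd <- fill_bands(inter_centers, spec$band_width)
    if (!is.null(spec$breaks)) {
      for (b in seq_len(nrow(spec$breaks))) {
        dx <- abs(xd[, 1] %% d$length_x - spec$breaks$x[b])
        dx <- pmin(dx, d$length_x - dx)
        drop <- xd[, 3] == spec$breaks$band[b] & dx < spec$breaks$width[b] / 2
        xd <- xd[!drop, , drop = FALSE]
      }
    }
    xl <- if (length(stripe_centers)) fill_bands(stripe_centers, stripe_width)
          else cbind(x = numeric(0), y = numeric(0), band = numeric(0))
    m <- if (length(stripe_centers)) fill_bands(stripe_centers, stripe_width)
         else cbind(x = numeric(0), y = numeric(0), band = numeric(0))
  })

  clamp <- function(pts) {
    pts[, 2] <- pmin(pmax(pts[, 2], 0), d$length_y)
    tibble::tibble(x = pts[, 1], y = pts[, 2])
  }
  patterns <- list(
    Xd = point_pattern(clamp(xd), d, cell_type = "Xd"),
    Xl = point_pattern(clamp(xl), d, cell_type = "Xl"),
    M = point_pattern(clamp(m), d, cell_type = "M"))
  truth <- list(
    n_interstripes = spec$n_bands,
    n_stripes = spec$n_bands - 1L,
    interstripe_centers = inter_centers,
    stripe_centers = stripe_centers,
    band_width = spec$band_width,
    stripe_width = stripe_width,
    # expected 2 * max finite loop persistence per cell type:
    width_from_xd = spec$gap - spec$cell_spacing,
    width_from_xl = spec$band_width + 2 * spec$margin - spec$cell_spacing,
    amplitude = spec$amplitude,
    wavelength = spec$wavelength,
    breaks = spec$breaks,
    cell_spacing = spec$cell_spacing)
  structure(list(patterns = patterns, truth = truth), class = "pattern_set")
}

#' Specification of a synthetic spotted pattern
#'
#' Ground truth for [generate_spots()]: `n_spots` elliptical spots arranged
#' in `n_rows` rows placed symmetrically about the horizontal midline,
#' `row_spacing` apart, with one spot column passing through the domain's
#' x midpoint. Spots are hexagonally packed ellipses with area-equivalent
#' radius `spot_radius` and axis ratio `elongation` (major axis horizontal).
#' `placement = "jittered"` perturbs spot centres by `placement_jitter_sd`.
#' `central_gap > 0` overrides `row_spacing` so the clearance between the
#' domain centre and the nearest spot edge band is the given gap (a
#' missing-cell-type-like enlarged light centre). `scattered_points` lone
#' cells are placed uniformly at least `scattered_min_sep` from every spot
#' cell and each other.
#'
#' @param n_spots Number of spots.
#' @param spot_radius Area-equivalent spot radius (um).
#' @param elongation Major/minor axis ratio (1 = round).
#' @param n_rows Number of spot rows; `NULL` for at most five spots per row,
#'   which keeps spots well separated on the default domain.
#' @param row_spacing Centre-to-centre distance between adjacent rows (um).
#' @param placement `"lattice"` or `"jittered"`.
#' @param placement_jitter_sd Centre jitter SD (um) for jittered placement.
#' @param central_gap Planted clearance across the domain midline (um), 0
#'   for none.
#' @param scattered_points Number of lone scattered cells.
#' @param scattered_min_sep Minimum separation of scattered cells from all
#'   other cells (um).
#' @param cell_spacing Nearest-neighbour spacing inside spots (um).
#' @param jitter_sd Cell positional jitter SD; `NULL` for 15% of spacing.
#' @param cell_type Label for the generated cells (default `"Il"`).
#' @param domain A [domain()].
#' @param seed Integer seed.
#'
#' @return A list of class `spot_spec`.
#' @export
spot_spec <- function(n_spots = 8, spot_radius = 100, elongation = 1,
                      n_rows = NULL, row_spacing = 600,
                      placement = c("lattice", "jittered"),
                      placement_jitter_sd = 50, central_gap = 0,
                      scattered_points = 0, scattered_min_sep = 250,
                      cell_spacing = 45, jitter_sd = NULL, cell_type = "Il",
                      domain = pigmentr::domain(3000, 2200), seed = 1) {
  placement <- match.arg(placement)
  if (is.null(jitter_sd)) jitter_sd <- 0.15 * cell_spacing
  if (is.null(n_rows)) n_rows <- max(1L, ceiling(n_spots / 5))
  stopifnot(n_spots >= 0, spot_radius > 0, elongation >= 1, n_rows >= 1,
            row_spacing > 0, cell_spacing > 0, scattered_points >= 0)
  if (central_gap > 0) row_spacing <- central_gap + 2 * spot_radius
  structure(list(n_spots = as.integer(n_spots), spot_radius = spot_radius,
                 elongation = elongation, n_rows = as.integer(n_rows),
                 row_spacing = row_spacing, placement = placement,
                 placement_jitter_sd = placement_jitter_sd,
                 central_gap = central_gap,
                 scattered_points = as.integer(scattered_points),
                 scattered_min_sep = scattered_min_sep,
                 cell_spacing = cell_spacing, jitter_sd = jitter_sd,
                 cell_type = cell_type, domain = domain,
                 seed = as.integer(seed)),
            class = "spot_spec")
}

#' Generate a synthetic spotted point pattern with known ground truth
#'
#' @param spec A [spot_spec()].
#'
#' @return A list of class `pattern_set`: `patterns` (single
#'   [point_pattern()] named by the cell type) and `truth` (`n_spots`,
#'   planted centres, `elongation`, `scattered_points`, `central_gap`).
#' @export
#'
#' @examples
#' spots <- generate_spots(spot_spec(n_spots = 8, seed = 3))
#' count_spots(trim_margins(spots$patterns[[1]]))
generate_spots <- function(spec) {
  if (!inherits(spec, "spot_spec")) rlang::abort("`spec` must be a `spot_spec`.")
  d <- spec$domain
  n_cols <- ceiling(spec$n_spots / spec$n_rows)
  row_y <- d$length_y / 2 +
    (seq_len(spec$n_rows) - (spec$n_rows + 1) / 2) * spec$row_spacing
  col_x <- (d$length_x / 2 +
              (seq_len(n_cols) - ceiling(n_cols / 2)) * d$length_x / n_cols) %%
    d$length_x
  centers <- cbind(x = rep(col_x, times = spec$n_rows),
                   y = rep(row_y, each = n_cols))[seq_len(spec$n_spots), ,
                                                  drop = FALSE]
  a <- spec$spot_radius * sqrt(spec$elongation)
  b <- spec$spot_radius / sqrt(spec$elongation)

  with_seed(spec$seed, {
    if (spec$placement == "jittered" && spec$n_spots > 0) {
      centers[, 1] <- centers[, 1] +
        stats::rnorm(spec$n_spots, 0, spec$placement_jitter_sd)
      centers[, 2] <- centers[, 2] +
        stats::rnorm(spec$n_spots, 0, spec$placement_jitter_sd)
    }
    pts <- do.call(rbind, lapply(seq_len(spec$n_spots), function(i) {
      disk <- hex_strip(4 * a, -b, b, spec$cell_spacing, jitter_sd = 0)
      disk[, 1] <- disk[, 1] - 2 * a
      keep <- (disk[, 1] / a)^2 + (disk[, 2] / b)^2 <= 1
      disk <- disk[keep, , drop = FALSE]
      disk <- disk + matrix(stats::rnorm(2 * nrow(disk), 0, spec$jitter_sd),
                            ncol = 2)
      cbind(disk[, 1] + centers[i, 1], disk[, 2] + centers[i, 2])
    }))
    if (is.null(pts)) pts <- cbind(numeric(0), numeric(0))
    scattered <- matrix(numeric(0), ncol = 2)
    tries <- 0
    while (nrow(scattered) < spec$scattered_points && tries < 10000) {
      tries <- tries + 1
      cand <- c(stats::runif(1, 0, d$length_x),
                stats::runif(1, 0.12 * d$length_y, 0.88 * d$length_y))
      others <- rbind(pts, scattered)
      if (nrow(others) == 0 ||
          min(cylinder_dist_cpp(c(others[, 1], cand[1]),
                                c(others[, 2], cand[2]),
                                d$length_x)[nrow(others) + 1, -(nrow(others) + 1)]) >
            spec$scattered_min_sep) {
        scattered <- rbind(scattered, cand)
      }
    }
  })
  if (nrow(scattered) < spec$scattered_points) {
    rlang::abort("could not place all scattered points at the required separation.")
  }
  all_pts <- rbind(pts, scattered)
  all_pts[, 2] <- pmin(pmax(all_pts[, 2], 0), d$length_y)
  pat <- point_pattern(tibble::tibble(x = all_pts[, 1], y = all_pts[, 2]),
                       d, cell_type = spec$cell_type)
  patterns <- stats::setNames(list(pat), spec$cell_type)
  truth <- list(n_spots = spec$n_spots,
                centers = centers,
                spot_radius = spec$spot_radius,
                elongation = spec$elongation,
                scattered_points = spec$scattered_points,
                central_gap = spec$central_gap,
                row_spacing = spec$row_spacing)
  structure(list(patterns = patterns, truth = truth), class = "pattern_set")
}

#' Generate a developmental snapshot series with planted formation days
#'
#' Emulates daily snapshots of interstripe (`Xd`) cells: a single central
#' band is present from the first day; a dorsal band (`X1D`) appears on
#' `day_X1D` and a ventral band (`X1V`) on `day_X1V`, each offset
#' `band_offset` um from the centre so the pattern bounds jump well past the
#' formation threshold. Day-to-day bound jitter below threshold/2 can be
#' added via `growth_jitter_sd`.
#'
#' @param spec A [band_spec()] providing the domain, band width, spacing and
#'   seed (its `n_bands`, `gap` and `breaks` are ignored).
#' @param day_X1D,day_X1V Planted appearance days (dpf); `NA` to never
#'   appear.
#' @param d_range Integer range `c(first, last)` of generated days.
#' @param band_offset Centre-to-centre offset of the new bands (um).
#' @param growth_jitter_sd SD (um) of daily jitter of band extents.
#'
#' @return A list of class `pattern_set`: `patterns` (list of `Xd`
#'   [point_pattern()]s with `day` attributes) and `truth`
#'   (`day_X1D`, `day_X1V`).
#' @export
generate_snapshot_series <- function(spec = band_spec(), day_X1D = 41,
                                     day_X1V = 43, d_range = c(32, 62),
                                     band_offset = 900,
                                     growth_jitter_sd = 0) {
  if (!inherits(spec, "band_spec")) rlang::abort("`spec` must be a `band_spec`.")
  d <- spec$domain
  days <- seq(d_range[1], d_range[2])
  snaps <- with_seed(spec$seed, lapply(days, function(day) {
    centers <- d$length_y / 2
    if (!is.na(day_X1D) && day >= day_X1D) {
      centers <- c(centers, d$length_y / 2 + band_offset)
    }
    if (!is.na(day_X1V) && day >= day_X1V) {
      centers <- c(centers, d$length_y / 2 - band_offset)
    }
    pts <- do.call(rbind, lapply(centers, function(yc) {
      w <- spec$band_width +
        if (growth_jitter_sd > 0) abs(stats::rnorm(1, 0, growth_jitter_sd)) else 0
      hex_strip(d$length_x, yc - w / 2, yc + w / 2, spec$cell_spacing,
                spec$jitter_sd)
    }))
    pts[, 2] <- pmin(pmax(pts[, 2], 0), d$length_y)
    point_pattern(tibble::tibble(x = pts[, 1], y = pts[, 2]), d,
                  cell_type = "Xd", day = day)
  }))
  structure(list(patterns = snaps,
                 truth = list(day_X1D = day_X1D, day_X1V = day_X1V)),
            class = "pattern_set")
}

#' Generate a noisy figure-eight sample
#'
#' Points on two tangent unit-radius circles with Gaussian jitter; the
#' classic shape with one connected component and two loops. Placed on a
#' 10 x 2 domain wide enough that the periodic x direction never links the
#' sample to itself, so the plain topology is measured.
#'
#' @param n Number of points (split evenly between the circles).
#' @param noise_sd Gaussian jitter SD per coordinate (same units as the
#'   unit-radius circles).
#' @param seed Integer seed.
#'
#' @return A [point_pattern()] (cell type `"figure8"`) on `domain(10, 2)`.
#' @export
#'
#' @examples
#' f8 <- generate_figure_eight(200, 0.05, seed = 1)
#' diag <- compute_persistence(f8, max_dim = 1)
#' count_significant(diag, 1, tp = 0.3, tb = 0.3)  # 2 loops
generate_figure_eight <- function(n = 200, noise_sd = 0.05, seed = 1) {
  stopifnot(n >= 2, noise_sd >= 0)
  d <- domain(10, 2)
  n1 <- floor(n / 2)
  with_seed(seed, {
    th1 <- stats::runif(n1, 0, 2 * pi)
    th2 <- stats::runif(n - n1, 0, 2 * pi)
    x <- c(4 + cos(th1), 6 + cos(th2)) + stats::rnorm(n, 0, noise_sd)
    y <- c(1 + sin(th1), 1 + sin(th2)) + stats::rnorm(n, 0, noise_sd)
  })
  y <- pmin(pmax(y, 0), d$length_y)
  point_pattern(tibble::tibble(x = x, y = y), d, cell_type = "figure8")
}
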