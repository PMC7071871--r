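# one shared wild-type-like fixture for the costlier persistence tests
wt <- generate_bands(band_spec(seed = 7))
wt_xd <- trim_margins(wt$patterns$Xd)
wt_xd_diag <- compute_persistence(wt_xd, max_dim = 1)

test_that("three complete interstripes give three significant loops", {
  expect_equal(count_bands(wt_xd, diagram = wt_xd_diag), 3)
  # exactly one wrap cycle survives the cap; the rest die at the band gaps
  d1 <- wt_xd_diag[wt_xd_diag$dim == 1, ]
  sig <- d1[(d1$death - d1$birth) >= 200 & d1$birth <= 80, ]
  expect_equal(nrow(sig), 3)
  expect_equal(sum(!is.finite(sig$death)), 1)
})

test_that("a wide break lowers the interstripe count and is flagged", {
  broken <- generate_bands(band_spec(
    seed = 7, breaks = data.frame(band = 2, x = 1500, width = 300)))
  xd <- trim_margins(broken$patterns$Xd)
  expect_equal(count_bands(xd), 2)  # 300 um gap >> 2 * tb1(Xd)
  flags <- detect_breaks(xd, trim_margins(broken$patterns$Xl),
                         trim_margins(broken$patterns$M))
  expect_true(flags$interstripe_break)
  expect_false(flags$stripe_break)  # both stripes are intact
  expect_equal(flags$n_stripes_xl, 2)
  expect_equal(flags$n_stripes_m, 2)
})

test_that("break flags follow the stated count rules", {
  # craft counts directly through config expectations
  cfg4 <- quant_config(expected_interstripes = 4)
  expect_true(count_bands(wt_xd, cfg4, diagram = wt_xd_diag) <
                cfg4$expected_interstripes)
  flags <- detect_breaks(wt_xd, trim_margins(wt$patterns$Xl),
                         trim_margins(wt$patterns$M), cfg4)
  expect_true(flags$interstripe_break)   # 3 < 4 expected
  expect_false(flags$stripe_break)
  expect_error(
    detect_breaks(wt_xd, trim_margins(wt$patterns$Xl),
                  random_pattern(10, 1, dom = domain(10, 10))),
    "domain")
})

test_that("max band width matches the analytic two-row construction", {
  # Two single-file rows, in-row spacing s = 100, y-gap g = 500, periodic x.
  # The band loop is born at s/2; it dies when the diagonal edges appear and
  # triangulate the gap, at radius sqrt(g^2 + s^2)/2 (the Rips death), so
  # width = sqrt(g^2 + s^2) - s, close to the g - s ball-picture idealization.
  dom <- domain(3000, 2200)
  s <- 100
  g <- 500
  xs <- seq(0, 2900, by = s)
  pp <- point_pattern(data.frame(x = rep(xs, 2),
                                 y = rep(c(850, 850 + g), each = length(xs))),
                      dom, "Xl")
  dg <- compute_persistence(pp, max_dim = 1)
  fin <- dg[dg$dim == 1 & is.finite(dg$death), ]
  fin <- fin[(fin$death - fin$birth) >= 200 & fin$birth <= 100, ]
  expect_equal(nrow(fin), 1)
  expect_equal(fin$birth, s / 2)
  expect_equal(fin$death, sqrt(g^2 + s^2) / 2)
  expect_equal(max_band_width(pp), sqrt(g^2 + s^2) - s)
  # and the idealized gap-minus-spacing value holds within one cell spacing
  expect_lt(abs(max_band_width(pp) - (g - s)), s)
  # scale equivariance: everything doubled doubles the width
  pp2 <- point_pattern(data.frame(x = pp$x * 2, y = pp$y * 2),
                       domain(6000, 4400), "Xl")
  expect_equal(max_band_width(pp2), 2 * (sqrt(g^2 + s^2) - s))
})

test_that("width recovers gap minus spacing on generated bands", {
  expect_equal(max_band_width(wt_xd, diagram = wt_xd_diag),
               wt$truth$width_from_xd, tolerance = 50 / 450)  # one cell spacing
  xl <- trim_margins(wt$patterns$Xl)
  expect_equal(max_band_width(xl), wt$truth$width_from_xl,
               tolerance = 50 / 450)
})

test_that("identical jitter-free bands report equal widths", {
  calm <- generate_bands(band_spec(seed = 1, jitter_sd = 0))
  dg <- compute_persistence(trim_margins(calm$patterns$Xd), max_dim = 1)
  fin <- dg[dg$dim == 1 & is.finite(dg$death), ]
  fin <- fin[(fin$death - fin$birth) >= 200 & fin$birth <= 80, ]
  expect_equal(nrow(fin), 2)
  expect_equal(diff(range(fin$death - fin$birth)), 0, tolerance = 1e-9)
})

test_that("no significant finite loop raises a typed 'no bands' error", {
  pp <- random_pattern(30, seed = 12)  # unstructured scatter
  expect_error(max_band_width(pp), class = "pigmentr_no_bands")
})

test_that("flat bands have near-zero curviness, sinusoidal bands match quadrature", {
  cl <- band_clusters(wt_xd, 3)
  flat <- curviness(cl)
  expect_lt(abs(flat$curviness), 2.5)  # jitter noise floor only
  amp <- 300
  wavy <- generate_bands(band_spec(seed = 7, n_bands = 2, amplitude = amp,
                                   wavelength = 3000))
  xdw <- trim_margins(wavy$patterns$Xd)
  clw <- band_clusters(xdw, 2)
  got <- curviness(clw)
  arc <- stats::integrate(function(x) {
    sqrt(1 + (amp * 2 * pi / 3000)^2 * cos(2 * pi * x / 3000)^2)
  }, 0, 3000)$value
  expected <- 100 * (arc / 3000 - 1)
  expect_equal(got$curviness, expected, tolerance = 3 / expected)
  # curviness strictly increases with amplitude
  expect_gt(got$curviness, flat$curviness)
})

test_that("curviness is invariant to wrapped x-translation and to duplicating a band", {
  shift <- 700
  dom <- pattern_domain(wt_xd)
  moved <- point_pattern(data.frame(x = (wt_xd$x + shift) %% dom$length_x,
                                    y = wt_xd$y), dom, "Xd")
  a <- curviness(band_clusters(wt_xd, 3))
  b <- curviness(band_clusters(moved, 3))
  expect_equal(a$curviness, b$curviness, tolerance = 0.15)
  # the mean over bands is unchanged by duplicating every band
  dup <- point_pattern(rbind(as.data.frame(wt_xd)[, c("x", "y")],
                             data.frame(x = wt_xd$x, y = wt_xd$y + 1e-9)),
                       dom, "Xd")
  d <- curviness(band_clusters(dup, 3), bin_width = a$bin_width)
  expect_equal(d$curviness, a$curviness, tolerance = 0.05)
})

test_that("non-spanning clusters are excluded from curviness with a warning", {
  dom <- domain(2000, 1000)
  pts <- rbind(
    data.frame(x = seq(0, 1990, by = 40), y = 300),   # a spanning band
    data.frame(x = seq(500, 700, by = 40), y = 700))  # a short arc
  pp <- point_pattern(pts, dom, "Xd")
  cl <- band_clusters(pp, 2)
  expect_warning(res <- curviness(cl), "span")
  expect_equal(res$n_bands_used, 1)
})

test_that("quantify_stripes assembles a coherent report", {
  rep <- quantify_stripes(wt_xd, trim_margins(wt$patterns$Xl),
                          trim_margins(wt$patterns$M))
  expect_s3_class(rep, "band_report")
  expect_equal(rep$n_interstripes, 3)
  expect_equal(rep$n_stripes_xl, 2)
  expect_equal(rep$n_stripes_m, 2)
  expect_false(rep$interstripe_break)
  expect_false(rep$stripe_break)
  expect_equal(rep$max_interstripe_width, wt$truth$width_from_xl,
               tolerance = 50 / 450)
  expect_equal(rep$max_stripe_width, wt$truth$width_from_xd,
               tolerance = 50 / 450)
  expect_lt(abs(rep$curviness), 2.5)
  td <- tidy(rep)
  expect_true(all(c("metric", "value") %in% names(td)))
})
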