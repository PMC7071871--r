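# hand-built cluster sets let the summary statistics be tested in isolation
fake_cluster_set <- function(clusters, dom = domain(3000, 2200),
                             cell_type = "Il") {
  asg <- tibble::tibble(x = numeric(0), y = numeric(0), cluster = integer(0))
  structure(list(assignments = asg, clusters = clusters),
            class = "cluster_set", domain = dom, cell_type = cell_type)
}

test_that("count_spots recovers the planted spot count", {
  spots <- generate_spots(spot_spec(n_spots = 8, seed = 3))
  pat <- trim_margins(spots$patterns$Il)
  expect_equal(count_spots(pat), 8)
  lone <- point_pattern(data.frame(x = 1500, y = 1100), domain(3000, 2200), "Il")
  expect_equal(count_spots(lone), 1)
  empty <- point_pattern(data.frame(x = numeric(0), y = numeric(0)),
                         domain(3000, 2200), "Il")
  expect_warning(k <- count_spots(empty), "empty")
  expect_equal(k, 0L)
})

test_that("scattered lone cells each add a spurious component", {
  spots <- generate_spots(spot_spec(n_spots = 6, scattered_points = 5,
                                    scattered_min_sep = 260, seed = 11))
  pat <- trim_margins(spots$patterns$Il)
  expect_equal(count_spots(pat), 6 + 5)
})

test_that("count_spots agrees with MST component count at 2 * tp0", {
  spots <- generate_spots(spot_spec(n_spots = 8, seed = 5))
  pat <- trim_margins(spots$patterns$Il)
  D <- pattern_dist(pat)
  expect_equal(count_spots(pat), oracle_components(D, 2 * 100))
})

test_that("spot_size uses the lower median of cluster cardinalities", {
  cs <- fake_cluster_set(tibble::tibble(cluster = 1:3, n = c(10, 20, 30),
                                        centroid_x = 1:3, centroid_y = 1:3,
                                        lambda1 = 1, lambda2 = 1, diameter = 1))
  expect_equal(spot_size(cs), 20)
  cs4 <- fake_cluster_set(tibble::tibble(cluster = 1:4, n = c(10, 20, 30, 40),
                                         centroid_x = 1:4, centroid_y = 1:4,
                                         lambda1 = 1, lambda2 = 1, diameter = 1))
  expect_equal(spot_size(cs4), 20)  # lower median on even counts
})

test_that("roundness is near 1 for round spots and grows with elongation", {
  round_set <- generate_spots(spot_spec(n_spots = 6, elongation = 1, seed = 2))
  pr <- trim_margins(round_set$patterns$Il)
  clr <- spot_clusters(pr, count_spots(pr))
  r1 <- spot_roundness(clr)
  expect_gte(r1, 1)
  expect_lt(r1, 1.6)
  oval_set <- generate_spots(spot_spec(n_spots = 6, elongation = 2, seed = 2))
  po <- trim_margins(oval_set$patterns$Il)
  clo <- spot_clusters(po, count_spots(po))
  r2 <- spot_roundness(clo)
  expect_gt(r2, r1)          # monotone in planted elongation
  expect_equal(r2, 4, tolerance = 0.4)  # (a/b)^2 = elongation^2
})

test_that("degenerate clusters are excluded from roundness", {
  cs <- fake_cluster_set(tibble::tibble(
    cluster = 1:3, n = c(25, 2, 30), centroid_x = 1:3, centroid_y = 1:3,
    lambda1 = c(4, 1, 9), lambda2 = c(2, 0, 3), diameter = 1))
  expect_warning(r <- spot_roundness(cs), "degenerate")
  expect_equal(r, 2.5)  # median of 2 and 3
  all_bad <- fake_cluster_set(tibble::tibble(
    cluster = 1, n = 2, centroid_x = 1, centroid_y = 1,
    lambda1 = 1, lambda2 = 0, diameter = 1))
  expect_error(suppressWarnings(spot_roundness(all_bad)), "degenerate")
})

test_that("spacing SD matches the hand-computed example and wraps in x", {
  dom <- domain(100000, 2200)  # wide: no wrap in play
  cs <- fake_cluster_set(tibble::tibble(
    cluster = 1:3, n = 10, centroid_x = c(0, 100, 300), centroid_y = 0,
    lambda1 = 1, lambda2 = 1, diameter = 1), dom = dom)
  expect_equal(spot_spacing_sd(cs), sd(c(100, 100, 200)))
  # translating the centroids across the seam changes nothing
  dom2 <- domain(1000, 2200)
  base <- tibble::tibble(cluster = 1:3, n = 10,
                         centroid_x = c(100, 400, 700), centroid_y = 500,
                         lambda1 = 1, lambda2 = 1, diameter = 1)
  moved <- dplyr::mutate(base, centroid_x = (centroid_x + 850) %% 1000)
  expect_equal(spot_spacing_sd(fake_cluster_set(moved, dom = dom2)),
               spot_spacing_sd(fake_cluster_set(base, dom = dom2)))
  one <- fake_cluster_set(base[1, ], dom = dom2)
  expect_error(spot_spacing_sd(one), "at least 2")
})

test_that("lattice-placed spots have near-zero spacing SD", {
  spots <- generate_spots(spot_spec(n_spots = 8, seed = 4))
  pat <- trim_margins(spots$patterns$Il)
  cl <- spot_clusters(pat, count_spots(pat))
  expect_lt(spot_spacing_sd(cl), 15)  # centroid noise only
  jittered <- generate_spots(spot_spec(n_spots = 8, placement = "jittered",
                                       placement_jitter_sd = 80, seed = 4))
  pj <- trim_margins(jittered$patterns$Il)
  clj <- spot_clusters(pj, count_spots(pj))
  expect_gt(spot_spacing_sd(clj), spot_spacing_sd(cl))
})

test_that("center width follows its defining formula", {
  dom <- domain(3000, 2200)
  mk <- function(d, diam) fake_cluster_set(tibble::tibble(
    cluster = 1:2, n = 10, centroid_x = 1500, centroid_y = 1100 + c(-d, d),
    lambda1 = 1, lambda2 = 1, diameter = diam), dom = dom)
  expect_equal(center_width(mk(400, 0)), 800)        # point-like spots: 2d
  expect_equal(center_width(mk(400, 150)), 650)      # 2d - median diameter
  expect_equal(center_width(mk(10, 500)), 0)         # floored at zero
  # midline variant ignores the x offset
  off <- fake_cluster_set(tibble::tibble(
    cluster = 1, n = 10, centroid_x = 300, centroid_y = 1500,
    lambda1 = 1, lambda2 = 1, diameter = 0), dom = dom)
  expect_equal(center_width(off, midline = TRUE), 800)
  expect_equal(center_width(off), 2 * sqrt(1200^2 + 400^2))
})

test_that("a planted central gap is recovered within one spot radius", {
  gap <- 700
  spots <- generate_spots(spot_spec(n_spots = 8, central_gap = gap, seed = 6))
  pat <- trim_margins(spots$patterns$Il)
  rep <- quantify_spots(pat)
  expect_equal(rep$n_spots, 8)
  expect_equal(rep$center_width, gap, tolerance = 100 / gap)
})

test_that("the spot pipeline is deterministic end to end", {
  a <- quantify_spots(trim_margins(generate_spots(spot_spec(seed = 8))$patterns$Il))
  b <- quantify_spots(trim_margins(generate_spots(spot_spec(seed = 8))$patterns$Il))
  expect_identical(a, b)
  expect_s3_class(a, "spot_report")
  expect_equal(a$n_spots, 8)
  expect_true(all(c("metric", "value") %in% names(tidy(a))))
})
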