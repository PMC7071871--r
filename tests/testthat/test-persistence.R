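test_that("two points give one dim-0 death at half their distance", {
  dom <- domain(1000, 400)
  pp <- point_pattern(data.frame(x = c(0, 120), y = c(0, 0)), dom, "M")
  dg <- compute_persistence(pp, max_dim = 1)
  d0 <- dg[dg$dim == 0, ]
  expect_equal(nrow(d0), 2)
  expect_equal(sort(d0$death), c(60, Inf))
  expect_equal(d0$birth, c(0, 0))
  expect_equal(sum(dg$dim == 1), 0)
})

test_that("diagrams match an independent dense GF(2) reduction", {
  for (seed in 1:8) {
    n <- sample(8:13, 1)
    pp <- random_pattern(n, seed = 100 + seed, dom = domain(400, 300))
    D <- pattern_dist(pp)
    cap <- 2 * min(300 / 2, 400 / 8)  # package default, distance scale
    got <- compute_persistence(pp, max_dim = 1, scale = "distance")
    ref <- oracle_rips_pairs(D, cap = cap)
    got <- as.data.frame(got[, c("dim", "birth", "death")])
    got <- got[order(got$dim, got$birth, got$death), ]
    expect_equal(unname(as.matrix(got)), unname(as.matrix(ref)),
                 tolerance = 1e-10)
  }
})

test_that("radius scale halves the distance scale", {
  pp <- random_pattern(30, seed = 2)
  a <- compute_persistence(pp, max_dim = 1, scale = "radius")
  b <- compute_persistence(pp, max_dim = 1, scale = "distance")
  expect_equal(a$birth * 2, b$birth)
  expect_equal(a$death * 2, b$death)
})

test_that("diagrams are equivariant under uniform scaling", {
  pp <- random_pattern(40, seed = 9, dom = domain(500, 400))
  big <- point_pattern(data.frame(x = pp$x * 2, y = pp$y * 2),
                       domain(1000, 800), "M")
  dg1 <- compute_persistence(pp, max_dim = 1)
  dg2 <- compute_persistence(big, max_dim = 1)
  expect_equal(dg2$birth, dg1$birth * 2, tolerance = 1e-9)
  expect_equal(dg2$death, dg1$death * 2, tolerance = 1e-9)
})

test_that("diagrams are invariant under wrapped x- and in-domain y-translation", {
  pp <- random_pattern(50, seed = 4, dom = domain(800, 1000))
  tr <- trim_margins(pp, 0.2)  # leave y room to translate
  dom <- pattern_domain(tr)
  moved <- point_pattern(data.frame(x = (tr$x + 333) %% dom$length_x,
                                    y = tr$y + 150), dom, "M")
  a <- compute_persistence(tr, max_dim = 1)
  b <- compute_persistence(moved, max_dim = 1)
  expect_equal(a$birth, b$birth, tolerance = 1e-9)
  expect_equal(a$death, b$death, tolerance = 1e-9)
})

test_that("count_significant applies the stated threshold rules", {
  dg <- tibble::tibble(dim = c(0L, 0L, 0L, 1L, 1L, 1L, 1L),
                       birth = c(0, 0, 0, 20, 20, 150, 30),
                       death = c(40, 150, Inf, 220, 219.99, 400, Inf))
  # dim 0: strictly greater than tp; essential counts
  expect_equal(count_significant(dg, 0, tp = 100), 2)
  expect_equal(count_significant(dg, 0, tp = 40), 2)   # 40 is not > 40
  expect_equal(count_significant(dg, 0, tp = 39.9), 3)
  # dim 1: persistence >= tp (boundary included), birth <= tb,
  # capped features count as infinitely persistent
  expect_equal(count_significant(dg, 1, tp = 200, tb = 80), 2)
  expect_equal(count_significant(dg, 1, tp = 199.99, tb = 80), 3)
  expect_equal(count_significant(dg, 1, tp = 200, tb = 200), 3)
  expect_equal(count_significant(tibble::tibble(dim = integer(0),
                                                birth = numeric(0),
                                                death = numeric(0)),
                                 1, tp = 200), 0)
})

test_that("dim-0 significant counts equal union-find components at 2*tp", {
  for (seed in 1:10) {
    n <- sample(30:120, 1)
    pp <- random_pattern(n, seed = 200 + seed)
    D <- pattern_dist(pp)
    dg <- compute_persistence(pp, max_dim = 0)
    for (tp in c(20, 40, 80)) {
      expect_equal(count_significant(dg, 0, tp = tp),
                   oracle_components(D, 2 * tp))
    }
  }
})

test_that("duplicating a point changes no significant count", {
  pp <- random_pattern(60, seed = 31)
  dup <- point_pattern(rbind(as.data.frame(pp)[, c("x", "y")],
                             as.data.frame(pp)[1, c("x", "y")]),
                       pattern_domain(pp), "M")
  a <- compute_persistence(pp, max_dim = 1)
  b <- compute_persistence(dup, max_dim = 1)
  for (tp in c(20, 50, 100)) {
    expect_equal(count_significant(a, 0, tp), count_significant(b, 0, tp))
    expect_equal(count_significant(a, 1, tp, tb = 60),
                 count_significant(b, 1, tp, tb = 60))
  }
})

test_that("diagram csv export round-trips", {
  pp <- random_pattern(25, seed = 8)
  dg <- compute_persistence(pp, max_dim = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_diagram(dg, path)
  back <- read_diagram(path)
  expect_equal(back$dim, dg$dim)
  expect_equal(back$birth, dg$birth)
  expect_equal(back$death, dg$death)  # Inf survives the round trip
})

test_that("invalid persistence inputs error clearly", {
  pp <- random_pattern(10, seed = 1)
  expect_error(compute_persistence(pp, max_dim = 2), "max_dim")
  empty <- point_pattern(data.frame(x = numeric(0), y = numeric(0)),
                         domain(10, 10), "M")
  expect_error(compute_persistence(empty), "empty")
  expect_error(compute_persistence(pp, max_radius = -1), "max_radius")
})
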