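test_that("shoelace area matches hand values and is orientation-invariant", {
  sq <- unit_square()
  expect_identical(polygon_area(sq), 1)
  rev_sq <- polygon2d(sq$vertices[4:1, ])
  expect_identical(polygon_area(rev_sq), 1)
  tri <- polygon2d(cbind(c(0, 4, 0), c(0, 0, 3)))
  expect_identical(polygon_area(tri), 6)
})

test_that("polygon_area is orientation- and translation-invariant on random polygons", {
  set.seed(42)
  for (i in 1:20) {
    p <- random_simple_polygon(sample(4:10, 1))
    a <- polygon_area(p)
    expect_equal(polygon_area(polygon2d(p$vertices[rev(seq_len(nrow(p$vertices))), ])), a)
    shift <- matrix(rep(stats::runif(2, -10, 10), each = nrow(p$vertices)), ncol = 2)
    expect_equal(polygon_area(polygon2d(p$vertices + shift)), a, tolerance = 1e-12)
    # independent oracle for the shoelace formula
    expect_equal(a, abs(pracma::polyarea(p$vertices[, 1], p$vertices[, 2])),
                 tolerance = 1e-12)
  }
})

test_that("invalid polygons are rejected", {
  expect_error(polygon2d(cbind(c(0, 1), c(0, 1))), "at least 3 vertices")
  # bow-tie self-intersection
  expect_error(polygon2d(cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))),
               "self-intersecting")
  # collinear, zero area
  expect_error(polygon2d(cbind(c(0, 1, 2), c(0, 1, 2))), "zero area")
  expect_error(polygon2d(cbind(c(0, 0, 1, 1), c(0, 0, 0, 1))), "duplicated")
})

test_that("union area: disjoint additivity, idempotence, and exact overlap", {
  a <- unit_square(0)
  b <- unit_square(2)
  expect_equal(union_area(list(a, b)), 2)
  expect_equal(union_area(list(a, a)), 1)
  expect_equal(union_area(list(a, unit_square(0.5))), 1.5)
  expect_identical(union_area(list()), 0)
  expect_equal(union_area(list(a)), 1)
})

test_that("union area never exceeds the area sum, with equality iff disjoint", {
  set.seed(7)
  for (i in 1:15) {
    centres <- matrix(stats::runif(6, 0, 3), ncol = 2)
    ps <- lapply(seq_len(3), function(k)
      random_simple_polygon(sample(5:9, 1), centres[k, ], radius = 1.2))
    u <- union_area(ps)
    s <- sum(vapply(ps, polygon_area, numeric(1)))
    expect_lte(u, s + 1e-9)
  }
  # far-apart polygons are disjoint: equality holds
  ps <- list(random_simple_polygon(7, c(0, 0)), random_simple_polygon(7, c(10, 0)))
  expect_equal(union_area(ps),
               sum(vapply(ps, polygon_area, numeric(1))), tolerance = 1e-12)
})

test_that("union area agrees with the Monte-Carlo point-in-union oracle", {
  set.seed(99)
  for (i in 1:8) {
    centres <- matrix(stats::runif(6, 0, 2), ncol = 2)
    ps <- lapply(seq_len(3), function(k)
      random_simple_polygon(sample(5:9, 1), centres[k, ], radius = 1.3))
    u <- union_area(ps)
    mc <- mc_union_area(ps, n_points = 2e5)
    expect_lt(abs(u - mc$est), 3.5 * mc$se + 1e-9)
  }
})

test_that("Bo/Ca ratio counts overlapping bone area once", {
  region <- unit_square(0, 0, side = 2)
  bone <- unit_square(0.25, 0.25)
  r <- carpal_radiograph(list(bone), region)
  expect_equal(compute_bo_ca(r), 0.25)
  # two coincident bones: common area counted once
  r2 <- carpal_radiograph(list(bone, bone), region)
  expect_equal(compute_bo_ca(r2), 0.25)
  # half-overlapping bones: union 1.5 over 4
  r3 <- carpal_radiograph(list(unit_square(0, 0), unit_square(0.5, 0)), region)
  expect_equal(compute_bo_ca(r3), 0.375)
})

test_that("carpal radiograph inputs are validated", {
  region <- unit_square(0, 0, side = 2)
  expect_error(carpal_radiograph(list(), region), "non-empty")
  big <- unit_square(0, 0, side = 3)
  expect_error(carpal_radiograph(list(big), region), "larger than the carpal region")
})
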