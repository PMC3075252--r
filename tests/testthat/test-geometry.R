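test_that("point-segment distance handles foot, endpoint and degenerate cases", {
  r <- point_segment_distance(c(2, 3), c(0, 0, 4, 0))
  expect_equal(r$distance, 3)
  expect_true(r$has_foot)
  expect_equal(r$foot, c(2, 0))

  # foot falls beyond the far endpoint: distance to that endpoint
  r <- point_segment_distance(c(6, 0), c(0, 0, 4, 0))
  expect_equal(r$distance, 2)
  expect_false(r$has_foot)

  # a point coincident with an endpoint projects onto the boundary
  r <- point_segment_distance(c(0, 0), c(0, 0, 4, 0))
  expect_equal(r$distance, 0)
  expect_true(r$has_foot)
  expect_equal(r$foot, c(0, 0))

  # degenerate segment treated as a point, never a foot
  r <- point_segment_distance(c(3, 4), c(0, 0, 0, 0))
  expect_equal(r$distance, 5)
  expect_false(r$has_foot)

  expect_error(point_segment_distance(c(NA, 1), c(0, 0, 1, 0)),
               "non-finite")
  expect_error(point_segment_distance(c(0, 1), c(0, 0, Inf, 0)),
               "non-finite")
})

test_that("point-segment distance matches the closed form on random pairs", {
  set.seed(101)
  for (i in 1:500) {
    p <- runif(2, -10, 10)
    s <- rand_segment()
    got <- point_segment_distance(p, s)
    ora <- psd_closed_form(p, s[1:2], s[3:4])
    expect_equal(got$distance, ora$dist, tolerance = 1e-9)
    expect_identical(got$has_foot, ora$t >= 0 && ora$t <= 1)
  }
})

test_that("segment pair geometry classifies the three overlap patterns", {
  # parallel congruent segments: full overlap both ways
  g <- segment_pair_geometry(c(0, 0, 4, 0), c(0, 1, 4, 1))
  expect_equal(g$dmin, 1)
  expect_equal(g$dmax, 1)
  expect_identical(g$pattern, "FULL_OVERLAP")
  expect_equal(g$dmax_line, 1)

  # collinear disjoint: no perpendicular feet at all
  g <- segment_pair_geometry(c(0, 0, 4, 0), c(10, 0, 14, 0))
  expect_identical(g$pattern, "NONE")
  expect_equal(g$dmin, 6)
  expect_true(is.na(g$dmax_line))

  # staggered parallel: one foot each way but no full overlap
  g <- segment_pair_geometry(c(0, 0, 4, 0), c(3, 2, 8, 2))
  expect_identical(g$pattern, "PARTIAL")
  expect_equal(g$dmin, 2)
  # all four endpoint projections, from the closed form
  d <- c(psd_closed_form(c(0, 0), c(3, 2), c(8, 2))$dist,
         psd_closed_form(c(4, 0), c(3, 2), c(8, 2))$dist,
         psd_closed_form(c(3, 2), c(0, 0), c(4, 0))$dist,
         psd_closed_form(c(8, 2), c(0, 0), c(4, 0))$dist)
  expect_equal(g$dmax, max(d), tolerance = 1e-12)
  expect_true(is.na(g$dmax_line))
})

test_that("asymmetric full overlap takes dmax_line from the overlapping side", {
  # short segment centred over a long one: only the short one's
  # endpoints have feet
  g <- segment_pair_geometry(c(1, 1, 3, 1), c(0, 0, 10, 0))
  expect_identical(g$pattern, "FULL_OVERLAP")
  expect_equal(g$dmax_line, 1)
  expect_equal(g$dmin, 1)
  expect_gt(g$dmax, 1)  # long segment's endpoints stick out

  # degenerate partner can never yield full overlap
  g <- segment_pair_geometry(c(2, 1, 2, 1), c(0, 0, 4, 0))
  expect_identical(g$pattern, "PARTIAL")
  expect_true(is.na(g$dmax_line))
})

test_that("pair geometry is symmetric in its arguments", {
  set.seed(202)
  for (i in 1:300) {
    s1 <- rand_segment(); s2 <- rand_segment()
    g12 <- segment_pair_geometry(s1, s2)
    g21 <- segment_pair_geometry(s2, s1)
    expect_equal(g12$dmin, g21$dmin)
    expect_equal(g12$dmax, g21$dmax)
    expect_identical(g12$pattern, g21$pattern)
    expect_equal(g12$dmax_line, g21$dmax_line)
  }
})

test_that("dmin agrees with a dense parametric sampling oracle", {
  set.seed(303)
  done <- 0
  while (done < 15) {
    s1 <- rand_segment(); s2 <- rand_segment()
    if (segments_cross(s1, s2)) next  # endpoint projections assume
    done <- done + 1                  # non-intersecting segments
    g <- segment_pair_geometry(s1, s2)
    ora <- dense_min_distance(s1, s2)
    # exact dmin can only undercut the sampled minimum ...
    expect_lte(g$dmin, ora + 1e-9)
    # ... and by no more than the sampling resolution
    len <- max(sqrt(sum((s1[3:4] - s1[1:2])^2)),
               sqrt(sum((s2[3:4] - s2[1:2])^2)))
    expect_lt(ora - g$dmin, 2 * len / 999)
    # dmin never exceeds any endpoint-to-endpoint distance
    ends1 <- rbind(s1[1:2], s1[3:4]); ends2 <- rbind(s2[1:2], s2[3:4])
    expect_lte(g$dmin,
               min(sqrt(outer(ends1[, 1], ends2[, 1], "-")^2 +
                        outer(ends1[, 2], ends2[, 2], "-")^2)) + 1e-12)
  }
})
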