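test_that("the decision rules reproduce the hand-derived truth table", {
  p <- default_params()
  tab <- congruence_truth_table()
  expect_gte(length(tab), 12)
  for (k in seq_along(tab)) {
    cs <- tab[[k]]
    v <- segments_congruent(cs$s1, cs$s2, p)
    expect_identical(v$congruent, cs$congruent, label = paste("case", k))
    expect_identical(v$geometry$pattern, cs$pattern,
                     label = paste("pattern, case", k))
    if (!is.null(cs$rule))
      expect_identical(v$rule, cs$rule, label = paste("rule, case", k))
    expect_identical(v$congruent, v$rule != "NONE")
  }
})

test_that("congruence verdicts are symmetric under argument swap", {
  set.seed(31)
  for (i in 1:300) {
    s1 <- rand_segment(5); s2 <- rand_segment(5)
    b <- sort(runif(3, 0, 6))
    p <- congruence_params(0, b[1], b[2], b[3], 0.5)
    expect_identical(segments_congruent(s1, s2, p)$congruent,
                     segments_congruent(s2, s1, p)$congruent)
  }
})

test_that("joint enlargement of the bounds never breaks congruence", {
  set.seed(32)
  for (i in 1:300) {
    s1 <- rand_segment(3); s2 <- rand_segment(3)
    b <- sort(runif(3, 0, 5))
    p1 <- congruence_params(0, b[1], b[2], b[3], 0.5)
    grow <- runif(1, 0, 3)
    p2 <- congruence_params(0, b[1] + grow, b[2] + grow, b[3] + grow, 0.5)
    v1 <- segments_congruent(s1, s2, p1)
    if (v1$congruent)
      expect_true(segments_congruent(s1, s2, p2)$congruent)
  }
})

test_that("all-zero bounds admit only coincident overlapping segments", {
  p0 <- congruence_params(0, 0, 0, 0, 0)
  expect_true(segments_congruent(c(0, 0, 4, 0), c(0, 0, 4, 0), p0)$congruent)
  # a sub-segment of the same line: full overlap at distance 0
  expect_true(segments_congruent(c(0, 0, 4, 0), c(1, 0, 3, 0), p0)$congruent)
  set.seed(33)
  for (i in 1:200) {
    s1 <- rand_segment(3); s2 <- rand_segment(3)
    v <- segments_congruent(s1, s2, p0)
    if (v$congruent) {
      g <- v$geometry
      # any admitted pair must lie exactly on top of one another
      expect_lt(g$dmin, 1e-6)
      expect_true(g$dmax < 1e-6 ||
                  (g$pattern == "FULL_OVERLAP" && g$dmax_line < 1e-6))
    }
  }
})

test_that("congruent_segment_map is exhaustive, symmetric and bounded", {
  p <- default_params()
  t1 <- build_mst(rbind(c(0, 0), c(4, 0), c(8, 0), c(12, 0)), "a")
  t2 <- build_mst(rbind(c(0, 1), c(4, 1), c(8, 1)), "b")
  m12 <- congruent_segment_map(t1, t2, p)
  m21 <- congruent_segment_map(t2, t1, p)
  expect_lte(nrow(m12), nrow(t1$edges) * nrow(t2$edges))
  # transpose symmetry
  expect_equal(m12[order(m12[, 1], m12[, 2]), , drop = FALSE],
               unname(m21[order(m21[, 2], m21[, 1]), c(2, 1),
                          drop = FALSE]),
               ignore_attr = TRUE)
  # self comparison: every edge pairs at least with itself
  m11 <- congruent_segment_map(t1, t1, p)
  expect_true(all(seq_len(nrow(t1$edges)) %in%
                  m11[m11[, 1] == m11[, 2], 1]))
  # far-apart tracks share nothing
  t3 <- build_mst(rbind(c(500, 500), c(504, 500)), "c")
  expect_equal(nrow(congruent_segment_map(t1, t3, p)), 0L)
  # single-vertex tracks are never congruent with anything
  t4 <- build_mst(rbind(c(0, 0)), "d")
  expect_equal(nrow(congruent_segment_map(t1, t4, p)), 0L)
})

test_that("merge_tracks unions congruent endpoints into a new MST", {
  p <- default_params()
  ta <- track1(0, 0, 4, 0, "a")
  tb <- track1(0, 1, 4, 1, "b")
  m <- merge_tracks(ta, tb, congruent_segment_map(ta, tb, p))
  expect_identical(m$kind, "generalized")
  expect_setequal(m$taxa, c("a", "b"))
  expect_equal(nrow(m$vertices), 4L)
  # K4 with two unit sides and two length-4 sides: MST = 4 + 1 + 1,
  # confirmed by exhaustive enumeration
  expect_equal(track_length(m), 6)
  expect_equal(track_length(m), brute_mst_length(m$vertices))
  # identical one-edge tracks merge to either of them
  m2 <- merge_tracks(ta, ta, congruent_segment_map(ta, ta, p))
  expect_equal(m2$vertices, ta$vertices)
  expect_equal(track_length(m2), track_length(ta))
  expect_error(merge_tracks(ta, tb, matrix(integer(0), 0, 2)),
               "non-empty")
})

test_that("merge collects only the endpoints of congruent segments", {
  # bounds tight enough that only the two parallel horizontal edges
  # match; the long vertical tails projecting onto each other at foot
  # distances up to 4 stay out
  p <- congruence_params(0.5, 1, 1.5, 2, 0.8)
  # 3-edge chains that share only their first edge region; the rest of
  # each chain veers far away
  ta <- build_mst(rbind(c(0, 0), c(4, 0), c(4, 100), c(4, 200)), "a")
  tb <- build_mst(rbind(c(0, 1), c(4, 1), c(4, -100), c(4, -200)), "b")
  pairs <- congruent_segment_map(ta, tb, p)
  expect_equal(nrow(pairs), 1L)
  m <- merge_tracks(ta, tb, pairs)
  expect_equal(nrow(m$vertices), 4L)  # not the full 8 vertices
  expect_true(all(abs(m$vertices[, 2]) <= 1))
  expect_equal(nrow(m$edges), 3L)
  expect_equal(track_length(m), brute_mst_length(m$vertices))
})
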