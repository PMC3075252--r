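# Planar geometric kernel. All coordinates are decimal degrees treated as
# plain planar (x = lon, y = lat); distances are Euclidean in that plane.

#' @keywords internal
GT_TOL <- 1e-9

.check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("non-finite coordinates in %s", what), call. = FALSE)
  invisible(x)
}

# Vectorised point-to-segment distance. All arguments are equal-length
# numeric vectors; returns list of vectors (dist, has_foot, t, foot_x,
# foot_y). Degenerate segments (length < tol) are treated as points:
# distance to the single endpoint, no foot.
psd_vec <- function(px, py, ax, ay, bx, by, tol = GT_TOL) {
  dx <- bx - ax
  dy <- by - ay
  l2 <- dx * dx + dy * dy
  deg <- l2 < tol * tol
  t <- ((px - ax) * dx + (py - ay) * dy) / l2
  t[deg] <- 0
  has_foot <- !deg & t >= -tol & t <= 1 + tol
  tc <- pmin(pmax(t, 0), 1)
  fx <- ax + tc * dx
  fy <- ay + tc * dy
  list(dist = sqrt((px - fx)^2 + (py - fy)^2),
       has_foot = has_foot, t = t, foot_x = fx, foot_y = fy)
}

#' Shortest distance from a point to a line segment
#'
#' Computes the planar Euclidean distance from a point to a segment,
#' reporting whether the perpendicular foot of the point falls within the
#' segment. When the foot falls outside, the distance is taken to the
#' nearer endpoint. This is the basic primitive behind all segment
#' congruence decisions.
#'
#' @param p numeric length-2, the point as \code{c(x, y)} (lon, lat).
#' @param s numeric length-4, the segment as \code{c(x1, y1, x2, y2)}.
#' @param tol numeric boundary tolerance in degrees; a projection
#'   parameter within \code{tol} of \code{[0, 1]} counts as a foot.
#' @return A list with components \code{distance}, \code{has_foot}
#'   (logical), and \code{foot} (numeric length-2, the nearest point on
#'   the segment).
#' @examples
#' point_segment_distance(c(2, 3), c(0, 0, 4, 0))  # distance 3, foot (2,0)
#' @export
point_segment_distance <- function(p, s, tol = GT_TOL) {
  .check_finite(p, "point")
  .check_finite(s, "segment")
  stopifnot(length(p) == 2L, length(s) == 4L)
  r <- psd_vec(p[1], p[2], s[1], s[2], s[3], s[4], tol)
  list(distance = r$dist, has_foot = r$has_foot,
       foot = c(r$foot_x, r$foot_y))
}

# Vectorised pair geometry. s1, s2 are n x 4 matrices (x1, y1, x2, y2).
# Returns list of vectors: dmin, dmax, dmax_line (NA unless full overlap),
# pattern (character). Pattern is symmetric: FULL_OVERLAP if both
# endpoints of either segment drop perpendicular feet on the other,
# PARTIAL if any single projection has a foot, NONE otherwise. A
# degenerate segment contributes only point projections and can never
# produce full overlap.
spg_vec <- function(s1, s2, tol = GT_TOL) {
  p1 <- psd_vec(s1[, 1], s1[, 2], s2[, 1], s2[, 2], s2[, 3], s2[, 4], tol)
  p2 <- psd_vec(s1[, 3], s1[, 4], s2[, 1], s2[, 2], s2[, 3], s2[, 4], tol)
  p3 <- psd_vec(s2[, 1], s2[, 2], s1[, 1], s1[, 2], s1[, 3], s1[, 4], tol)
  p4 <- psd_vec(s2[, 3], s2[, 4], s1[, 1], s1[, 2], s1[, 3], s1[, 4], tol)

  dmin <- pmin(p1$dist, p2$dist, p3$dist, p4$dist)
  dmax <- pmax(p1$dist, p2$dist, p3$dist, p4$dist)

  len1 <- sqrt((s1[, 3] - s1[, 1])^2 + (s1[, 4] - s1[, 2])^2)
  len2 <- sqrt((s2[, 3] - s2[, 1])^2 + (s2[, 4] - s2[, 2])^2)
  # full overlap of s1 onto s2: both endpoints of s1 have feet on s2
  full12 <- len1 >= tol & p1$has_foot & p2$has_foot
  full21 <- len2 >= tol & p3$has_foot & p4$has_foot
  any_foot <- p1$has_foot | p2$has_foot | p3$has_foot | p4$has_foot

  max12 <- pmax(p1$dist, p2$dist)
  max21 <- pmax(p3$dist, p4$dist)
  dmax_line <- rep(NA_real_, nrow(s1))
  both <- full12 & full21
  dmax_line[full12] <- max12[full12]
  dmax_line[full21 & !full12] <- max21[full21 & !full12]
  # both directions qualify: take the smaller side-maximum
  dmax_line[both] <- pmin(max12, max21)[both]

  pattern <- ifelse(full12 | full21, "FULL_OVERLAP",
                    ifelse(any_foot, "PARTIAL", "NONE"))
  list(dmin = dmin, dmax = dmax, dmax_line = dmax_line, pattern = pattern)
}

#' Distance summary between two line segments
#'
#' Projects each endpoint of each segment onto the other segment and
#' summarises the four resulting distances. \code{dmin} and \code{dmax}
#' are the minimum and maximum of the four endpoint projections. The
#' overlap \code{pattern} classifies the configuration:
#' \code{"FULL_OVERLAP"} when both endpoints of one segment drop
#' perpendicular feet onto the other, \code{"PARTIAL"} when at least one
#' projection has a foot but full overlap fails, \code{"NONE"} when no
#' perpendicular foot exists. Under full overlap, \code{dmax_line} is the
#' larger of the two foot distances on the fully-overlapping side (the
#' smaller side-maximum when both sides qualify); otherwise it is
#' \code{NA}.
#'
#' @param s1,s2 numeric length-4 segments, \code{c(x1, y1, x2, y2)}.
#' @param tol boundary tolerance in degrees.
#' @return list with \code{dmin}, \code{dmax}, \code{dmax_line},
#'   \code{pattern}.
#' @export
segment_pair_geometry <- function(s1, s2, tol = GT_TOL) {
  .check_finite(s1, "segment 1")
  .check_finite(s2, "segment 2")
  stopifnot(length(s1) == 4L, length(s2) == 4L)
  r <- spg_vec(matrix(s1, 1L), matrix(s2, 1L), tol)
  list(dmin = r$dmin, dmax = r$dmax, dmax_line = r$dmax_line,
       pattern = r$pattern)
}
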