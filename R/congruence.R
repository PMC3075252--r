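# Segment-pair congruence rules and track merging.

# Vectorised rule evaluation over n segment pairs (n x 4 matrices).
# Returns list(congruent, rule, geometry). Rule 2 (full overlap with
# dmax.line <= lmax.line) is checked first; rule 1 requires an
# intersecting point (any perpendicular foot), dmin <= lmin and
# dmax <= lmax. No foot at all means no congruence whatever the
# distances.
congruent_vec <- function(s1, s2, params, tol = GT_TOL) {
  g <- spg_vec(s1, s2, tol)
  rule2 <- g$pattern == "FULL_OVERLAP" &
    !is.na(g$dmax_line) & g$dmax_line <= params$lmax_line + tol
  rule1 <- g$pattern != "NONE" &
    g$dmin <= params$lmin + tol & g$dmax <= params$lmax + tol
  rule <- ifelse(rule2, "RULE2", ifelse(rule1, "RULE1", "NONE"))
  list(congruent = rule2 | rule1, rule = rule, geometry = g)
}

#' Decide congruence of two track segments
#'
#' Applies the two decision rules of segment congruence. Rule 1: the
#' segments have at least one intersecting point (a perpendicular foot of
#' an endpoint of one segment on the other), the minimum of the four
#' endpoint-projection distances does not exceed \code{lmin}, and the
#' maximum does not exceed \code{lmax}. Rule 2: one segment overlaps the
#' other fully (both endpoints drop perpendicular feet) and the maximum
#' foot distance \code{dmax_line} does not exceed \code{lmax_line} --
#' this admits laterally offset but fully aligned segments that rule 1
#' would reject. Segments with no intersecting points are never
#' congruent. Rule 2 is evaluated first; the verdict records the first
#' rule that fires.
#'
#' @param s1,s2 numeric length-4 segments \code{c(x1, y1, x2, y2)}.
#' @param params a \code{\link{congruence_params}} object.
#' @return list with \code{congruent} (logical), \code{rule}
#'   (\code{"RULE1"}, \code{"RULE2"} or \code{"NONE"}), and
#'   \code{geometry} (the \code{\link{segment_pair_geometry}} summary).
#' @export
segments_congruent <- function(s1, s2, params) {
  .check_params(params)
  .check_finite(s1, "segment 1"); .check_finite(s2, "segment 2")
  r <- congruent_vec(matrix(s1, 1L), matrix(s2, 1L), params)
  list(congruent = r$congruent, rule = r$rule,
       geometry = list(dmin = r$geometry$dmin, dmax = r$geometry$dmax,
                       dmax_line = r$geometry$dmax_line,
                       pattern = r$geometry$pattern))
}

# exact prefilter: any congruent pair has dmin <= lmax_line (rule 1 needs
# dmin <= lmin <= lmax_line; rule 2 needs dmax_line <= lmax_line and
# dmin <= dmax_line), and dmin is bounded below by the bounding-box gap.
.bbox_gap_exceeds <- function(t1, t2, limit) {
  v1 <- t1$vertices; v2 <- t2$vertices
  gx <- max(min(v1[, 1L]) - max(v2[, 1L]), min(v2[, 1L]) - max(v1[, 1L]), 0)
  gy <- max(min(v1[, 2L]) - max(v2[, 2L]), min(v2[, 2L]) - max(v1[, 2L]), 0)
  gx * gx + gy * gy > limit * limit
}

#' All congruent segment pairs between two tracks
#'
#' Compares every edge of one track against every edge of the other and
#' returns the index pairs found congruent under either decision rule.
#' The relation is symmetric: swapping the tracks transposes the pairs.
#'
#' @param t1,t2 \code{geo_track} objects.
#' @param params a \code{\link{congruence_params}} object.
#' @return integer matrix with columns \code{edge1} (index into
#'   \code{t1$edges}) and \code{edge2} (index into \code{t2$edges}); zero
#'   rows when no pair is congruent.
#' @export
congruent_segment_map <- function(t1, t2, params) {
  .check_params(params)
  empty <- matrix(integer(0), 0L, 2L,
                  dimnames = list(NULL, c("edge1", "edge2")))
  n1 <- nrow(t1$edges); n2 <- nrow(t2$edges)
  if (n1 == 0L || n2 == 0L) return(empty)
  if (.bbox_gap_exceeds(t1, t2, params$lmax_line)) return(empty)
  s1 <- .track_segments(t1); s2 <- .track_segments(t2)
  i <- rep(seq_len(n1), times = n2)
  j <- rep(seq_len(n2), each = n1)
  r <- congruent_vec(s1[i, , drop = FALSE], s2[j, , drop = FALSE], params)
  out <- cbind(edge1 = i[r$congruent], edge2 = j[r$congruent])
  out
}

#' Merge two congruent tracks into a generalized track
#'
#' Collects the endpoint vertices of every congruent segment from both
#' tracks, unions them (dropping exact coordinate duplicates), and builds
#' a new minimum spanning tree over the union. Only the congruent
#' segments contribute vertices; parts of either track that found no
#' counterpart are left out, so the generalized track summarises the
#' shared distribution pattern rather than the union of ranges.
#'
#' @param t1,t2 \code{geo_track} objects.
#' @param pairs congruent pair matrix from
#'   \code{\link{congruent_segment_map}}; must be non-empty.
#' @return a \code{geo_track} of kind \code{"generalized"} whose taxa set
#'   is the union of the inputs' taxa.
#' @export
merge_tracks <- function(t1, t2, pairs) {
  if (is.null(dim(pairs)) || nrow(pairs) == 0L)
    stop("merge_tracks requires a non-empty congruent pair set",
         call. = FALSE)
  e1 <- unique(pairs[, 1L]); e2 <- unique(pairs[, 2L])
  v1 <- unique(as.vector(t1$edges[e1, , drop = FALSE]))
  v2 <- unique(as.vector(t2$edges[e2, , drop = FALSE]))
  pts <- rbind(t1$vertices[v1, , drop = FALSE],
               t2$vertices[v2, , drop = FALSE])
  build_mst(pts, taxa = sort(unique(c(t1$taxa, t2$taxa))),
            kind = "generalized")
}
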