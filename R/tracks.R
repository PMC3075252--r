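# Individual track construction: point deduplication by the cut value,
# then a minimum spanning tree per species.

.as_xy <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L, byrow = TRUE)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) stop("points must have two columns (lon, lat)",
                               call. = FALSE)
  .check_finite(points, "points")
  unname(points)
}

#' Collapse near-duplicate occurrence points
#'
#' Greedy single pass in input order: a point is dropped iff it lies
#' within \code{cut_value} (planar Euclidean degrees) of a point already
#' retained. Retained points keep their original coordinates; the first
#' point of each cluster survives. With \code{cut_value = 0} only exact
#' coordinate duplicates are removed. Idempotent.
#'
#' @param points n x 2 matrix (lon, lat) or coercible.
#' @param cut_value non-negative deduplication radius in degrees.
#' @return the retained points as an m x 2 matrix, m <= n.
#' @export
dedup_points <- function(points, cut_value) {
  if (!is.numeric(cut_value) || length(cut_value) != 1L ||
      is.na(cut_value) || cut_value < 0)
    .param_error("0 <= cut_value is violated")
  xy <- .as_xy(points)
  n <- nrow(xy)
  if (n == 0L) return(xy)
  keep <- 1L
  for (i in seq_len(n)[-1L]) {
    d2 <- (xy[keep, 1L] - xy[i, 1L])^2 + (xy[keep, 2L] - xy[i, 2L])^2
    if (all(d2 > cut_value^2)) keep <- c(keep, i)
  }
  # cut 0 still removes exact duplicates (d2 == 0 fails d2 > 0)
  xy[keep, , drop = FALSE]
}

# Kruskal's algorithm with deterministic tie-breaking: among equal-weight
# edges prefer the lexicographically smaller (i, j) index pair. Returns
# an (n-1) x 2 integer matrix of vertex indices with i < j.
.kruskal <- function(xy) {
  n <- nrow(xy)
  if (n <= 1L) return(matrix(integer(0), 0L, 2L))
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1L]; j <- ij[, 2L]
  w <- sqrt((xy[i, 1L] - xy[j, 1L])^2 + (xy[i, 2L] - xy[j, 2L])^2)
  ord <- order(w, i, j)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  edges <- matrix(integer(0), 0L, 2L)
  for (k in ord) {
    ri <- find(i[k]); rj <- find(j[k])
    if (ri != rj) {
      parent[ri] <- rj
      edges <- rbind(edges, c(i[k], j[k]))
      if (nrow(edges) == n - 1L) break
    }
  }
  edges
}

#' Minimum spanning tree over a point set
#'
#' Builds the MST of the complete planar Euclidean graph on the points,
#' the panbiogeographic representation of a distribution: the acyclic
#' connected edge set whose total length is smallest. Exact duplicate
#' coordinates are merged first so the tree never carries zero-length
#' edges. Ties between equal-length edges are broken deterministically
#' in favour of the lexicographically smaller vertex-index pair.
#'
#' @param points n x 2 matrix (lon, lat); at least one point.
#' @param taxa character vector of taxon names the track summarises.
#' @param kind \code{"individual"} or \code{"generalized"}.
#' @return an object of class \code{geo_track}: list with
#'   \code{vertices} (m x 2 matrix), \code{edges} ((m-1) x 2 integer
#'   matrix), \code{taxa}, \code{kind}.
#' @export
build_mst <- function(points, taxa = character(0), kind = "individual") {
  xy <- .as_xy(points)
  if (nrow(xy) == 0L) stop("cannot build a track from zero points",
                           call. = FALSE)
  xy <- dedup_points(xy, 0)  # forbid zero-length edges
  structure(list(vertices = xy, edges = .kruskal(xy),
                 taxa = as.character(taxa), kind = kind),
            class = "geo_track")
}

#' Individual track of one species
#'
#' Deduplicates the species' occurrence points by the cut value, then
#' connects the survivors with a minimum spanning tree.
#'
#' @param taxon species name.
#' @param points n x 2 matrix (lon, lat) of occurrence coordinates.
#' @param params a \code{\link{congruence_params}} object.
#' @return a \code{geo_track} of kind \code{"individual"}.
#' @export
individual_track <- function(taxon, points, params) {
  .check_params(params)
  build_mst(dedup_points(points, params$cut_value), taxa = taxon,
            kind = "individual")
}

# edge coordinates of a track as an m x 4 matrix (x1, y1, x2, y2)
.track_segments <- function(track) {
  e <- track$edges
  if (nrow(e) == 0L) return(matrix(numeric(0), 0L, 4L))
  cbind(track$vertices[e[, 1L], , drop = FALSE],
        track$vertices[e[, 2L], , drop = FALSE])
}

.edge_lengths <- function(track) {
  s <- .track_segments(track)
  if (nrow(s) == 0L) return(numeric(0))
  sqrt((s[, 3L] - s[, 1L])^2 + (s[, 4L] - s[, 2L])^2)
}

#' Total length of a track
#'
#' @param track a \code{geo_track}.
#' @return sum of its edge lengths in degrees.
#' @export
track_length <- function(track) sum(.edge_lengths(track))

#' @export
print.geo_track <- function(x, ...) {
  cat(sprintf("<geo_track: %s, %d vertices, %d edges, length %.4f deg>\n",
              x$kind, nrow(x$vertices), nrow(x$edges), track_length(x)))
  if (length(x$taxa))
    cat("  taxa:", paste(x$taxa, collapse = ", "), "\n")
  invisible(x)
}
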