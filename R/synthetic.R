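# Synthetic occurrence data with known generalized-track structure: each
# corridor is a polyline along which several species are sampled with
# Gaussian jitter, so the corridor is recoverable as a generalized track
# by construction.

#' Define a synthetic distribution corridor
#'
#' A corridor is the ground-truth generalized track: a polyline along
#' which a set of species share their distribution. Species occurrence
#' points are sampled uniformly by arc length along the polyline (or
#' along a sub-range of it, to emulate species occupying only part of a
#' shared pattern) and perturbed with isotropic Gaussian noise.
#'
#' @param polyline k x 2 (lon, lat) matrix with k >= 2, the true track.
#' @param n_species number of species sharing the corridor.
#' @param points_per_species occurrence records per species.
#' @param jitter_sd standard deviation of the isotropic Gaussian
#'   coordinate noise, in degrees.
#' @param span numeric length-2 in [0, 1]: the arc-length fraction of
#'   the corridor each species occupies; \code{c(0, 1)} is the whole
#'   corridor.
#' @return an object of class \code{corridor_spec}.
#' @export
corridor <- function(polyline, n_species, points_per_species,
                     jitter_sd = 0, span = c(0, 1)) {
  polyline <- .as_xy(polyline)
  stopifnot(nrow(polyline) >= 2L, n_species >= 1L,
            points_per_species >= 1L, jitter_sd >= 0,
            length(span) == 2L, span[1] >= 0, span[2] <= 1,
            span[1] < span[2])
  structure(list(polyline = polyline, n_species = as.integer(n_species),
                 points_per_species = as.integer(points_per_species),
                 jitter_sd = jitter_sd, span = span),
            class = "corridor_spec")
}

# point at arc-length fraction f of a polyline (f in [0,1])
.polyline_point <- function(polyline, f) {
  seg <- diff(polyline)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  tot <- cum[length(cum)]
  s <- f * tot
  i <- pmin(findInterval(s, cum, rightmost.closed = TRUE),
            length(len))
  t <- (s - cum[i]) / len[i]
  polyline[i, , drop = FALSE] + seg[i, , drop = FALSE] * t
}

#' Generate a synthetic occurrence dataset from corridors
#'
#' For each corridor and species, samples occurrence positions uniformly
#' by arc length along the corridor polyline (restricted to the
#' corridor's span) and adds isotropic Gaussian jitter. Species names
#' encode corridor membership as \code{c<i>_sp<j>} so recovery can be
#' scored. Deterministic for a given seed.
#'
#' @param corridors list of \code{\link{corridor}} specs.
#' @param seed integer RNG seed.
#' @return a list of record sets (\code{list(taxon, points)}), the same
#'   shape \code{\link{read_occurrences}} returns.
#' @export
simulate_corridors <- function(corridors, seed = 1L) {
  if (inherits(corridors, "corridor_spec")) corridors <- list(corridors)
  stopifnot(all(vapply(corridors, inherits, TRUE, "corridor_spec")))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  out <- list()
  for (ci in seq_along(corridors)) {
    co <- corridors[[ci]]
    for (sj in seq_len(co$n_species)) {
      f <- stats::runif(co$points_per_species, co$span[1], co$span[2])
      base <- .polyline_point(co$polyline, f)
      noise <- matrix(stats::rnorm(2L * co$points_per_species,
                                   sd = co$jitter_sd),
                      ncol = 2L)
      out[[length(out) + 1L]] <- list(
        taxon = sprintf("c%d_sp%d", ci, sj),
        points = base + noise)
    }
  }
  out
}

# directed Hausdorff distance from a point set to a polyline
.hausdorff_to_polyline <- function(points, polyline) {
  seg <- cbind(polyline[-nrow(polyline), , drop = FALSE],
               polyline[-1L, , drop = FALSE])
  d <- vapply(seq_len(nrow(points)), function(i) {
    r <- psd_vec(points[i, 1L], points[i, 2L],
                 seg[, 1L], seg[, 2L], seg[, 3L], seg[, 4L])
    min(r$dist)
  }, 0)
  max(d)
}

#' Score corridor recovery of an analysis
#'
#' Compares the generalized tracks of a fit against the ground-truth
#' corridors that generated the data (species names must carry the
#' \code{c<i>_} corridor prefix from \code{\link{simulate_corridors}}).
#'
#' @param result a \code{\link{track_analysis}} fit.
#' @param corridors the list of \code{\link{corridor}} specs used to
#'   generate the data.
#' @return list with \code{n_tracks} (recovered), \code{n_corridors}
#'   (truth), \code{count_match} (logical), and a per-track data frame
#'   \code{tracks} with the majority corridor, taxa purity (fraction of
#'   the track's taxa from its majority corridor) and directed Hausdorff
#'   distance from the track's vertices to the majority corridor
#'   polyline.
#' @export
score_recovery <- function(result, corridors) {
  stopifnot(inherits(result, "track_analysis"))
  if (inherits(corridors, "corridor_spec")) corridors <- list(corridors)
  gts <- result$generalized_tracks
  tab <- lapply(seq_along(gts), function(k) {
    t <- gts[[k]]
    cid <- as.integer(sub("^c(\\d+)_.*$", "\\1", t$taxa))
    maj <- as.integer(names(which.max(table(cid))))
    data.frame(
      track = names(gts)[k],
      majority_corridor = maj,
      purity = mean(cid == maj),
      hausdorff = .hausdorff_to_polyline(t$vertices,
                                         corridors[[maj]]$polyline),
      stringsAsFactors = FALSE)
  })
  tab <- if (length(tab)) do.call(rbind, tab) else
    data.frame(track = character(0), majority_corridor = integer(0),
               purity = numeric(0), hausdorff = numeric(0))
  list(n_tracks = length(gts), n_corridors = length(corridors),
       count_match = length(gts) == length(corridors), tracks = tab)
}
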