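# Full analysis: individual tracks, pairwise merging into generalized
# track candidates, and similarity-index reduction to a non-redundant set.

#' Asymmetric similarity index between two tracks
#'
#' The similarity index of track A toward track B is the summed length of
#' A's edges that are congruent with at least one edge of B, divided by
#' the total length of A. It is asymmetric because it is normalised by
#' each track's own length: a short track lying along part of a long one
#' scores 1 toward the long track while the long track scores only the
#' shared fraction. A track of zero total length (single vertex) scores 0
#' in both directions.
#'
#' @param t1,t2 \code{geo_track} objects.
#' @param params a \code{\link{congruence_params}} object.
#' @return list with \code{si_ab} (t1 toward t2), \code{si_ba} (t2 toward
#'   t1) and \code{si_max = max(si_ab, si_ba)}, all in \code{[0, 1]}.
#' @export
similarity_index <- function(t1, t2, params) {
  .check_params(params)
  len1 <- track_length(t1); len2 <- track_length(t2)
  if (len1 <= 0 && len2 <= 0)
    return(list(si_ab = 0, si_ba = 0, si_max = 0))
  pairs <- congruent_segment_map(t1, t2, params)
  l1 <- .edge_lengths(t1); l2 <- .edge_lengths(t2)
  si_ab <- if (len1 > 0) sum(l1[unique(pairs[, 1L])]) / len1 else 0
  si_ba <- if (len2 > 0) sum(l2[unique(pairs[, 2L])]) / len2 else 0
  list(si_ab = si_ab, si_ba = si_ba, si_max = max(si_ab, si_ba))
}

.coerce_records <- function(records) {
  if (is.data.frame(records)) {
    need <- c("taxon", "lat", "lon")
    if (!all(need %in% names(records)))
      stop("data frame input needs columns taxon, lat, lon", call. = FALSE)
    taxa <- unique(as.character(records$taxon))
    records <- lapply(taxa, function(tx) {
      r <- records[records$taxon == tx, , drop = FALSE]
      list(taxon = tx, points = cbind(r$lon, r$lat))
    })
  }
  if (!is.list(records) || length(records) == 0L)
    stop("no species records supplied", call. = FALSE)
  for (r in records) {
    if (is.null(r$taxon) || !nzchar(r$taxon) || is.null(r$points))
      stop("each record set needs a non-empty taxon and points",
           call. = FALSE)
  }
  records
}

#' Panbiogeographic track analysis
#'
#' The main entry point. Builds an individual track (minimum spanning
#' tree after cut-value deduplication) for every species, compares every
#' pair of individual tracks segment-by-segment under the two congruence
#' rules, merges each congruent pair into a candidate generalized track,
#' and then reduces the candidates to a non-redundant set: as long as any
#' two candidates have max-direction similarity index at or above
#' \code{min_si}, the most similar pair is replaced by the minimum
#' spanning tree over the union of their vertices. Finally, candidates
#' whose taxa are a subset of a surviving track's taxa and whose
#' similarity toward it reaches \code{min_si} are discarded as
#' redundant. The whole procedure is deterministic given the input
#' order.
#'
#' @param records either a data frame with columns \code{taxon},
#'   \code{lat}, \code{lon}, or a list of record sets
#'   (\code{list(taxon =, points = )} with points as an n x 2 lon/lat
#'   matrix), e.g. from \code{\link{read_occurrences}}.
#' @param params a \code{\link{congruence_params}} object.
#' @return an object of class \code{track_analysis}: list with
#'   \code{individual_tracks} (named by taxon), \code{generalized_tracks}
#'   (named GT-1, GT-2, ...), \code{params}, \code{log} (data frame of
#'   merge/reduce/discard events) and \code{call}.
#' @seealso \code{\link{summary.track_analysis}},
#'   \code{\link{plot.track_analysis}}, \code{\link{write_kml}}
#' @examples
#' recs <- data.frame(
#'   taxon = rep(c("sp_a", "sp_b"), each = 3),
#'   lat = c(0, 0, 0, 0.2, 0.2, 0.2),
#'   lon = c(0, 1, 2, 0, 1, 2))
#' fit <- track_analysis(recs, congruence_params(0.05, 0.5, 0.6, 0.8, 0.8))
#' summary(fit)
#' @export
track_analysis <- function(records, params) {
  .check_params(params)
  records <- .coerce_records(records)
  cl <- match.call()

  taxa <- vapply(records, `[[`, "", "taxon")
  if (anyDuplicated(taxa))
    stop("duplicate taxon in records: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "),
         call. = FALSE)
  indiv <- lapply(records, function(r)
    individual_track(r$taxon, r$points, params))
  names(indiv) <- taxa

  log <- list()
  note <- function(event, tracks, si = NA_real_) {
    log[[length(log) + 1L]] <<- data.frame(
      event = event, tracks = tracks, si = si,
      stringsAsFactors = FALSE)
  }

  # candidate generalized tracks from every congruent species pair,
  # unordered pairs in input order
  candidates <- list()
  n <- length(indiv)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      pairs <- congruent_segment_map(indiv[[i]], indiv[[j]], params)
      if (nrow(pairs) > 0L) {
        candidates[[length(candidates) + 1L]] <-
          merge_tracks(indiv[[i]], indiv[[j]], pairs)
        note("merge", paste(taxa[i], taxa[j], sep = " + "))
      }
    }
  }

  # reduction: repeatedly join the most similar candidate pair
  # (si_max >= min_si) into one MST, to a fixed point
  if (length(candidates) >= 2L) {
    m <- length(candidates)
    si <- matrix(0, m, m)
    for (a in seq_len(m - 1L)) for (b in seq.int(a + 1L, m))
      si[a, b] <- similarity_index(candidates[[a]], candidates[[b]],
                                   params)$si_max
    repeat {
      best <- max(si)
      # merging requires some congruence: si_max of 0 never joins tracks,
      # so min_si = 0 collapses exactly the congruence-connected components
      if (length(candidates) < 2L || best <= 0 || best < params$min_si) break
      hit <- which(si == best, arr.ind = TRUE)
      # ties: lexicographically smallest combined taxa label
      if (nrow(hit) > 1L) {
        lab <- apply(hit, 1L, function(h)
          paste(sort(c(candidates[[h[1L]]]$taxa,
                       candidates[[h[2L]]]$taxa)), collapse = "|"))
        hit <- hit[order(lab, hit[, 1L], hit[, 2L]), , drop = FALSE]
      }
      a <- hit[1L, 1L]; b <- hit[1L, 2L]
      merged <- build_mst(
        rbind(candidates[[a]]$vertices, candidates[[b]]$vertices),
        taxa = sort(unique(c(candidates[[a]]$taxa, candidates[[b]]$taxa))),
        kind = "generalized")
      note("reduce",
           paste(paste(candidates[[a]]$taxa, collapse = ","),
                 paste(candidates[[b]]$taxa, collapse = ","),
                 sep = " + "), si = best)
      keep <- setdiff(seq_along(candidates), c(a, b))
      candidates <- c(candidates[keep], list(merged))
      m <- length(candidates)
      if (m < 2L) break
      si <- si[keep, keep, drop = FALSE]
      si <- rbind(cbind(si, 0), 0)
      for (a in seq_len(m - 1L))
        si[a, m] <- similarity_index(candidates[[a]], candidates[[m]],
                                     params)$si_max
    }
  }

  # discard candidates subsumed by another surviving track: taxa subset
  # and similarity toward it at or above the threshold
  if (length(candidates) >= 2L) {
    drop <- rep(FALSE, length(candidates))
    for (a in seq_along(candidates)) {
      for (b in seq_along(candidates)) {
        if (a == b || drop[b]) next
        sub <- all(candidates[[a]]$taxa %in% candidates[[b]]$taxa)
        if (sub && setequal(candidates[[a]]$taxa, candidates[[b]]$taxa) &&
            a < b) next  # equal taxa sets: keep the earlier one
        if (sub &&
            similarity_index(candidates[[a]], candidates[[b]],
                             params)$si_ab >= params$min_si) {
          drop[a] <- TRUE
          note("discard", paste(candidates[[a]]$taxa, collapse = ","))
          break
        }
      }
    }
    candidates <- candidates[!drop]
  }

  if (length(candidates))
    names(candidates) <- paste0("GT-", seq_along(candidates))
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(event = character(0), tracks = character(0),
               si = numeric(0), stringsAsFactors = FALSE)

  structure(list(individual_tracks = indiv,
                 generalized_tracks = candidates,
                 params = params, log = log, call = cl),
            class = "track_analysis")
}

#' @export
print.track_analysis <- function(x, ...) {
  cat("Panbiogeographic track analysis\n")
  print(x$params)
  cat(sprintf("  %d individual tracks, %d generalized tracks\n",
              length(x$individual_tracks), length(x$generalized_tracks)))
  invisible(x)
}

#' Summarise a track analysis
#'
#' @param object a \code{track_analysis} fit.
#' @param ... unused.
#' @return a \code{summary.track_analysis} object: per-track tables of
#'   taxa counts, vertex counts and total lengths.
#' @export
summary.track_analysis <- function(object, ...) {
  tab <- function(tracks) {
    if (!length(tracks))
      return(data.frame(track = character(0), n_taxa = integer(0),
                        n_vertices = integer(0), length_deg = numeric(0)))
    data.frame(
      track = names(tracks),
      n_taxa = vapply(tracks, function(t) length(t$taxa), 0L),
      n_vertices = vapply(tracks, function(t) nrow(t$vertices), 0L),
      length_deg = vapply(tracks, track_length, 0),
      taxa = vapply(tracks, function(t) paste(t$taxa, collapse = ","), ""),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(individual = tab(object$individual_tracks),
                 generalized = tab(object$generalized_tracks),
                 params = object$params),
            class = "summary.track_analysis")
}

#' @export
print.summary.track_analysis <- function(x, ...) {
  print(x$params)
  cat("\nIndividual tracks:\n")
  print(x$individual[, c("track", "n_vertices", "length_deg")],
        row.names = FALSE)
  cat("\nGeneralized tracks:\n")
  if (nrow(x$generalized) == 0L) cat("  (none)\n") else
    print(x$generalized[, c("track", "n_taxa", "n_vertices",
                            "length_deg", "taxa")], row.names = FALSE)
  invisible(x)
}

#' Plot the tracks of an analysis
#'
#' Draws individual tracks in grey and generalized tracks in colour over
#' a lon/lat plane.
#'
#' @param x a \code{track_analysis} fit.
#' @param ... passed to \code{plot.default}.
#' @export
plot.track_analysis <- function(x, ...) {
  all_v <- do.call(rbind, lapply(c(x$individual_tracks,
                                   x$generalized_tracks),
                                 `[[`, "vertices"))
  graphics::plot(all_v, type = "n", xlab = "longitude",
                 ylab = "latitude", asp = 1, ...)
  draw <- function(t, col, lwd) {
    e <- t$edges
    if (nrow(e) == 0L) {
      graphics::points(t$vertices, col = col, pch = 16, cex = 0.5)
      return(invisible())
    }
    graphics::segments(t$vertices[e[, 1L], 1L], t$vertices[e[, 1L], 2L],
                       t$vertices[e[, 2L], 1L], t$vertices[e[, 2L], 2L],
                       col = col, lwd = lwd)
  }
  for (t in x$individual_tracks) draw(t, "grey60", 1)
  cols <- grDevices::hcl.colors(max(1L, length(x$generalized_tracks)),
                                "Dark 3")
  for (k in seq_along(x$generalized_tracks))
    draw(x$generalized_tracks[[k]], cols[k], 2.5)
  invisible(x)
}
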