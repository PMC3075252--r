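# Occurrence text input and KML / report output.
#
# Input lines are "taxon, latitude, longitude" (comma, tab or whitespace
# delimited; detected per file). Note the input order is lat then lon,
# while KML coordinates are written lon,lat,0 -- the two conventions are
# deliberately kept explicit at the two boundaries.

.input_error <- function(msg) {
  stop(structure(class = c("gt_input_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.detect_sep <- function(lines) {
  if (any(grepl(",", lines, fixed = TRUE))) return(",")
  if (any(grepl("\t", lines, fixed = TRUE))) return("\t")
  "[[:space:]]+"
}

#' Read an occurrence table
#'
#' Parses a plain-text occurrence file, one record per line:
#' taxon name, latitude, longitude in decimal degrees. The delimiter
#' (comma, tab, or whitespace) is auto-detected once per file. Records
#' are grouped by exact taxon string in first-appearance order. Lines
#' whose coordinates do not parse as finite numbers, or fall outside
#' latitude [-90, 90] / longitude [-180, 180], are rejected --
#' collected with their line numbers in the \code{"rejected"} attribute
#' and reported via a warning, fatal only if every line is rejected.
#' Duplicate records are kept; collapsing near-duplicates is the cut
#' value's job. Near-identical taxon names (differing only by case or
#' underscore/space) trigger a warning but are never merged.
#'
#' @param path path to the text file.
#' @return a list of record sets, each \code{list(taxon, points)} with
#'   \code{points} an n x 2 (lon, lat) matrix, ordered by first
#'   appearance; attribute \code{"rejected"} is a data frame with
#'   columns \code{line_no}, \code{line}, \code{reason}.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) .input_error(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^[[:space:]]*#", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) .input_error(paste0("empty input file: ", path))
  sep <- .detect_sep(lines)

  rejected <- list()
  reject <- function(no, line, reason)
    rejected[[length(rejected) + 1L]] <<- data.frame(
      line_no = no, line = line, reason = reason, stringsAsFactors = FALSE)

  taxa <- character(0)
  pts <- list()
  for (k in seq_along(lines)) {
    f <- trimws(strsplit(lines[k], sep)[[1]])
    f <- f[nzchar(f)]
    if (length(f) < 3L) {
      reject(line_no[k], lines[k], "fewer than 3 fields")
      next
    }
    # taxon may contain the delimiter-free remainder; coords are the
    # last two fields, taxon everything before them
    lat <- suppressWarnings(as.numeric(f[length(f) - 1L]))
    lon <- suppressWarnings(as.numeric(f[length(f)]))
    taxon <- paste(f[seq_len(length(f) - 2L)], collapse = " ")
    if (is.na(lat) || is.na(lon) || !is.finite(lat) || !is.finite(lon)) {
      reject(line_no[k], lines[k], "unparseable coordinates")
      next
    }
    if (abs(lat) > 90) {
      reject(line_no[k], lines[k], "latitude out of [-90, 90]")
      next
    }
    if (abs(lon) > 180) {
      reject(line_no[k], lines[k], "longitude out of [-180, 180]")
      next
    }
    if (!(taxon %in% taxa)) {
      taxa <- c(taxa, taxon)
      pts[[taxon]] <- matrix(numeric(0), 0L, 2L)
    }
    pts[[taxon]] <- rbind(pts[[taxon]], c(lon, lat))
  }

  rejected <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(line_no = integer(0), line = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  if (length(taxa) == 0L)
    .input_error(sprintf("all %d lines rejected in %s",
                         nrow(rejected), path))
  if (nrow(rejected) > 0L)
    warning(sprintf("%d of %d lines rejected (first: line %d, %s)",
                    nrow(rejected), length(lines), rejected$line_no[1],
                    rejected$reason[1]), call. = FALSE)
  norm <- tolower(gsub("[_ ]+", " ", taxa))
  if (anyDuplicated(norm))
    warning("near-identical taxon names kept distinct: ",
            paste(taxa[norm %in% norm[duplicated(norm)]],
                  collapse = ", "), call. = FALSE)

  out <- lapply(taxa, function(tx) list(taxon = tx, points = pts[[tx]]))
  attr(out, "rejected") <- rejected
  out
}

#' Write an occurrence table
#'
#' Writes record sets in the text format \code{\link{read_occurrences}}
#' reads: one \code{taxon, lat, lon} line per record.
#'
#' @param records list of \code{list(taxon, points)} record sets
#'   (points n x 2 lon/lat).
#' @param path output path.
#' @export
write_occurrences <- function(records, path) {
  lines <- unlist(lapply(records, function(r)
    sprintf("%s, %.6f, %.6f", r$taxon, r$points[, 2L], r$points[, 1L])))
  writeLines(lines, path)
  invisible(path)
}

.kml_coords <- function(v) {
  paste(sprintf("%.6f,%.6f,0", v[, 1L], v[, 2L]), collapse = " ")
}

.kml_track_geometry <- function(doc_node, track) {
  # an MST branches, so each edge is its own 2-point LineString inside a
  # MultiGeometry; a 0-edge track degrades to a Point
  if (nrow(track$edges) == 0L) {
    pt <- xml2::xml_add_child(doc_node, "Point")
    xml2::xml_add_child(pt, "coordinates",
                        .kml_coords(track$vertices[1L, , drop = FALSE]))
    return(invisible())
  }
  mg <- xml2::xml_add_child(doc_node, "MultiGeometry")
  for (e in seq_len(nrow(track$edges))) {
    ls <- xml2::xml_add_child(mg, "LineString")
    xml2::xml_add_child(ls, "tessellate", "1")
    xml2::xml_add_child(
      ls, "coordinates",
      .kml_coords(track$vertices[track$edges[e, ], , drop = FALSE]))
  }
}

#' Export an analysis as KML
#'
#' Writes a KML 2.2 document with two folders: \emph{Individual tracks}
#' (one placemark per species, named by taxon) and \emph{Generalized
#' tracks} (one placemark per generalized track, named GT-k, description
#' listing the member taxa). Each track is a MultiGeometry of two-point
#' LineStrings, one per MST edge. KML coordinate order is lon,lat,0.
#' Output is byte-deterministic for identical input.
#'
#' @param result a \code{\link{track_analysis}} fit.
#' @param path output path for the .kml file.
#' @export
write_kml <- function(result, path) {
  stopifnot(inherits(result, "track_analysis"))
  doc <- xml2::xml_new_root("kml",
                            xmlns = "http://www.opengis.net/kml/2.2")
  d <- xml2::xml_add_child(doc, "Document")
  xml2::xml_add_child(d, "name", "Track analysis")

  style <- function(id, color, width) {
    st <- xml2::xml_add_child(d, "Style", id = id)
    ln <- xml2::xml_add_child(st, "LineStyle")
    xml2::xml_add_child(ln, "color", color)
    xml2::xml_add_child(ln, "width", width)
  }
  style("individualTrack", "ff999999", "1")   # grey, thin
  style("generalizedTrack", "ff0000ff", "3")  # red (KML aabbggrr), wide

  fi <- xml2::xml_add_child(d, "Folder")
  xml2::xml_add_child(fi, "name", "Individual tracks")
  for (nm in names(result$individual_tracks)) {
    pm <- xml2::xml_add_child(fi, "Placemark")
    xml2::xml_add_child(pm, "name", nm)
    xml2::xml_add_child(pm, "styleUrl", "#individualTrack")
    .kml_track_geometry(pm, result$individual_tracks[[nm]])
  }

  fg <- xml2::xml_add_child(d, "Folder")
  xml2::xml_add_child(fg, "name", "Generalized tracks")
  for (nm in names(result$generalized_tracks)) {
    tr <- result$generalized_tracks[[nm]]
    pm <- xml2::xml_add_child(fg, "Placemark")
    xml2::xml_add_child(pm, "name", nm)
    xml2::xml_add_child(pm, "description",
                        paste(tr$taxa, collapse = ", "))
    xml2::xml_add_child(pm, "styleUrl", "#generalizedTrack")
    .kml_track_geometry(pm, tr)
  }

  ok <- tryCatch({
    xml2::write_xml(doc, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(structure(class = c("gt_io_error", "error", "condition"),
                   list(message = paste0("cannot write KML: ",
                                         conditionMessage(ok)),
                        call = NULL)))
  invisible(path)
}

#' Write a plain-text track report
#'
#' Tab-separated table: track id, kind, member taxa, vertex count and
#' total length in degrees, for individual and generalized tracks.
#'
#' @param result a \code{\link{track_analysis}} fit.
#' @param path output path for the .tsv file.
#' @export
write_track_report <- function(result, path) {
  stopifnot(inherits(result, "track_analysis"))
  row <- function(id, t)
    sprintf("%s\t%s\t%s\t%d\t%.6f", id, t$kind,
            paste(t$taxa, collapse = ","), nrow(t$vertices),
            track_length(t))
  lines <- c("track\tkind\ttaxa\tn_vertices\tlength_deg",
             mapply(row, names(result$individual_tracks),
                    result$individual_tracks),
             mapply(row, names(result$generalized_tracks),
                    result$generalized_tracks))
  writeLines(unlist(lines), path)
  invisible(path)
}
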