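# Per-cell scalar layers (richness, PD, proportions) and their export.

#' Construct a grid map layer
#'
#' A grid map is a named numeric vector of per-cell values (names are
#' 6-digit mesh codes; NA marks an undefined value, e.g. PD over fewer than
#' two tips) plus layer metadata recording how it was built.
#'
#' @param values Named numeric vector; names must parse as mesh codes.
#' @param name Layer name.
#' @param meta List of provenance metadata (filters applied etc.).
#' @return A \code{grid_map}.
#' @export
grid_map <- function(values, name = "layer", meta = list()) {
  if (is.null(names(values))) stop("grid_map values must be named by mesh code")
  parse_mesh(names(values))
  structure(list(values = values, name = name, meta = meta),
            class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  v <- x$values
  cat(sprintf("grid_map '%s': %d cells (%d defined)\n",
              x$name, length(v), sum(!is.na(v))))
  if (any(!is.na(v))) {
    cat(sprintf("  range of defined values: [%g, %g]\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  }
  invisible(x)
}

#' Taxon richness per grid cell
#'
#' Counts the taxa present in each cell of the matrix, optionally excluding
#' nothotaxa. Cells carried by the matrix with no remaining taxa get count
#' zero (counts are always defined).
#'
#' @param m An \code{occurrence_matrix}.
#' @param table The \code{taxon_table}.
#' @param include_hybrids Count hybrid taxa? The headline richness layer
#'   includes them; the PD-related layers do not.
#' @return A \code{grid_map} of non-negative integer counts.
#' @export
richness_map <- function(m, table, include_hybrids = TRUE) {
  mf <- filter_matrix(m, table, include_hybrids = include_hybrids)
  values <- Matrix::colSums(mf$presence)
  grid_map(stats::setNames(as.numeric(values), mf$cells),
           name = "richness",
           meta = list(filter = list(include_hybrids = include_hybrids)))
}

#' Richness restricted to a trait subset
#'
#' The apomictic layer follows the convention of the apomict map: ferns
#' only, hybrids excluded (optionally counting taxa capable of either mode).
#' The threatened layer counts taxa in any of the seven national red-list
#' threat categories, hybrids included.
#'
#' @param m An \code{occurrence_matrix}.
#' @param table The \code{taxon_table}.
#' @param predicate "apomictic" or "redlisted".
#' @param include_both For the apomictic layer, also count mode-"both" taxa.
#' @return A \code{grid_map} of counts.
#' @export
subset_richness_map <- function(m, table,
                                predicate = c("apomictic", "redlisted"),
                                include_both = FALSE) {
  predicate <- match.arg(predicate)
  mf <- if (predicate == "apomictic") {
    filter_matrix(m, table, include_hybrids = FALSE, lineage = "ferns",
                  subset = "apomictic", include_both = include_both)
  } else {
    filter_matrix(m, table, include_hybrids = TRUE, subset = "redlisted")
  }
  values <- Matrix::colSums(mf$presence)
  grid_map(stats::setNames(as.numeric(values), mf$cells),
           name = paste0("richness_", predicate),
           meta = list(predicate = predicate, include_both = include_both))
}

#' Cellwise proportion of one count layer out of another
#'
#' Used e.g. for the proportion of apomictic taxa out of all taxa per cell.
#' Cells with zero denominator are undefined (NA), not zero.
#'
#' @param numerator,denominator \code{grid_map}s of counts over the same
#'   cells; the numerator may not exceed the denominator anywhere.
#' @return A \code{grid_map} of proportions in [0, 1].
#' @export
proportion_map <- function(numerator, denominator) {
  if (!identical(names(numerator$values), names(denominator$values))) {
    stop("numerator and denominator layers must cover identical cells")
  }
  num <- numerator$values
  den <- denominator$values
  if (any(num > den, na.rm = TRUE)) {
    bad <- names(num)[which(num > den)[1]]
    stop("numerator exceeds denominator in cell ", bad)
  }
  values <- ifelse(den > 0, num / den, NA_real_)
  grid_map(stats::setNames(values, names(num)),
           name = paste0("proportion_", numerator$name),
           meta = list(numerator = numerator$name, denominator = denominator$name))
}

#' Highest-valued cells of a layer
#'
#' @param g A \code{grid_map}.
#' @param k Number of cells to return; if larger than the number of defined
#'   cells, all of them are returned ranked.
#' @return data.frame (mesh_code, value), sorted by decreasing value; ties
#'   broken by ascending mesh code so the ranking is deterministic.
#' @export
top_cells <- function(g, k = 10L) {
  defined <- !is.na(g$values)
  if (!any(defined)) stop("grid_map '", g$name, "' has no defined values")
  v <- g$values[defined]
  ord <- order(-v, names(v))
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(mesh_code = names(v)[ord], value = unname(v[ord]),
             stringsAsFactors = FALSE)
}

#' Export a grid map layer as CSV or GeoJSON
#'
#' CSV rows are (mesh_code, value, defined); re-importing with
#' \code{\link{import_layer_csv}} reproduces the map. GeoJSON emits one
#' polygon feature per cell — the cell's bounding rectangle from
#' \code{\link{cell_bounds}}, coordinates in (lon, lat) order per the
#' format — with the value as a property (null where undefined).
#'
#' @param g A \code{grid_map}.
#' @param path Output file path.
#' @param format "csv" or "geojson".
#' @param frame Optional character vector of mesh codes for the full study
#'   frame; frame cells absent from the layer are exported with value 0 for
#'   count layers (\code{fill = 0}) or as undefined (\code{fill = NA}, the
#'   default, appropriate for PD and proportion layers).
#' @param fill Value given to frame cells missing from the layer.
#' @return The path, invisibly.
#' @export
export_layer <- function(g, path, format = c("csv", "geojson"),
                         frame = NULL, fill = NA_real_) {
  format <- match.arg(format)
  values <- g$values
  if (!is.null(frame)) {
    extra <- setdiff(frame, names(values))
    values <- c(values, stats::setNames(rep(fill, length(extra)), extra))
    values <- values[sort(names(values))]
  }
  if (format == "csv") {
    utils::write.csv(
      data.frame(mesh_code = names(values), value = unname(values),
                 defined = !is.na(values)),
      path, row.names = FALSE, quote = FALSE)
  } else {
    b <- cell_bounds(names(values))
    features <- lapply(seq_along(values), function(i) {
      ring <- list(c(b$lon_sw[i], b$lat_sw[i]), c(b$lon_ne[i], b$lat_sw[i]),
                   c(b$lon_ne[i], b$lat_ne[i]), c(b$lon_sw[i], b$lat_ne[i]),
                   c(b$lon_sw[i], b$lat_sw[i]))
      list(type = "Feature",
           properties = list(mesh_code = names(values)[i],
                             layer = g$name,
                             value = if (is.na(values[i])) NULL else unname(values[i])),
           geometry = list(type = "Polygon", coordinates = list(ring)))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = features),
                         path, auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(path)
}

#' Re-import a CSV layer written by \code{\link{export_layer}}
#' @param path CSV path.
#' @param name Layer name for the reconstructed map.
#' @return A \code{grid_map}.
#' @export
import_layer_csv <- function(path, name = "layer") {
  x <- utils::read.csv(path, colClasses = c(mesh_code = "character"))
  values <- stats::setNames(x$value, x$mesh_code)
  values[!as.logical(x$defined)] <- NA_real_
  grid_map(values, name = name)
}
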