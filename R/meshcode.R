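#' Parse a 6-digit secondary standard-area-mesh grid code
#'
#' Japan's standard area mesh (JIS X 0410) addresses the archipelago with a
#' hierarchical grid; the 6-digit secondary mesh cell spans 5 minutes of
#' latitude by 7.5 minutes of longitude (roughly 10 km by 10 km), and is the
#' resolution at which all occurrence records in this package are kept.
#' The first two digits index a primary cell's latitude band (40 minutes,
#' i.e. \code{lat_index / 1.5} degrees north), digits 3-4 its longitude
#' (\code{100 + lon_index} degrees east), and digits 5-6 the row and column
#' of the secondary subdivision within the primary cell.
#'
#' Codes are handled as strings throughout so that leading zeros survive;
#' only the 6-digit secondary mesh is accepted.
#'
#' @param code Character vector of 6-digit mesh codes.
#' @return A data.frame of class \code{mesh_cell} with columns \code{code},
#'   \code{lat_index}, \code{lon_index}, \code{row}, \code{col}.
#' @examples
#' parse_mesh("453034")  # a cell on Yakushima Island
#' @export
parse_mesh <- function(code) {
  code <- as.character(code)
  bad <- !grepl("^[0-9]{6}$", code)
  if (any(bad)) {
    stop("malformed mesh code (must be exactly 6 digits): ",
         paste(unique(code[bad]), collapse = ", "))
  }
  cell <- data.frame(
    code = code,
    lat_index = as.integer(substr(code, 1L, 2L)),
    lon_index = as.integer(substr(code, 3L, 4L)),
    row = as.integer(substr(code, 5L, 5L)),
    col = as.integer(substr(code, 6L, 6L)),
    stringsAsFactors = FALSE
  )
  class(cell) <- c("mesh_cell", "data.frame")
  cell
}

#' Format parsed mesh cells back to their 6-digit codes
#'
#' @param cell A \code{mesh_cell} as returned by \code{\link{parse_mesh}}.
#' @return Character vector of codes; \code{format_mesh(parse_mesh(x)) == x}.
#' @export
format_mesh <- function(cell) {
  sprintf("%02d%02d%d%d", cell$lat_index, cell$lon_index, cell$row, cell$col)
}

#' Geographic bounds of secondary mesh cells
#'
#' Each cell is an axis-aligned rectangle of exactly 1/12 degree latitude by
#' 1/8 degree longitude. The south-west corner is at
#' \code{lat_index/1.5 + row/12} degrees north and
#' \code{100 + lon_index + col/8} degrees east.
#'
#' @param cell A \code{mesh_cell}, or a character vector of codes.
#' @return data.frame with \code{lat_sw}, \code{lon_sw}, \code{lat_ne},
#'   \code{lon_ne} in decimal degrees.
#' @export
cell_bounds <- function(cell) {
  if (is.character(cell)) cell <- parse_mesh(cell)
  lat_sw <- cell$lat_index / 1.5 + cell$row / 12
  lon_sw <- 100 + cell$lon_index + cell$col / 8
  data.frame(lat_sw = lat_sw, lon_sw = lon_sw,
             lat_ne = lat_sw + 1 / 12, lon_ne = lon_sw + 1 / 8)
}

#' Centroid of secondary mesh cells
#'
#' The centroid (bounds midpoint) is the canonical per-cell coordinate used
#' for all latitude statistics; latitudinal breadth is identical whether
#' computed from centroids or south-west corners since the half-cell offset
#' cancels.
#'
#' @inheritParams cell_bounds
#' @return data.frame with columns \code{lat}, \code{lon} (decimal degrees).
#' @export
cell_centroid <- function(cell) {
  b <- cell_bounds(cell)
  data.frame(lat = (b$lat_sw + b$lat_ne) / 2, lon = (b$lon_sw + b$lon_ne) / 2)
}

#' Encode geographic coordinates as a secondary mesh code
#'
#' Floor-arithmetic inverse of \code{\link{cell_bounds}}:
#' \code{encode_mesh(cell_centroid(c))} recovers \code{c} for every valid
#' cell.
#'
#' @param lat,lon Numeric vectors of decimal degrees. The mesh system covers
#'   latitudes >= 0 and longitudes in [100, 200).
#' @return Character vector of 6-digit codes.
#' @export
encode_mesh <- function(lat, lon) {
  if (any(lat < 0) || any(lon < 100) || any(lon >= 200) || any(lat >= 200 / 3)) {
    stop("coordinates outside the standard-area-mesh domain ",
         "(need 0 <= lat < 66.67, 100 <= lon < 200)")
  }
  lat_index <- floor(lat * 1.5)
  row <- floor((lat - lat_index / 1.5) * 12)
  lon_index <- floor(lon - 100)
  col <- floor((lon - 100 - lon_index) * 8)
  # guard against the upper edge landing in the next cell through rounding
  row <- pmin(row, 7L)
  col <- pmin(col, 7L)
  sprintf("%02d%02d%d%d", lat_index, lon_index, row, col)
}
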