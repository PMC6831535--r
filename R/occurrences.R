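# Presence-only occurrence records deduplicated to a taxon x cell matrix.
# Records are presence-only: absence of a record never implies absence of
# the taxon, and nothing here infers it.

#' Construct an occurrence matrix from (taxon_id, mesh_code) pairs
#'
#' @param records data.frame with columns \code{taxon_id} and
#'   \code{mesh_code} (one presence record per row; duplicates allowed and
#'   collapsed).
#' @param table The \code{taxon_table} the records must reference.
#' @return An \code{occurrence_matrix}: list with \code{taxa} (ordered
#'   taxon_ids), \code{cells} (ordered mesh codes), \code{presence} (sparse
#'   logical taxa x cells matrix), \code{provenance} (record count before
#'   deduplication).
#' @export
occurrence_matrix <- function(records, table) {
  stopifnot(all(c("taxon_id", "mesh_code") %in% names(records)))
  records$taxon_id <- as.character(records$taxon_id)
  records$mesh_code <- as.character(records$mesh_code)
  unknown <- setdiff(records$taxon_id, table$taxon_id)
  if (length(unknown)) {
    stop("occurrence records reference taxon_id(s) absent from the checklist: ",
         paste(utils::head(sort(unknown), 10), collapse = ", "),
         if (length(unknown) > 10) sprintf(" (and %d more)", length(unknown) - 10))
  }
  parse_mesh(unique(records$mesh_code))  # validates every code
  provenance <- nrow(records)
  records <- unique(records[, c("taxon_id", "mesh_code")])
  taxa <- intersect(table$taxon_id, unique(records$taxon_id))
  cells <- sort(unique(records$mesh_code))
  presence <- Matrix::sparseMatrix(
    i = match(records$taxon_id, taxa),
    j = match(records$mesh_code, cells),
    x = TRUE,
    dims = c(length(taxa), length(cells)),
    dimnames = list(taxa, cells)
  )
  structure(list(taxa = taxa, cells = cells, presence = presence,
                 provenance = provenance),
            class = "occurrence_matrix")
}

#' Load presence records from a two-column CSV
#'
#' The CSV has a header and columns \code{taxon_id}, \code{mesh_code}
#' (UTF-8). Duplicate (taxon, cell) pairs are collapsed; the pre-deduplication
#' row count is kept as \code{provenance}. Records whose taxon_id is not in
#' the checklist are an error, never silently dropped.
#'
#' @param path Path to the occurrence CSV.
#' @param table The \code{taxon_table} to validate against.
#' @return An \code{occurrence_matrix}.
#' @export
load_occurrences <- function(path, table) {
  records <- utils::read.csv(path, colClasses = "character",
                             stringsAsFactors = FALSE, encoding = "UTF-8")
  occurrence_matrix(records, table)
}

#' Write an occurrence matrix back to the two-column CSV dialect
#' @param m An \code{occurrence_matrix}.
#' @param path Output CSV path.
#' @export
write_occurrences <- function(m, path) {
  idx <- Matrix::which(m$presence, arr.ind = TRUE)
  records <- data.frame(taxon_id = m$taxa[idx[, 1]],
                        mesh_code = m$cells[idx[, 2]])
  records <- records[order(records$taxon_id, records$mesh_code), ]
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("occurrence_matrix: %d taxa x %d cells, %d presences (%d records)\n",
              length(x$taxa), length(x$cells), Matrix::nnzero(x$presence),
              x$provenance))
  invisible(x)
}

#' Restrict an occurrence matrix by checklist predicates
#'
#' Taxa are filtered; cells are all retained (even if left empty) so that
#' denominators over "all grid cells" stay fixed across filtered views.
#' Filters compose: applying them in any order yields the same matrix.
#'
#' @param m An \code{occurrence_matrix}.
#' @param table The \code{taxon_table}.
#' @param include_hybrids Keep nothotaxa? (The richness and threatened-taxa
#'   layers include hybrids; the PD and apomict layers do not.)
#' @param lineage "all" or "ferns" (drops lycophytes).
#' @param subset "all", "apomictic" (see \code{include_both}) or "redlisted"
#'   (any of the seven threat categories).
#' @param include_both For \code{subset = "apomictic"}: also keep taxa capable
#'   of either reproductive mode.
#' @return A filtered \code{occurrence_matrix} (provenance preserved).
#' @export
filter_matrix <- function(m, table,
                          include_hybrids = TRUE,
                          lineage = c("all", "ferns"),
                          subset = c("all", "apomictic", "redlisted"),
                          include_both = FALSE) {
  lineage <- match.arg(lineage)
  subset <- match.arg(subset)
  traits <- table[match(m$taxa, table$taxon_id), , drop = FALSE]
  keep <- rep(TRUE, length(m$taxa))
  if (!include_hybrids) keep <- keep & !traits$is_hybrid
  if (lineage == "ferns") keep <- keep & traits$lineage == "fern"
  if (subset == "apomictic") {
    modes <- if (include_both) c("apomictic", "both") else "apomictic"
    keep <- keep & traits$reproductive_mode %in% modes
  } else if (subset == "redlisted") {
    keep <- keep & traits$redlist != "none"
  }
  structure(list(taxa = m$taxa[keep], cells = m$cells,
                 presence = m$presence[keep, , drop = FALSE],
                 provenance = m$provenance),
            class = "occurrence_matrix")
}

#' Grid-cell occupancy of an occurrence matrix
#'
#' @param m An \code{occurrence_matrix}.
#' @param total_cells Total number of grid cells in the study frame. This is
#'   configuration, not inferred from the data: a presence-only file cannot
#'   reveal cells where nothing was ever recorded (the national frame has
#'   4852 cells, 510 of them without any record).
#' @return List with \code{occupied_cells}, \code{total_cells},
#'   \code{percent} (one decimal).
#' @export
occupancy_summary <- function(m, total_cells) {
  occupied <- sum(Matrix::colSums(m$presence) > 0)
  if (occupied > total_cells) {
    stop("total_cells (", total_cells, ") is smaller than the number of occupied cells (",
         occupied, ")")
  }
  list(occupied_cells = occupied, total_cells = total_cells,
       percent = if (occupied == 0) 0 else percent(occupied, total_cells))
}
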