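# Trait-annotated taxon checklist: loading, validation, flora summaries.
# The checklist is the unit of every denominator in the flora statistics;
# "native taxa" always means non-hybrid species + subspecies + varieties.

.rank_levels <- c("species", "subspecies", "variety")
.lineage_levels <- c("fern", "lycophyte")
.mode_levels <- c("sexual", "apomictic", "both", "unknown")
.ploidy_levels <- c("diploid", "polyploid", "unknown")
.phenology_levels <- c("evergreen", "seasonal_green", "unknown")
.redlist_levels <- c("EX", "EW", "CR", "EN", "VU", "NT", "DD", "none")
.threat_categories <- c("EX", "EW", "CR", "EN", "VU", "NT", "DD")

.checklist_columns <- c("taxon_id", "name", "rank", "is_hybrid", "lineage",
                        "reproductive_mode", "ploidy_class", "phenology",
                        "endemic", "redlist", "in_tree")

.check_category <- function(x, levels, column) {
  bad <- which(!x %in% levels)
  if (length(bad)) {
    stop(sprintf("invalid %s value '%s' in checklist row %d (allowed: %s)",
                 column, x[bad[1]], bad[1], paste(levels, collapse = ", ")))
  }
}

#' Validate a checklist data.frame as a taxon table
#'
#' Checks column presence, taxon_id uniqueness and every categorical field
#' against its enumeration. Unknown trait values must be spelled out as
#' \code{"unknown"}; they are never imputed, and any summary described as
#' "whose ... are known" excludes them from its denominator.
#'
#' @param x data.frame with the checklist columns (see
#'   \code{\link{load_checklist}}).
#' @return \code{x} with class \code{taxon_table} prepended.
#' @export
as_taxon_table <- function(x) {
  missing_cols <- setdiff(.checklist_columns, names(x))
  if (length(missing_cols)) {
    stop("checklist is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- duplicated(x$taxon_id)
  if (any(dup)) {
    stop("duplicate taxon_id in checklist row(s) ",
         paste(which(dup), collapse = ", "), ": ",
         paste(unique(x$taxon_id[dup]), collapse = ", "))
  }
  for (col in c("is_hybrid", "endemic", "in_tree")) {
    if (is.character(x[[col]])) x[[col]] <- as.logical(toupper(x[[col]]))
    if (!is.logical(x[[col]]) || anyNA(x[[col]])) {
      stop("column ", col, " must be logical (TRUE/FALSE) with no missing values")
    }
  }
  .check_category(x$rank, .rank_levels, "rank")
  .check_category(x$lineage, .lineage_levels, "lineage")
  .check_category(x$reproductive_mode, .mode_levels, "reproductive_mode")
  .check_category(x$ploidy_class, .ploidy_levels, "ploidy_class")
  .check_category(x$phenology, .phenology_levels, "phenology")
  .check_category(x$redlist, .redlist_levels, "redlist")
  class(x) <- unique(c("taxon_table", class(x)))
  x
}

#' Load the trait-annotated checklist from CSV
#'
#' The CSV must be UTF-8 with a header naming exactly the taxon fields:
#' \code{taxon_id}, \code{name}, \code{rank} (species/subspecies/variety),
#' \code{is_hybrid}, \code{lineage} (fern/lycophyte), \code{reproductive_mode}
#' (sexual/apomictic/both/unknown), \code{ploidy_class}
#' (diploid/polyploid/unknown), \code{phenology}
#' (evergreen/seasonal_green/unknown), \code{endemic}, \code{redlist}
#' (EX/EW/CR/EN/VU/NT/DD/none) and \code{in_tree} (has an rbcL tip in the
#' reference phylogeny).
#'
#' @param path Path to the checklist CSV.
#' @return A \code{taxon_table} (validated data.frame).
#' @seealso \code{\link{write_checklist}} for the inverse.
#' @export
load_checklist <- function(path) {
  x <- utils::read.csv(path, colClasses = "character",
                       stringsAsFactors = FALSE, encoding = "UTF-8")
  as_taxon_table(x)
}

#' Write a taxon table back to CSV
#'
#' Writes the same dialect \code{\link{load_checklist}} reads, so a written
#' table reloads to identical summaries.
#'
#' @param table A \code{taxon_table}.
#' @param path Output CSV path.
#' @export
write_checklist <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, .checklist_columns],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Count native (non-hybrid) taxa
#' @param table A \code{taxon_table}.
#' @return Integer count of non-hybrid rows (species + subspecies + varieties).
#' @export
n_native <- function(table) sum(!table$is_hybrid)

#' Count hybrid taxa (nothotaxa)
#' @param table A \code{taxon_table}.
#' @return Integer count of hybrid rows.
#' @export
n_hybrid <- function(table) sum(table$is_hybrid)

#' Count native taxa at species rank only
#' @param table A \code{taxon_table}.
#' @return Integer count of non-hybrid rows with rank "species".
#' @export
n_native_species <- function(table) sum(!table$is_hybrid & table$rank == "species")

#' Percentage at one decimal, rounded half away from zero
#'
#' All flora proportions are reported at one decimal. R's \code{round} uses
#' round-half-to-even; the printed convention is round-half-away-from-zero
#' (e.g. 487/721 -> 67.5), so that is implemented directly.
#'
#' @param numerator,denominator Counts; the denominator must be positive.
#' @return Percentage \code{100 * numerator / denominator} at one decimal.
#' @examples
#' percent(487, 721)  # 67.5
#' percent(125, 721)  # 17.3
#' @export
percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) {
    stop("undefined proportion: denominator must be positive")
  }
  p <- 100 * numerator / denominator
  sign(p) * floor(abs(p) * 10 + 0.5) / 10
}

#' Total taxa across the seven red-list threat categories
#'
#' @param counts Named numeric vector of per-category counts; names from
#'   EX, EW, CR, EN, VU, NT, DD. Missing categories count zero.
#' @return Sum over the seven threat categories ("none" never counts).
#' @examples
#' redlist_total(c(EX = 7, EW = 2, CR = 82, EN = 59, VU = 67, NT = 37, DD = 1))
#' @export
redlist_total <- function(counts) {
  if (any(counts < 0)) stop("red-list category counts must be non-negative")
  extra <- setdiff(names(counts), c(.threat_categories, "none"))
  if (is.null(names(counts)) || length(extra)) {
    stop("counts must be named by red-list category (EX, EW, CR, EN, VU, NT, DD)")
  }
  sum(counts[names(counts) %in% .threat_categories])
}

#' Per-category red-list counts of a taxon table
#'
#' @param table A \code{taxon_table}.
#' @param include_hybrids Count hybrid taxa too? The national red list covers
#'   nothotaxa as well, so the default is TRUE.
#' @return Named integer vector over the seven threat categories.
#' @export
redlist_counts <- function(table, include_hybrids = TRUE) {
  if (!include_hybrids) table <- table[!table$is_hybrid, , drop = FALSE]
  counts <- table(factor(table$redlist, levels = .threat_categories))
  stats::setNames(as.integer(counts), .threat_categories)
}

#' Apomixis rate among native taxa with known reproductive mode
#'
#' The rate is the percentage of apomictic taxa among native (non-hybrid)
#' taxa whose reproductive mode is known (mode not "unknown"). By default
#' the numerator counts strictly apomictic taxa; taxa capable of either mode
#' ("both") can be added with \code{include_both = TRUE}, which some
#' summaries prefer since such taxa are apomixis-capable.
#'
#' @param table A \code{taxon_table}.
#' @param include_both Count mode-"both" taxa in the numerator?
#' @return Percentage at one decimal (see \code{\link{percent}}).
#' @export
apomixis_rate <- function(table, include_both = FALSE) {
  native <- table[!table$is_hybrid, , drop = FALSE]
  known <- native$reproductive_mode != "unknown"
  if (!any(known)) {
    stop("undefined proportion: no native taxon with known reproductive mode")
  }
  numerator_modes <- if (include_both) c("apomictic", "both") else "apomictic"
  percent(sum(native$reproductive_mode[known] %in% numerator_modes), sum(known))
}

#' Flora-level summary of a checklist
#'
#' Counts and percentages mirroring the flora account: native vs hybrid
#' totals, endemism, red-list breakdown, apomixis rate, and the sexual
#' diploid/polyploid split.
#'
#' @param table A \code{taxon_table}.
#' @param include_both Passed to \code{\link{apomixis_rate}}.
#' @return A list of class \code{flora_summary}.
#' @export
flora_summary <- function(table, include_both = FALSE) {
  native <- table[!table$is_hybrid, , drop = FALSE]
  sexual <- native[native$reproductive_mode == "sexual", , drop = FALSE]
  rl <- redlist_counts(table)
  out <- list(
    n_taxa = nrow(table),
    n_native = n_native(table),
    n_native_species = n_native_species(table),
    n_hybrid = n_hybrid(table),
    n_endemic = sum(native$endemic),
    pct_endemic = percent(sum(native$endemic), nrow(native)),
    redlist_counts = rl,
    redlist_total = redlist_total(rl),
    apomixis_rate = apomixis_rate(table, include_both = include_both),
    n_sexual_diploid = sum(sexual$ploidy_class == "diploid"),
    n_sexual_polyploid = sum(sexual$ploidy_class == "polyploid"),
    pct_in_tree = percent(sum(native$in_tree), nrow(native))
  )
  class(out) <- "flora_summary"
  out
}

#' @export
print.flora_summary <- function(x, ...) {
  cat("Flora summary\n")
  cat(sprintf("  taxa: %d (%d native, %d hybrids; %d native species)\n",
              x$n_taxa, x$n_native, x$n_hybrid, x$n_native_species))
  cat(sprintf("  endemic: %d (%.1f%% of native taxa)\n",
              x$n_endemic, x$pct_endemic))
  cat(sprintf("  red-listed: %d (%s)\n", x$redlist_total,
              paste(sprintf("%d %s", x$redlist_counts,
                            names(x$redlist_counts)), collapse = ", ")))
  cat(sprintf("  apomixis rate (known-mode natives): %.1f%%\n", x$apomixis_rate))
  cat(sprintf("  sexual diploid/polyploid: %d / %d\n",
              x$n_sexual_diploid, x$n_sexual_polyploid))
  cat(sprintf("  rbcL tree coverage: %.1f%% of native taxa\n", x$pct_in_tree))
  invisible(x)
}
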