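# Orchestration: thin wrappers tying the modules into the four pipeline
# steps (summarize, maps, rangestats, simulate). Machine-readable CSV/JSON
# outputs are authoritative; printed tables are convenience only.

#' Pipeline run configuration
#'
#' @param checklist,occurrences,tree Input file paths (checklist CSV,
#'   occurrence CSV, Newick tree).
#' @param out_dir Output directory for exported layers and tables.
#' @param total_cells Total grid-cell count of the study frame (the national
#'   frame has 4852; synthetic frames use \code{length(frame_codes(cfg))}).
#' @param include_both Apomict-layer and apomixis-rate numerator convention
#'   (see \code{\link{apomixis_rate}}).
#' @param alpha Significance level for Tukey letter displays.
#' @param keep_root_path PD convention (see \code{\link{faith_pd}}).
#' @param seed Seed used by \code{\link{cmd_simulate}}.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(checklist = NULL, occurrences = NULL, tree = NULL,
                       out_dir = ".", total_cells = 4852,
                       include_both = FALSE, alpha = 0.05,
                       keep_root_path = FALSE, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

.load_inputs <- function(cfg, need_tree = FALSE) {
  for (f in c("checklist", "occurrences", if (need_tree) "tree")) {
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]])) {
      stop("input file for '", f, "' is missing: ", cfg[[f]])
    }
  }
  table <- load_checklist(cfg$checklist)
  m <- load_occurrences(cfg$occurrences, table)
  tree <- if (need_tree) read_newick(cfg$tree) else NULL
  list(table = table, m = m, tree = tree)
}

#' Flora summary report
#'
#' Loads and validates the checklist (and, when available, the occurrence
#' file) and reports the flora-level counts and percentages plus grid-cell
#' occupancy. Writes \code{flora_summary.json} under \code{out_dir}.
#'
#' @param cfg A \code{run_config}.
#' @return The summary list, invisibly.
#' @export
cmd_summarize <- function(cfg) {
  if (is.null(cfg$checklist) || !file.exists(cfg$checklist)) {
    stop("checklist file is missing: ", cfg$checklist)
  }
  table <- load_checklist(cfg$checklist)
  if (nrow(table) == 0) stop("checklist is empty")
  fs <- flora_summary(table, include_both = cfg$include_both)
  out <- unclass(fs)
  out$redlist_counts <- as.list(out$redlist_counts)
  if (!is.null(cfg$occurrences) && file.exists(cfg$occurrences)) {
    m <- load_occurrences(cfg$occurrences, table)
    occ <- occupancy_summary(m, cfg$total_cells)
    out$occupied_cells <- occ$occupied_cells
    out$total_cells <- occ$total_cells
    out$pct_occupied <- occ$percent
    out$n_records <- m$provenance
  }
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  jsonlite::write_json(out, file.path(cfg$out_dir, "flora_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  print(fs)
  invisible(out)
}

#' Build and export the diversity map layers
#'
#' Richness (hybrids included), PD for all taxa and for ferns only (hybrids
#' excluded), apomict richness, apomict proportion, and threatened-taxon
#' richness (hybrids included); each exported as CSV under \code{out_dir}.
#'
#' @param cfg A \code{run_config}.
#' @return Named list of \code{grid_map}s, invisibly.
#' @export
cmd_maps <- function(cfg) {
  inputs <- .load_inputs(cfg, need_tree = TRUE)
  table <- inputs$table; m <- inputs$m; tree <- inputs$tree
  layers <- list(
    richness = richness_map(m, table, include_hybrids = TRUE),
    richness_native = richness_map(m, table, include_hybrids = FALSE),
    pd_all = pd_map(m, tree, table, lineage = "all",
                    keep_root_path = cfg$keep_root_path),
    pd_ferns = pd_map(m, tree, table, lineage = "ferns",
                      keep_root_path = cfg$keep_root_path),
    richness_apomictic = subset_richness_map(m, table, "apomictic",
                                             include_both = cfg$include_both),
    richness_redlisted = subset_richness_map(m, table, "redlisted")
  )
  layers$proportion_apomictic <- proportion_map(layers$richness_apomictic,
                                                layers$richness_native)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  for (nm in names(layers)) {
    export_layer(layers[[nm]], file.path(cfg$out_dir, paste0(nm, ".csv")))
  }
  invisible(layers)
}

#' Compute and export the trait-group range comparisons
#'
#' The per-taxon range table plus the four comparisons: occupied cells and
#' latitudinal breadth by reproductive mode (ANOVA + Tukey HSD), occupied
#' cells by phenology and by ploidy among sexual taxa (Student's t).
#'
#' @param cfg A \code{run_config}.
#' @return Named list of \code{group_comparison}s, invisibly.
#' @export
cmd_rangestats <- function(cfg) {
  inputs <- .load_inputs(cfg)
  table <- inputs$table; m <- inputs$m
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  utils::write.csv(range_table(m), file.path(cfg$out_dir, "range_table.csv"),
                   row.names = FALSE, quote = FALSE)
  cmps <- list(
    cells_by_mode = compare_by_trait(m, table, "n_cells", "reproductive_mode",
                                     alpha = cfg$alpha),
    breadth_by_mode = compare_by_trait(m, table, "lat_breadth",
                                       "reproductive_mode", alpha = cfg$alpha),
    cells_by_phenology = compare_by_trait(m, table, "n_cells", "phenology",
                                          alpha = cfg$alpha),
    cells_by_ploidy = compare_by_trait(m, table, "n_cells", "ploidy_class",
                                       alpha = cfg$alpha)
  )
  for (nm in names(cmps)) {
    write_comparison(cmps[[nm]], file.path(cfg$out_dir, paste0(nm, ".csv")))
    print(cmps[[nm]])
  }
  invisible(cmps)
}

#' Generate a synthetic dataset triple on disk
#'
#' @param cfg A \code{run_config}; its \code{seed} drives the generator.
#' @param sim A \code{sim_config} (defaults to \code{sim_config(seed =
#'   cfg$seed)}).
#' @return Invisible result of \code{\link{simulate_dataset}}.
#' @export
cmd_simulate <- function(cfg, sim = NULL) {
  if (is.null(sim)) sim <- sim_config(seed = cfg$seed)
  simulate_dataset(sim, cfg$out_dir)
}
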