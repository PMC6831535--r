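# Shared fixtures and independent oracles, built in code at test time.

# Minimal checklist rows with overridable columns.
make_checklist <- function(n = 3, ...) {
  df <- data.frame(
    taxon_id = sprintf("t%03d", seq_len(n)),
    name = sprintf("Genus species%03d", seq_len(n)),
    rank = "species",
    is_hybrid = FALSE,
    lineage = "fern",
    reproductive_mode = "sexual",
    ploidy_class = "diploid",
    phenology = "evergreen",
    endemic = FALSE,
    redlist = "none",
    in_tree = TRUE,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  as_taxon_table(df)
}

# Brute-force Faith's PD oracle: marks every edge on the path from each
# retained tip to the subtree root (the tips' MRCA, or the tree root when
# keep_root_path) using ape's nodepath/getMRCA, then sums the marked edges.
# Deliberately independent of the package's postorder tip-count traversal.
pd_oracle <- function(tree, tips, keep_root_path = FALSE) {
  retained <- intersect(unique(tips), tree$tip.label)
  if (length(retained) < 2) return(NA_real_)
  root <- length(tree$tip.label) + 1L
  anc <- if (keep_root_path) root else ape::getMRCA(tree, retained)
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  marked <- character(0)
  for (tip in match(retained, tree$tip.label)) {
    path <- ape::nodepath(tree, anc, tip)
    if (length(path) > 1) {
      marked <- c(marked, paste(path[-length(path)], path[-1]))
    }
  }
  sum(tree$edge.length[match(unique(marked), edge_key)])
}

# Random rooted tree with positive branch lengths.
random_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.01, 2)
  tr
}

# A small sim_config over a reduced frame so unit tests stay fast; the
# full-size study conditions are exercised in the acceptance tests.
small_sim <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_taxa = 80L, hybrid_fraction = 0.25,
                   lat_range = c(30, 36), lon_range = c(130, 135),
                   center_mean = 33, center_sd = 1.5,
                   occupancy_density = 0.05)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
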