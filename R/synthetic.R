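# Synthetic checklist / occurrence / tree triples.
#
# The generator emulates the statistical structure of the national fern and
# lycophyte dataset: a latitude-band archipelago frame of secondary mesh
# cells (24-46 degrees N), taxa with latitudinal range centers and breadths,
# apomicts with southward-shifted centers and narrower breadths,
# seasonal-green taxa shifted north, a Yule tree over the non-hybrid taxa
# with a small fraction of taxa missing (emulating incomplete rbcL
# sampling), and optional duplicate records to exercise deduplication.
# Occupancy is sampled independently per cell within each taxon's band; no
# spatial autocorrelation or coastline mask is simulated.

#' Configuration for the synthetic dataset generator
#'
#' Defaults mirror the flora being emulated: 721 native taxa plus 371
#' hybrids, an 11\% apomict fraction (1.1\% capable of either mode), a 45\%
#' polyploid fraction among sexual taxa, 75\% evergreen, 17.3\% endemism,
#' a 35.4\% red-list fraction split across the seven threat categories in
#' the proportions 7:2:82:59:67:37:1 (EX:EW:CR:EN:VU:NT:DD), 2.1\% of taxa
#' missing from the tree, and group latitudinal-breadth distributions with
#' means 7.62 (sexual) vs 5.93 (apomictic) degrees, sds 5.02 vs 3.77.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param n_taxa Number of native (non-hybrid) taxa.
#' @param hybrid_fraction Hybrids generated as a fraction of \code{n_taxa}.
#' @param apomict_fraction,both_fraction,unknown_mode_fraction Probabilities
#'   of the apomictic / either-mode / unknown reproductive modes per native
#'   taxon (the rest are sexual).
#' @param polyploid_fraction Probability of polyploidy among sexual taxa.
#' @param evergreen_fraction Probability of evergreen (vs seasonal-green)
#'   phenology.
#' @param lycophyte_fraction Probability a native taxon is a lycophyte.
#' @param endemic_fraction,redlist_fraction Per-taxon probabilities of
#'   endemism and of red-list membership (categories drawn with
#'   \code{redlist_weights}).
#' @param redlist_weights Named weights over EX, EW, CR, EN, VU, NT, DD.
#' @param lat_range,lon_range Latitude/longitude band of the mesh frame
#'   (degrees).
#' @param center_mean,center_sd Latitude distribution of range centers.
#' @param apomict_center_shift Southward shift (degrees, negative) of
#'   apomict range centers.
#' @param seasonal_center_shift Northward shift of seasonal-green centers.
#' @param breadth_mean,breadth_sd Named vectors (sexual, apomictic, both) of
#'   latitudinal-breadth distribution parameters in degrees.
#' @param occupancy_density Probability that a frame cell inside a taxon's
#'   latitude band is occupied.
#' @param duplicate_rate Fraction of extra duplicated records injected.
#' @param missing_tip_fraction Fraction of native taxa withheld from the
#'   tree (no rbcL tip).
#' @param tree_birth_rate Birth rate of the Yule topology.
#' @param branch_mean Mean of the exponential branch lengths (expected
#'   substitutions per site).
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_taxa = 721L,
                       hybrid_fraction = 371 / 721,
                       apomict_fraction = 0.11,
                       both_fraction = 0.011,
                       unknown_mode_fraction = 0,
                       polyploid_fraction = 0.45,
                       evergreen_fraction = 0.75,
                       lycophyte_fraction = 0.08,
                       endemic_fraction = 0.173,
                       redlist_fraction = 255 / 721,
                       redlist_weights = c(EX = 7, EW = 2, CR = 82, EN = 59,
                                           VU = 67, NT = 37, DD = 1),
                       lat_range = c(24, 46),
                       lon_range = c(123, 146),
                       center_mean = 33,
                       center_sd = 4,
                       apomict_center_shift = -2,
                       seasonal_center_shift = 4,
                       breadth_mean = c(sexual = 7.62, apomictic = 5.93,
                                        both = 7.62),
                       breadth_sd = c(sexual = 5.02, apomictic = 3.77,
                                      both = 5.02),
                       occupancy_density = 0.02,
                       duplicate_rate = 0,
                       missing_tip_fraction = 0.021,
                       tree_birth_rate = 1,
                       branch_mean = 0.02) {
  cfg <- as.list(environment())
  fracs <- c(cfg$apomict_fraction, cfg$both_fraction, cfg$unknown_mode_fraction,
             cfg$polyploid_fraction, cfg$evergreen_fraction,
             cfg$lycophyte_fraction, cfg$endemic_fraction, cfg$redlist_fraction,
             cfg$occupancy_density, cfg$missing_tip_fraction,
             cfg$hybrid_fraction, cfg$duplicate_rate)
  if (any(fracs < 0) || any(fracs[-11] > 1)) {
    stop("sim_config fractions must lie in [0, 1]")
  }
  if (cfg$apomict_fraction + cfg$both_fraction + cfg$unknown_mode_fraction > 1) {
    stop("reproductive-mode fractions exceed 1")
  }
  if (diff(cfg$lat_range) <= 0 || diff(cfg$lon_range) <= 0) {
    stop("empty grid frame")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' All secondary mesh codes of the configured frame
#' @param cfg A \code{sim_config}.
#' @return Character vector of 6-digit codes covering the latitude/longitude
#'   band (cells whose SW corner lies inside it).
#' @export
frame_codes <- function(cfg) {
  lat_sw <- seq(cfg$lat_range[1], cfg$lat_range[2] - 1e-9, by = 1 / 12)
  lon_sw <- seq(cfg$lon_range[1], cfg$lon_range[2] - 1e-9, by = 1 / 8)
  grid <- expand.grid(lat = lat_sw, lon = lon_sw)
  sort(encode_mesh(grid$lat + 1e-9, grid$lon + 1e-9))
}

#' Generate a synthetic trait-annotated checklist
#'
#' Native taxa get reproductive mode, ploidy, phenology, lineage, endemism
#' and red-list category by independent draws at the configured fractions
#' (so realised counts vary binomially around them); hybrids carry unknown
#' mode and ploidy and are absent from the tree. \code{in_tree} is
#' provisional here (TRUE for natives) and is finalised by
#' \code{\link{gen_tree}}, which withholds the configured fraction.
#'
#' @param cfg A \code{sim_config}.
#' @return A \code{taxon_table}.
#' @export
gen_checklist <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_taxa
  n_hyb <- round(n * cfg$hybrid_fraction)
  mode_probs <- c(apomictic = cfg$apomict_fraction, both = cfg$both_fraction,
                  unknown = cfg$unknown_mode_fraction)
  mode_probs <- c(mode_probs, sexual = 1 - sum(mode_probs))
  mode <- sample(names(mode_probs), n, replace = TRUE, prob = mode_probs)
  ploidy <- ifelse(mode == "sexual",
                   ifelse(stats::runif(n) < cfg$polyploid_fraction,
                          "polyploid", "diploid"),
                   "unknown")
  rl <- ifelse(stats::runif(n) < cfg$redlist_fraction,
               sample(names(cfg$redlist_weights), n, replace = TRUE,
                      prob = cfg$redlist_weights),
               "none")
  native <- data.frame(
    taxon_id = sprintf("tax%04d", seq_len(n)),
    name = sprintf("Taxon species%04d", seq_len(n)),
    rank = sample(c("species", "subspecies", "variety"), n, replace = TRUE,
                  prob = c(0.9, 0.04, 0.06)),
    is_hybrid = FALSE,
    lineage = ifelse(stats::runif(n) < cfg$lycophyte_fraction,
                     "lycophyte", "fern"),
    reproductive_mode = mode,
    ploidy_class = ploidy,
    phenology = ifelse(stats::runif(n) < cfg$evergreen_fraction,
                       "evergreen", "seasonal_green"),
    endemic = stats::runif(n) < cfg$endemic_fraction,
    redlist = rl,
    in_tree = TRUE,
    stringsAsFactors = FALSE
  )
  if (n_hyb > 0) {
    hybrid <- data.frame(
      taxon_id = sprintf("hyb%04d", seq_len(n_hyb)),
      name = sprintf("Taxon xhybridum%04d", seq_len(n_hyb)),
      rank = "species",
      is_hybrid = TRUE,
      lineage = ifelse(stats::runif(n_hyb) < cfg$lycophyte_fraction,
                       "lycophyte", "fern"),
      reproductive_mode = "unknown",
      ploidy_class = "unknown",
      phenology = ifelse(stats::runif(n_hyb) < cfg$evergreen_fraction,
                         "evergreen", "seasonal_green"),
      endemic = FALSE,
      redlist = "none",
      in_tree = FALSE,
      stringsAsFactors = FALSE
    )
    native <- rbind(native, hybrid)
  }
  as_taxon_table(native)
}

#' Generate a Yule reference tree over the non-hybrid taxa
#'
#' Pure-birth topology with i.i.d. exponential branch lengths (mean
#' \code{branch_mean} expected substitutions per site). A configured
#' fraction of native taxa is withheld from the tree, emulating incomplete
#' rbcL sampling; their \code{in_tree} flags are set FALSE in the returned
#' table.
#'
#' @param cfg A \code{sim_config}.
#' @param table The checklist from \code{\link{gen_checklist}}.
#' @return List with \code{tree} (a \code{phylo}) and \code{table} (the
#'   checklist with final \code{in_tree} flags).
#' @export
gen_tree <- function(cfg, table) {
  set.seed(cfg$seed + 1L)
  native_ids <- table$taxon_id[!table$is_hybrid]
  withheld <- stats::runif(length(native_ids)) < cfg$missing_tip_fraction
  tip_ids <- native_ids[!withheld]
  if (length(tip_ids) < 2) stop("need at least 2 tree tips")
  tree <- ape::rphylo(length(tip_ids), birth = cfg$tree_birth_rate, death = 0)
  tree$tip.label <- sample(tip_ids)
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1 / cfg$branch_mean)
  table$in_tree <- !table$is_hybrid & table$taxon_id %in% tip_ids
  list(tree = validate_phylogeny(tree), table = as_taxon_table(table))
}

#' Generate synthetic presence records
#'
#' Each taxon receives a latitudinal range center (normal around
#' \code{center_mean}, apomicts shifted south, seasonal-green taxa shifted
#' north) and a breadth drawn from its reproductive-mode group's
#' distribution (truncated below at one cell height); every frame cell
#' whose centroid latitude falls inside the band is then occupied
#' independently with probability \code{occupancy_density}. Duplicate
#' records are appended at \code{duplicate_rate} to exercise deduplication.
#'
#' @param cfg A \code{sim_config}.
#' @param table The checklist.
#' @return data.frame of records (taxon_id, mesh_code), plus attribute
#'   \code{centers}/\code{breadths} (named vectors of the true per-taxon
#'   parameters, for parameter-recovery tests).
#' @export
gen_occurrences <- function(cfg, table) {
  set.seed(cfg$seed + 2L)
  codes <- frame_codes(cfg)
  cell_lat <- cell_centroid(codes)$lat
  n <- nrow(table)
  shift <- ifelse(table$reproductive_mode == "apomictic",
                  cfg$apomict_center_shift, 0) +
    ifelse(table$phenology == "seasonal_green", cfg$seasonal_center_shift, 0)
  grp <- ifelse(table$reproductive_mode %in% names(cfg$breadth_mean),
                table$reproductive_mode, "sexual")
  centers <- stats::rnorm(n, cfg$center_mean + shift, cfg$center_sd)
  breadths <- pmax(1 / 12,
                   stats::rnorm(n, cfg$breadth_mean[grp], cfg$breadth_sd[grp]))
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    in_band <- which(abs(cell_lat - centers[i]) <= breadths[i] / 2)
    hit <- in_band[stats::runif(length(in_band)) < cfg$occupancy_density]
    if (length(hit)) {
      recs[[i]] <- data.frame(taxon_id = table$taxon_id[i],
                              mesh_code = codes[hit],
                              stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  if (is.null(records)) {
    records <- data.frame(taxon_id = character(0), mesh_code = character(0))
  }
  if (cfg$duplicate_rate > 0 && nrow(records) > 0) {
    n_dup <- floor(cfg$duplicate_rate * nrow(records))
    if (n_dup > 0) {
      dup <- records[sample(nrow(records), n_dup, replace = TRUE), ]
      records <- rbind(records, dup)
      rownames(records) <- NULL
    }
  }
  attr(records, "centers") <- stats::setNames(centers, table$taxon_id)
  attr(records, "breadths") <- stats::setNames(breadths, table$taxon_id)
  records
}

#' Generate and write a complete synthetic dataset
#'
#' Writes \code{checklist.csv}, \code{occurrences.csv} and \code{tree.nwk}
#' in the exact dialects the loaders read.
#'
#' @param cfg A \code{sim_config}.
#' @param dir Output directory (created if needed).
#' @return Invisible list with \code{paths} (the three file paths) plus the
#'   in-memory \code{table}, \code{tree} and \code{records}.
#' @export
simulate_dataset <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  table <- gen_checklist(cfg)
  tt <- gen_tree(cfg, table)
  records <- gen_occurrences(cfg, tt$table)
  paths <- list(checklist = file.path(dir, "checklist.csv"),
                occurrences = file.path(dir, "occurrences.csv"),
                tree = file.path(dir, "tree.nwk"))
  write_checklist(tt$table, paths$checklist)
  utils::write.csv(records[, c("taxon_id", "mesh_code")], paths$occurrences,
                   row.names = FALSE, quote = FALSE)
  ape::write.tree(tt$tree, paths$tree)
  invisible(list(paths = paths, table = tt$table, tree = tt$tree,
                 records = records))
}
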