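test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- small_sim(seed = 61, duplicate_rate = 0.05)
  t1 <- gen_checklist(cfg); t2 <- gen_checklist(cfg)
  expect_identical(t1, t2)
  tr1 <- gen_tree(cfg, t1); tr2 <- gen_tree(cfg, t2)
  expect_identical(ape::write.tree(tr1$tree), ape::write.tree(tr2$tree))
  r1 <- gen_occurrences(cfg, tr1$table); r2 <- gen_occurrences(cfg, tr2$table)
  expect_identical(r1, r2)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1); simulate_dataset(cfg, d2)
  for (f in c("checklist.csv", "occurrences.csv", "tree.nwk")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("checklist trait counts track the configured fractions", {
  cfg <- sim_config(seed = 62, lat_range = c(30, 36), lon_range = c(130, 135))
  tab <- gen_checklist(cfg)
  expect_equal(n_native(tab), 721)
  expect_equal(n_hybrid(tab), 371)
  # realised counts within 4 binomial sds of expectation
  binom_ok <- function(count, n, p) abs(count - n * p) <= 4 * sqrt(n * p * (1 - p))
  expect_true(binom_ok(sum(tab$reproductive_mode == "apomictic" & !tab$is_hybrid),
                       721, cfg$apomict_fraction))
  expect_true(binom_ok(sum(tab$endemic), 721, cfg$endemic_fraction))
  expect_true(binom_ok(sum(tab$redlist != "none" & !tab$is_hybrid),
                       721, cfg$redlist_fraction))

  none <- gen_checklist(sim_config(seed = 63, n_taxa = 50, hybrid_fraction = 0))
  expect_equal(n_hybrid(none), 0)

  expect_error(sim_config(apomict_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(apomict_fraction = 0.9, both_fraction = 0.2),
               "exceed 1")
  expect_error(sim_config(lat_range = c(40, 30)), "empty grid frame")
})

test_that("the tree spans non-hybrid taxa with the configured coverage gap", {
  cfg <- small_sim(seed = 64, n_taxa = 400L, missing_tip_fraction = 0.1)
  tab <- gen_checklist(cfg)
  tt <- gen_tree(cfg, tab)
  expect_true(all(tt$tree$tip.label %in% tab$taxon_id[!tab$is_hybrid]))
  expect_setequal(tt$tree$tip.label, tt$table$taxon_id[tt$table$in_tree])
  n_missing <- sum(!tt$table$in_tree & !tt$table$is_hybrid)
  expect_true(abs(n_missing - 40) <= 4 * sqrt(400 * 0.1 * 0.9))
  expect_true(all(tt$tree$edge.length > 0))

  two <- sim_config(seed = 65, n_taxa = 2, hybrid_fraction = 0,
                    missing_tip_fraction = 0)
  cherry <- gen_tree(two, gen_checklist(two))
  expect_equal(length(cherry$tree$tip.label), 2)
})

test_that("generated files pass every loader without warnings", {
  cfg <- small_sim(seed = 66)
  d <- withr::local_tempdir()
  sim <- simulate_dataset(cfg, d)
  expect_no_warning({
    tab <- load_checklist(file.path(d, "checklist.csv"))
    m <- load_occurrences(file.path(d, "occurrences.csv"), tab)
    tr <- read_newick(file.path(d, "tree.nwk"))
  })
  expect_equal(m$provenance, nrow(sim$records))
  expect_equal(Matrix::nnzero(m$presence),
               nrow(unique(sim$records[, c("taxon_id", "mesh_code")])))
  # tree round-trips through Newick with topology and lengths intact
  expect_true(ape::all.equal.phylo(tr, sim$tree, use.edge.length = FALSE))
  expect_equal(sort(tr$edge.length), sort(sim$tree$edge.length),
               tolerance = 1e-8)
})

test_that("duplicate injection only affects provenance, and zero density empties the data", {
  cfg <- small_sim(seed = 67, duplicate_rate = 0.2)
  tab <- gen_checklist(cfg)
  rec <- gen_occurrences(cfg, tab)
  m <- occurrence_matrix(rec, tab)
  expect_gt(m$provenance, Matrix::nnzero(m$presence))

  none <- small_sim(seed = 67, occupancy_density = 0)
  expect_equal(nrow(gen_occurrences(none, gen_checklist(none))), 0)
})

test_that("apomicts are generated south of and narrower than sexual taxa", {
  cfg <- sim_config(seed = 68, n_taxa = 400, hybrid_fraction = 0,
                    apomict_fraction = 0.3, lat_range = c(24, 46),
                    lon_range = c(130, 133), occupancy_density = 0.4)
  tab <- gen_checklist(cfg)
  rec <- gen_occurrences(cfg, tab)
  centers <- attr(rec, "centers")
  breadths <- attr(rec, "breadths")
  apo <- tab$reproductive_mode == "apomictic"
  sex <- tab$reproductive_mode == "sexual"
  expect_lt(mean(centers[apo]), mean(centers[sex]))
  expect_lt(mean(breadths[apo]), mean(breadths[sex]))
  # recovered per-taxon breadth is within one cell height of the truth
  m <- occurrence_matrix(rec, tab)
  rt <- range_table(m)
  well_sampled <- rt$taxon_id[rt$n_cells >= 200]
  frame_lat <- range(cell_centroid(frame_codes(cfg))$lat)
  for (id in utils::head(well_sampled, 30)) {
    lo <- max(centers[id] - breadths[id] / 2, frame_lat[1])
    hi <- min(centers[id] + breadths[id] / 2, frame_lat[2])
    true_breadth <- max(hi - lo, 0)
    obs <- rt$lat_breadth[rt$taxon_id == id]
    expect_lt(abs(obs - true_breadth), 2 / 12 + 1e-9)
  }
})
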