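test_that("richness layers count presences under their filters", {
  tab <- make_checklist(4,
    is_hybrid = c(FALSE, FALSE, FALSE, TRUE),
    reproductive_mode = c("apomictic", "sexual", "apomictic", "unknown"),
    redlist = c("CR", "none", "none", "VU"))
  rec <- data.frame(
    taxon_id = c("t001", "t002", "t003", "t004", "t001", "t002"),
    mesh_code = c("503501", "503501", "503501", "503502", "503502", "503503"))
  m <- occurrence_matrix(rec, tab)

  r <- richness_map(m, tab)
  expect_equal(unname(r$values[c("503501", "503502", "503503")]), c(3, 2, 1))
  # total over cells equals total presences
  expect_equal(sum(r$values), Matrix::nnzero(m$presence))

  rn <- richness_map(m, tab, include_hybrids = FALSE)
  expect_equal(unname(rn$values["503502"]), 1)

  apo <- subset_richness_map(m, tab, "apomictic")
  expect_equal(unname(apo$values[c("503501", "503502", "503503")]), c(2, 1, 0))
  rl <- subset_richness_map(m, tab, "redlisted")
  expect_equal(unname(rl$values[c("503501", "503502", "503503")]), c(1, 2, 0))

  # subset richness never exceeds overall richness
  expect_true(all(apo$values <= r$values[names(apo$values)]))
  expect_true(all(rl$values <= r$values[names(rl$values)]))
})

test_that("proportion layers divide cellwise with undefined zero denominators", {
  num <- grid_map(c("503501" = 0, "503502" = 2, "503503" = 0), "apo")
  den <- grid_map(c("503501" = 4, "503502" = 2, "503503" = 0), "all")
  p <- proportion_map(num, den)
  expect_equal(unname(p$values[c("503501", "503502")]), c(0, 1))
  expect_true(is.na(p$values[["503503"]]))

  bad <- grid_map(c("503501" = 9, "503502" = 1, "503503" = 0), "apo")
  expect_error(proportion_map(bad, den), "exceeds denominator in cell 503501")
  expect_error(proportion_map(num, grid_map(c("503509" = 1), "x")),
               "identical cells")
})

test_that("top_cells ranks deterministically with ties broken by code", {
  g <- grid_map(c("503502" = 5, "503501" = 2, "403501" = 5), "r")
  top <- top_cells(g, 2)
  expect_equal(top$mesh_code, c("403501", "503502"))
  expect_equal(top$value, c(5, 5))
  # k larger than the map returns everything ranked
  expect_equal(nrow(top_cells(g, 99)), 3)
  expect_error(top_cells(grid_map(c("503501" = NA_real_), "x")), "no defined")
})

test_that("CSV export round-trips and GeoJSON polygons equal cell bounds", {
  g <- grid_map(c("453034" = 7, "503547" = NA_real_), "richness")
  csv <- withr::local_tempfile(fileext = ".csv")
  export_layer(g, csv, "csv")
  back <- import_layer_csv(csv, "richness")
  expect_equal(back$values, g$values)

  # frame cells absent from a count layer export as zero
  csv2 <- withr::local_tempfile(fileext = ".csv")
  export_layer(g, csv2, "csv", frame = c("453034", "503547", "453035"),
               fill = 0)
  back2 <- import_layer_csv(csv2)
  expect_equal(unname(back2$values["453035"]), 0)

  gj <- withr::local_tempfile(fileext = ".geojson")
  export_layer(g, gj, "geojson")
  parsed <- jsonlite::read_json(gj)
  expect_equal(parsed$type, "FeatureCollection")
  expect_length(parsed$features, 2)
  f1 <- parsed$features[[1]]
  expect_equal(f1$properties$mesh_code, "453034")
  ring <- f1$geometry$coordinates[[1]]
  expect_equal(unlist(ring[[1]]), c(130.5, 30.25))          # SW, (lon, lat)
  expect_equal(unlist(ring[[3]]), c(130.625, 30.25 + 1 / 12))  # NE
  expect_equal(unlist(ring[[1]]), unlist(ring[[5]]))        # closed ring
  # undefined value serialises as null
  expect_null(parsed$features[[2]]$properties$value)
})

test_that("per-cell layers agree with independent summation on synthetic data", {
  cfg <- small_sim(seed = 51)
  tab <- gen_checklist(cfg)
  m <- occurrence_matrix(gen_occurrences(cfg, tab), tab)
  r <- richness_map(m, tab)
  dense <- as.matrix(m$presence)
  expect_equal(unname(r$values), unname(colSums(dense)))
  # the ranked richest cell agrees with a full sort (lowest code on ties)
  expect_equal(top_cells(r, 1)$mesh_code,
               min(names(r$values)[r$values == max(r$values)]))
})
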