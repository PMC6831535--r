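test_that("range summaries count cells and centroid-latitude extremes", {
  tab <- make_checklist(2)
  rec <- data.frame(taxon_id = c("t001", "t002", "t002"),
                    mesh_code = c("453034", "453034", "503547"))
  m <- occurrence_matrix(rec, tab)

  one <- range_summary(m, "t001")
  expect_equal(one$n_cells, 1)
  expect_equal(one$lat_breadth, 0)

  two <- range_summary(m, "t002")
  expect_equal(two$n_cells, 2)
  # centroid latitudes: 453034 -> 30.2916..., 503547 -> 33.7083...
  expect_equal(two$lat_breadth, (50 / 1.5 + 4 / 12) - 30.25, tolerance = 1e-12)
  expect_equal(two$lat_breadth, 41 / 12, tolerance = 1e-12)

  expect_error(range_summary(m, "t999"), "no occupied cells")
})

test_that("one-way ANOVA matches the classical decomposition and aov", {
  g0 <- list(a = rep(2, 4), b = rep(2, 5), c = rep(2, 3))
  a0 <- one_way_anova(g0)
  expect_equal(a0$F, 0)
  expect_equal(a0$p, 1)

  set.seed(41)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    g <- lapply(seq_len(k), function(j) rnorm(sample(3:20, 1), runif(1, 0, 3)))
    names(g) <- paste0("g", seq_len(k))
    a <- one_way_anova(g)
    y <- unlist(g)
    f <- factor(rep(names(g), lengths(g)))
    ref <- summary(stats::aov(y ~ f))[[1]]
    expect_equal(a$F, ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(a$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
    expect_gte(a$F, 0)
    expect_true(a$p >= 0 && a$p <= 1)
  }

  # two groups: F is the square of the pooled t statistic
  x <- rnorm(9); y <- rnorm(12, 1)
  expect_equal(one_way_anova(list(x = x, y = y))$F,
               student_t(x, y)$t^2, tolerance = 1e-10)

  expect_error(one_way_anova(list(a = 1, b = rnorm(3))), "degenerate")
})

test_that("studentized-range CDF matches stats::ptukey and is monotone", {
  set.seed(42)
  for (i in 1:30) {
    q <- runif(1, 0.2, 6)
    k <- sample(2:6, 1)
    df <- sample(c(4, 8, 20, 60, 240), 1)
    expect_equal(ptukey_sr(q, k, df), stats::ptukey(q, k, df),
                 tolerance = 1e-6)
  }
  expect_equal(ptukey_sr(3, 4, Inf), stats::ptukey(3, 4, Inf), tolerance = 1e-6)
  expect_equal(ptukey_sr(0, 3, 10), 0)
  qs <- seq(0.1, 8, by = 0.5)
  vals <- vapply(qs, ptukey_sr, numeric(1), k = 3, df = 12)
  expect_true(all(diff(vals) > 0))
})

test_that("Tukey HSD pairwise p-values and letters behave", {
  # identical groups: p exactly 1, one shared letter
  gid <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  t1 <- tukey_hsd(gid)
  expect_equal(t1$pairs$p, 1)
  expect_equal(unname(t1$letters), c("a", "a"))

  # well-separated groups: all pairs significant, three distinct letters
  set.seed(43)
  gsep <- list(a = rnorm(10), b = rnorm(10, 20), c = rnorm(10, 40))
  t2 <- tukey_hsd(gsep)
  expect_true(all(t2$pairs$p < 1e-6))
  expect_equal(length(unique(t2$letters)), 3)

  # random fixtures against TukeyHSD
  for (i in 1:15) {
    k <- sample(3:5, 1)
    g <- lapply(seq_len(k), function(j) rnorm(sample(4:15, 1), runif(1, 0, 2)))
    names(g) <- paste0("g", seq_len(k))
    mine <- tukey_hsd(g)
    y <- unlist(g)
    f <- factor(rep(names(g), lengths(g)))
    ref <- stats::TukeyHSD(stats::aov(y ~ f))$f
    for (r in seq_len(nrow(mine$pairs))) {
      nm <- paste0(mine$pairs$group2[r], "-", mine$pairs$group1[r])
      expect_lt(abs(mine$pairs$p[r] - ref[nm, "p adj"]), 1e-6)
    }
  }
})

test_that("letter display follows insert-and-absorb", {
  # only the extreme pair differs: middle group shares both letters
  out <- letter_display(c("lo", "mid", "hi"),
                        data.frame(g1 = "lo", g2 = "hi"))
  expect_equal(nchar(out[["mid"]]), 2)
  expect_true(out[["lo"]] != out[["hi"]])
  expect_false(any(strsplit(out[["lo"]], "")[[1]] %in%
                     strsplit(out[["hi"]], "")[[1]]))

  # no significant pairs: everyone shares one letter
  same <- letter_display(letters[1:4], data.frame(g1 = character(0),
                                                  g2 = character(0)))
  expect_equal(length(unique(same)), 1)
})

test_that("Student's t matches t.test in pooled and Welch forms", {
  x <- c(1, 2, 3, 4)
  expect_equal(student_t(x, x)$t, 0)
  expect_equal(student_t(x, x)$p, 1)

  set.seed(44)
  for (i in 1:15) {
    a <- rnorm(sample(3:20, 1))
    b <- rnorm(sample(3:20, 1), 0.5, 2)
    mine <- student_t(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    welch <- student_t(a, b, pooled = FALSE)
    refw <- stats::t.test(a, b)
    expect_equal(welch$t, unname(refw$statistic), tolerance = 1e-10)
    expect_equal(welch$p, refw$p.value, tolerance = 1e-10)
    expect_equal(welch$df, unname(refw$parameter), tolerance = 1e-10)
    # swapping groups flips the sign, not the p-value
    flip <- student_t(b, a)
    expect_equal(flip$t, -mine$t)
    expect_equal(flip$p, mine$p)
  }
  expect_error(student_t(1, c(1, 2)), "degenerate")
})

test_that("trait comparisons apply the exclusion rules", {
  tab <- make_checklist(8,
    is_hybrid = c(rep(FALSE, 7), TRUE),
    reproductive_mode = c("sexual", "sexual", "sexual", "apomictic",
                          "apomictic", "both", "unknown", "sexual"),
    ploidy_class = c("diploid", "polyploid", "diploid", "unknown",
                     "unknown", "unknown", "diploid", "diploid"))
  set.seed(45)
  cells <- sprintf("%02d%02d%d%d", sample(30:50, 40, TRUE),
                   sample(20:40, 40, TRUE), sample(0:7, 40, TRUE),
                   sample(0:7, 40, TRUE))
  rec <- data.frame(taxon_id = rep(tab$taxon_id, each = 5),
                    mesh_code = cells)
  m <- occurrence_matrix(rec, tab)

  # the single-taxon "both" group is dropped with a warning; hybrids and
  # unknown-mode taxa never enter
  expect_warning(
    cmp <- compare_by_trait(m, tab, "n_cells", "reproductive_mode"),
    "fewer than 2")
  expect_setequal(cmp$groups$group, c("sexual", "apomictic"))
  expect_equal(sum(cmp$groups$n), 5)
  expect_equal(cmp$test, "student_t")

  # ploidy comparison is restricted to sexual taxa
  tab2 <- make_checklist(8,
    reproductive_mode = c(rep("sexual", 4), rep("apomictic", 4)),
    ploidy_class = c("diploid", "diploid", "polyploid", "polyploid",
                     "polyploid", "polyploid", "polyploid", "polyploid"))
  m_p <- occurrence_matrix(rec, tab2)
  cmp2 <- compare_by_trait(m_p, tab2, "n_cells", "ploidy_class")
  expect_equal(sum(cmp2$groups$n), 4)  # only the four sexual natives
  expect_equal(cmp2$groups$n, c(2, 2))

  # group stats invariant to taxon ordering
  m2 <- occurrence_matrix(rec[sample(nrow(rec)), ], tab)
  expect_warning(cmp3 <- compare_by_trait(m2, tab, "n_cells",
                                          "reproductive_mode"), "fewer")
  expect_equal(cmp3$groups, cmp$groups)
})
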