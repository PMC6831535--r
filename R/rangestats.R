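# Per-taxon range metrics and trait-group comparisons.
#
# The tests (one-way ANOVA, Tukey's HSD, Student's t) are implemented from
# the classical formulas; the studentized-range tail probability, the one
# piece without a simple closed form, is obtained by numerical integration
# of its CDF. Unit tests validate all three against independent library
# implementations.

#' Range summary for every taxon in an occurrence matrix
#'
#' For each taxon: number of occupied 10-km cells and the minimum, maximum
#' and breadth of the occupied cells' centroid latitudes. Latitudinal
#' breadth (max minus min latitude, degrees) is identical whether computed
#' from centroids or cell corners, since the half-cell offset cancels.
#'
#' @param m An \code{occurrence_matrix}.
#' @return data.frame with columns \code{taxon_id}, \code{n_cells},
#'   \code{lat_min}, \code{lat_max}, \code{lat_breadth}, one row per taxon
#'   present in the matrix.
#' @export
range_table <- function(m) {
  lat <- cell_centroid(m$cells)$lat
  trip <- Matrix::summary(m$presence)
  by_taxon <- split(lat[trip$j], trip$i)
  idx <- as.integer(names(by_taxon))
  data.frame(
    taxon_id = m$taxa[idx],
    n_cells = vapply(by_taxon, length, integer(1)),
    lat_min = vapply(by_taxon, min, numeric(1)),
    lat_max = vapply(by_taxon, max, numeric(1)),
    lat_breadth = vapply(by_taxon, function(x) max(x) - min(x), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Range summary for a single taxon
#'
#' @param m An \code{occurrence_matrix}.
#' @param taxon A taxon_id present in the matrix (a taxon with zero occupied
#'   cells is an error).
#' @return One-row data.frame as in \code{\link{range_table}}.
#' @export
range_summary <- function(m, taxon) {
  i <- match(taxon, m$taxa)
  if (is.na(i) || sum(m$presence[i, ]) == 0) {
    stop("taxon '", taxon, "' has no occupied cells in this matrix")
  }
  rt <- range_table(m)
  rt[rt$taxon_id == taxon, , drop = FALSE]
}

.check_groups <- function(groups, min_k = 2L) {
  if (length(groups) < min_k) {
    stop("need at least ", min_k, " groups, got ", length(groups))
  }
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) {
    stop("degenerate group(s) with fewer than 2 observations: ",
         paste(names(groups)[ns < 2], collapse = ", "))
  }
  invisible(ns)
}

#' One-way analysis of variance from the classical decomposition
#'
#' Splits the total sum of squares into between-group and within-group
#' components; F = MSB/MSW on (k - 1, N - k) degrees of freedom.
#'
#' @param groups Named list of numeric vectors, one per group, each of
#'   length at least 2.
#' @return List with \code{F}, \code{p}, \code{df} (numerator, denominator),
#'   \code{mse} (within-group mean square, reused by Tukey's HSD).
#' @export
one_way_anova <- function(groups) {
  .check_groups(groups)
  ns <- vapply(groups, length, integer(1))
  N <- sum(ns)
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  msb <- ss_between / (k - 1)
  msw <- ss_within / (N - k)
  f <- if (msw == 0) {
    if (msb == 0) 0 else Inf
  } else msb / msw
  p <- if (is.infinite(f)) 0 else stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  list(F = f, p = p, df = c(k - 1, N - k), mse = msw)
}

#' CDF of the studentized range distribution
#'
#' Probability that the range of \code{k} independent standard normal means,
#' divided by an independent estimate of their standard deviation on
#' \code{df} degrees of freedom, is at most \code{q}. Computed by nested
#' numerical integration: the inner integral gives the CDF of the normal
#' range at a fixed scale, the outer integrates over the scaled-chi density
#' of the standard-deviation estimate.
#'
#' @param q Quantile (non-negative).
#' @param k Number of groups.
#' @param df Error degrees of freedom (Inf for the known-variance range).
#' @return P(Q <= q).
#' @export
ptukey_sr <- function(q, k, df) {
  if (q <= 0) return(0)
  # CDF of the range of k iid N(0,1), vectorised over x; the integrand is
  # analytic and vanishes beyond |z| ~ 8.5, so fixed Gauss-Legendre nodes
  # give ~1e-12 accuracy
  gz <- .gauss_legendre(160L)
  z <- 8.5 * gz$nodes
  wz <- 8.5 * gz$weights * k * stats::dnorm(z)
  pz <- stats::pnorm(z)
  range_cdf <- function(x) {
    as.vector(crossprod(wz, (pz - stats::pnorm(outer(z, x, "-")))^(k - 1)))
  }
  if (is.infinite(df)) return(min(1, range_cdf(q)))
  # mix over the scaled-chi distribution of the sd estimate: s has density
  # proportional to s^(df-1) exp(-df s^2 / 2), concentrated around 1
  half_width <- min(1, 11 / sqrt(df))
  smin <- 1 - half_width
  smax <- 1 + 11 / sqrt(df)
  gs <- .gauss_legendre(120L)
  s <- (smin + smax) / 2 + (smax - smin) / 2 * gs$nodes
  ws <- (smax - smin) / 2 * gs$weights
  log_const <- (df / 2) * log(df) - lgamma(df / 2) - (df / 2 - 1) * log(2)
  dens_s <- exp(log_const + (df - 1) * log(s) - df * s^2 / 2)
  min(1, sum(ws * dens_s * range_cdf(q * s)))
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch), cached
.gl_cache <- new.env(parent = emptyenv())
.gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  out <- list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
  .gl_cache[[key]] <- out
  out
}

#' Tukey's honestly significant difference over all group pairs
#'
#' Tukey–Kramer pairwise comparisons using the within-group mean square from
#' \code{\link{one_way_anova}}: for groups i, j the studentized statistic is
#' \code{|mi - mj| / sqrt(mse/2 * (1/ni + 1/nj))} referred to the
#' studentized range distribution with k groups and N - k degrees of
#' freedom. Letters come from the insert-and-absorb algorithm: groups
#' sharing a letter are not significantly different at \code{alpha}.
#'
#' @param groups Named list of numeric vectors (each n >= 2).
#' @param alpha Family-wise significance level for the letter display.
#' @return List with \code{pairs} (data.frame: group1, group2, diff, p) and
#'   \code{letters} (named character vector over groups).
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  .check_groups(groups)
  ns <- vapply(groups, length, integer(1))
  k <- length(groups)
  df <- sum(ns) - k
  means <- vapply(groups, mean, numeric(1))
  a <- one_way_anova(groups)
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("group", seq_len(k))
  combs <- utils::combn(k, 2)
  pairs <- data.frame(
    group1 = labs[combs[1, ]], group2 = labs[combs[2, ]],
    diff = means[combs[2, ]] - means[combs[1, ]],
    p = NA_real_, stringsAsFactors = FALSE
  )
  for (r in seq_len(ncol(combs))) {
    i <- combs[1, r]; j <- combs[2, r]
    se <- sqrt(a$mse / 2 * (1 / ns[i] + 1 / ns[j]))
    pairs$p[r] <- if (se == 0) {
      if (means[i] == means[j]) 1 else 0
    } else 1 - ptukey_sr(abs(means[i] - means[j]) / se, k, df)
  }
  list(pairs = pairs,
       letters = letter_display(labs, pairs[pairs$p < alpha, 1:2, drop = FALSE]))
}

#' Compact letter display by insert-and-absorb
#'
#' Starts from one letter covering every group; each significantly different
#' pair splits any letter set containing both members into two sets, one
#' lacking each member; duplicate or subset columns are absorbed. Groups
#' sharing a letter are therefore exactly the groups never declared
#' different.
#'
#' @param labels Character vector of group labels.
#' @param sig_pairs data.frame (or 2-column matrix) of significantly
#'   different label pairs.
#' @return Named character vector of letter strings, e.g. "a", "ab".
#' @export
letter_display <- function(labels, sig_pairs) {
  sets <- list(labels)
  if (nrow(sig_pairs)) {
    for (r in seq_len(nrow(sig_pairs))) {
      g1 <- sig_pairs[r, 1]; g2 <- sig_pairs[r, 2]
      new_sets <- list()
      for (s in sets) {
        if (g1 %in% s && g2 %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, g1)), list(setdiff(s, g2)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb: drop any set contained in (or duplicating) another
      keep <- rep(TRUE, length(new_sets))
      for (i in seq_along(new_sets)) {
        for (j in seq_along(new_sets)) {
          if (i != j && keep[i] && keep[j] &&
              all(new_sets[[i]] %in% new_sets[[j]]) &&
              (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j)) {
            keep[i] <- FALSE
          }
        }
      }
      sets <- new_sets[keep]
      sets <- sets[lengths(sets) > 0]
    }
  }
  out <- stats::setNames(rep("", length(labels)), labels)
  for (s in seq_along(sets)) {
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  }
  out
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classical pooled-variance two-sided t-test; Welch's unequal-variance
#' version is available since group spreads in range data are often very
#' unequal.
#'
#' @param x,y Numeric samples, each of length at least 2.
#' @param pooled If FALSE, use the Welch statistic and the
#'   Welch–Satterthwaite degrees of freedom.
#' @return List with \code{t}, \code{p}, \code{df}.
#' @export
student_t <- function(x, y, pooled = TRUE) {
  .check_groups(list(x = x, y = y))
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (pooled) {
    df <- nx + ny - 2
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tval <- if (se == 0) {
    if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y))
  } else (mean(x) - mean(y)) / se
  p <- if (is.infinite(tval)) 0 else 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(t = tval, p = p, df = df)
}

#' Trait-group comparison of range size or latitudinal breadth
#'
#' Reproduces the range-comparison design: hybrids are excluded, taxa with
#' an unknown value of the trait are excluded, and the ploidy comparison is
#' further restricted to sexually reproducing taxa (apomicts, dominated by
#' triploids, would otherwise drive it). Groups left with fewer than 2 taxa
#' are dropped with a warning. Two remaining groups are compared with
#' Student's t; three or more with one-way ANOVA plus Tukey's HSD and a
#' compact letter display.
#'
#' @param m An \code{occurrence_matrix}.
#' @param table The \code{taxon_table}.
#' @param metric "n_cells" (occupied 10-km cells) or "lat_breadth" (degrees).
#' @param trait "reproductive_mode", "phenology" or "ploidy_class".
#' @param alpha Significance level for Tukey letters.
#' @param pooled Passed to \code{\link{student_t}}.
#' @return A \code{group_comparison}: list with \code{groups} (data.frame:
#'   group, n, mean, sd), \code{test} ("anova_tukey" or "student_t"),
#'   \code{anova}, \code{tukey} or \code{t} results, \code{metric},
#'   \code{trait}.
#' @export
compare_by_trait <- function(m, table,
                             metric = c("n_cells", "lat_breadth"),
                             trait = c("reproductive_mode", "phenology",
                                       "ploidy_class"),
                             alpha = 0.05, pooled = TRUE) {
  metric <- match.arg(metric)
  trait <- match.arg(trait)
  rt <- range_table(m)
  traits <- table[match(rt$taxon_id, table$taxon_id), , drop = FALSE]
  keep <- !traits$is_hybrid & traits[[trait]] != "unknown"
  if (trait == "ploidy_class") keep <- keep & traits$reproductive_mode == "sexual"
  rt <- rt[keep, , drop = FALSE]
  grp <- traits[[trait]][keep]
  groups <- split(rt[[metric]], grp)
  small <- vapply(groups, length, integer(1)) < 2
  if (any(small)) {
    warning("dropping group(s) with fewer than 2 taxa: ",
            paste(names(groups)[small], collapse = ", "))
    groups <- groups[!small]
  }
  if (length(groups) < 2) stop("fewer than 2 usable groups for trait ", trait)
  stats_df <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- list(groups = stats_df, metric = metric, trait = trait, alpha = alpha)
  if (length(groups) == 2) {
    out$test <- "student_t"
    out$t <- student_t(groups[[1]], groups[[2]], pooled = pooled)
  } else {
    out$test <- "anova_tukey"
    out$anova <- one_way_anova(groups)
    out$tukey <- tukey_hsd(groups, alpha = alpha)
    out$groups$letters <- out$tukey$letters[out$groups$group]
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s by %s (hybrids and unknown-trait taxa excluded)\n",
              x$metric, x$trait))
  for (r in seq_len(nrow(x$groups))) {
    g <- x$groups[r, ]
    cat(sprintf("  %s = %.1f ± %.1f (n = %d)%s\n", g$group, g$mean, g$sd,
                g$n, if (!is.null(g$letters)) paste0("  [", g$letters, "]") else ""))
  }
  if (x$test == "student_t") {
    cat(sprintf("  Student's t = %.3f, df = %.1f, P = %.3g\n",
                x$t$t, x$t$df, x$t$p))
  } else {
    cat(sprintf("  ANOVA F = %.3f (df %d, %d), P = %.3g\n",
                x$anova$F, x$anova$df[1], x$anova$df[2], x$anova$p))
    p <- x$tukey$pairs
    for (r in seq_len(nrow(p))) {
      cat(sprintf("  Tukey %s vs %s: P = %.3g\n", p$group1[r], p$group2[r], p$p[r]))
    }
  }
  invisible(x)
}

#' Write a group comparison (and its pairwise tests) to CSV
#'
#' @param cmp A \code{group_comparison}.
#' @param path Output CSV path for the per-group statistics; pairwise Tukey
#'   p-values (when present) go to \code{<path stem>_pairs.csv}.
#' @export
write_comparison <- function(cmp, path) {
  df <- cmp$groups
  df$metric <- cmp$metric
  df$trait <- cmp$trait
  if (cmp$test == "student_t") {
    df$test <- "student_t"; df$statistic <- cmp$t$t; df$p <- cmp$t$p
  } else {
    df$test <- "anova"; df$statistic <- cmp$anova$F; df$p <- cmp$anova$p
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (cmp$test == "anova_tukey") {
    utils::write.csv(cmp$tukey$pairs,
                     sub("(\\.[^.]+)?$", "_pairs\\1", path),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
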