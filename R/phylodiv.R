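# Faith's phylogenetic diversity on a rooted reference tree.
#
# PD of a taxon set is the total branch length of the minimal subtree
# connecting the set's tips. Following the convention for "excluding the
# root", the pruned subtree is rooted at the retained tips' most recent
# common ancestor and any residual edge above it is discarded; the
# alternative (keeping the path up to the original root) is available via
# `keep_root_path` so real data can arbitrate between the two readings.

#' Read a rooted phylogeny with branch lengths from a Newick file
#'
#' Thin validating wrapper around \code{\link[ape]{read.tree}}. The tree is
#' taken as rooted where the Newick string roots it; polytomies (as in a
#' majority consensus tree) are fine. Every edge must carry a non-negative
#' branch length — a missing length is an error, never a silent zero. Any
#' root edge is kept but never summed into PD.
#'
#' @param path Path to a single-tree Newick file.
#' @return An \code{ape} \code{phylo} object.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (inherits(tree, "multiPhylo")) stop("expected a single tree, got several: ", path)
  validate_phylogeny(tree)
}

#' Validate a phylo object for PD computation
#' @param tree An \code{ape} \code{phylo} object.
#' @return The tree, invisibly checked (unique tips, complete non-negative
#'   branch lengths).
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  dup <- duplicated(tree$tip.label)
  if (any(dup)) {
    stop("duplicate tip label(s): ", paste(unique(tree$tip.label[dup]), collapse = ", "))
  }
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    stop("tree must have a branch length on every edge (no silent zeros)")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  tree
}

# Number of retained tips descending through each edge, in the tree's
# postorder edge ordering. Returns list(edge, edge.length, count).
.edge_tip_counts <- function(tree, retained) {
  po <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  cnt_node <- numeric(n_tip + tree$Nnode)
  cnt_node[seq_len(n_tip)] <- as.numeric(tree$tip.label %in% retained)
  parent <- po$edge[, 1]
  child <- po$edge[, 2]
  for (e in seq_along(parent)) {
    cnt_node[parent[e]] <- cnt_node[parent[e]] + cnt_node[child[e]]
  }
  list(edge.length = po$edge.length, count = cnt_node[child])
}

#' Faith's phylogenetic diversity of a taxon set
#'
#' Tips in \code{tips} that are absent from the tree (taxa without an rbcL
#' sequence) are dropped before computing and reported in
#' \code{n_tips_dropped}. PD is undefined — a value, not an error — when
#' fewer than two tips remain, since a single tip spans no branch length.
#'
#' The computation marks each edge with the number of retained tips below
#' it; the minimal spanning subtree below the retained tips' MRCA is exactly
#' the set of edges whose count is strictly between 0 and the number of
#' retained tips, so PD is one pass over the edges.
#'
#' @param tree A validated \code{phylo}.
#' @param tips Character vector of taxon ids.
#' @param keep_root_path If TRUE, also sum the edges from the retained tips'
#'   MRCA up to the tree's root (the root edge itself is never summed).
#' @return A \code{pd_value}: list with \code{value} (NA when undefined),
#'   \code{n_tips_used}, \code{n_tips_dropped}.
#' @export
faith_pd <- function(tree, tips, keep_root_path = FALSE) {
  tips <- unique(as.character(tips))
  retained <- tips[tips %in% tree$tip.label]
  n_used <- length(retained)
  out <- list(value = NA_real_, n_tips_used = n_used,
              n_tips_dropped = length(tips) - n_used)
  class(out) <- "pd_value"
  if (n_used < 2) return(out)
  ec <- .edge_tip_counts(tree, retained)
  on_subtree <- ec$count > 0 & ec$count < n_used
  if (keep_root_path) on_subtree <- ec$count > 0
  out$value <- sum(ec$edge.length[on_subtree])
  out
}

#' @export
print.pd_value <- function(x, ...) {
  if (is.na(x$value)) {
    cat(sprintf("PD undefined (%d tip(s) in tree, %d dropped)\n",
                x$n_tips_used, x$n_tips_dropped))
  } else {
    cat(sprintf("PD = %g over %d tips (%d dropped)\n",
                x$value, x$n_tips_used, x$n_tips_dropped))
  }
  invisible(x)
}

#' Per-cell Faith's PD map
#'
#' Computes PD for every grid cell of an occurrence matrix, after
#' restricting it to native (non-hybrid) taxa and optionally to ferns only
#' (the deep fern/lycophyte divergence can dominate PD when lycophytes are
#' included). Taxa without a tip in the tree contribute to richness but are
#' dropped from PD; the per-cell dropped count is returned alongside. Cells
#' with fewer than two in-tree taxa carry an undefined (NA) PD.
#'
#' Internally the per-edge retained-tip counts for all cells are obtained in
#' one sparse matrix product between the edge-by-tip descendant incidence
#' matrix and the presence matrix, processed in blocks of cells.
#'
#' @param m An \code{occurrence_matrix}.
#' @param tree A validated \code{phylo}.
#' @param table The \code{taxon_table} (for the hybrid/lineage filters).
#' @param lineage "all" or "ferns".
#' @param keep_root_path Passed to the PD convention (see
#'   \code{\link{faith_pd}}).
#' @param block_size Number of cells per dense block.
#' @return A \code{grid_map} of PD values (NA = undefined), with elements
#'   \code{n_tips_used} and \code{n_tips_dropped} per cell in \code{meta}.
#' @export
pd_map <- function(m, tree, table, lineage = c("all", "ferns"),
                   keep_root_path = FALSE, block_size = 1024L) {
  lineage <- match.arg(lineage)
  m <- filter_matrix(m, table, include_hybrids = FALSE, lineage = lineage)
  in_tree <- m$taxa %in% tree$tip.label
  n_dropped_by_cell <- Matrix::colSums(m$presence[!in_tree, , drop = FALSE])
  p_tree <- m$presence[in_tree, , drop = FALSE]

  # edge-by-tip incidence: which tips of the matrix descend through each edge
  n_tip <- length(tree$tip.label)
  parent_of <- integer(n_tip + tree$Nnode)
  edge_of <- integer(n_tip + tree$Nnode)  # edge index whose child is the node
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- n_tip + 1L
  tip_idx <- match(m$taxa[in_tree], tree$tip.label)
  ii <- integer(0); jj <- integer(0)
  for (k in seq_along(tip_idx)) {
    node <- tip_idx[k]
    path <- integer(0)
    while (node != root) {
      path <- c(path, edge_of[node])
      node <- parent_of[node]
    }
    ii <- c(ii, path)
    jj <- c(jj, rep.int(k, length(path)))
  }
  D <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(nrow(tree$edge), length(tip_idx)))

  n_cells <- length(m$cells)
  values <- rep(NA_real_, n_cells)
  n_used <- Matrix::colSums(p_tree)
  blocks <- split(seq_len(n_cells), ceiling(seq_len(n_cells) / block_size))
  for (b in blocks) {
    counts <- as.matrix(D %*% p_tree[, b, drop = FALSE])
    nret <- n_used[b]
    upper <- if (keep_root_path) rep(Inf, length(b)) else nret
    on_subtree <- counts > 0 & sweep(counts, 2, upper, "<")
    if (keep_root_path) on_subtree <- counts > 0
    vals <- colSums(tree$edge.length * on_subtree)
    vals[nret < 2] <- NA_real_
    values[b] <- vals
  }
  names(values) <- m$cells
  grid_map(values, name = paste0("pd_", lineage),
           meta = list(filter = list(include_hybrids = FALSE, lineage = lineage),
                       keep_root_path = keep_root_path,
                       n_tips_used = stats::setNames(as.integer(n_used), m$cells),
                       n_tips_dropped = stats::setNames(as.integer(n_dropped_by_cell),
                                                        m$cells)))
}
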