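# Neighbor-joining trees, nonparametric bootstrap with majority-rule
# condensation, and mean-path-length ultrametric smoothing.

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration (via ape's NJ). Negative branch-length
#' estimates are clamped to zero with the deficit transferred to the sister
#' edge, so downstream methods always see non-negative lengths. The returned
#' tree is midpoint-rooted for display and for ultrametric smoothing; no
#' outgroup is assumed.
#'
#' @param dm A `genetic_dist` (or plain symmetric) matrix with >= 3 taxa and
#'   no undefined entries.
#' @return A rooted `phylo` object.
#' @export
nj_tree <- function(dm) {
  d <- unclass(dm)
  if (nrow(d) < 3L) stop("input error: NJ needs >= 3 taxa")
  if (anyNA(d)) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    pairs <- apply(bad, 1L, function(ij) {
      paste(rownames(d)[ij[1]], colnames(d)[ij[2]], sep = "/")
    })
    stop("input error: undefined distances for pairs ",
         paste(utils::head(pairs, 5L), collapse = ", "),
         if (length(pairs) > 5L) " ..." else "",
         "; prune these samples before tree building")
  }
  tr <- ape::nj(stats::as.dist(d))
  tr <- .clamp_negative_edges(tr)
  phangorn::midpoint(tr)
}

# Zero out negative NJ edge estimates, moving the deficit onto the sister
# edge so tip-to-tip path lengths are approximately preserved.
.clamp_negative_edges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    i <- neg[1]
    par <- tree$edge[i, 1L]
    sib <- which(tree$edge[, 1L] == par)
    sib <- sib[sib != i]
    tree$edge.length[sib] <- tree$edge.length[sib] + tree$edge.length[i]
    tree$edge.length[i] <- 0
    tree$edge.length[tree$edge.length < 0 & abs(tree$edge.length) < 1e-12] <- 0
    if (all(tree$edge.length[sib] >= 0)) next
    # residual negativity: clamp outright (degenerate matrices only)
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and scores each internal bipartition of the full-data tree by
#' the percentage of replicates containing it. Deterministic under a fixed
#' seed.
#'
#' @param aln A `labeled_alignment`.
#' @param model Distance model passed to [distance_matrix()].
#' @param n_reps Number of bootstrap replicates (study default 1000).
#' @param seed Integer RNG seed.
#' @return An unrooted NJ `phylo` whose `node.label` holds bootstrap support
#'   percentages (root label `NA`).
#' @export
bootstrap_support <- function(aln, model = "k2p", n_reps = 1000L,
                              seed = 1L) {
  if (n_reps < 1L) stop("input error: n_reps must be >= 1")
  ref_dm <- suppressWarnings(distance_matrix(aln, model))
  ref <- ape::nj(stats::as.dist(unclass(ref_dm)))
  ref <- .clamp_negative_edges(ref)
  L <- aln$length
  set.seed(seed)
  boots <- vector("list", n_reps)
  kept <- 0L
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    sub <- aln
    sub$seq <- aln$seq[, cols, drop = FALSE]
    d <- suppressWarnings(distance_matrix(sub, model))
    if (anyNA(unclass(d))) next  # saturated replicate: drop it
    kept <- kept + 1L
    boots[[kept]] <- .clamp_negative_edges(ape::nj(stats::as.dist(unclass(d))))
  }
  if (kept == 0L) stop("input error: all bootstrap replicates undefined")
  boots <- boots[seq_len(kept)]
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  sup <- round(100 * counts / kept, 2)
  sup[1L] <- NA_real_  # root pseudo-bipartition
  ref$node.label <- sup
  attr(ref, "n_replicates") <- kept
  ref
}

#' Condense a tree below a support cutoff
#'
#' Collapses every internal edge whose child-node support is below `cutoff`
#' percent into a polytomy (the majority-rule "condensed tree" display).
#'
#' @param tree A `phylo` with numeric `node.label` support values.
#' @param cutoff Support percentage below which edges collapse (default 50).
#' @return A possibly multifurcating `phylo`; the leaf set is unchanged.
#' @export
condense_tree <- function(tree, cutoff = 50) {
  if (is.null(tree$node.label)) {
    stop("input error: tree has no support values")
  }
  repeat {
    ntip <- length(tree$tip.label)
    sup <- suppressWarnings(as.numeric(tree$node.label))
    child <- tree$edge[, 2L]
    ii <- which(child > ntip)
    sup_child <- sup[child[ii] - ntip]
    bad <- ii[!is.na(sup_child) & sup_child < cutoff]
    if (length(bad) == 0L) break
    i <- bad[1L]
    gone <- tree$edge[i, 2L]
    par <- tree$edge[i, 1L]
    tree$edge[tree$edge[, 1L] == gone, 1L] <- par
    keep <- seq_len(nrow(tree$edge)) != i
    tree$edge <- tree$edge[keep, , drop = FALSE]
    tree$edge.length <- tree$edge.length[keep]
    tree$edge[tree$edge > gone] <- tree$edge[tree$edge > gone] - 1L
    tree$node.label <- tree$node.label[-(gone - ntip)]
    tree$Nnode <- tree$Nnode - 1L
  }
  tree
}

# Heights above the tips for every node of a rooted tree, assuming the tips
# are contemporaneous (ultrametric input).
.node_heights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(length(tree$tip.label))]) - depth
}

#' Mean-path-length ultrametric smoothing
#'
#' Assigns every internal node the mean path length to its descendant tips,
#' then raises any parent sitting at or below a child so that all branches
#' keep strictly positive length (`epsilon` floor). All root-to-leaf paths
#' in the result are equal, as required by GMYC-style single-threshold
#' models; an already-ultrametric tree is returned unchanged (within 1e-9).
#'
#' @param tree A rooted or unrooted binary `phylo` with branch lengths;
#'   unrooted input is midpoint-rooted first.
#' @param epsilon Minimum internal branch length (default 1e-8).
#' @return An ultrametric rooted `phylo` with attribute `ultrametric = TRUE`.
#' @export
ultrametricize <- function(tree, epsilon = 1e-8) {
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  sumd <- numeric(nnode)   # summed path length to descendant tips
  ntips_below <- integer(nnode)
  ntips_below[seq_len(ntip)] <- 1L
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    len <- tree$edge.length[i]
    sumd[par] <- sumd[par] + sumd[ch] + ntips_below[ch] * len
    ntips_below[par] <- ntips_below[par] + ntips_below[ch]
  }
  h <- numeric(nnode)
  internal <- (ntip + 1L):nnode
  h[internal] <- sumd[internal] / ntips_below[internal]
  # enforce strictly decreasing heights root -> tips (postorder = children
  # before parents, so one sweep suffices)
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    h[par] <- max(h[par], h[ch] + epsilon)
  }
  tree$edge.length <- h[tree$edge[, 1L]] - h[tree$edge[, 2L]]
  attr(tree, "ultrametric") <- TRUE
  tree
}

#' Is a rooted tree ultrametric?
#' @param tree A rooted `phylo`.
#' @param tol Allowed spread of root-to-tip path lengths.
#' @return Logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)
  tips <- depth[seq_len(length(tree$tip.label))]
  diff(range(tips)) <= tol
}
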