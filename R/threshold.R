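# Distance-threshold clustering (single linkage), the classical 2% barcode
# threshold rule, plus a tree-guided variant.

#' Single-linkage threshold clustering
#'
#' Connected components of the graph joining samples whose pairwise distance
#' is strictly below `threshold`. Undefined distances are treated as at or
#' above the threshold (no edge) and reported via a message.
#'
#' @param dm A `genetic_dist` matrix.
#' @param threshold Distance threshold as a proportion; the aphid barcoding
#'   convention is 0.02.
#' @return A `partition` with groups labeled `C1`, `C2`, ... in order of
#'   first appearance.
#' @export
threshold_cluster <- function(dm, threshold = 0.02) {
  if (!(threshold > 0 && threshold < 1)) {
    stop("input error: threshold must be in (0, 1)")
  }
  d <- unclass(dm)
  if (anyNA(d)) {
    message(sum(is.na(d[upper.tri(d)])),
            " undefined distance(s) treated as >= threshold")
  }
  adj <- !is.na(d) & d < threshold
  comp <- .components(adj)
  partition(stats::setNames(paste0("C", comp), rownames(d)))
}

# Connected components of a logical adjacency matrix; labels numbered by
# first-seen row order.
.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Tree-guided threshold clustering
#'
#' Maximal clades of a rooted tree whose internal pairwise distances are all
#' below `threshold`; leaves not absorbed into such a clade become
#' singletons. Coincides with [threshold_cluster()] whenever the data show a
#' clean barcode gap.
#'
#' @param tree A rooted `phylo` whose tips are the samples of `dm`.
#' @inheritParams threshold_cluster
#' @return A `partition`.
#' @export
threshold_cluster_tree <- function(tree, dm, threshold = 0.02) {
  d <- unclass(dm)
  ntip <- length(tree$tip.label)
  clusters <- list()
  assigned <- character(0)
  # preorder over internal nodes: largest clades first
  tree <- stats::reorder(tree, "cladewise")
  subtrees <- ape::prop.part(tree)
  tipsets <- lapply(subtrees, function(ix) tree$tip.label[ix])
  ord <- order(-lengths(tipsets))
  for (ts in tipsets[ord]) {
    if (any(ts %in% assigned)) next
    v <- d[ts, ts][upper.tri(d[ts, ts])]
    if (length(v) == 0L || all(v[!is.na(v)] < threshold)) {
      clusters <- c(clusters, list(ts))
      assigned <- c(assigned, ts)
    }
  }
  left <- setdiff(tree$tip.label, assigned)
  clusters <- c(clusters, as.list(left))
  names(clusters) <- paste0("C", seq_along(clusters))
  partition(clusters)
}
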