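# Poisson Tree Processes delimitation: branch lengths are modeled as
# exponential with one rate for speciation-level branches and one for
# within-species (coalescent-level) branches; a configuration is a set of
# "crown" nodes whose subtrees are within-species.

# Per-tree lookup tables so likelihood evaluations are O(n) vector ops:
# children of each node, descendants of each node (excluding itself), and
# descendant tip labels.
.ptp_tables <- function(tree, min_branch = 1e-4) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  kids <- split(tree$edge[, 2L], factor(tree$edge[, 1L], levels = 1:nnode))
  desc <- vector("list", nnode)
  tree <- stats::reorder(tree, "postorder")
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    desc[[p]] <- c(desc[[p]], ch, desc[[ch]])
  }
  parent <- integer(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  list(tree = tree, ntip = ntip, nnode = nnode, kids = kids, desc = desc,
       parent = parent, edge_parent = tree$edge[, 1L],
       edge_len = tree$edge.length,
       informative = tree$edge.length >= min_branch)
}

# Log likelihood of a crown configuration. Coalescent-class edges are those
# whose parent is a crown node or a descendant of one; every other edge is
# speciation-class. Each non-empty class contributes its exponential ML
# likelihood n log(n/S) - n. Edges shorter than the minimum branch length
# (tb$minbr) are excluded: effectively zero-length branches carry no
# information and would otherwise make an all-zero class degenerate.
.ptp_loglik <- function(tb, crown, eps = 1e-9) {
  mark <- logical(tb$nnode)
  mark[crown] <- TRUE
  mark[unlist(tb$desc[crown], use.names = FALSE)] <- TRUE
  coal <- mark[tb$edge_parent] & tb$informative
  spec <- !mark[tb$edge_parent] & tb$informative
  ll <- 0
  for (idx in list(coal, spec)) {
    n <- sum(idx)
    if (n == 0L) next
    s <- sum(tb$edge_len[idx]) + eps
    ll <- ll + n * log(n / s) - n
  }
  ll
}

# Neighbor configurations: split one internal crown node into its children,
# or merge a complete sibling set of crown nodes into their parent.
.ptp_neighbors <- function(tb, crown) {
  out <- list()
  for (i in seq_along(crown)) {
    nd <- crown[i]
    if (nd > tb$ntip) {
      out <- c(out, list(sort(c(crown[-i], tb$kids[[nd]]))))
    }
  }
  pars <- unique(tb$parent[crown])
  pars <- pars[pars != 0L]
  for (p in pars) {
    if (all(tb$kids[[p]] %in% crown)) {
      out <- c(out, list(sort(c(setdiff(crown, tb$kids[[p]]), p))))
    }
  }
  out
}

.ptp_random_crown <- function(tb, p_split = 0.5) {
  crown <- integer(0)
  stack <- tb$ntip + 1L  # root
  while (length(stack) > 0L) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    if (nd <= tb$ntip || stats::runif(1) > p_split) {
      crown <- c(crown, nd)
    } else {
      stack <- c(stack, tb$kids[[nd]])
    }
  }
  sort(crown)
}

#' Poisson Tree Processes fit
#'
#' Maximum-likelihood PTP delimitation on a rooted tree with branch lengths
#' in expected substitutions. Branches are split into a speciation class
#' (forming a rooted connected subgraph containing the root) and a
#' within-species class (the subtrees hanging below "crown" nodes); each
#' class's lengths are modeled as exponential with its own rate, estimated
#' as the reciprocal class mean. The crown set is optimized by greedy
#' hill-climbing over split/merge moves from two deterministic starts
#' (all-singletons and the root's children) plus seeded random restarts.
#' Branches shorter than `min_branch` (e.g. between identical haplotypes)
#' are uninformative and excluded from the likelihood; residual zero-length
#' sums are guarded by a 1e-9 offset.
#'
#' @param tree A rooted `phylo` with branch lengths and >= 3 leaves;
#'   unrooted input is midpoint-rooted.
#' @param seed Integer seed controlling the restarts.
#' @param n_restarts Number of random restarts (default 10).
#' @param min_branch Minimum informative branch length (default 1e-4,
#'   below one substitution on a barcode-length fragment).
#' @return List with `fit` (class `ptp_fit`: `lambda_sp`, `lambda_coal`,
#'   `logL`, `n_entities`) and `partition` (leaf sets of the crown
#'   subtrees).
#' @export
ptp_fit <- function(tree, seed = 1L, n_restarts = 10L, min_branch = 1e-4) {
  if (length(tree$tip.label) < 3L) stop("input error: need >= 3 leaves")
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  tb <- .ptp_tables(tree, min_branch = min_branch)
  tree <- tb$tree
  root <- tb$ntip + 1L
  set.seed(seed)
  starts <- c(list(seq_len(tb$ntip), sort(tb$kids[[root]])),
              replicate(n_restarts, .ptp_random_crown(tb),
                        simplify = FALSE))
  best <- NULL
  for (crown in starts) {
    ll <- .ptp_loglik(tb, crown)
    repeat {
      nbrs <- .ptp_neighbors(tb, crown)
      if (length(nbrs) == 0L) break
      lls <- vapply(nbrs, function(cr) .ptp_loglik(tb, cr), numeric(1))
      if (max(lls) <= ll + 1e-12) break
      crown <- nbrs[[which.max(lls)]]
      ll <- max(lls)
    }
    if (is.null(best) || ll > best$ll) best <- list(ll = ll, crown = crown)
  }
  ll_one <- .ptp_loglik(tb, root)  # one-species configuration
  if (ll_one > best$ll) best <- list(ll = ll_one, crown = root)

  mark <- logical(tb$nnode)
  mark[best$crown] <- TRUE
  mark[unlist(tb$desc[best$crown], use.names = FALSE)] <- TRUE
  coal <- mark[tb$edge_parent] & tb$informative
  spec <- !mark[tb$edge_parent] & tb$informative
  rate_of <- function(sel) {
    if (sum(sel) == 0L) NA_real_
    else sum(sel) / (sum(tb$edge_len[sel]) + 1e-9)
  }
  groups <- lapply(best$crown, function(nd) {
    if (nd <= tb$ntip) tree$tip.label[nd]
    else tree$tip.label[tb$desc[[nd]][tb$desc[[nd]] <= tb$ntip]]
  })
  names(groups) <- paste0("G", seq_along(groups))
  part <- partition(groups)
  fit <- structure(list(lambda_sp = rate_of(spec),
                        lambda_coal = rate_of(coal),
                        logL = best$ll, n_entities = n_groups(part)),
                   class = "ptp_fit")
  list(fit = fit, partition = part)
}

#' @export
print.ptp_fit <- function(x, ...) {
  cat("PTP maximum-likelihood fit\n")
  cat(sprintf("  entities: %d  logL: %.4f\n", x$n_entities, x$logL))
  cat(sprintf("  speciation rate: %.4g  coalescent rate: %.4g\n",
              x$lambda_sp, x$lambda_coal))
  invisible(x)
}
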