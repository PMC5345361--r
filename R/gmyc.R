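# Single-threshold General Mixed Yule Coalescent model: likelihood over
# inter-event intervals of an ultrametric tree, with a Yule branching term
# above the threshold and per-cluster coalescent terms below it.

# Interval decomposition of an ultrametric rooted tree for one candidate
# threshold T. Events are internal-node heights in descending order; at any
# instant the total branching rate is
#   lambda1 * k^p1 + sum_j lambda2 * (m_j (m_j - 1))^p2
# with k the number of species-level lineages (grows with each speciation
# event above T, then stays at the number of threshold-crossing branches)
# and m_j the lineage count inside cluster j (grows with each coalescent
# event below T). Returns per-interval durations and the (k, sum_j term)
# bookkeeping needed to evaluate the likelihood for any parameter vector.
.gmyc_intervals <- function(tree, T_thr) {
  ntip <- length(tree$tip.label)
  h <- .node_heights(tree)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  root <- nodes[!(nodes %in% tree$edge[, 2L])]
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]

  # cluster id per node: nearest ancestor (or self) whose parent edge
  # crosses T; nodes above T get 0
  crossing <- which(h[tree$edge[, 2L]] <= T_thr & h[tree$edge[, 1L]] > T_thr)
  cluster_root <- tree$edge[crossing, 2L]
  k_star <- length(cluster_root)
  cl <- integer(ntip + tree$Nnode)
  cl[cluster_root] <- seq_len(k_star)
  ord <- order(h[tree$edge[, 2L]], decreasing = TRUE)  # parents first
  for (i in ord) {
    ch <- tree$edge[i, 2L]
    if (cl[ch] == 0L && h[ch] <= T_thr) cl[ch] <- cl[tree$edge[i, 1L]]
  }

  ev_nodes <- nodes[order(h[nodes], decreasing = TRUE)]
  ev_h <- h[ev_nodes]
  # state just below the root event
  k <- if (h[root] > T_thr) 2L else k_star
  m <- rep(1L, k_star)
  n_ev <- length(ev_nodes)
  dur <- k_vec <- coal_n <- numeric(0)
  add_interval <- function(x, kk, mm) {
    dur <<- c(dur, x)
    k_vec <<- c(k_vec, kk)
    coal_n <<- c(coal_n, list(mm))
  }
  coal_n <- list()
  prev_h <- ev_h[1L]
  if (n_ev >= 2L) {
    for (i in 2L:n_ev) {
      add_interval(prev_h - ev_h[i], k, m[m > 1L])
      nd <- ev_nodes[i]
      if (h[nd] > T_thr) k <- k + 1L else {
        j <- cl[nd]
        m[j] <- m[j] + 1L
      }
      prev_h <- ev_h[i]
    }
  }
  list(event_dur = dur, event_k = k_vec, event_m = coal_n,
       final_dur = prev_h, final_k = k, final_m = m[m > 1L],
       n_entities = k_star)
}

.gmyc_loglik <- function(par, iv) {
  l1 <- exp(par[1L]); p1 <- par[2L]; l2 <- exp(par[3L]); p2 <- par[4L]
  rate <- function(k, m) {
    r <- l1 * k^p1
    if (length(m) > 0L) r <- r + l2 * sum((m * (m - 1))^p2)
    r
  }
  ll <- 0
  for (i in seq_along(iv$event_dur)) {
    r <- rate(iv$event_k[i], iv$event_m[[i]])
    if (!is.finite(r) || r <= 0) return(-Inf)
    ll <- ll + log(r) - r * iv$event_dur[i]
  }
  rf <- rate(iv$final_k, iv$final_m)
  if (!is.finite(rf) || rf <= 0) return(-Inf)
  ll - rf * iv$final_dur
}

.gmyc_null_loglik <- function(par, dur, m_counts, final_dur, final_m) {
  l2 <- exp(par[1L]); p2 <- par[2L]
  ll <- 0
  for (i in seq_along(dur)) {
    r <- l2 * (m_counts[i] * (m_counts[i] - 1))^p2
    if (!is.finite(r) || r <= 0) return(-Inf)
    ll <- ll + log(r) - r * dur[i]
  }
  ll - l2 * (final_m * (final_m - 1))^p2 * final_dur
}

#' Single-threshold GMYC fit
#'
#' Fits the mixed Yule/coalescent model on an ultrametric binary tree: for
#' every candidate threshold (midpoints between consecutive internal-node
#' heights) the four parameters (Yule rate and exponent, coalescent rate and
#' exponent) are optimized numerically, and the threshold maximizing the log
#' likelihood is selected. The null model is a single coalescent population
#' spanning the whole tree; the likelihood-ratio statistic is referred to a
#' chi-square with 3 degrees of freedom. When the test is not significant
#' (p >= `alpha`) the single-group partition is returned.
#'
#' @param tree An ultrametric, binary, rooted `phylo` with >= 3 leaves.
#' @param alpha Significance level gating the delimitation (default 0.05).
#' @return List with `fit` (class `gmyc_fit`: `lambda1`, `p1`, `lambda2`,
#'   `p2`, `T`, `logL`, `logL_null`, `LR`, `p_value`, `df`, `n_entities`)
#'   and `partition` (a `partition` of the leaves).
#' @export
gmyc_fit <- function(tree, alpha = 0.05) {
  if (length(tree$tip.label) < 3L) stop("input error: need >= 3 leaves")
  if (!ape::is.rooted(tree) || !ape::is.binary(tree)) {
    stop("input error: GMYC needs a rooted binary tree")
  }
  if (!is_ultrametric(tree)) {
    stop("input error: GMYC needs an ultrametric tree; see ultrametricize()")
  }
  ntip <- length(tree$tip.label)
  h <- .node_heights(tree)
  nh <- sort(unique(h[(ntip + 1L):(ntip + tree$Nnode)]), decreasing = TRUE)
  # candidate thresholds: between consecutive event heights, and below the
  # shallowest event (all tips singletons)
  cand <- c((nh[-length(nh)] + nh[-1L]) / 2, nh[length(nh)] / 2)

  # null model: one coalescent population
  ev_h <- sort(h[(ntip + 1L):(ntip + tree$Nnode)], decreasing = TRUE)
  m_counts <- seq(2L, length.out = length(ev_h) - 1L)
  dur0 <- -diff(ev_h)
  init_rate <- (ntip - 1L) / sum(c(dur0, ev_h[length(ev_h)]) *
                                   c(m_counts, ntip) *
                                   (c(m_counts, ntip) - 1L))
  opt0 <- stats::optim(c(log(max(init_rate, 1e-8)), 1),
                       function(p) -.gmyc_null_loglik(p, dur0, m_counts,
                                                     ev_h[length(ev_h)],
                                                     ntip),
                       method = "Nelder-Mead",
                       control = list(maxit = 500))
  logL_null <- -opt0$value

  best <- NULL
  for (T_thr in cand) {
    iv <- .gmyc_intervals(tree, T_thr)
    if (iv$n_entities < 2L || iv$n_entities >= ntip + 1L) next
    init <- c(log(max(iv$n_entities / max(h), 1e-6)), 1,
              opt0$par[1L], opt0$par[2L])
    opt <- stats::optim(init, function(p) -.gmyc_loglik(p, iv),
                        method = "Nelder-Mead",
                        control = list(maxit = 800))
    if (is.null(best) || -opt$value > best$logL) {
      best <- list(logL = -opt$value, par = opt$par, T = T_thr, iv = iv)
    }
  }
  if (is.null(best)) {  # degenerate tiny tree: everything is one cluster
    best <- list(logL = logL_null, par = c(opt0$par[1L], 1, opt0$par),
                 T = max(h), iv = NULL)
  }
  LR <- max(0, 2 * (best$logL - logL_null))
  df <- 3L
  p_value <- stats::pchisq(LR, df = df, lower.tail = FALSE)

  if (!is.null(best$iv) && p_value < alpha) {
    part <- .threshold_partition(tree, best$T)
  } else {
    part <- partition(stats::setNames(rep("G1", ntip), tree$tip.label))
  }
  fit <- structure(list(lambda1 = exp(best$par[1L]), p1 = best$par[2L],
                        lambda2 = exp(best$par[3L]), p2 = best$par[4L],
                        T = best$T, logL = best$logL,
                        logL_null = logL_null, LR = LR, p_value = p_value,
                        df = df, n_entities = n_groups(part)),
                   class = "gmyc_fit")
  list(fit = fit, partition = part)
}

# Leaf partition induced by the branches crossing height T.
.threshold_partition <- function(tree, T_thr) {
  ntip <- length(tree$tip.label)
  h <- .node_heights(tree)
  crossing <- which(h[tree$edge[, 2L]] <= T_thr & h[tree$edge[, 1L]] > T_thr)
  roots <- tree$edge[crossing, 2L]
  groups <- lapply(roots, function(nd) {
    if (nd <= ntip) tree$tip.label[nd]
    else ape::extract.clade(tree, nd)$tip.label
  })
  names(groups) <- paste0("G", seq_along(groups))
  partition(groups)
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat("GMYC single-threshold fit\n")
  cat(sprintf("  entities: %d  threshold height: %.6g\n", x$n_entities, x$T))
  cat(sprintf("  logL: %.4f  null logL: %.4f  LR: %.4f (df=%d, p=%.4g)\n",
              x$logL, x$logL_null, x$LR, x$df, x$p_value))
  invisible(x)
}

#' Expand a haplotype partition back to all samples
#'
#' Maps a partition of haplotype representatives onto the full sample set
#' using the membership mapping from [collapse_haplotypes()].
#'
#' @param p A `partition` of haplotype representative ids.
#' @param members Named list: representative id -> member sample ids.
#' @return A `partition` over all member samples.
#' @export
expand_partition <- function(p, members) {
  ids <- unlist(members[names(p)], use.names = FALSE)
  lab <- rep(unclass(p), lengths(members[names(p)]))
  partition(stats::setNames(lab, ids))
}
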