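# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized code paths: distances by a per-site loop, cluster
# classification by direct set comparison, clustering by exhaustive
# component search.

# Per-site tally + closed-form transforms for one pair of sequences.
oracle_pair_distance <- function(s1, s2, model = c("p", "jc69", "k2p")) {
  model <- match.arg(model)
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- 0L; ts <- 0L; tv <- 0L
  pur <- c("A", "G")
  for (i in seq_along(a)) {
    x <- a[i]; y <- b[i]
    if (!(x %in% c("A", "C", "G", "T")) || !(y %in% c("A", "C", "G", "T"))) {
      next
    }
    n <- n + 1L
    if (x != y) {
      if ((x %in% pur) == (y %in% pur)) ts <- ts + 1L else tv <- tv + 1L
    }
  }
  if (n == 0L) return(NA_real_)
  p <- (ts + tv) / n
  if (model == "p") return(p)
  if (model == "jc69") {
    if (p >= 0.75) return(NA_real_)
    return(-3 / 4 * log(1 - 4 * p / 3))
  }
  P <- ts / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# Random aligned sequence pair with controllable divergence and gaps.
random_pair <- function(len = 658, p_sub = 0.05, p_gap = 0.02) {
  bases <- c("A", "C", "G", "T")
  s1 <- sample(bases, len, replace = TRUE)
  s2 <- s1
  mut <- runif(len) < p_sub
  s2[mut] <- sample(bases, sum(mut), replace = TRUE)
  g <- runif(len) < p_gap
  s1[g & runif(len) < 0.5] <- "-"
  g2 <- runif(len) < p_gap
  s2[g2] <- sample(c("-", "N"), sum(g2), replace = TRUE)
  c(paste(s1, collapse = ""), paste(s2, collapse = ""))
}

# Direct set-relation classification of a cluster against truth groups.
oracle_classify <- function(cluster, truth) {
  groups <- split(names(truth), unclass(truth))
  contains <- vapply(groups, function(g) any(cluster %in% g), logical(1))
  touched <- groups[contains]
  if (length(touched) == 1L) {
    g <- touched[[1]]
    if (setequal(cluster, g)) "accurate" else "split"
  } else {
    complete <- vapply(touched, function(g) all(g %in% cluster), logical(1))
    if (all(complete)) "lumped" else "partial_lumped"
  }
}

# Random partition of a sample universe into at most k groups.
random_partition <- function(ids, k) {
  partition(stats::setNames(paste0("g", sample.int(k, length(ids),
                                                   replace = TRUE)), ids))
}

# Exhaustive single-linkage components (edge iff d < thr), O(n^3) closure.
oracle_components <- function(d, thr) {
  n <- nrow(d)
  adj <- !is.na(d) & d < thr
  diag(adj) <- TRUE
  reach <- adj
  for (k in seq_len(n)) {
    reach <- reach | (reach %*% reach > 0)
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[reach[i, ]] <- cur
    }
  }
  comp
}

# Tiny labeled alignment straight from strings.
aln_from <- function(seqs, species = NULL, genus = "g", ids = NULL) {
  n <- length(seqs)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  if (is.null(species)) species <- rep("sp", n)
  labeled_alignment(seqs, data.frame(sample_id = ids, species = species,
                                     genus = genus,
                                     stringsAsFactors = FALSE))
}

# Planted two-class tree for PTP-style checks: nsp species subtrees with
# short internal branches grafted onto a species-level backbone with long
# branches.
planted_tree <- function(nsp = 10, k = 4, mean_in = 0.002, mean_out = 0.05) {
  spt <- ape::rtree(nsp, tip.label = paste0("T", seq_len(nsp)),
                    br = function(n) rexp(n, 1 / mean_out))
  for (i in seq_len(nsp)) {
    sub <- ape::rtree(k, tip.label = paste0("sp", i, "_s", seq_len(k)),
                      br = function(n) rexp(n, 1 / mean_in))
    spt <- ape::bind.tree(spt, sub,
                          where = which(spt$tip.label == paste0("T", i)))
  }
  spt
}
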