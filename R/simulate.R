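# Benchmark simulator: Yule species tree, multispecies-coalescent gene
# tree, K2P sequence evolution, asymmetric sampling and optional missing
# data, with a calibrated default profile.

#' Simulation configuration
#'
#' @param n_species Number of species (>= 1).
#' @param samples_per_species Scalar, or per-species integer vector.
#' @param birth_rate Yule speciation rate (events per lineage per unit
#'   time).
#' @param coalescent_Ne_scale Within-species coalescent time scale: a pair
#'   of lineages coalesces at rate 1/`coalescent_Ne_scale`.
#' @param seq_length Alignment length in bp (default 658, the standard
#'   animal barcode fragment).
#' @param kappa Transition/transversion rate ratio of the two-parameter
#'   substitution process.
#' @param mutation_scale Expected substitutions per site per unit tree time.
#' @param missing_fraction Probability that a base is masked to `N`.
#' @param stem_depth Constant added to every species-tree node height
#'   (units of tree time): a floor on species divergence emulating deep
#'   species stems. 0 gives a pure Yule tree.
#' @param seed Integer seed; per-stage streams are derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 10L, samples_per_species = 5L,
                       birth_rate = 16, coalescent_Ne_scale = 0.0015,
                       seq_length = 658L, kappa = 4, mutation_scale = 1,
                       missing_fraction = 0, stem_depth = 0.025,
                       seed = 1L) {
  if (n_species < 1L) stop("input error: n_species must be >= 1")
  if (seq_length < 1L) stop("input error: seq_length must be >= 1")
  if (kappa <= 0) stop("input error: kappa must be > 0")
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("input error: missing_fraction must be in [0, 1)")
  }
  if (length(samples_per_species) == 1L) {
    samples_per_species <- rep(as.integer(samples_per_species), n_species)
  }
  if (length(samples_per_species) != n_species) {
    stop("input error: samples_per_species length != n_species")
  }
  structure(list(n_species = as.integer(n_species),
                 samples_per_species = as.integer(samples_per_species),
                 birth_rate = birth_rate,
                 coalescent_Ne_scale = coalescent_Ne_scale,
                 seq_length = as.integer(seq_length), kappa = kappa,
                 mutation_scale = mutation_scale,
                 missing_fraction = missing_fraction,
                 stem_depth = stem_depth, seed = as.integer(seed)),
            class = "sim_config")
}

#' Calibrated simulation profiles
#'
#' `"chaitophorus-like"` reproduces the divergence structure typical of
#' densely sampled aphid barcode studies: 10 species with 5 samples each,
#' 658 bp, within-species K2P divergence around 0.001-0.02 and smallest
#' interspecific divergence around 0.06-0.14.
#'
#' @param name Profile name.
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_profile <- function(name = "chaitophorus-like", seed = 1L, ...) {
  name <- match.arg(name, "chaitophorus-like")
  args <- utils::modifyList(
    list(n_species = 10L, samples_per_species = 5L, birth_rate = 16,
         coalescent_Ne_scale = 0.0015, seq_length = 658L, kappa = 4,
         mutation_scale = 1, missing_fraction = 0, stem_depth = 0.025,
         seed = seed),
    list(...))
  do.call(sim_config, args)
}

# Derived per-stage seed stream: Lehmer step on the user seed, keeping the
# value inside 32-bit integer range.
.stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 7919) %% 2147483647)
}

#' Simulate a Yule species tree
#'
#' Backward construction: with k extant lineages the waiting time to the
#' next (most recent remaining) split is exponential with rate
#' `birth_rate * k`, and the joining pair is uniform -- giving the Yule
#' node-height law with mean root height `sum_{k=2..n} 1/(k b)`. A positive
#' `stem_depth` is added to every node height afterwards.
#'
#' @param cfg A `sim_config`.
#' @return An ultrametric `phylo` with tips `sp1..spN`.
#' @export
simulate_species_tree <- function(cfg) {
  set.seed(.stage_seed(cfg$seed, 1L))
  n <- cfg$n_species
  if (n == 1L) return(ape::read.tree(text = "(sp1:0);"))
  nwk <- paste0("sp", seq_len(n))
  hts <- numeric(n)
  h <- cfg$stem_depth
  for (k in seq(n, 2L)) {
    h <- h + stats::rexp(1L, rate = cfg$birth_rate * k)
    pick <- sample.int(length(nwk), 2L)
    merged <- sprintf("(%s:%.12f,%s:%.12f)", nwk[pick[1L]],
                      h - hts[pick[1L]], nwk[pick[2L]], h - hts[pick[2L]])
    nwk <- c(nwk[-pick], merged)
    hts <- c(hts[-pick], h)
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

#' Simulate a gene tree under the multispecies coalescent
#'
#' Within each species-tree branch, the lineages present coalesce at rate
#' `choose(k,2) / coalescent_Ne_scale`; survivors enter the ancestral
#' species' pool, and remaining lineages coalesce freely above the root.
#' Tips are labeled `spX_sY`; the species of every tip is attached as the
#' `species` attribute.
#'
#' @param species_tree Ultrametric `phylo` from [simulate_species_tree()].
#' @param cfg A `sim_config`.
#' @return An ultrametric binary `phylo` with attribute `species` (named
#'   character vector tip id -> species).
#' @export
simulate_gene_tree <- function(species_tree, cfg) {
  set.seed(.stage_seed(cfg$seed, 2L))
  Ne <- cfg$coalescent_Ne_scale
  n_sp <- cfg$n_species
  counts <- cfg$samples_per_species

  # pool entries: newick fragment + its height
  new_pool <- function(sp_name, k) {
    ids <- paste0(sp_name, "_s", seq_len(k))
    list(nwk = ids, h = numeric(k))
  }
  coalesce_in <- function(pool, h_start, h_end) {
    t <- h_start
    while (length(pool$nwk) >= 2L) {
      k <- length(pool$nwk)
      t <- t + stats::rexp(1L, rate = choose(k, 2L) / Ne)
      if (t >= h_end) break
      pick <- sample.int(k, 2L)
      merged <- sprintf("(%s:%.12f,%s:%.12f)", pool$nwk[pick[1L]],
                        t - pool$h[pick[1L]], pool$nwk[pick[2L]],
                        t - pool$h[pick[2L]])
      pool$nwk <- c(pool$nwk[-pick], merged)
      pool$h <- c(pool$h[-pick], t)
    }
    pool
  }

  if (n_sp == 1L) {
    pool <- new_pool("sp1", counts[1L])
    if (counts[1L] == 1L) {
      tr <- ape::read.tree(text = paste0(pool$nwk, ":0;"))
    } else {
      pool <- coalesce_in(pool, 0, Inf)
      tr <- ape::read.tree(text = paste0(pool$nwk, ";"))
    }
    attr(tr, "species") <- stats::setNames(
      rep("sp1", counts[1L]), paste0("sp1_s", seq_len(counts[1L])))
    return(tr)
  }

  st <- stats::reorder(species_tree, "postorder")
  ntip <- length(st$tip.label)
  heights <- .node_heights(st)
  root <- ntip + 1L
  # species index per species-tree tip
  sp_idx <- match(st$tip.label, paste0("sp", seq_len(n_sp)))
  pools <- vector("list", ntip + st$Nnode)
  for (i in seq_len(ntip)) {
    pools[[i]] <- new_pool(st$tip.label[i], counts[sp_idx[i]])
  }
  # postorder edges: children resolved before parents
  for (e in seq_len(nrow(st$edge))) {
    par <- st$edge[e, 1L]; ch <- st$edge[e, 2L]
    p <- coalesce_in(pools[[ch]], heights[ch], heights[par])
    if (is.null(pools[[par]])) {
      pools[[par]] <- p
    } else {
      pools[[par]] <- list(nwk = c(pools[[par]]$nwk, p$nwk),
                           h = c(pools[[par]]$h, p$h))
    }
  }
  final <- coalesce_in(pools[[root]], heights[root], Inf)
  tr <- ape::read.tree(text = paste0(final$nwk, ";"))
  sp_of_tip <- sub("_s[0-9]+$", "", tr$tip.label)
  attr(tr, "species") <- stats::setNames(sp_of_tip, tr$tip.label)
  tr
}

#' Evolve sequences along a gene tree under the K2P process
#'
#' The root sequence is uniform over A/C/G/T; along each branch, each site
#' mutates according to the two-parameter transition matrix with
#' transition/transversion rate ratio `kappa` and total substitution rate
#' `mutation_scale` per unit time. A `missing_fraction` of bases is then
#' masked to `N` independently.
#'
#' @param gene_tree A rooted `phylo` (branch lengths in tree time) carrying
#'   a `species` tip attribute (as from [simulate_gene_tree()]).
#' @param cfg A `sim_config`.
#' @return A `labeled_alignment`; genus is `"simulated"` for all samples.
#' @export
evolve_sequences <- function(gene_tree, cfg) {
  set.seed(.stage_seed(cfg$seed, 3L))
  L <- cfg$seq_length
  mu <- cfg$mutation_scale
  beta <- mu / (cfg$kappa + 2)
  alpha <- cfg$kappa * beta
  ts_map <- c(3L, 4L, 1L, 2L)               # A<->G, C<->T
  tv_map <- matrix(c(2L, 4L,  1L, 3L,  2L, 4L,  1L, 3L), nrow = 4L,
                   byrow = TRUE)            # the two transversion targets
  sp <- attr(gene_tree, "species")
  ntip <- length(gene_tree$tip.label)
  if (ntip == 1L) {
    seqs <- matrix(c("A", "C", "G", "T")[sample.int(4L, L, replace = TRUE)],
                   nrow = 1L)
  } else {
    tr <- stats::reorder(gene_tree, "cladewise")  # parents before children
    nnode <- ntip + tr$Nnode
    seqs_i <- matrix(0L, nrow = nnode, ncol = L)
    rootn <- ntip + 1L
    seqs_i[rootn, ] <- sample.int(4L, L, replace = TRUE)
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
      t <- tr$edge.length[e]
      e1 <- exp(-4 * beta * t)
      e2 <- exp(-2 * (alpha + beta) * t)
      p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
      p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
      u <- stats::runif(L)
      s <- seqs_i[par, ]
      child <- s
      is_ts <- u >= p_same & u < p_same + p_ts
      child[is_ts] <- ts_map[s[is_ts]]
      tv1 <- u >= p_same + p_ts & u < 1 - (0.25 - 0.25 * e1)
      tv2 <- u >= 1 - (0.25 - 0.25 * e1)
      child[tv1] <- tv_map[cbind(s[tv1], 1L)]
      child[tv2] <- tv_map[cbind(s[tv2], 2L)]
      seqs_i[ch, ] <- child
    }
    seqs <- matrix(c("A", "C", "G", "T")[seqs_i[seq_len(ntip), ]],
                   nrow = ntip)
    gene_tree <- tr
  }
  if (cfg$missing_fraction > 0) {
    mask <- matrix(stats::runif(length(seqs)) < cfg$missing_fraction,
                   nrow = nrow(seqs))
    seqs[mask] <- "N"
  }
  ids <- gene_tree$tip.label
  species <- if (!is.null(sp)) unname(sp[ids]) else ids
  meta <- data.frame(sample_id = ids, species = species,
                     genus = "simulated", stringsAsFactors = FALSE)
  rownames(seqs) <- ids
  labeled_alignment(seqs, meta, gene = "sim")
}

#' Generate a full benchmark bundle
#'
#' Composes the species-tree, gene-tree and sequence simulators and records
#' the realized divergence statistics (average intraspecific and smallest
#' interspecific K2P distance) so calibration can be checked.
#'
#' @param cfg A `sim_config` (e.g. from [sim_profile()]).
#' @return List of class `benchmark_bundle`: `alignment`, `gene_tree`,
#'   `species_tree`, `truth` (a `partition`), `config`, and `realized`
#'   (named numeric: `avg_intraspecific`, `smallest_interspecific`).
#' @export
make_benchmark <- function(cfg = sim_profile()) {
  st <- simulate_species_tree(cfg)
  gt <- simulate_gene_tree(st, cfg)
  aln <- evolve_sequences(gt, cfg)
  truth <- partition(stats::setNames(aln$meta$species, aln$meta$sample_id))
  realized <- c(avg_intraspecific = NA_real_,
                smallest_interspecific = NA_real_)
  if (n_samples(aln) >= 2L) {
    dm <- suppressWarnings(distance_matrix(aln, "k2p"))
    fm <- five_metrics(dm, truth)
    realized <- c(avg_intraspecific = fm$avg_intraspecific_mean[1L],
                  smallest_interspecific = fm$smallest_interspecific_mean[1L])
  }
  structure(list(alignment = aln, gene_tree = gt, species_tree = st,
                 truth = truth, config = cfg, realized = realized),
            class = "benchmark_bundle")
}

#' Write a benchmark bundle to plain-text files
#'
#' FASTA + metadata TSV + gene/species newick + truth-partition TSV.
#'
#' @param bundle A `benchmark_bundle`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_benchmark <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(bundle$alignment, file.path(dir, "alignment.fasta"),
                  file.path(dir, "metadata.tsv"))
  write_newick(bundle$gene_tree, file.path(dir, "gene_tree.nwk"))
  write_newick(bundle$species_tree, file.path(dir, "species_tree.nwk"))
  write_partition(bundle$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
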