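test_that("simulators are bit-deterministic under a fixed seed and match
           the sampling configuration", {
  cfg <- sim_profile(seed = 17)
  b1 <- make_benchmark(cfg)
  b2 <- make_benchmark(cfg)
  expect_identical(b1$alignment$seq, b2$alignment$seq)
  expect_identical(ape::write.tree(b1$gene_tree),
                   ape::write.tree(b2$gene_tree))
  expect_equal(n_samples(b1$alignment), sum(cfg$samples_per_species))
  expect_equal(n_groups(b1$truth), cfg$n_species)

  # asymmetric sampling passes straight through
  cfg2 <- sim_config(n_species = 3, samples_per_species = c(20, 2, 2),
                     seed = 2)
  b3 <- make_benchmark(cfg2)
  expect_equal(sort(unname(table(unclass(b3$truth)))), c(2, 2, 20),
               ignore_attr = TRUE)
})

test_that("species-tree heights follow the Yule expectation", {
  b <- 1
  hts <- vapply(1:400, function(s) {
    tr <- simulate_species_tree(sim_config(n_species = 10, birth_rate = b,
                                           stem_depth = 0, seed = s))
    max(ape::node.depth.edgelength(tr))
  }, numeric(1))
  expect_equal(mean(hts), sum(1 / (2:10 * b)), tolerance = 0.1)
  # single species: a lone tip
  expect_equal(length(simulate_species_tree(
    sim_config(n_species = 1, seed = 1))$tip.label), 1L)
})

test_that("pairwise coalescence times average to the Ne scale and deep
           stems give species monophyly", {
  Ne <- 0.003
  tm <- vapply(1:1000, function(s) {
    cfg <- sim_config(n_species = 1, samples_per_species = 2,
                      coalescent_Ne_scale = Ne, seed = s)
    gt <- simulate_gene_tree(simulate_species_tree(cfg), cfg)
    max(ape::node.depth.edgelength(gt))
  }, numeric(1))
  expect_equal(mean(tm), Ne, tolerance = 0.05)

  # species-tree depths >= 20x Ne: gene trees species-monophyletic
  mono <- 0
  for (s in 1:50) {
    cfg <- sim_config(n_species = 4, samples_per_species = 4,
                      birth_rate = 2, stem_depth = 0.02,
                      coalescent_Ne_scale = 0.001, seed = s)
    gt <- simulate_gene_tree(simulate_species_tree(cfg), cfg)
    sp <- attr(gt, "species")
    ok <- all(vapply(unique(sp), function(x) {
      ape::is.monophyletic(gt, names(sp)[sp == x])
    }, logical(1)))
    mono <- mono + ok
  }
  expect_gte(mono, 49)
})

test_that("sequence evolution matches the substitution model", {
  # zero rate: all sequences identical to the root
  cfg0 <- sim_profile(seed = 4, mutation_scale = 0)
  b0 <- make_benchmark(cfg0)
  expect_equal(length(unique(apply(b0$alignment$seq, 1, paste,
                                   collapse = ""))), 1L)

  # K2P distance estimates are consistent for a known divergence
  t_div <- 0.05
  ds <- vapply(1:200, function(s) {
    gt <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t_div / 2,
                                        t_div / 2))
    attr(gt, "species") <- c(a = "a", b = "b")
    cfg <- sim_config(n_species = 2, samples_per_species = 1, seed = s)
    a <- evolve_sequences(gt, cfg)
    suppressWarnings(distance_matrix(a, "k2p"))[1, 2]
  }, numeric(1))
  expect_equal(mean(ds), t_div, tolerance = 0.1)

  # transition:transversion counts reflect kappa on a long branch
  gt <- ape::read.tree(text = "(a:0.15,b:0.15);")
  attr(gt, "species") <- c(a = "a", b = "b")
  cfg <- sim_config(n_species = 2, samples_per_species = 1, kappa = 4,
                    seq_length = 6580L, seed = 10)
  a <- evolve_sequences(gt, cfg)
  cts <- count_substitutions(paste(a$seq[1, ], collapse = ""),
                             paste(a$seq[2, ], collapse = ""))
  # expected observable ts:tv at this depth (substitution-saturated sites
  # fold back), from the K2P transition probabilities at t = 0.3
  beta <- 1 / (4 + 2); alpha <- 4 * beta; t <- 0.3
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * t) - 0.5 * exp(-2 * (alpha + beta) * t)
  p_tv <- 2 * (0.25 - 0.25 * exp(-4 * beta * t))
  bt <- binom.test(cts$n_transitions, cts$n_transitions + cts$n_transversions,
                   p = p_ts / (p_ts + p_tv))
  expect_gt(bt$p.value, 0.01)

  # missing-data masking hits the requested fraction
  cfgm <- sim_profile(seed = 6, missing_fraction = 0.05)
  bm <- make_benchmark(cfgm)
  frac <- mean(bm$alignment$seq == "N")
  expect_equal(frac, 0.05, tolerance = 0.15)
})

test_that("the calibrated profile lands in the study's divergence bands
           and distances track tree path lengths", {
  in_intra <- in_inter <- 0
  for (s in 1:20) {
    b <- make_benchmark(sim_profile(seed = 800 + s))
    in_intra <- in_intra +
      (b$realized["avg_intraspecific"] >= 0.001 &&
         b$realized["avg_intraspecific"] <= 0.02)
    in_inter <- in_inter +
      (b$realized["smallest_interspecific"] >= 0.06 &&
         b$realized["smallest_interspecific"] <= 0.14)
  }
  expect_gte(in_intra, 18)
  expect_gte(in_inter, 18)

  b <- make_benchmark(sim_profile(seed = 900))
  dm <- suppressWarnings(distance_matrix(b$alignment, "k2p"))
  paths <- ape::cophenetic.phylo(b$gene_tree)
  ids <- rownames(dm)
  r <- cor(unclass(dm)[upper.tri(dm)], paths[ids, ids][upper.tri(dm)])
  expect_gt(r, 0.9)

  # benchmark file output is plain text and complete
  dir <- tempfile()
  write_benchmark(b, dir)
  expect_setequal(list.files(dir),
                  c("alignment.fasta", "metadata.tsv", "gene_tree.nwk",
                    "species_tree.nwk", "truth.tsv"))
})
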