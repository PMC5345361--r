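test_that("threshold clustering is single-linkage over the strict-<
           graph", {
  ids <- c("a", "b", "c")
  d <- matrix(c(0, .015, .03, .015, 0, .015, .03, .015, 0), 3, 3,
              dimnames = list(ids, ids))
  # chain a-b, b-c below threshold joins all three despite d(a,c) = 0.03
  expect_equal(n_groups(threshold_cluster(d, 0.02)), 1L)

  # two blocks
  ids <- paste0("s", 1:6)
  d <- matrix(0.1, 6, 6, dimnames = list(ids, ids))
  d[1:3, 1:3] <- 0.005; d[4:6, 4:6] <- 0.005; diag(d) <- 0
  p <- threshold_cluster(d, 0.02)
  expect_true(partitions_equal(p, partition(list(ids[1:3], ids[4:6]))))

  # all close: one cluster; threshold monotonicity
  d2 <- matrix(0.001, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d2) <- 0
  expect_equal(n_groups(threshold_cluster(d2, 0.02)), 1L)
  set.seed(31)
  dd <- as.matrix(dist(matrix(runif(20), 10)))
  ks <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8),
               function(t) n_groups(threshold_cluster(dd, t)), integer(1))
  expect_true(all(diff(ks) <= 0))

  # agreement with the exhaustive component oracle
  for (i in 1:20) {
    n <- sample(5:10, 1)
    dmat <- as.matrix(dist(matrix(runif(n * 2), n)))
    dimnames(dmat) <- list(paste0("x", 1:n), paste0("x", 1:n))
    thr <- runif(1, 0.1, 0.6)
    got <- unclass(threshold_cluster(dmat, thr))[rownames(dmat)]
    want <- oracle_components(dmat, thr)
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(x) length(unique(x))) == 1))
  }
})

test_that("single-prior ABGD honors its window and boundary semantics", {
  # planted gap: intra <= 0.01, inter >= 0.08
  ids <- paste0("s", 1:8)
  d <- matrix(0.09, 8, 8, dimnames = list(ids, ids))
  set.seed(2)
  d[1:4, 1:4] <- 0.005; d[5:8, 5:8] <- 0.005
  d <- d + matrix(runif(64, 0, 0.004), 8)
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  diag(d) <- 0
  res <- abgd_partition(d, abgd_config(prior_p = 0.055, n_prior_steps = 1))
  expect_true(partitions_equal(res$partition,
                               partition(list(ids[1:4], ids[5:8]))))
  expect_true(res$gap_distance > 0.01 && res$gap_distance < 0.08)
  expect_gte(res$n_recursion_rounds, 1L)

  # prior exceeding every distance: window empty, one group
  res2 <- abgd_partition(d, abgd_config(prior_p = 0.5, n_prior_steps = 1))
  expect_equal(n_groups(res2$partition), 1L)

  # all identical sequences: one group, no gap
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  res3 <- abgd_partition(z, abgd_config(n_prior_steps = 1))
  expect_equal(n_groups(res3$partition), 1L)
  expect_true(is.na(res3$gap_distance))
})

test_that("ABGD scan recovers planted partitions and agrees with the
           threshold rule under a perfect gap", {
  set.seed(77)
  hits <- 0
  for (s in 1:10) {
    b <- make_benchmark(sim_profile(seed = 300 + s))
    dm <- suppressWarnings(distance_matrix(b$alignment, "k2p"))
    res <- abgd_partition(dm, abgd_config(prior_p = 0.1))
    hits <- hits + partitions_equal(res$partition, b$truth)
    # perfect-gap coincidence with single-linkage threshold at the gap
    thr <- threshold_cluster(dm, 0.02)
    if (partitions_equal(thr, b$truth)) {
      expect_true(n_groups(res$partition) >= n_groups(b$truth) - 2)
    }
  }
  expect_gte(hits, 8)
})

test_that("GMYC separates deep-stem species trees from single-population
           nulls", {
  cfg <- sim_profile(seed = 5)
  gt <- simulate_gene_tree(simulate_species_tree(cfg), cfg)
  g <- gmyc_fit(gt)
  expect_lte(abs(g$fit$n_entities - 10L), 2L)
  expect_true(g$fit$LR >= 0)
  expect_lt(g$fit$p_value, 0.05)
  expect_equal(g$fit$n_entities, n_groups(g$partition))

  # single coalescent population: LR small, one entity preferred
  cfg0 <- sim_config(n_species = 1, samples_per_species = 15,
                     coalescent_Ne_scale = 0.005, seed = 9)
  gt0 <- simulate_gene_tree(simulate_species_tree(cfg0), cfg0)
  g0 <- gmyc_fit(gt0)
  expect_lt(g0$fit$LR, stats::qchisq(0.99, df = 3))
  expect_equal(g0$fit$n_entities, 1L)

  expect_error(gmyc_fit(ape::rtree(6)), "ultrametric")
})

test_that("GMYC partitions are identical on haplotype-collapsed and
           identical-sequence-padded trees", {
  cfg <- sim_profile(seed = 12)
  b <- make_benchmark(cfg)
  hap <- collapse_haplotypes(b$alignment)
  dmh <- suppressWarnings(distance_matrix(hap$alignment, "k2p"))
  ut <- ultrametricize(nj_tree(dmh))
  g1 <- gmyc_fit(ut)
  g2 <- gmyc_fit(ut)   # deterministic likelihood fit
  expect_true(partitions_equal(g1$partition, g2$partition))
  full <- expand_partition(g1$partition, hap$members)
  expect_setequal(names(full), b$alignment$meta$sample_id)
})

test_that("PTP recovers planted two-rate partitions and prefers one
           species on star-like trees", {
  set.seed(55)
  ok <- 0
  for (i in 1:10) {
    tr <- planted_tree()
    p <- ptp_fit(tr, seed = i)
    ok <- ok + (abs(p$fit$n_entities - 10L) <= 2L)
  }
  expect_gte(ok, 8)

  # star-like single population: the one-species configuration is at
  # least as likely as the n-singletons configuration
  set.seed(6)
  star <- ape::rtree(12, br = function(n) rexp(n, 1 / 0.004))
  star <- phangorn::midpoint(star)
  tb <- barcodegap:::.ptp_tables(star, min_branch = 0)
  ll_one <- barcodegap:::.ptp_loglik(tb, tb$ntip + 1L)
  ll_tips <- barcodegap:::.ptp_loglik(tb, seq_len(tb$ntip))
  expect_gte(ll_one, ll_tips)

  # determinism under a fixed seed
  tr <- planted_tree()
  pa <- ptp_fit(tr, seed = 42)
  pb <- ptp_fit(tr, seed = 42)
  expect_identical(pa$fit$logL, pb$fit$logL)
  expect_true(partitions_equal(pa$partition, pb$partition))
})
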