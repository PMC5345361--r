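# Hand-checkable distance matrix: species A = {a1, a2}, B = {b1}.
.toy_dm <- function() {
  d <- matrix(0, 3, 3, dimnames = list(c("a1", "a2", "b1"),
                                       c("a1", "a2", "b1")))
  d["a1", "a2"] <- d["a2", "a1"] <- 0.004
  d["a1", "b1"] <- d["b1", "a1"] <- 0.10
  d["a2", "b1"] <- d["b1", "a2"] <- 0.10
  structure(d, model = "k2p", class = c("genetic_dist", "matrix", "array"))
}

test_that("intra- and inter-specific pair extraction enumerates the right
           pairs", {
  dm <- .toy_dm()
  truth <- partition(c(a1 = "A", a2 = "A", b1 = "B"))
  intra <- intraspecific_distances(dm, truth)
  expect_equal(intra$A, 0.004)
  expect_length(intra$B, 0L)  # singleton species

  inter <- interspecific_distances(dm, truth)
  expect_equal(sort(inter$all), c(0.10, 0.10))

  # a species of 3 yields choose(3,2) intraspecific values
  d4 <- matrix(0.01, 4, 4); diag(d4) <- 0
  dimnames(d4) <- list(paste0("s", 1:4), paste0("s", 1:4))
  t4 <- partition(c(s1 = "X", s2 = "X", s3 = "X", s4 = "Y"))
  expect_length(intraspecific_distances(d4, t4)$X, 3L)
  # 2 x 2 samples give 4 heterospecific values
  t22 <- partition(c(s1 = "X", s2 = "X", s3 = "Y", s4 = "Y"))
  expect_length(interspecific_distances(d4, t22)$all, 4L)
  # single-species genus is empty
  expect_length(interspecific_distances(d4, partition(
    c(s1 = "X", s2 = "X", s3 = "X", s4 = "X")))$all, 0L)
})

test_that("the five divergence metrics match the hand computation and
           single-species genera report absent interspecific fields", {
  dm <- .toy_dm()
  truth <- partition(c(a1 = "A", a2 = "A", b1 = "B"))
  fm <- five_metrics(dm, truth)
  expect_equal(fm$avg_interspecific_mean, 0.10)
  expect_equal(fm$smallest_interspecific_mean, 0.10)
  expect_equal(fm$avg_intraspecific_mean, 0.004)
  expect_equal(fm$mean_theta_mean, 0.004)
  expect_equal(fm$avg_coalescent_depth_mean, 0.004)
  expect_equal(fm$n_species, 2L)
  expect_equal(fm$n_specimens, 3L)

  # one genus with one species: dashes (NA) in interspecific columns
  g1 <- five_metrics(dm, partition(c(a1 = "A", a2 = "A", b1 = "A")))
  expect_true(is.na(g1$avg_interspecific_mean))
  expect_true(is.na(g1$smallest_interspecific_mean))
  expect_false(is.na(g1$avg_intraspecific_mean))

  # all-singleton species: intraspecific columns absent instead
  g2 <- five_metrics(dm, partition(c(a1 = "A", a2 = "B", b1 = "C")))
  expect_true(is.na(g2$avg_intraspecific_mean))
  expect_true(is.na(g2$mean_theta_mean))
  expect_false(is.na(g2$avg_interspecific_mean))
})

test_that("mean theta weights species equally under asymmetric sampling", {
  set.seed(21)
  # species X sampled 20 times, species Y twice, identical within-species
  # distance level
  ids <- c(paste0("x", 1:20), "y1", "y2")
  n <- length(ids)
  d <- matrix(0.1, n, n, dimnames = list(ids, ids))
  d[1:20, 1:20] <- 0.004
  d[21:22, 21:22] <- 0.004
  diag(d) <- 0
  truth <- partition(stats::setNames(c(rep("X", 20), rep("Y", 2)), ids))
  fm <- five_metrics(d, truth)
  expect_equal(fm$mean_theta_mean, 0.004)
  # pooled intraspecific equals the pair-count weighted mean of thetas
  intra <- intraspecific_distances(d, truth)
  pooled <- mean(unlist(intra))
  weighted <- sum(vapply(intra, function(v) mean(v) * length(v),
                         numeric(1))) / sum(lengths(intra))
  expect_equal(fm$avg_intraspecific_mean, pooled)
  expect_equal(pooled, weighted)
})

test_that("metric relations hold on simulated data", {
  b <- make_benchmark(sim_profile(seed = 101))
  dm <- suppressWarnings(distance_matrix(b$alignment, "k2p"))
  fm <- five_metrics(dm, b$truth)
  expect_true(fm$smallest_interspecific_mean <= fm$avg_interspecific_mean)
  expect_true(fm$smallest_interspecific_mean >
                fm$avg_coalescent_depth_mean)
  # duplicating a sequence inside a species leaves theta and depth of that
  # species' contribution unchanged only through re-averaging; check the
  # depth never decreases and theta stays within the species range
  expect_true(fm$avg_coalescent_depth_mean >= fm$avg_intraspecific_mean)
})

test_that("between-group distance averages cross pairs and rejects
           overlapping groups", {
  dm <- .toy_dm()
  expect_equal(between_group_distance(dm, "a1", "b1"), 0.10)
  ids <- c("a1", "a2", "b")
  d <- matrix(0, 3, 3, dimnames = list(ids, ids))
  d["a1", "a2"] <- d["a2", "a1"] <- 0.01
  d["a1", "b"] <- d["b", "a1"] <- 0.04
  d["a2", "b"] <- d["b", "a2"] <- 0.06
  expect_equal(between_group_distance(d, c("a1", "a2"), "b"), 0.05)
  expect_error(between_group_distance(d, c("a1", "a2"), c("a2", "b")),
               "overlap")
  expect_error(between_group_distance(d, character(0), "b"), "empty")
})

test_that("overlap analysis finds the crossing region and counts its
           frequency", {
  # disjoint distributions: empty region
  o0 <- overlap_analysis(c(0.001, 0.005, 0.009), c(0.05, 0.07, 0.1))
  expect_null(o0$overlap_interval)
  expect_equal(o0$total_frequency_in_overlap, 0L)

  o1 <- overlap_analysis(c(0.01, 0.03), c(0.02, 0.05))
  expect_equal(o1$overlap_interval, c(0.02, 0.03))
  expect_equal(o1$total_frequency_in_overlap, 2L)

  # brute-force frequency on a random overlapping pair of multisets
  set.seed(9)
  intra <- round(runif(40, 0, 0.04), 3)
  inter <- round(runif(60, 0.02, 0.12), 3)
  o2 <- overlap_analysis(intra, inter)
  lo <- min(round(inter, 3)); hi <- max(round(intra, 3))
  expect_equal(o2$overlap_interval, c(lo, hi))
  expect_equal(o2$total_frequency_in_overlap,
               sum(round(intra, 3) >= lo) + sum(round(inter, 3) <= hi))

  # removing the outlier samples that create the overlap shrinks it
  intra_out <- c(intra, 0.06, 0.07)   # two queried samples
  o3 <- overlap_analysis(intra_out, inter)
  expect_true(o3$overlap_interval[2] > o2$overlap_interval[2])
  expect_true(o3$total_frequency_in_overlap > o2$total_frequency_in_overlap)

  expect_error(overlap_analysis(numeric(0), inter), "empty")
})
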