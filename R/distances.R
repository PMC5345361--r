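# Pairwise genetic distances: p-distance, JC69 and K2P under pairwise
# deletion, plus vectorized distance-matrix assembly and CSV export in the
# square, label-headed dialect used to feed ABGD.

#' Count substitutions between two aligned sequences
#'
#' Pairwise deletion: a site is compared only when both sequences carry an
#' unambiguous base (A/C/G/T); gaps and IUPAC ambiguity codes are excluded.
#' Transitions are A<->G and C<->T; every other mismatch is a transversion.
#'
#' @param s1,s2 Equal-length DNA strings (or character vectors of residues).
#' @return List with `n_compared`, `n_transitions`, `n_transversions`, and
#'   the proportions `P` (transitions) and `Q` (transversions); `P` and `Q`
#'   are `NaN` when no site is comparable.
#' @export
count_substitutions <- function(s1, s2) {
  a <- if (length(s1) == 1L) strsplit(toupper(s1), "")[[1]] else toupper(s1)
  b <- if (length(s2) == 1L) strsplit(toupper(s2), "")[[1]] else toupper(s2)
  if (length(a) != length(b)) {
    stop("input error: sequences have unequal lengths")
  }
  ok <- a %in% UNAMBIGUOUS & b %in% UNAMBIGUOUS
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  diff <- a != b
  ts <- sum(diff & ((a == "A" & b == "G") | (a == "G" & b == "A") |
                      (a == "C" & b == "T") | (a == "T" & b == "C")))
  tv <- sum(diff) - ts
  list(n_compared = n, n_transitions = ts, n_transversions = tv,
       P = if (n > 0) ts / n else NaN, Q = if (n > 0) tv / n else NaN)
}

#' Distance transforms
#'
#' `p_distance` is the raw mismatch proportion; `jc69_distance` applies the
#' one-parameter correction -(3/4) log(1 - 4p/3); `k2p_distance` applies the
#' two-parameter correction -(1/2) log((1-2P-Q) sqrt(1-2Q)) distinguishing
#' the transition proportion P from the transversion proportion Q. Outside
#' the log domain (p >= 3/4, or 1-2P-Q <= 0 or 1-2Q <= 0) the corrected
#' distances are undefined and returned as `NA`.
#'
#' @param counts A list as returned by [count_substitutions()].
#' @return A single distance (NA when undefined).
#' @export
p_distance <- function(counts) {
  if (counts$n_compared == 0L) return(NA_real_)
  (counts$n_transitions + counts$n_transversions) / counts$n_compared
}

#' @rdname p_distance
#' @export
jc69_distance <- function(counts) {
  p <- p_distance(counts)
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' @rdname p_distance
#' @export
k2p_distance <- function(counts) {
  if (counts$n_compared == 0L) return(NA_real_)
  P <- counts$P; Q <- counts$Q
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1 * sqrt(w2))
}

# Vectorized substitution tallies for all pairs at once: indicator-matrix
# cross-products give, per pair, the counts of compared sites, transitions
# and transversions in O(n^2 L) flops inside BLAS.
.pairwise_counts <- function(m) {
  ind <- lapply(UNAMBIGUOUS, function(b) (m == b) * 1)
  names(ind) <- UNAMBIGUOUS
  valid <- ind$A + ind$C + ind$G + ind$T
  ncmp <- valid %*% t(valid)
  matches <- Reduce(`+`, lapply(ind, function(x) x %*% t(x)))
  ts <- ind$A %*% t(ind$G) + ind$G %*% t(ind$A) +
    ind$C %*% t(ind$T) + ind$T %*% t(ind$C)
  tv <- ncmp - matches - ts
  list(n = ncmp, ts = ts, tv = tv)
}

#' Pairwise distance matrix under a named model
#'
#' Computes all pairwise distances with pairwise deletion. Undefined entries
#' (no comparable sites, or model transform out of domain) are stored as
#' `NA` and reported via a warning.
#'
#' @param aln A `labeled_alignment` with at least 2 sequences.
#' @param model One of `"p"`, `"jc69"`, `"k2p"`.
#' @return A symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames, and attributes `model` and `n_undefined`; class
#'   `genetic_dist`.
#' @export
distance_matrix <- function(aln, model = c("k2p", "p", "jc69")) {
  model <- match.arg(model)
  if (n_samples(aln) < 2L) stop("input error: need >= 2 sequences")
  cts <- .pairwise_counts(aln$seq)
  n <- cts$n
  p <- (cts$ts + cts$tv) / n            # NaN where n == 0
  d <- switch(model,
    p = p,
    jc69 = {
      x <- 1 - 4 * p / 3
      out <- suppressWarnings(-0.75 * log(x))
      out[x <= 0] <- NA_real_
      out
    },
    k2p = {
      P <- cts$ts / n; Q <- cts$tv / n
      w1 <- 1 - 2 * P - Q
      w2 <- 1 - 2 * Q
      out <- suppressWarnings(-0.5 * log(w1 * sqrt(w2)))
      out[w1 <= 0 | w2 <= 0] <- NA_real_
      out
    })
  d[is.nan(d)] <- NA_real_
  diag(d) <- 0
  d <- (d + t(d)) / 2  # symmetrize exactly against float asymmetry
  dimnames(d) <- list(rownames(aln$seq), rownames(aln$seq))
  n_undef <- sum(is.na(d[upper.tri(d)]))
  if (n_undef > 0L) {
    warning(n_undef, " undefined pairwise distance(s) under model ", model)
  }
  structure(d, model = model, n_undefined = n_undef,
            class = c("genetic_dist", "matrix", "array"))
}

#' Export / import a distance matrix as CSV
#'
#' Full square matrix, first row and first column carrying the sample ids --
#' the layout produced by distance-matrix exports and consumed by ABGD.
#'
#' @param dm A `genetic_dist` matrix.
#' @param path CSV path.
#' @return `write_distance_csv` invisibly returns `path`;
#'   `read_distance_csv` returns a `genetic_dist`.
#' @export
write_distance_csv <- function(dm, path) {
  utils::write.csv(as.data.frame(unclass(dm)), path)
  invisible(path)
}

#' @rdname write_distance_csv
#' @param model Model tag to attach on import.
#' @export
read_distance_csv <- function(path, model = "k2p") {
  d <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  structure(d, model = model, n_undefined = sum(is.na(d[upper.tri(d)])),
            class = c("genetic_dist", "matrix", "array"))
}

# Off-diagonal unordered-pair distances as a flat vector.
.pair_values <- function(dm, ids = NULL) {
  d <- unclass(dm)
  if (!is.null(ids)) d <- d[ids, ids, drop = FALSE]
  d[upper.tri(d)]
}
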