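# Concordance of an estimated partition with reference (morphological)
# species: every estimated cluster is classified as accurate, split, lumped,
# or partial-lumped.

#' Classify one estimated cluster against reference species
#'
#' \describe{
#'   \item{accurate}{the cluster equals one species' full sample set}
#'   \item{split}{a strict subset of a single species}
#'   \item{lumped}{the union of two or more complete species}
#'   \item{partial_lumped}{spans two or more species otherwise (including
#'     the case of partial samples of several species with no complete one,
#'     which keeps the four categories exhaustive)}
#' }
#'
#' @param cluster Non-empty character vector of sample ids.
#' @param truth A `partition` mapping every sample id to its species.
#' @return One of `"accurate"`, `"split"`, `"lumped"`, `"partial_lumped"`.
#' @export
classify_cluster <- function(cluster, truth) {
  if (length(cluster) == 0L) stop("input error: empty cluster")
  unknown <- setdiff(cluster, names(truth))
  if (length(unknown) > 0L) {
    stop("input error: unlabeled samples: ", paste(unknown, collapse = ", "))
  }
  sp <- unclass(truth)[cluster]
  species <- unique(sp)
  sizes_in <- table(sp)
  sizes_all <- table(unclass(truth))[names(sizes_in)]
  complete <- sizes_in == sizes_all
  if (length(species) == 1L) {
    if (complete) "accurate" else "split"
  } else {
    if (all(complete)) "lumped" else "partial_lumped"
  }
}

#' Concordance report for an estimated partition
#'
#' Classifies every estimated cluster with [classify_cluster()] and tallies
#' counts and percentages of clusters per category.
#'
#' @param est Estimated `partition`.
#' @param truth Reference `partition` over the same sample universe.
#' @return List of class `concordance_report`: `n_morphospecies`,
#'   `n_clusters`, counts `n_accurate`, `n_split`, `n_lumped`,
#'   `n_partial_lumped`, matching percentages (`pct_*`, of `n_clusters`),
#'   and `categories` (per-cluster labels).
#' @export
concordance_report <- function(est, truth) {
  if (!setequal(names(est), names(truth))) {
    stop("input error: estimated and reference partitions cover different ",
         "samples")
  }
  clusters <- partition_groups(est)
  cats <- vapply(clusters, classify_cluster, character(1), truth = truth)
  tab <- table(factor(cats, levels = c("accurate", "split", "lumped",
                                       "partial_lumped")))
  k <- length(clusters)
  out <- list(n_morphospecies = n_groups(truth),
              n_clusters = k,
              n_accurate = unname(tab[["accurate"]]),
              n_split = unname(tab[["split"]]),
              n_lumped = unname(tab[["lumped"]]),
              n_partial_lumped = unname(tab[["partial_lumped"]]),
              pct_accurate = 100 * tab[["accurate"]] / k,
              pct_split = 100 * tab[["split"]] / k,
              pct_lumped = 100 * tab[["lumped"]] / k,
              pct_partial_lumped = 100 * tab[["partial_lumped"]] / k,
              categories = cats)
  class(out) <- "concordance_report"
  out
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance: %d clusters vs %d morphospecies\n",
              x$n_clusters, x$n_morphospecies))
  cat(sprintf("  accurate %d (%.2f%%)  split %d (%.2f%%)  lumped %d",
              x$n_accurate, x$pct_accurate, x$n_split, x$pct_split,
              x$n_lumped))
  cat(sprintf(" (%.2f%%)  partial lumped %d (%.2f%%)\n",
              x$pct_lumped, x$n_partial_lumped, x$pct_partial_lumped))
  invisible(x)
}

#' Concordance report as a one-row data frame
#'
#' Table-style summary row (dataset, method, cluster number, four
#' percentages), convenient for binding across genes and methods.
#'
#' @param report A `concordance_report`.
#' @param dataset,method Identifier strings for the row.
#' @return A one-row data frame.
#' @export
concordance_row <- function(report, dataset = "", method = "") {
  data.frame(dataset = dataset, method = method,
             n_morphospecies = report$n_morphospecies,
             n_clusters = report$n_clusters,
             pct_accurate = report$pct_accurate,
             pct_split = report$pct_split,
             pct_lumped = report$pct_lumped,
             pct_partial_lumped = report$pct_partial_lumped,
             stringsAsFactors = FALSE)
}
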