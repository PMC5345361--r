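# Inter/intra-specific divergence statistics (the five classical barcoding
# metrics, per genus), between-group divergences, and the barcode-gap
# overlap-region frequency analysis.

.mean_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(c(mean = NA_real_, sd = NA_real_))
  c(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0)
}

#' Per-species intraspecific distance multisets
#'
#' @param dm A `genetic_dist` matrix.
#' @param truth A `partition` mapping sample ids to species.
#' @return Named list (one element per species) of conspecific pairwise
#'   distances; species with fewer than two samples yield empty vectors.
#'   Undefined distances are dropped.
#' @export
intraspecific_distances <- function(dm, truth) {
  lapply(partition_groups(truth), function(ids) {
    v <- .pair_values(dm, ids)
    v[!is.na(v)]
  })
}

#' Per-genus heterospecific pair distances
#'
#' Distances between samples of different species within the same genus;
#' genera with a single species yield empty vectors.
#'
#' @param dm A `genetic_dist` matrix.
#' @param truth A `partition` mapping sample ids to species.
#' @param genus_map Named character vector mapping species labels to genus
#'   labels; defaults to a single genus covering every species.
#' @return Named list (one element per genus) of interspecific distances.
#' @export
interspecific_distances <- function(dm, truth, genus_map = NULL) {
  genus_map <- .default_genus_map(truth, genus_map)
  sp <- unclass(truth)[rownames(dm)]
  gn <- genus_map[sp]
  out <- lapply(unique(genus_map), function(g) {
    idx <- which(gn == g)
    if (length(idx) < 2L) return(numeric(0))
    d <- unclass(dm)[idx, idx, drop = FALSE]
    hetero <- outer(sp[idx], sp[idx], `!=`) & upper.tri(d)
    v <- d[hetero]
    v[!is.na(v)]
  })
  stats::setNames(out, unique(genus_map))
}

.default_genus_map <- function(truth, genus_map) {
  species <- unique(unclass(truth))
  if (is.null(genus_map)) {
    genus_map <- stats::setNames(rep("all", length(species)), species)
  }
  missing <- setdiff(species, names(genus_map))
  if (length(missing) > 0L) {
    stop("input error: species without genus assignment: ",
         paste(missing, collapse = ", "))
  }
  genus_map
}

#' The five inter/intra-specific divergence metrics, per genus
#'
#' For every genus reports mean and standard deviation of:
#' \describe{
#'   \item{avg_interspecific}{all heterospecific sample pairs within the
#'     genus, pooled (defined only for genera with >= 2 species);
#'     `inter_by_species_pair = TRUE` instead averages the per-species-pair
#'     mean distances.}
#'   \item{smallest_interspecific}{per species, the minimum distance to any
#'     heterospecific sample of the genus (nearest neighbor), averaged over
#'     species.}
#'   \item{avg_intraspecific}{all conspecific pairs pooled over species with
#'     >= 2 samples.}
#'   \item{mean_theta}{per species with >= 2 samples, the species' average
#'     pairwise distance; species weighted equally, countering asymmetric
#'     sampling.}
#'   \item{avg_coalescent_depth}{per species with >= 2 samples, the species'
#'     maximum pairwise distance, averaged over species.}
#' }
#' Fields that are undefined for a genus (single species, or no species
#' sampled twice) are reported as `NA`, the analogue of a dashed table cell.
#'
#' @inheritParams interspecific_distances
#' @param inter_by_species_pair Pool heterospecific sample pairs (default)
#'   or average species-pair means.
#' @return Data frame, one row per genus: `genus`, `n_species`,
#'   `n_specimens`, then `<metric>_mean` / `<metric>_sd` for the five
#'   metrics.
#' @export
five_metrics <- function(dm, truth, genus_map = NULL,
                         inter_by_species_pair = FALSE) {
  genus_map <- .default_genus_map(truth, genus_map)
  sp_of <- unclass(truth)
  genera <- unique(genus_map)
  rows <- lapply(genera, function(g) {
    species <- names(genus_map)[genus_map == g]
    ids <- names(truth)[sp_of %in% species]
    species <- intersect(species, sp_of[ids])
    d <- unclass(dm)[ids, ids, drop = FALSE]
    sp <- sp_of[ids]
    multi <- length(species) >= 2L

    inter <- c(mean = NA_real_, sd = NA_real_)
    smallest <- c(mean = NA_real_, sd = NA_real_)
    if (multi) {
      hetero <- outer(sp, sp, `!=`)
      if (inter_by_species_pair) {
        pairs <- utils::combn(species, 2L, simplify = FALSE)
        pm <- vapply(pairs, function(pr) {
          v <- d[sp == pr[1], sp == pr[2], drop = FALSE]
          mean(v, na.rm = TRUE)
        }, numeric(1))
        inter <- .mean_sd(pm)
      } else {
        inter <- .mean_sd(d[hetero & upper.tri(d)])
      }
      nn <- vapply(species, function(s) {
        v <- d[sp == s, sp != s, drop = FALSE]
        if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
      }, numeric(1))
      smallest <- .mean_sd(nn)
    }

    per_sp <- lapply(species, function(s) {
      v <- .pair_values(dm, ids[sp == s])
      v[!is.na(v)]
    })
    per_sp <- per_sp[lengths(per_sp) > 0L]
    intra <- .mean_sd(unlist(per_sp))
    theta <- .mean_sd(vapply(per_sp, mean, numeric(1)))
    depth <- .mean_sd(vapply(per_sp, max, numeric(1)))

    data.frame(genus = g, n_species = length(species),
               n_specimens = length(ids),
               avg_interspecific_mean = inter[["mean"]],
               avg_interspecific_sd = inter[["sd"]],
               smallest_interspecific_mean = smallest[["mean"]],
               smallest_interspecific_sd = smallest[["sd"]],
               avg_intraspecific_mean = intra[["mean"]],
               avg_intraspecific_sd = intra[["sd"]],
               mean_theta_mean = theta[["mean"]],
               mean_theta_sd = theta[["sd"]],
               avg_coalescent_depth_mean = depth[["mean"]],
               avg_coalescent_depth_sd = depth[["sd"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean between-group distance
#'
#' Mean of all cross distances between two disjoint sample sets, skipping
#' undefined entries. Used e.g. for the divergence between two geographic
#' clades of one nominal species.
#'
#' @param dm A `genetic_dist` matrix.
#' @param groupA,groupB Disjoint, non-empty character vectors of sample ids.
#' @return A single mean distance.
#' @export
between_group_distance <- function(dm, groupA, groupB) {
  if (length(groupA) == 0L || length(groupB) == 0L) {
    stop("input error: empty group")
  }
  if (length(intersect(groupA, groupB)) > 0L) {
    stop("input error: groups overlap: ",
         paste(intersect(groupA, groupB), collapse = ", "))
  }
  mean(unclass(dm)[groupA, groupB], na.rm = TRUE)
}

#' Barcode-gap overlap-region analysis
#'
#' Values are rounded to `rounding` decimals, then the overlap region is the
#' interval \[min(inter), max(intra)\] whenever the smallest interspecific
#' value does not exceed the largest intraspecific value (otherwise the
#' distributions are disjoint and the region is empty). The total frequency
#' in the region counts intraspecific values at or above its lower bound
#' plus interspecific values at or below its upper bound -- the samples a
#' distance threshold could not identify.
#'
#' @param intra,inter Non-empty numeric multisets of intra- and
#'   inter-specific distances.
#' @param rounding Decimal places used for frequency counting (default 3).
#' @return List with `overlap_interval` (length-2 numeric, or `NULL` when
#'   empty), `total_frequency_in_overlap`, and the rounded `intra_values` /
#'   `inter_values`.
#' @export
overlap_analysis <- function(intra, inter, rounding = 3) {
  intra <- intra[!is.na(intra)]; inter <- inter[!is.na(inter)]
  if (length(intra) == 0L || length(inter) == 0L) {
    stop("input error: empty distance multiset")
  }
  intra <- round(intra, rounding)
  inter <- round(inter, rounding)
  lo <- min(inter); hi <- max(intra)
  if (lo > hi) {
    return(list(overlap_interval = NULL, total_frequency_in_overlap = 0L,
                intra_values = intra, inter_values = inter))
  }
  freq <- sum(intra >= lo) + sum(inter <= hi)
  list(overlap_interval = c(lo, hi), total_frequency_in_overlap = freq,
       intra_values = intra, inter_values = inter)
}
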