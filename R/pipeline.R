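# Pipeline orchestration: distances -> divergence metrics -> trees -> four
# delimitation methods -> concordance, per gene data set, with reproducible
# seeds and plain-text artifacts.

#' Pipeline run configuration
#'
#' Defaults match the conventional study settings: K2P distances with
#' pairwise deletion, a 2% clustering threshold, ABGD scan up to prior 0.1
#' (use `abgd_config(prior_p = 0.055)` for the aphid COI profile), 1000
#' bootstrap replicates and a 50% consensus cutoff.
#'
#' @param inputs List of gene inputs; each element is a list with `gene`
#'   and either `alignment` (a `labeled_alignment`) or `fasta` +
#'   `metadata` paths.
#' @param distance_model `"k2p"`, `"p"`, or `"jc69"`.
#' @param threshold Clustering threshold (proportion).
#' @param abgd An [abgd_config()].
#' @param bootstrap_reps Bootstrap replicate count.
#' @param consensus_cutoff Condensation cutoff percentage.
#' @param seed Integer seed for all stochastic stages.
#' @param output_dir Optional directory for TSV/JSON/newick artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(inputs, distance_model = "k2p", threshold = 0.02,
                       abgd = abgd_config(), bootstrap_reps = 1000L,
                       consensus_cutoff = 50, seed = 1L,
                       output_dir = NULL) {
  if (length(inputs) == 0L) stop("input error: at least one input required")
  structure(list(inputs = inputs, distance_model = distance_model,
                 threshold = threshold, abgd = abgd,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 consensus_cutoff = consensus_cutoff,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

.load_input <- function(inp) {
  if (!is.null(inp$alignment)) return(inp$alignment)
  read_alignment(inp$fasta, inp$metadata, gene = inp$gene)
}

# One gene's full analysis.
.run_gene <- function(aln, gene, cfg) {
  dm <- suppressWarnings(distance_matrix(aln, cfg$distance_model))
  truth <- partition(stats::setNames(aln$meta$species, aln$meta$sample_id))
  genus_map <- stats::setNames(aln$meta$genus, aln$meta$species)
  genus_map <- genus_map[!duplicated(names(genus_map))]

  metrics <- five_metrics(dm, truth, genus_map)
  intra <- unlist(intraspecific_distances(dm, truth), use.names = FALSE)
  d <- unclass(dm)
  sp <- unclass(truth)[rownames(d)]
  inter <- d[outer(sp, sp, `!=`) & upper.tri(d)]
  inter <- inter[!is.na(inter)]
  overlap <- if (length(intra) > 0L && length(inter) > 0L) {
    overlap_analysis(intra, inter)
  } else NULL

  boot <- bootstrap_support(aln, cfg$distance_model, cfg$bootstrap_reps,
                            seed = cfg$seed)
  condensed <- condense_tree(boot, cfg$consensus_cutoff)
  nj <- nj_tree(dm)

  parts <- list()
  parts$threshold <- threshold_cluster(dm, cfg$threshold)
  abgd_res <- abgd_partition(dm, cfg$abgd)
  parts$abgd <- abgd_res$partition

  # tree-based methods run on the haplotype-collapsed tree (identical
  # sequences carry no branch information and are re-expanded afterwards)
  hap <- collapse_haplotypes(aln)
  gmyc_part <- NULL
  gmyc_fit_obj <- NULL
  ptp_part <- NULL
  ptp_fit_obj <- NULL
  if (n_samples(hap$alignment) >= 3L) {
    dm_h <- suppressWarnings(distance_matrix(hap$alignment,
                                             cfg$distance_model))
    nj_h <- nj_tree(dm_h)
    g <- gmyc_fit(ultrametricize(nj_h))
    gmyc_fit_obj <- g$fit
    gmyc_part <- expand_partition(g$partition, hap$members)
    p <- ptp_fit(nj_h, seed = cfg$seed)
    ptp_fit_obj <- p$fit
    ptp_part <- expand_partition(p$partition, hap$members)
  }
  parts$gmyc <- gmyc_part
  parts$ptp <- ptp_part

  conc <- lapply(parts[!vapply(parts, is.null, logical(1))],
                 concordance_report, truth = truth)
  list(gene = gene, n_samples = n_samples(aln), metrics = metrics,
       overlap = overlap, nj_tree = nj, bootstrap_tree = boot,
       condensed_tree = condensed, partitions = parts,
       abgd = abgd_res[c("gap_distance", "n_recursion_rounds")],
       gmyc = gmyc_fit_obj, ptp = ptp_fit_obj, concordance = conc,
       truth = truth)
}

.write_gene_outputs <- function(res, dir) {
  gd <- file.path(dir, res$gene)
  dir.create(gd, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$metrics, file.path(gd, "divergence_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_newick(res$nj_tree, file.path(gd, "nj.nwk"))
  write_newick(res$bootstrap_tree, file.path(gd, "nj_bootstrap.nwk"))
  write_newick(res$condensed_tree, file.path(gd, "nj_condensed.nwk"))
  for (m in names(res$partitions)) {
    if (!is.null(res$partitions[[m]])) {
      write_partition(res$partitions[[m]],
                      file.path(gd, paste0("partition_", m, ".tsv")))
    }
  }
  conc_tab <- do.call(rbind, lapply(names(res$concordance), function(m) {
    concordance_row(res$concordance[[m]], dataset = res$gene, method = m)
  }))
  utils::write.table(conc_tab, file.path(gd, "concordance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    gene = res$gene, n_samples = res$n_samples,
    abgd = res$abgd,
    gmyc = if (!is.null(res$gmyc)) unclass(res$gmyc)[
      c("n_entities", "logL", "logL_null", "LR", "p_value", "df")],
    ptp = if (!is.null(res$ptp)) unclass(res$ptp)[
      c("n_entities", "logL", "lambda_sp", "lambda_coal")],
    overlap = if (!is.null(res$overlap)) res$overlap[
      c("overlap_interval", "total_frequency_in_overlap")])
  jsonlite::write_json(report, file.path(gd, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(gd)
}

#' Run the full delimitation pipeline
#'
#' Per gene: distances, five divergence metrics, overlap analysis,
#' bootstrapped NJ tree with condensation, and the four delimitation
#' methods (threshold, ABGD, GMYC on the haplotype-collapsed ultrametric
#' tree, PTP), each scored against the metadata species labels. A failing
#' gene is recorded and does not stop the others. Identical config and seed
#' give identical outputs.
#'
#' @param cfg A [run_config()].
#' @return List of class `run_report`: `genes` (per-gene result lists),
#'   `failures` (named error messages), and `provenance`.
#' @export
run_pipeline <- function(cfg) {
  results <- list()
  failures <- list()
  for (inp in cfg$inputs) {
    gene <- inp$gene
    res <- tryCatch({
      aln <- .load_input(inp)
      .run_gene(aln, gene, cfg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[gene]] <- conditionMessage(res)
      next
    }
    results[[gene]] <- res
    if (!is.null(cfg$output_dir)) .write_gene_outputs(res, cfg$output_dir)
  }
  report <- structure(list(genes = results, failures = failures,
                           provenance = list(
                             distance_model = cfg$distance_model,
                             threshold = cfg$threshold,
                             abgd = unclass(cfg$abgd),
                             bootstrap_reps = cfg$bootstrap_reps,
                             consensus_cutoff = cfg$consensus_cutoff,
                             seed = cfg$seed,
                             timestamp = format(Sys.time(), tz = "UTC"),
                             package_version =
                               as.character(utils::packageVersion("barcodegap")))),
                      class = "run_report")
  if (!is.null(cfg$output_dir)) {
    prov <- report$provenance
    jsonlite::write_json(prov, file.path(cfg$output_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Restrict several gene data sets to their common samples
#'
#' Keeps only the samples present in every alignment (the "complete cases"
#' comparison design), preserving the first alignment's sample order.
#'
#' @param alns List of `labeled_alignment` objects (>= 2).
#' @return List of restricted alignments; empty-intersection input yields
#'   zero-sample alignments with a warning.
#' @export
intersect_datasets <- function(alns) {
  if (length(alns) < 2L) stop("input error: need >= 2 data sets")
  common <- Reduce(intersect, lapply(alns, function(a) a$meta$sample_id))
  common <- alns[[1L]]$meta$sample_id[alns[[1L]]$meta$sample_id %in% common]
  if (length(common) == 0L) {
    warning("empty sample intersection across data sets")
  }
  lapply(alns, subset_alignment, ids = common)
}

#' Subset a labeled alignment by sample ids
#' @param aln A `labeled_alignment`.
#' @param ids Sample ids to keep, in the order given.
#' @return A `labeled_alignment`.
#' @export
subset_alignment <- function(aln, ids) {
  missing <- setdiff(ids, aln$meta$sample_id)
  if (length(missing) > 0L) {
    stop("input error: unknown sample ids: ",
         paste(missing, collapse = ", "))
  }
  idx <- match(ids, aln$meta$sample_id)
  structure(list(seq = aln$seq[idx, , drop = FALSE],
                 meta = aln$meta[idx, , drop = FALSE], gene = aln$gene,
                 length = aln$length),
            class = "labeled_alignment")
}
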