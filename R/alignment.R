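# Labeled alignments, site statistics, haplotype collapsing, and the
# plain-text I/O surface (FASTA + TSV metadata, newick trees, partition TSV).

IUPAC_DNA <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-", "?")
UNAMBIGUOUS <- c("A", "C", "G", "T")

#' Construct a labeled alignment
#'
#' Bundles an equal-length DNA alignment with per-sample species/genus labels.
#' Sequences are stored as a character matrix (rows = samples, columns =
#' sites) in upper case over the IUPAC DNA alphabet plus gap.
#'
#' @param sequences Character vector of equal-length DNA strings, or a
#'   character matrix of single residues with one row per sample.
#' @param meta Data frame with columns `sample_id`, `species`, `genus` and
#'   optionally `locality`; one row per sequence, matched by `sample_id`.
#' @param gene Gene name (single string), e.g. `"COI"`.
#' @return An object of class `labeled_alignment` with elements `seq`
#'   (character matrix, rownames = sample ids), `meta` (data frame), `gene`,
#'   and `length` (alignment length in bp).
#' @export
labeled_alignment <- function(sequences, meta, gene = "gene") {
  if (is.matrix(sequences)) {
    m <- toupper(sequences)
  } else {
    sequences <- toupper(trimws(sequences))
    lens <- nchar(sequences)
    if (length(unique(lens)) > 1L) {
      stop("alignment error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    }
    m <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "species", "genus")
  if (!all(req %in% names(meta))) {
    stop("metadata error: required columns missing: ",
         paste(setdiff(req, names(meta)), collapse = ", "))
  }
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    stop("metadata error: duplicated sample ids")
  }
  if (nrow(m) != nrow(meta)) {
    stop("metadata error: ", nrow(m), " sequences but ", nrow(meta),
         " metadata rows")
  }
  bad <- setdiff(unique(as.vector(m)), IUPAC_DNA)
  if (length(bad) > 0L) {
    stop("alphabet error: non-IUPAC characters in sequences: ",
         paste(bad, collapse = ", "))
  }
  rownames(m) <- meta$sample_id
  structure(list(seq = m, meta = meta, gene = gene, length = ncol(m)),
            class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat("labeled_alignment:", nrow(x$seq), "samples x", x$length, "bp,",
      "gene", x$gene, "\n")
  cat("  species:", length(unique(x$meta$species)),
      " genera:", length(unique(x$meta$genus)), "\n")
  invisible(x)
}

#' Number of samples in a labeled alignment
#' @param aln A `labeled_alignment`.
#' @return Integer sample count.
#' @export
n_samples <- function(aln) nrow(aln$seq)

#' Read an aligned FASTA plus metadata table
#'
#' FASTA records and metadata rows must match one-to-one by id. Sequences
#' are upper-cased; ragged lengths or non-IUPAC characters are errors.
#'
#' @param fasta_path Path to an aligned FASTA file.
#' @param metadata_path Path to a TSV with columns `sample_id`, `species`,
#'   `genus` and optionally `locality`, `gene`.
#' @param gene Gene name; defaults to the metadata `gene` column when present.
#' @return A [labeled_alignment()].
#' @export
read_alignment <- function(fasta_path, metadata_path, gene = NULL) {
  lines <- readLines(fasta_path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("alignment error: no FASTA records in ", fasta_path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(trimws(x), collapse = ""), character(1))
  names(seqs) <- ids
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  if (!"sample_id" %in% names(meta)) {
    stop("metadata error: no sample_id column in ", metadata_path)
  }
  if (!setequal(ids, meta$sample_id) || length(ids) != nrow(meta)) {
    stop("metadata error: FASTA ids and metadata sample_id do not match ",
         "one-to-one")
  }
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (is.null(gene)) {
    gene <- if ("gene" %in% names(meta)) meta$gene[1] else "gene"
  }
  labeled_alignment(unname(seqs), meta, gene = gene)
}

#' Write a labeled alignment as FASTA + metadata TSV
#'
#' @param aln A `labeled_alignment`.
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, `fasta_path`.
#' @export
write_alignment <- function(aln, fasta_path, metadata_path) {
  seqs <- apply(aln$seq, 1L, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), fasta_path)
  utils::write.table(aln$meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fasta_path)
}

#' Alignment site statistics
#'
#' Counts conserved, variable and parsimony-informative sites, and the mean
#' T/C/A/G composition. Gaps and ambiguity codes are treated as missing:
#' a site is conserved iff all of its unambiguous residues are identical,
#' variable otherwise, and parsimony-informative iff at least two distinct
#' residues each occur in at least two sequences. Composition is the mean
#' over sequences of each sequence's base fractions (unambiguous bases only),
#' reported in the conventional T, C, A, G order.
#'
#' @param aln A `labeled_alignment` with at least 2 sequences.
#' @return List with `n_conserved`, `n_variable`, `n_parsimony_informative`,
#'   `n_counted_sites`, and `composition` (named fractions summing to 1).
#' @export
site_statistics <- function(aln) {
  m <- aln$seq
  if (nrow(m) < 2L) stop("input error: site_statistics needs >= 2 sequences")
  counts <- vapply(UNAMBIGUOUS, function(b) colSums(m == b),
                   numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L)  # guard 1-site case
  n_res <- rowSums(counts)
  distinct <- rowSums(counts > 0L)
  counted <- n_res >= 1L
  conserved <- counted & distinct <= 1L
  variable <- counted & distinct >= 2L
  informative <- rowSums(counts >= 2L) >= 2L
  comp_seq <- t(apply(m, 1L, function(s) {
    s <- s[s %in% UNAMBIGUOUS]
    tab <- table(factor(s, levels = c("T", "C", "A", "G")))
    if (sum(tab) == 0L) rep(NA_real_, 4L) else as.numeric(tab) / sum(tab)
  }))
  colnames(comp_seq) <- c("T", "C", "A", "G")
  list(n_conserved = sum(conserved),
       n_variable = sum(variable),
       n_parsimony_informative = sum(informative),
       n_counted_sites = sum(counted),
       composition = colMeans(comp_seq, na.rm = TRUE))
}

#' Collapse identical sequences into haplotypes
#'
#' One representative per distinct sequence string; the representative is the
#' first member in input order. If members of one haplotype carry different
#' species labels the representative's label is retained and the conflict
#' recorded.
#'
#' @param aln A `labeled_alignment`.
#' @return List with `alignment` (collapsed `labeled_alignment`), `members`
#'   (named list: haplotype id -> member sample ids) and `conflicts`
#'   (character vector of haplotype ids spanning several species).
#' @export
collapse_haplotypes <- function(aln) {
  key <- apply(aln$seq, 1L, paste, collapse = "")
  first <- !duplicated(key)
  reps <- rownames(aln$seq)[first]
  members <- split(rownames(aln$seq), factor(key, levels = key[first]))
  names(members) <- reps
  conflicts <- names(members)[vapply(members, function(ids) {
    length(unique(aln$meta$species[match(ids, aln$meta$sample_id)])) > 1L
  }, logical(1))]
  sub <- labeled_alignment(aln$seq[first, , drop = FALSE],
                           aln$meta[first, , drop = FALSE], gene = aln$gene)
  list(alignment = sub, members = members, conflicts = conflicts)
}

#' Partitions: sample-to-group assignments
#'
#' A partition is a named character vector mapping sample ids to group
#' labels.
#'
#' @param groups Named character vector (names = sample ids, values = group
#'   labels), or a list of character vectors of sample ids (one per group).
#' @return A named character vector of class `partition`.
#' @export
partition <- function(groups) {
  if (is.list(groups)) {
    nm <- names(groups)
    if (is.null(nm)) nm <- paste0("G", seq_along(groups))
    groups <- stats::setNames(rep(nm, lengths(groups)),
                              unlist(groups, use.names = FALSE))
  }
  groups <- stats::setNames(as.character(groups), names(groups))
  if (is.null(names(groups)) || anyDuplicated(names(groups))) {
    stop("input error: partition needs unique sample ids as names")
  }
  class(groups) <- "partition"
  groups
}

#' Number of groups in a partition
#' @param p A `partition`.
#' @return Integer group count.
#' @export
n_groups <- function(p) length(unique(unclass(p)))

#' Group sample ids by partition label
#' @param p A `partition`.
#' @return Named list of character vectors of sample ids.
#' @export
partition_groups <- function(p) split(names(p), unclass(p))

#' Do two partitions induce the same grouping?
#'
#' Group labels are ignored; only the induced set-of-sets is compared.
#'
#' @param p1,p2 `partition` objects.
#' @return Logical.
#' @export
partitions_equal <- function(p1, p2) {
  sig <- function(p) {
    g <- vapply(partition_groups(p),
                function(ids) paste(sort(ids), collapse = ","), character(1))
    paste(sort(unname(g)), collapse = ";")
  }
  setequal(names(p1), names(p2)) && sig(p1) == sig(p2)
}

#' Write / read a partition as a two-column TSV (sample, group)
#' @param p A `partition`.
#' @param path Output (or input) path.
#' @return `write_partition` invisibly returns `path`; `read_partition`
#'   returns a `partition`.
#' @export
write_partition <- function(p, path) {
  utils::write.table(data.frame(sample = names(p), group = unclass(p)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  partition(stats::setNames(d$group, d$sample))
}

#' Read / write newick trees
#'
#' Thin wrappers around ape's newick parser that turn malformed input into
#' an error rather than a malformed `phylo` object.
#'
#' @param path File path.
#' @param tree An ape `phylo` object.
#' @return `read_newick` returns a `phylo`; `write_newick` invisibly returns
#'   `path`.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("parse error: malformed newick in ", path)
  }
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
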