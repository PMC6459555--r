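# Post-screen gene scoring: anchored sgRNA counting from reads,
# median-of-ratios count normalization, high/low-bin enrichment scores,
# replicate averaging, and reference-gene normalization of the resulting
# gene x reporter table.

#' sgRNA x sample count container
#'
#' @param counts integer matrix, rows = sgRNAs (rownames required),
#'   columns = samples (colnames required).
#' @param sgrna_to_gene named character vector mapping each sgRNA id to
#'   exactly one gene.
#' @param sample_meta optional data frame with columns `sample`,
#'   `replicate`, `bin` (`input`/`high`/`low`) and optionally `reporter`.
#' @return a `screen_counts` object.
#' @export
screen_counts <- function(counts, sgrna_to_gene, sample_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    pf_stop("invalid_input", "counts must have sgRNA rownames and sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    pf_stop("invalid_input", "counts must be nonnegative integers")
  missing_map <- setdiff(rownames(counts), names(sgrna_to_gene))
  if (length(missing_map))
    pf_stop("invalid_library", "sgRNAs without a gene mapping: %s",
            paste(head(missing_map, 5), collapse = ", "))
  structure(list(counts = counts,
                 sgrna_to_gene = sgrna_to_gene[rownames(counts)],
                 sample_meta = sample_meta),
            class = "screen_counts")
}

#' @export
print.screen_counts <- function(x, ...) {
  cat(sprintf("<screen_counts> %d sgRNAs x %d samples, %d genes\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$sgrna_to_gene))))
  invisible(x)
}

#' Read an sgRNA library definition
#'
#' CSV with columns `sgrna`, `gene`, `sequence` (20-nt, unique).
#'
#' @param path CSV path.
#' @return data frame; errors on duplicate sequences or sgRNAs mapped to
#'   two genes.
#' @export
read_sgrna_library <- function(path) {
  lib <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sgrna", "gene", "sequence")
  if (!all(need %in% names(lib)))
    pf_stop("invalid_library", "library CSV must have columns %s",
            paste(need, collapse = ", "))
  validate_sgrna_library(lib)
}

validate_sgrna_library <- function(lib) {
  lib$sequence <- toupper(lib$sequence)
  if (anyDuplicated(lib$sequence))
    pf_stop("invalid_library", "duplicate sgRNA sequences in library")
  if (anyDuplicated(lib$sgrna))
    pf_stop("invalid_library", "duplicate sgRNA ids in library")
  if (any(nchar(lib$sequence) != 20L))
    pf_stop("invalid_library", "sgRNA sequences must be 20 nt")
  lib
}

#' Count sgRNAs from raw reads by vector-anchor matching
#'
#' For each read, finds the first exact occurrence of the vector anchor
#' `CACCG`, takes the following 20 nt, and increments the exactly matching
#' library sgRNA. Reads with no anchor, too little sequence after it, or
#' no library match are tallied separately, never counted.
#'
#' @param fastq path to a FASTQ file (plain or gzip).
#' @param library library data frame as from [read_sgrna_library()].
#' @param anchor anchor sequence (default `"CACCG"`).
#' @param sample name for the resulting count column.
#' @return a `screen_counts` with one column and attribute `read_log`
#'   (`n_reads`, `n_no_anchor`, `n_no_match`, `n_matched`).
#' @export
count_sgrnas_from_reads <- function(fastq, library, anchor = "CACCG",
                                    sample = "sample1") {
  library <- validate_sgrna_library(library)
  reads <- as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  pos <- regexpr(anchor, reads, fixed = TRUE)
  start <- as.integer(pos) + nchar(anchor)
  has_anchor <- pos > 0L & (start + 19L) <= nchar(reads)
  guides <- substr(reads[has_anchor], start[has_anchor],
                   start[has_anchor] + 19L)
  hit <- match(guides, library$sequence)
  counts_vec <- tabulate(hit[!is.na(hit)], nbins = nrow(library))
  counts <- matrix(as.integer(counts_vec), ncol = 1,
                   dimnames = list(library$sgrna, sample))
  sc <- screen_counts(counts, setNames(library$gene, library$sgrna))
  attr(sc, "read_log") <- c(n_reads = length(reads),
                            n_no_anchor = sum(pos <= 0L),
                            n_no_match = sum(has_anchor) - sum(!is.na(hit)),
                            n_matched = sum(!is.na(hit)))
  sc
}

#' Median-of-ratios count normalization
#'
#' Size factor per sample = median over sgRNAs of the ratio between the
#' sample's count and the sgRNA's geometric mean across samples (computed
#' over sgRNAs with all-positive counts), the standard sequencing-depth
#' correction for count matrices. Scaled counts are
#' `counts / size_factor`.
#'
#' @param counts a `screen_counts`.
#' @return `screen_counts` with scaled (non-integer) counts in
#'   `$normalized` and `size_factors` attribute; original integer counts
#'   retained in `$counts`.
#' @export
normalize_counts <- function(counts) {
  m <- counts$counts
  if (any(colSums(m) == 0))
    pf_stop("degenerate_sample", "sample(s) with all-zero counts: %s",
            paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  log_gm <- rowMeans(log(m))
  use <- is.finite(log_gm)
  if (!any(use))
    pf_stop("degenerate_sample",
            "no sgRNA has positive counts in every sample")
  sf <- apply(m[use, , drop = FALSE], 2L,
              function(col) exp(median(log(col) - log_gm[use])))
  counts$normalized <- sweep(m, 2L, sf, "/")
  attr(counts, "size_factors") <- sf
  counts
}

#' Per-gene enrichment score between sorted bins
#'
#' A simplified beta-score-like statistic: per sgRNA,
#' `log2((high + c) / (low + c))` on size-factor-normalized counts with
#' pseudocount `c`; per gene, the mean over that gene's sgRNAs. Positive
#' scores mean enrichment in the high Red:Green bin (flux suppressors for
#' reporters whose ratio rises when flux is blocked). Genes with no
#' detected sgRNA are missing, not zero. Not an MLE: full count tables
#' from dedicated screen software can be fed to the downstream averaging
#' and normalization steps instead.
#'
#' @param counts a `screen_counts` containing `high` and `low` bin
#'   samples for the requested replicate (per `sample_meta`, or columns
#'   named `high_rep<k>` / `low_rep<k>`).
#' @param replicate replicate number.
#' @param pseudocount `c` above (default 0.5).
#' @return data frame `gene`, `score`, `n_sgrna`.
#' @export
gene_enrichment_score <- function(counts, replicate = 1L, pseudocount = 0.5) {
  if (is.null(counts$normalized)) counts <- normalize_counts(counts)
  meta <- counts$sample_meta
  pick <- function(bin) {
    if (!is.null(meta)) {
      s <- meta$sample[meta$bin == bin & meta$replicate == replicate]
    } else {
      s <- sprintf("%s_rep%d", bin, replicate)
    }
    if (length(s) != 1L || !(s %in% colnames(counts$normalized)))
      pf_stop("invalid_input", "no unique %s-bin sample for replicate %d",
              bin, replicate)
    counts$normalized[, s]
  }
  high <- pick("high")
  low <- pick("low")
  detected <- counts$counts[, , drop = FALSE]
  sg_detected <- rowSums(detected) > 0
  score_sg <- log2((high + pseudocount) / (low + pseudocount))
  gene <- counts$sgrna_to_gene
  keep <- sg_detected
  df <- aggregate(list(score = score_sg[keep]),
                  by = list(gene = gene[keep]), FUN = mean)
  n_sg <- aggregate(list(n_sgrna = rep(1L, sum(keep))),
                    by = list(gene = gene[keep]), FUN = sum)
  merge(df, n_sg, by = "gene")
}

#' Average per-gene scores across replicates
#'
#' Arithmetic mean over the replicates in which a gene was measured, with
#' the replicate count recorded per cell of the table.
#'
#' @param scores named list of per-replicate score data frames (`gene`,
#'   `score`), e.g. one [gene_enrichment_score()] result per replicate;
#'   list names identify the reporter when building multi-reporter tables.
#' @param reporter reporter label for the resulting column.
#' @return a `gene_score_table`: data frame `gene`, `score`,
#'   `n_replicates`, plus attribute `reporter`.
#' @export
average_replicates <- function(scores, reporter = "reporter1") {
  stopifnot(length(scores) >= 1L)
  all_genes <- sort(unique(unlist(lapply(scores, `[[`, "gene"))))
  mat <- sapply(scores, function(df) {
    df$score[match(all_genes, df$gene)]
  })
  mat <- matrix(mat, nrow = length(all_genes))
  out <- data.frame(gene = all_genes,
                    score = rowMeans(mat, na.rm = TRUE),
                    n_replicates = rowSums(!is.na(mat)))
  out$score[out$n_replicates == 0] <- NA_real_
  structure(out, class = c("gene_score_table", "data.frame"),
            reporter = reporter)
}

#' Combine per-reporter score tables into a gene x reporter matrix
#'
#' @param tables named list (reporter -> `gene_score_table` or data frame
#'   with `gene`, `score`).
#' @return numeric matrix, rows = genes, columns = reporters.
#' @export
gene_score_matrix <- function(tables) {
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene"))))
  out <- sapply(tables, function(df) df$score[match(genes, df$gene)])
  out <- matrix(out, nrow = length(genes),
                dimnames = list(genes, names(tables)))
  out
}

#' Normalize a gene-score table by a reference gene
#'
#' Divides every column of a gene x reporter score matrix by that
#' column's reference-gene score, so the reference row becomes exactly 1
#' (the convention that anchors screen heat maps on a known-null
#' knockout, canonically ATG9A). Columns where the reference is absent or
#' zero are left unscaled and flagged, never silently skipped. The
#' operation is idempotent and preserves within-column gene ranking for a
#' positive reference.
#'
#' @param scores numeric matrix (genes x reporters) or a
#'   `gene_score_table` (converted to a one-column matrix).
#' @param reference reference gene name (default `"ATG9A"`).
#' @return matrix of normalized scores with attribute
#'   `unnormalized_columns` naming flagged columns.
#' @export
normalize_by_reference_gene <- function(scores, reference = "ATG9A") {
  if (inherits(scores, "gene_score_table")) {
    m <- matrix(scores$score, ncol = 1,
                dimnames = list(scores$gene, attr(scores, "reporter")))
  } else {
    m <- as.matrix(scores)
  }
  if (!(reference %in% rownames(m)))
    pf_stop("invalid_input", "reference gene %s absent from score table",
            reference)
  ref <- m[reference, ]
  flagged <- colnames(m)[!is.finite(ref) | ref == 0]
  scale <- ifelse(!is.finite(ref) | ref == 0, 1, ref)
  out <- sweep(m, 2L, scale, "/")
  attr(out, "reference_gene") <- reference
  attr(out, "unnormalized_columns") <- flagged
  out
}

#' Read a count table in the standard screen-count layout
#'
#' Tab-separated with columns `sgRNA`, `Gene`, then one column per sample
#' (the layout emitted by common screen-counting tools).
#'
#' @param path TSV path.
#' @param sample_meta optional sample metadata (see [screen_counts()]).
#' @return a `screen_counts`.
#' @export
read_screen_counts_tsv <- function(path, sample_meta = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sgRNA", "Gene") %in% names(df)))
    pf_stop("invalid_input", "count TSV must start with sgRNA and Gene columns")
  split_map <- tapply(df$Gene, df$sgRNA, function(g) length(unique(g)))
  if (any(split_map > 1L))
    pf_stop("invalid_library", "sgRNA(s) mapped to more than one gene: %s",
            paste(head(names(split_map)[split_map > 1L], 5), collapse = ", "))
  m <- as.matrix(df[, setdiff(names(df), c("sgRNA", "Gene")), drop = FALSE])
  rownames(m) <- df$sgRNA
  screen_counts(m, setNames(df$Gene, df$sgRNA), sample_meta)
}

#' Read a gene-summary table of beta scores
#'
#' Tab-separated gene-level output with a `Gene` column and one
#' `<sample>|beta` column per condition (the layout of MLE-based screen
#' analysis gene summaries), so externally computed beta scores can feed
#' [average_replicates()] / [normalize_by_reference_gene()] directly.
#'
#' @param path TSV path.
#' @return data frame: `gene` plus one numeric column per condition.
#' @export
read_gene_summary_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!("Gene" %in% names(df)))
    pf_stop("invalid_input", "gene summary must have a Gene column")
  beta_cols <- grep("\\|beta$", names(df), value = TRUE)
  if (!length(beta_cols))
    pf_stop("invalid_input", "gene summary has no '|beta' columns")
  out <- data.frame(gene = df$Gene)
  for (bc in beta_cols)
    out[[sub("\\|beta$", "", bc)]] <- as.numeric(df[[bc]])
  out
}
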