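# Simulator of a FACS-sorted pooled CRISPR screen: each cell carries one
# sgRNA; hit genes shift the cell's Red:Green ratio; cells are sorted into
# top/bottom tails of the *realized* ratio distribution (so sorting
# misclassification noise is captured); read counts are multinomial over
# the sgRNAs collected in each bin.

#' Specification of a simulated sorted screen
#'
#' @param n_genes number of genes in the library.
#' @param sgrnas_per_gene guides per gene.
#' @param hits named numeric vector: gene name -> effect size, the shift
#'   (in log2 units) the knockout adds to a cell's log2 Red:Green ratio.
#'   Positive effects enrich in the high bin. Genes are named
#'   `gene0001 ...`; the reference gene can be planted by naming it here.
#' @param sorted_fraction tail fraction collected per bin (default 1/3:
#'   top and bottom third by realized ratio).
#' @param mean_reads_per_sgrna sequencing depth per bin (default 300,
#'   within the routine 200-400 band).
#' @param cells_per_sgrna simulated cells per guide (default 200).
#' @param cell_log2_sd SD of a cell's baseline log2 ratio (biological +
#'   measurement spread; default 1).
#' @param n_replicates independent sorted replicates (2-4 typical).
#' @param seed integer seed.
#' @return a validated `screen_sim_spec`.
#' @export
screen_sim_spec <- function(n_genes = 1000L, sgrnas_per_gene = 4L,
                            hits = c(), sorted_fraction = 1 / 3,
                            mean_reads_per_sgrna = 300,
                            cells_per_sgrna = 200L,
                            cell_log2_sd = 1,
                            n_replicates = 2L, seed = 1L) {
  if (sorted_fraction <= 0 || sorted_fraction > 0.5)
    pf_stop("invalid_spec", "sorted_fraction must lie in (0, 0.5]")
  genes <- sprintf("gene%04d", seq_len(n_genes))
  if (length(hits)) {
    if (is.null(names(hits)) || any(!nzchar(names(hits))))
      pf_stop("invalid_spec", "hits must be a named numeric vector")
    unknown <- setdiff(names(hits), genes)
    if (length(unknown))
      pf_stop("unknown_gene", "hit gene(s) not in library: %s",
              paste(unknown, collapse = ", "))
  }
  structure(list(n_genes = as.integer(n_genes),
                 sgrnas_per_gene = as.integer(sgrnas_per_gene),
                 genes = genes, hits = hits,
                 sorted_fraction = sorted_fraction,
                 mean_reads_per_sgrna = mean_reads_per_sgrna,
                 cells_per_sgrna = as.integer(cells_per_sgrna),
                 cell_log2_sd = cell_log2_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "screen_sim_spec")
}

#' Simulate a FACS-sorted CRISPR screen
#'
#' For each replicate: every simulated cell carries one sgRNA (uniform
#' over the library), its log2 Red:Green ratio is `Normal(effect,
#' cell_log2_sd)` where `effect` is the cell's gene effect (0 for
#' non-hits), cells are ranked by realized ratio and the top/bottom
#' `sorted_fraction` collected, and reads are drawn multinomially from
#' each bin's sgRNA composition at `mean_reads_per_sgrna` average depth.
#' The input sample sequences the unsorted pool the same way.
#'
#' @param spec a [screen_sim_spec()].
#' @return a `screen_counts` object (see [screen_counts()]) whose samples
#'   are named `input_rep<k>`, `high_rep<k>`, `low_rep<k>`, with a `truth`
#'   attribute recording the hit table and per-replicate bin sizes.
#' @export
simulate_sorted_screen <- function(spec) {
  with_seed(spec$seed, {
    n_sg <- spec$n_genes * spec$sgrnas_per_gene
    sg_ids <- sprintf("sg_%s_%d", rep(spec$genes, each = spec$sgrnas_per_gene),
                      rep(seq_len(spec$sgrnas_per_gene), spec$n_genes))
    sg_gene <- rep(spec$genes, each = spec$sgrnas_per_gene)
    effect <- numeric(n_sg)
    if (length(spec$hits))
      effect <- unname(ifelse(sg_gene %in% names(spec$hits),
                              spec$hits[sg_gene], 0))
    n_cells <- n_sg * spec$cells_per_sgrna
    depth <- round(spec$mean_reads_per_sgrna * n_sg)

    samples <- list()
    meta <- list()
    bin_sizes <- list()
    for (r in seq_len(spec$n_replicates)) {
      cell_sg <- sample.int(n_sg, n_cells, replace = TRUE)
      ratio <- rnorm(n_cells, mean = effect[cell_sg], sd = spec$cell_log2_sd)
      ord <- order(ratio)
      n_tail <- floor(n_cells * spec$sorted_fraction)
      low_cells <- ord[seq_len(n_tail)]
      high_cells <- ord[seq(n_cells - n_tail + 1L, n_cells)]
      comp <- function(cells) tabulate(cell_sg[cells], nbins = n_sg)
      draw <- function(weights) {
        if (sum(weights) == 0) return(integer(n_sg))
        as.vector(rmultinom(1, depth, weights))
      }
      samples[[sprintf("input_rep%d", r)]] <- draw(tabulate(cell_sg, n_sg))
      samples[[sprintf("high_rep%d", r)]] <- draw(comp(high_cells))
      samples[[sprintf("low_rep%d", r)]] <- draw(comp(low_cells))
      meta[[length(meta) + 1L]] <-
        data.frame(sample = sprintf(c("input_rep%d", "high_rep%d", "low_rep%d"), r),
                   replicate = r, bin = c("input", "high", "low"))
      bin_sizes[[r]] <- c(high = length(high_cells), low = length(low_cells),
                          middle = n_cells - 2L * n_tail)
    }
    counts <- do.call(cbind, samples)
    rownames(counts) <- sg_ids
    sc <- screen_counts(counts, setNames(sg_gene, sg_ids),
                        do.call(rbind, meta))
    attr(sc, "truth") <- list(hits = spec$hits, effects = setNames(effect, sg_ids),
                              bin_sizes = bin_sizes, n_cells = n_cells)
    sc
  })
}
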