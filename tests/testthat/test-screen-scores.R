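# Anchored sgRNA counting, count normalization, enrichment scoring,
# replicate averaging, reference-gene normalization, table readers.

make_library <- function(n = 100, seed = 1) {
  set.seed(seed)
  repeat {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""),
      character(1))
    if (!anyDuplicated(seqs)) break
  }
  data.frame(sgrna = sprintf("sg%03d", seq_len(n)),
             gene = sprintf("gene%03d", rep(seq_len(n / 4), each = 4)),
             sequence = seqs)
}

write_fastq <- function(reads, path) {
  con <- file(path, "w")
  for (i in seq_along(reads))
    writeLines(c(sprintf("@read%d", i), reads[i], "+",
                 strrep("I", nchar(reads[i]))), con)
  close(con)
}

test_that("anchored read counting recovers an exact multinomial draw", {
  lib <- make_library(100)
  set.seed(3)
  draw <- as.vector(rmultinom(1, 10000, rep(1, 100)))
  reads <- rep(paste0("NN", "CACCG", lib$sequence, "TTAGC"), draw)
  # add reads without the anchor and with an unknown guide
  reads <- c(reads, "ACGTACGTACGTACGTACGTACGTACGT",
             paste0("CACCG", strrep("A", 20), "GG"))
  fq <- tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  sc <- count_sgrnas_from_reads(fq, lib)
  expect_equal(unname(sc$counts[, 1]), draw)
  lg <- attr(sc, "read_log")
  expect_equal(unname(lg["n_no_anchor"]), 1)
  # unknown guide counts as unmatched unless it collides with the library
  expect_equal(unname(lg["n_matched"] + lg["n_no_match"] + lg["n_no_anchor"]),
               length(reads))
  # duplicate sequences rejected
  lib2 <- lib; lib2$sequence[2] <- lib2$sequence[1]
  expect_error(count_sgrnas_from_reads(fq, lib2), class = "invalid_library")
})

test_that("median-of-ratios normalization matches the closed form and DESeq2", {
  set.seed(8)
  m <- matrix(rpois(400, 100), nrow = 100,
              dimnames = list(sprintf("sg%03d", 1:100),
                              c("input", "high", "low", "extra")))
  m[, "high"] <- m[, "input"] * 2L   # sample at exactly twice the depth
  sc <- screen_counts(m, setNames(rep(sprintf("g%02d", 1:25), each = 4),
                                  rownames(m)))
  scn <- normalize_counts(sc)
  sf <- attr(scn, "size_factors")
  expect_equal(unname(sf["high"] / sf["input"]), 2, tolerance = 1e-12)
  # two identical samples get identical factors
  m2 <- cbind(a = m[, 1], b = m[, 1])
  sc2 <- normalize_counts(screen_counts(m2, sc$sgrna_to_gene))
  sfs <- attr(sc2, "size_factors")
  expect_equal(unname(sfs["a"]), unname(sfs["b"]))
  # independent oracle: DESeq2's estimator on the same matrix
  sf_oracle <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf / exp(mean(log(sf)))),
               unname(sf_oracle / exp(mean(log(sf_oracle)))),
               tolerance = 1e-8)
  # all-zero sample is degenerate
  m3 <- m; m3[, 2] <- 0L
  expect_error(normalize_counts(screen_counts(m3, sc$sgrna_to_gene)),
               class = "degenerate_sample")
})

test_that("enrichment scores follow the log2 pseudocount formula", {
  # identical bins -> all zero
  m <- matrix(50L, nrow = 8, ncol = 2,
              dimnames = list(sprintf("sg%d", 1:8),
                              c("high_rep1", "low_rep1")))
  sc <- screen_counts(m, setNames(rep(c("gA", "gB"), each = 4),
                                  rownames(m)))
  s <- gene_enrichment_score(sc, 1)
  expect_equal(s$score, c(0, 0))

  # one gene 4x enriched in high across its 4 sgRNAs -> score 2 with c=0
  m2 <- m; m2[1:4, "high_rep1"] <- 200L
  # balance depth so size factors stay 1 for the formula check
  sc2 <- screen_counts(m2, sc$sgrna_to_gene)
  sc2 <- normalize_counts(sc2)
  sf <- attr(sc2, "size_factors")
  s2 <- gene_enrichment_score(sc2, 1, pseudocount = 0)
  hand <- mean(log2((200 / sf["high_rep1"]) / (50 / sf["low_rep1"])))
  expect_equal(s2$score[s2$gene == "gA"], unname(hand), tolerance = 1e-12)
  expect_equal(s2$n_sgrna, c(4L, 4L))
})

test_that("replicate averaging records reduced n for missing genes", {
  r1 <- data.frame(gene = c("gA", "gB"), score = c(1.0, 2.0))
  r2 <- data.frame(gene = c("gA"), score = c(3.0))
  avg <- average_replicates(list(r1, r2))
  expect_equal(avg$score[avg$gene == "gA"], 2.0)
  expect_equal(avg$score[avg$gene == "gB"], 2.0)
  expect_equal(avg$n_replicates[avg$gene == "gB"], 1)
  single <- average_replicates(list(r1))
  expect_equal(single$score, r1$score)
})

test_that("reference-gene normalization fixes the reference row at 1", {
  m <- matrix(c(2, 1, 4, 3, 1.5, 6), nrow = 3,
              dimnames = list(c("ATG9A", "gB", "gC"), c("tfLC3", "tfNDP52")))
  n <- normalize_by_reference_gene(m)
  expect_equal(unname(n["ATG9A", ]), c(1, 1))
  expect_equal(unname(n["gB", "tfLC3"]), 0.5)
  # idempotence
  expect_equal(normalize_by_reference_gene(n), n,
               ignore_attr = TRUE)
  # rank preservation within a column for a positive reference
  expect_equal(order(m[, 1]), order(n[, 1]))
  # zero reference flagged, column left unscaled
  m2 <- m; m2["ATG9A", 2] <- 0
  n2 <- normalize_by_reference_gene(m2)
  expect_equal(attr(n2, "unnormalized_columns"), "tfNDP52")
  expect_equal(unname(n2[, 2]), unname(m2[, 2]))
  expect_error(normalize_by_reference_gene(m[-1, , drop = FALSE]),
               class = "invalid_input")
})

test_that("count and gene-summary readers parse the standard layouts", {
  tsv <- tempfile(fileext = ".txt")
  writeLines(c("sgRNA\tGene\ts1\ts2",
               "sgA_1\tgA\t10\t20",
               "sgA_2\tgA\t5\t2",
               "sgB_1\tgB\t7\t3"), tsv)
  sc <- read_screen_counts_tsv(tsv)
  expect_equal(dim(sc$counts), c(3L, 2L))
  expect_equal(unname(sc$sgrna_to_gene["sgB_1"]), "gB")
  # sgRNA mapped to two genes is an invalid library
  writeLines(c("sgRNA\tGene\ts1",
               "sgA_1\tgA\t10",
               "sgA_1\tgB\t5"), tsv)
  expect_error(read_screen_counts_tsv(tsv), class = "invalid_library")

  gs <- tempfile(fileext = ".txt")
  writeLines(c("Gene\tsgRNA\ttfLC3|beta\ttfLC3|fdr\ttfNDP52|beta",
               "ATG9A\t4\t-1.2\t0.001\t-0.9",
               "TMEM41B\t4\t-0.8\t0.01\t-0.7"), gs)
  tab <- read_gene_summary_tsv(gs)
  expect_equal(names(tab), c("gene", "tfLC3", "tfNDP52"))
  expect_equal(tab$tfLC3, c(-1.2, -0.8))
  # externally computed beta scores flow into reference normalization
  m <- as.matrix(tab[, -1]); rownames(m) <- tab$gene
  n <- normalize_by_reference_gene(m)
  expect_equal(unname(n["ATG9A", ]), c(1, 1))
})

test_that("FASTQ to normalized scores is deterministic end to end", {
  lib <- make_library(40)
  set.seed(5)
  draw <- as.vector(rmultinom(1, 4000, rep(1, 40)))
  reads <- rep(paste0("CACCG", lib$sequence), draw)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  one <- count_sgrnas_from_reads(fq, lib)
  two <- count_sgrnas_from_reads(fq, lib)
  expect_identical(one$counts, two$counts)
})
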