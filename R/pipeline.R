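# Orchestration: a resolved run configuration with documented defaults,
# deterministic per-stage seed fan-out, and the three runnable stages
# (image pipeline, flux statistics, screen scoring). Every run directory
# receives the fully-resolved config, a per-stage object-count log, and
# the tables needed to re-derive figure-style statistics without
# re-running segmentation.

#' Run configuration with documented defaults
#'
#' Every parameter defaults to the pipeline's documented value; a run
#' serializes its fully-resolved configuration alongside its outputs.
#' The Canny thresholds default to absolute gradient magnitudes
#' empirically determined for the synthetic default scene (quantile mode
#' is available through [canny_params()]).
#'
#' @param seed root seed; per-stage seeds are derived deterministically
#'   from it (`seed * 1000 + stage offset`) so stage subsets re-run
#'   reproducibly.
#' @param alpha background tail probability for the cell mask.
#' @param smoothing_sigma mask smoothing SD `(z, y, x)`.
#' @param speck_min_voxels speck-filter volume bound (scale with the
#'   field; the full-frame confocal default is 100000).
#' @param focus_f_min fallback focus-classifier masked-fraction floor.
#' @param nucleus_relative_threshold,nucleus_min_volume nucleus
#'   segmentation parameters.
#' @param erosion_radius in-plane cell edge erosion radius.
#' @param canny Canny parameter list from [canny_params()].
#' @param min_overlap_vox colocalization overlap rule.
#' @param reference_gene screen normalization reference.
#' @param min_events flow summary event floor.
#' @param out_dir output directory (`NULL` = no files written).
#' @param verbose print per-stage progress.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       alpha = 1e-5,
                       smoothing_sigma = c(1, 2, 2),
                       speck_min_voxels = 1000,
                       focus_f_min = 0.001,
                       nucleus_relative_threshold = 0.5,
                       nucleus_min_volume = 500,
                       erosion_radius = 2,
                       canny = canny_params(sigma = 0.8, low = 180, high = 400,
                                            quantiles = FALSE),
                       min_overlap_vox = 1,
                       reference_gene = "ATG9A",
                       min_events = 1000,
                       out_dir = NULL,
                       verbose = FALSE) {
  structure(list(seed = as.integer(seed), alpha = alpha,
                 smoothing_sigma = smoothing_sigma,
                 speck_min_voxels = speck_min_voxels,
                 focus_f_min = focus_f_min,
                 nucleus_relative_threshold = nucleus_relative_threshold,
                 nucleus_min_volume = nucleus_min_volume,
                 erosion_radius = erosion_radius,
                 canny = canny,
                 min_overlap_vox = min_overlap_vox,
                 reference_gene = reference_gene,
                 min_events = min_events,
                 out_dir = out_dir, verbose = verbose),
            class = "run_config")
}

stage_seed <- function(config, offset) (config$seed %% 2000000L) * 1000L + offset

# flat key=value serialization of the resolved config
write_config_txt <- function(config, path) {
  flat <- unlist(config[setdiff(names(config), "verbose")])
  flat <- flat[!is.na(flat) & vapply(flat, length, integer(1)) == 1L]
  lines <- sprintf("%s=%s", names(flat), vapply(flat, as.character, ""))
  writeLines(lines, path)
  invisible(path)
}

log_msg <- function(config, log, fmt, ...) {
  line <- sprintf(fmt, ...)
  if (isTRUE(config$verbose)) message(line)
  c(log, line)
}

finalize_run <- function(config, log, files) {
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config_txt(config, file.path(config$out_dir, "config.txt"))
    writeLines(log, file.path(config$out_dir, "run_log.txt"))
  }
  invisible(files)
}

#' Run the full image-analysis pipeline on one field
#'
#' Executes the complete chain: smooth the green stack, fit the
#' empty-field background model, compute and clean the cell mask (speck
#' removal, focus-plane filter), segment nuclei and cells, erode cell
#' edges, drop border cells, segment punctae in both fluorescence
#' channels, assign them to cells, count colocalization, and (when
#' `config$out_dir` is set) write the per-cell CSV, label-volume TIFFs,
#' focus log, resolved config and run log. Identical config + inputs give
#' identical outputs.
#'
#' @param stacks named list of [image_stack()]s: `green`, `red`, `blue`.
#' @param empty_field green-channel calibration [image_stack()]; its
#'   absence is a calibration error.
#' @param config a [run_config()].
#' @param focus_classifier optional trained `focus_classifier`; defaults
#'   to the fixed-threshold fallback.
#' @param field_id field identifier for the output table.
#' @return list: `table` (a `puncta_table`), `cells`, `nuclei`, `puncta_green`,
#'   `puncta_red` label volumes, `mask`, `model`, `log`.
#' @export
run_image_pipeline <- function(stacks, empty_field, config = run_config(),
                               focus_classifier = NULL, field_id = "field1") {
  for (ch in c("green", "red", "blue"))
    if (is.null(stacks[[ch]]))
      pf_stop("invalid_input", "stage input: missing %s channel stack", ch)
  if (is.null(empty_field))
    pf_stop("calibration_error",
            "stage fit_background: empty-field calibration stack is required")
  log <- character(0)

  model <- fit_background_gaussian(empty_field, config$smoothing_sigma,
                                   config$alpha)
  log <- log_msg(config, log, "background: mu=%.3f sd=%.3f cutoff=%.3f",
                 model$mu_bg, model$sigma_bg, model$cutoff)

  mask <- compute_cell_mask(stacks$green, model)
  log <- log_msg(config, log, "mask: %d voxels above cutoff", sum(mask))
  mask <- remove_small_specks(mask, config$speck_min_voxels)
  log <- log_msg(config, log, "specks: %d voxels retained", sum(mask))
  fc <- if (is.null(focus_classifier))
    fallback_focus_classifier(config$focus_f_min) else focus_classifier
  mask <- filter_out_of_focus_planes(mask, stacks$green, fc)
  focus_log <- attr(mask, "focus_log")
  log <- log_msg(config, log, "focus: %d/%d planes in focus, %d voxels",
                 sum(focus_log$in_focus), nrow(focus_log), sum(mask))

  nuclei <- segment_nuclei(stacks$blue,
                           relative_threshold = config$nucleus_relative_threshold,
                           min_volume = config$nucleus_min_volume)
  log <- log_msg(config, log, "nuclei: %d", max(nuclei))
  if (max(nuclei) == 0L)
    pf_stop("no_seeds", "stage segment_nuclei: no nuclei found to seed cells")
  cells <- segment_cells(mask, nuclei)
  cells <- erode_cell_edges(cells, config$erosion_radius)
  cells <- remove_border_cells(cells)
  n_cells <- length(setdiff(unique(as.vector(cells)), 0L))
  log <- log_msg(config, log, "cells: %d after erosion + border removal",
                 n_cells)

  pg <- segment_puncta(stacks$green, cells, config$canny)
  pr <- segment_puncta(stacks$red, cells, config$canny)
  log <- log_msg(config, log, "punctae: %d green, %d red", max(pg), max(pr))
  ag <- assign_puncta_to_cells(pg, cells)
  ar <- assign_puncta_to_cells(pr, cells)
  table <- count_colocalization(pg, pr, ag, ar, cells,
                                config$min_overlap_vox, field_id)

  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(config$out_dir, sprintf("%s_puncta.csv", field_id))
    write_puncta_csv(table, csv)
    write.csv(attr(mask, "focus_log"),
              file.path(config$out_dir, sprintf("%s_focus.csv", field_id)),
              row.names = FALSE)
    write.csv(label_table(cells),
              file.path(config$out_dir, sprintf("%s_cells.csv", field_id)),
              row.names = FALSE)
    write_label_tiff(cells, file.path(config$out_dir,
                                      sprintf("%s_cells.tif", field_id)))
    write_label_tiff(nuclei, file.path(config$out_dir,
                                       sprintf("%s_nuclei.tif", field_id)))
    files <- c(csv)
  }
  finalize_run(config, log, files)
  list(table = table, cells = cells, nuclei = nuclei, puncta_green = pg,
       puncta_red = pr, mask = mask, model = model, log = log)
}

# 16-bit label TIFF (labels above 65535 are not expected at this scale)
write_label_tiff <- function(labels, path) {
  arr <- array(as.integer(labels), dim(labels))
  pages <- lapply(seq_len(dim(arr)[1]), function(k) arr[k, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Run the flux-statistics stage
#'
#' Summarizes each sample of a per-event flow table, optionally
#' normalizes to a reference sample's median, and computes the
#' fold-repression matrix when ATG9A-null and control samples are
#' present.
#'
#' @param events data frame with columns `sample_id`, `RFP`, `GFP` (e.g.
#'   from [read_flow_csv()] or [generate_flow_population()]).
#' @param config a [run_config()].
#' @param reference_sample optional `sample_id` whose median normalizes
#'   all summaries.
#' @param sample_table optional data frame `sample_id`, `gene`,
#'   `reporter` enabling the fold-repression matrix (needs `ATG9A` and
#'   `control` gene rows per reporter).
#' @return list: `summaries` (data frame, one row per sample),
#'   `fold_repression` (matrix or NULL), `log`.
#' @export
run_flux <- function(events, config = run_config(), reference_sample = NULL,
                     sample_table = NULL) {
  ids <- unique(events$sample_id)
  log <- character(0)
  sums <- lapply(ids, function(id) {
    r <- compute_ratios(events[events$sample_id == id, ])
    s <- summarize_flux(r, min_events = config$min_events)
    c(list(sample_id = id, n_excluded = attr(r, "n_excluded")),
      s[c("median", "q25", "q75", "p10", "p90", "n")])
  })
  summaries <- do.call(rbind, lapply(sums, as.data.frame))
  log <- log_msg(config, log, "flux: %d samples, %d events",
                 length(ids), sum(summaries$n))
  if (!is.null(reference_sample)) {
    ref_med <- summaries$median[summaries$sample_id == reference_sample]
    if (length(ref_med) != 1L || ref_med <= 0)
      pf_stop("invalid_parameter", "reference sample %s not usable",
              reference_sample)
    for (f in c("median", "q25", "q75", "p10", "p90"))
      summaries[[f]] <- summaries[[f]] / ref_med
    log <- log_msg(config, log, "flux: normalized to %s", reference_sample)
  }
  fr <- NULL
  if (!is.null(sample_table)) {
    med <- merge(summaries[, c("sample_id", "median")], sample_table,
                 by = "sample_id")
    med <- data.frame(gene = med$gene, reporter = med$reporter,
                      median = med$median)
    fr <- fold_repression_matrix(med, control_gene = "control")
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(summaries, file.path(config$out_dir, "flux_summaries.csv"),
              row.names = FALSE)
    if (!is.null(fr))
      write.csv(fr, file.path(config$out_dir, "fold_repression.csv"))
  }
  finalize_run(config, log, character(0))
  list(summaries = summaries, fold_repression = fr, log = log)
}

#' Run the screen-scoring stage
#'
#' Normalizes counts, scores every replicate found in the sample
#' metadata, averages replicates, and normalizes by the reference gene.
#'
#' @param counts a `screen_counts` (e.g. from [simulate_sorted_screen()]
#'   or [read_screen_counts_tsv()]).
#' @param config a [run_config()].
#' @param reporter reporter label for the score column.
#' @return list: `scores` (per-replicate data frames), `averaged`
#'   (`gene_score_table`), `normalized` (matrix, reference row = 1),
#'   `log`.
#' @export
run_screen <- function(counts, config = run_config(), reporter = "reporter1") {
  counts <- normalize_counts(counts)
  meta <- counts$sample_meta
  reps <- if (!is.null(meta)) sort(unique(meta$replicate)) else 1L
  log <- character(0)
  log <- log_msg(config, log, "screen: %d sgRNAs, %d samples, %d replicates",
                 nrow(counts$counts), ncol(counts$counts), length(reps))
  scores <- lapply(reps, function(r) gene_enrichment_score(counts, r))
  names(scores) <- sprintf("rep%d", reps)
  averaged <- average_replicates(scores, reporter = reporter)
  normalized <- NULL
  if (config$reference_gene %in% averaged$gene) {
    normalized <- normalize_by_reference_gene(averaged,
                                              config$reference_gene)
    log <- log_msg(config, log, "screen: normalized to %s",
                   config$reference_gene)
  } else {
    log <- log_msg(config, log, "screen: reference gene %s absent; skipped",
                   config$reference_gene)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(averaged, file.path(config$out_dir, "gene_scores.csv"),
              row.names = FALSE)
    if (!is.null(normalized))
      write.csv(normalized,
                file.path(config$out_dir, "gene_scores_normalized.csv"))
  }
  finalize_run(config, log, character(0))
  list(scores = scores, averaged = averaged, normalized = normalized,
       log = log)
}
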