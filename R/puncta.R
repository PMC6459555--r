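# Puncta segmentation by per-plane Canny edge detection, assignment of
# punctae to cells by plurality vote, and object-based colocalization
# counting. Canny runs in 2D per plane (matching slice-wise processing of
# anisotropic confocal stacks); closed contours are filled, planes are
# stacked, and components are connected in 3D.

#' Canny parameters for puncta segmentation
#'
#' @param sigma in-plane Gaussian smoothing SD before gradient
#'   computation.
#' @param low,high hysteresis thresholds on gradient magnitude. With
#'   `quantiles = TRUE` (default) they are quantiles of the per-plane
#'   gradient-magnitude image (defaults q0.90 / q0.99); with
#'   `quantiles = FALSE` they are absolute gradient magnitudes, the mode
#'   to use once thresholds have been determined empirically for an
#'   imaging configuration.
#' @param min_volume,max_volume punctum volume gates in voxels; components
#'   outside `[min_volume, max_volume]` are discarded.
#' @param blank_guard a plane is skipped when its maximum gradient
#'   magnitude is below `blank_guard` times its median (pure noise has a
#'   max/median ratio around 4 at these plane sizes; real edges push it
#'   far higher). Prevents quantile thresholds from hallucinating
#'   contours on empty planes; 0 disables.
#' @return a validated `canny_params` list.
#' @export
canny_params <- function(sigma = 1.4, low = 0.90, high = 0.99,
                         quantiles = TRUE, min_volume = 4, max_volume = 10000,
                         blank_guard = 8) {
  if (low >= high)
    pf_stop("invalid_parameter", "Canny low threshold must be < high")
  if (min_volume <= 0 || max_volume <= 0 || min_volume > max_volume)
    pf_stop("invalid_parameter", "punctum volume gates must be positive and ordered")
  if (quantiles && (low < 0 || high > 1))
    pf_stop("invalid_parameter", "quantile thresholds must lie in [0, 1]")
  structure(list(sigma = sigma, low = low, high = high,
                 quantiles = quantiles, min_volume = min_volume,
                 max_volume = max_volume, blank_guard = blank_guard),
            class = "canny_params")
}

#' Segment punctae in a fluorescence channel
#'
#' Per plane: Canny edge detection (Gaussian smooth, Sobel gradients,
#' non-maximum suppression, hysteresis) followed by filling of closed
#' contours. Filled planes are stacked and 3D connected components
#' (26-connectivity) labelled; components outside the volume gates are
#' dropped, and — unless `restrict_to_cells = FALSE` — only components
#' whose centroid lies inside a cell are retained. Labels are contiguous
#' in raster order.
#'
#' @param channel green or red [image_stack()].
#' @param cells cell `label_volume` (used for the centroid restriction;
#'   may be `NULL` when `restrict_to_cells = FALSE`).
#' @param params a [canny_params()].
#' @param restrict_to_cells keep only punctae whose centroid falls inside
#'   a segmented cell. Whether out-of-cell punctae belong in field totals
#'   is ambiguous in practice; both behaviours are supported and the
#'   choice is recorded in the result's `restricted` attribute.
#' @return a `label_volume` of kind `"punctae"`.
#' @export
segment_puncta <- function(channel, cells = NULL, params = canny_params(),
                           restrict_to_cells = !is.null(cells)) {
  arr <- if (inherits(channel, "image_stack")) channel$voxels else channel
  d <- dim(arr)
  filled <- array(FALSE, d)
  for (k in seq_len(d[1]))
    filled[k, , ] <- .canny_fill_plane(arr[k, , ], params$sigma,
                                       params$low, params$high,
                                       params$quantiles, params$blank_guard)
  lab <- .label3d(filled, 26L)
  if (max(lab) == 0L) {
    out <- new_label_volume(lab, "punctae")
    attr(out, "restricted") <- restrict_to_cells
    return(out)
  }
  st <- .label_stats(lab)
  keep <- st$volume >= params$min_volume & st$volume <= params$max_volume
  if (restrict_to_cells) {
    if (is.null(cells))
      pf_stop("invalid_input", "restrict_to_cells needs a cell label volume")
    cz <- pmin(pmax(round(st$centroid_z), 1L), d[1])
    cy <- pmin(pmax(round(st$centroid_y), 1L), d[2])
    cx <- pmin(pmax(round(st$centroid_x), 1L), d[3])
    in_cell <- cells[cbind(cz, cy, cx)] > 0L
    keep <- keep & in_cell
  }
  remap <- integer(max(lab))
  remap[which(keep)] <- seq_len(sum(keep))
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  out <- new_label_volume(lab, "punctae")
  attr(out, "restricted") <- restrict_to_cells
  out
}

#' Assign punctae to cells by plurality vote
#'
#' Each punctum goes to the cell owning the plurality of its voxels; ties
#' break toward the smaller cell label; punctae with zero in-cell voxels
#' are marked unassigned (cell 0).
#'
#' @param punctae puncta `label_volume`.
#' @param cells cell `label_volume`, congruent shape.
#' @return data frame: `punctum`, `cell` (0 = unassigned), `volume_vox`,
#'   `in_cell_vox`.
#' @export
assign_puncta_to_cells <- function(punctae, cells) {
  if (!all(dim(punctae) == dim(cells)))
    pf_stop("invalid_input", "puncta and cell volumes must be congruent")
  np <- max(punctae)
  nc <- max(cells)
  if (np == 0L)
    return(data.frame(punctum = integer(0), cell = integer(0),
                      volume_vox = integer(0), in_cell_vox = integer(0)))
  votes <- .vote_counts(array(as.integer(punctae), dim(punctae)),
                        array(as.integer(cells), dim(cells)),
                        np, max(nc, 1L))
  in_cell <- votes[, seq_len(max(nc, 1L)), drop = FALSE]
  best <- apply(in_cell, 1L, which.max)        # ties -> smaller label
  best_n <- in_cell[cbind(seq_len(np), best)]
  cell <- ifelse(best_n > 0L, best, 0L)
  data.frame(punctum = seq_len(np), cell = as.integer(cell),
             volume_vox = as.integer(rowSums(votes)),
             in_cell_vox = as.integer(rowSums(in_cell)))
}

#' Count per-cell punctae and cross-channel overlaps
#'
#' A green punctum counts as overlapping when it shares at least
#' `min_overlap_vox` voxels with one or more red punctae (and
#' symmetrically). Produces the pipeline's central product: per-cell rows
#' of `n_green`, `n_red`, `n_green_overlapping_red`,
#' `n_red_overlapping_green` and the derived overlap fractions (reported
#' as `NA`, not zero, for cells with no punctae in the numerator channel),
#' plus a field-level summary row covering unassigned punctae.
#'
#' @param green,red puncta `label_volume`s of congruent shape.
#' @param assignment_green,assignment_red outputs of
#'   [assign_puncta_to_cells()] for each channel.
#' @param cells cell `label_volume` (defines the set of reported cells).
#' @param min_overlap_vox minimum shared voxels to call an overlap
#'   (default 1; boundary-kissing objects are ambiguous, so the knob is
#'   exposed).
#' @param field_id identifier stored in the table's `field` column.
#' @return a `puncta_table`: list with `cells` (per-cell data frame) and
#'   `field` (one-row totals including unassigned punctae).
#' @export
count_colocalization <- function(green, red, assignment_green, assignment_red,
                                 cells, min_overlap_vox = 1,
                                 field_id = "field1") {
  if (!all(dim(green) == dim(red)))
    pf_stop("invalid_input", "green and red volumes must be congruent")
  ng <- max(green); nr <- max(red)
  ov <- if (ng > 0 && nr > 0)
    .label_overlap(array(as.integer(green), dim(green)),
                   array(as.integer(red), dim(red)), ng, nr)
  else matrix(0L, max(ng, 1L), max(nr, 1L))
  g_hit <- if (ng > 0) apply(ov >= min_overlap_vox, 1L, any) else logical(0)
  r_hit <- if (nr > 0) apply(ov >= min_overlap_vox, 2L, any) else logical(0)

  cell_ids <- sort(setdiff(unique(as.vector(cells)), 0L))
  tab <- data.frame(field = rep(field_id, length(cell_ids)),
                    cell = cell_ids)
  cnt <- function(assign, hit, id) {
    n <- sum(assign$cell == id)
    n_ov <- sum(assign$cell == id & hit[assign$punctum])
    c(n, n_ov)
  }
  gmat <- vapply(cell_ids, function(id) cnt(assignment_green, g_hit, id),
                 numeric(2))
  rmat <- vapply(cell_ids, function(id) cnt(assignment_red, r_hit, id),
                 numeric(2))
  if (length(cell_ids)) {
    tab$n_green <- as.integer(gmat[1, ])
    tab$n_red <- as.integer(rmat[1, ])
    tab$n_green_overlapping_red <- as.integer(gmat[2, ])
    tab$n_red_overlapping_green <- as.integer(rmat[2, ])
  } else {
    tab$n_green <- tab$n_red <- integer(0)
    tab$n_green_overlapping_red <- tab$n_red_overlapping_green <- integer(0)
  }
  tab$frac_green_overlapping <- ifelse(tab$n_green > 0,
                                       tab$n_green_overlapping_red / tab$n_green,
                                       NA_real_)
  tab$frac_red_overlapping <- ifelse(tab$n_red > 0,
                                     tab$n_red_overlapping_green / tab$n_red,
                                     NA_real_)
  field <- data.frame(
    field = field_id,
    n_green_total = ng, n_red_total = nr,
    n_green_unassigned = sum(assignment_green$cell == 0L),
    n_red_unassigned = sum(assignment_red$cell == 0L),
    n_green_overlapping_red = sum(g_hit),
    n_red_overlapping_green = sum(r_hit),
    frac_green_overlapping = if (ng > 0) sum(g_hit) / ng else NA_real_,
    frac_red_overlapping = if (nr > 0) sum(r_hit) / nr else NA_real_)
  structure(list(cells = tab, field = field), class = "puncta_table")
}

#' @export
print.puncta_table <- function(x, ...) {
  cat(sprintf("<puncta_table> field %s: %d cells, %d green / %d red punctae\n",
              x$field$field[1], nrow(x$cells), x$field$n_green_total,
              x$field$n_red_total))
  invisible(x)
}

#' Write / read a puncta table as CSV
#'
#' Per-cell rows followed by a field-summary block (rows with
#' `row_type = "field"`); counts are serialized as integers and fractions
#' as decimals with 6 significant digits. The round trip through
#' [read_puncta_csv()] is lossless at that precision.
#'
#' @param table a `puncta_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_puncta_csv <- function(table, path) {
  cells <- table$cells
  field <- table$field
  fmt <- function(df) {
    for (nm in names(df))
      if (is.double(df[[nm]])) df[[nm]] <- signif(df[[nm]], 6)
    df
  }
  cells <- cbind(row_type = rep("cell", nrow(cells)), fmt(cells))
  f <- fmt(field)
  frow <- data.frame(row_type = "field", field = f$field, cell = NA_integer_,
                     n_green = f$n_green_total, n_red = f$n_red_total,
                     n_green_overlapping_red = f$n_green_overlapping_red,
                     n_red_overlapping_green = f$n_red_overlapping_green,
                     frac_green_overlapping = f$frac_green_overlapping,
                     frac_red_overlapping = f$frac_red_overlapping,
                     n_green_unassigned = f$n_green_unassigned,
                     n_red_unassigned = f$n_red_unassigned)
  cells$n_green_unassigned <- rep(NA_integer_, nrow(cells))
  cells$n_red_unassigned <- rep(NA_integer_, nrow(cells))
  out <- rbind(cells, frow[, names(cells)])
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_puncta_csv
#' @export
read_puncta_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  cells <- raw[raw$row_type == "cell",
               setdiff(names(raw), c("row_type", "n_green_unassigned",
                                     "n_red_unassigned"))]
  rownames(cells) <- NULL
  f <- raw[raw$row_type == "field", ]
  field <- data.frame(field = f$field,
                      n_green_total = f$n_green, n_red_total = f$n_red,
                      n_green_unassigned = f$n_green_unassigned,
                      n_red_unassigned = f$n_red_unassigned,
                      n_green_overlapping_red = f$n_green_overlapping_red,
                      n_red_overlapping_green = f$n_red_overlapping_green,
                      frac_green_overlapping = f$frac_green_overlapping,
                      frac_red_overlapping = f$frac_red_overlapping)
  rownames(field) <- NULL
  structure(list(cells = cells, field = field), class = "puncta_table")
}
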