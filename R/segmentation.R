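# Nucleus and cell segmentation.
#
# Nuclei: slice-by-slice relative thresholding of the DAPI channel, then
# 3D connected components with a watershed split (on the negated distance
# transform) for touching nuclei. Cells: seeded watershed flood of the
# cell mask from nucleus seeds, by geodesic distance, followed by edge
# erosion and removal of cells contacting the lateral field border.

new_label_volume <- function(lab, kind) {
  structure(lab, class = "label_volume", kind = kind)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> kind=%s, %d objects, dim %s\n",
              attr(x, "kind"), length(setdiff(unique(as.vector(x)), 0L)),
              paste(dim(x), collapse = " x ")))
  invisible(x)
}

#' Object table for a label volume
#'
#' @param labels a `label_volume` (or integer 3D array).
#' @return data frame: `label`, `volume_vox`, centroid and bounding box
#'   (1-based voxel coordinates, axis order z/y/x), and `border_flag`
#'   marking objects with voxels on the lateral (row/column) field border.
#' @export
label_table <- function(labels) {
  st <- .label_stats(array(as.integer(labels), dim(labels)))
  df <- data.frame(label = st$label, volume_vox = st$volume,
                   centroid_z = st$centroid_z, centroid_y = st$centroid_y,
                   centroid_x = st$centroid_x,
                   bbox_z0 = st$bbox_z0, bbox_z1 = st$bbox_z1,
                   bbox_y0 = st$bbox_y0, bbox_y1 = st$bbox_y1,
                   bbox_x0 = st$bbox_x0, bbox_x1 = st$bbox_x1)
  d <- dim(labels)
  df$border_flag <- !is.na(df$bbox_y0) &
    (df$bbox_y0 == 1L | df$bbox_y1 == d[2] |
     df$bbox_x0 == 1L | df$bbox_x1 == d[3])
  df[df$volume_vox > 0, , drop = FALSE]
}

# per-slice relative threshold: slice mode (256-bin histogram) plus
# relative_threshold * (slice max - mode). Slices whose dynamic range is
# indistinguishable from noise (max < mode + blank_guard_sd * robust SD)
# contribute no foreground.
slice_relative_threshold <- function(plane, relative_threshold,
                                     blank_guard_sd = 6) {
  rng <- range(plane)
  if (rng[2] <= rng[1]) return(array(FALSE, dim(plane)))
  br <- seq(rng[1], rng[2], length.out = 257L)
  h <- tabulate(findInterval(plane, br, rightmost.closed = TRUE), nbins = 256L)
  mode_val <- (br[which.max(h)] + br[which.max(h) + 1L]) / 2
  rsd <- mad(plane)   # robust noise; 0 on noiseless data (guard skipped)
  if (rsd > 0 && rng[2] < mode_val + blank_guard_sd * rsd)
    return(array(FALSE, dim(plane)))   # blank plane
  if (rsd <= 0 && rng[2] <= mode_val)
    return(array(FALSE, dim(plane)))
  plane >= mode_val + relative_threshold * (rng[2] - mode_val)
}

#' Segment nuclei from the DAPI channel
#'
#' Each plane is thresholded at `mode + relative_threshold * (max - mode)`
#' (mode from a 256-bin histogram; planes with no signal above a noise
#' guard contribute nothing). Thresholded planes are stacked, connected
#' components labelled in 3D (26-connectivity), and components holding
#' more than one strong distance-transform maximum are split by seeded
#' watershed on the negated Euclidean distance transform. Objects smaller
#' than `min_volume` voxels are discarded and labels renumbered
#' contiguously.
#'
#' @param blue DAPI-channel [image_stack()].
#' @param relative_threshold fraction in (0, 1) of the mode-to-max range;
#'   default 0.5.
#' @param min_volume minimum object volume in voxels (default 500 at the
#'   synthetic default scale).
#' @param smoothing_sigma pre-threshold blur `(z, y, x)`; default
#'   `c(1, 1, 1)`.
#' @param seed_height fraction of a component's distance-transform maximum
#'   a voxel must reach to act as a watershed seed (split sensitivity).
#' @return a `label_volume` of kind `"nuclei"`.
#' @export
segment_nuclei <- function(blue, relative_threshold = 0.5, min_volume = 500,
                           smoothing_sigma = c(1, 1, 1), seed_height = 0.7) {
  if (relative_threshold <= 0 || relative_threshold >= 1)
    pf_stop("invalid_parameter", "relative_threshold must lie in (0, 1)")
  arr <- if (inherits(blue, "image_stack")) blue$voxels else blue
  if (any(smoothing_sigma > 0))
    arr <- .gaussian_smooth3d(arr, as.numeric(smoothing_sigma))
  d <- dim(arr)
  fg <- array(FALSE, d)
  for (k in seq_len(d[1]))
    fg[k, , ] <- slice_relative_threshold(arr[k, , ], relative_threshold)
  if (!any(fg)) return(new_label_volume(array(0L, d), "nuclei"))

  step <- c(2, 1, 1)  # mild z weighting: axial sampling is coarser
  lab <- .label3d(fg, 26L)
  edt <- .edt3d(fg, step)

  # seeds: within each component, voxels reaching seed_height of the
  # component's EDT maximum; if that yields >1 seed blob, watershed-split
  nlab <- max(lab)
  vols <- tabulate(lab[lab > 0], nbins = nlab)
  comp_max <- vapply(seq_len(nlab), function(L) {
    idx <- lab == L
    if (any(idx)) max(edt[idx]) else 0
  }, numeric(1))
  out <- array(0L, d)
  next_label <- 0L
  for (L in seq_len(nlab)) {
    if (vols[L] == 0) next
    comp <- lab == L
    seeds_mask <- comp & (edt >= seed_height * comp_max[L])
    seed_lab <- .label3d(seeds_mask, 26L)
    nseeds <- max(seed_lab)
    if (nseeds <= 1L) {
      next_label <- next_label + 1L
      out[comp] <- next_label
    } else {
      ws <- .flood_priority(comp, seed_lab, -edt)
      for (s in seq_len(nseeds)) {
        next_label <- next_label + 1L
        out[ws == s] <- next_label
      }
    }
  }

  # volume gate + contiguous relabel
  if (next_label > 0) {
    vols <- tabulate(out[out > 0], nbins = next_label)
    keep <- which(vols >= min_volume)
    remap <- integer(next_label)
    remap[keep] <- seq_along(keep)
    pos <- out > 0
    out[pos] <- remap[out[pos]]
  }
  new_label_volume(out, "nuclei")
}

#' Segment cells by seeded watershed from nucleus seeds
#'
#' Floods the binary cell mask from the nucleus labels by geodesic
#' distance (26-neighbour Dijkstra with Euclidean step lengths), so every
#' masked voxel reachable from a seed joins the cell of its geodesically
#' nearest nucleus; cell label ids equal their seed nucleus ids. Masked
#' voxels unreachable from any seed stay unassigned and are reported via
#' the `unassigned_voxels` attribute.
#'
#' @param mask a `cell_mask`.
#' @param nuclei nucleus `label_volume` (nonempty).
#' @param step physical voxel edge lengths `(z, y, x)` used for geodesic
#'   step costs; default `c(2, 1, 1)` reflects coarser axial sampling.
#' @return a `label_volume` of kind `"cells"`.
#' @export
segment_cells <- function(mask, nuclei, step = c(2, 1, 1)) {
  if (max(nuclei) == 0L)
    pf_stop("no_seeds", "nucleus volume contains no labels to seed from")
  m <- array(as.logical(mask), dim(mask))
  # seeds must live inside the flooded domain
  seeds <- array(as.integer(nuclei), dim(nuclei))
  dom <- m | seeds > 0L
  lab <- .flood_geodesic(dom, seeds, as.numeric(step))
  lab[!m] <- 0L
  out <- new_label_volume(lab, "cells")
  attr(out, "unassigned_voxels") <- sum(m & lab == 0L)
  out
}

disk_offsets <- function(radius_xy, radius_z = 0, shape = c("disk", "diamond")) {
  shape <- match.arg(shape)
  offs <- expand.grid(dz = -radius_z:radius_z, dy = -radius_xy:radius_xy,
                      dx = -radius_xy:radius_xy)
  keep <- if (shape == "diamond") {
    rz <- max(radius_z, 1e-9); rxy <- max(radius_xy, 1e-9)
    abs(offs$dz) / rz + abs(offs$dy) / rxy + abs(offs$dx) / rxy <= 1 |
      (radius_z == 0 & offs$dz == 0 &
         abs(offs$dy) + abs(offs$dx) <= radius_xy)
  } else {
    rz <- max(radius_z, 1e-9); rxy <- max(radius_xy, 1e-9)
    (offs$dz / rz)^2 + (offs$dy / rxy)^2 + (offs$dx / rxy)^2 <= 1
  }
  offs <- offs[keep & !(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  as.matrix(offs[, c("dz", "dy", "dx")])
}

#' Erode cell edges
#'
#' Label-preserving morphological erosion by an anisotropy-aware
#' structuring element (default: in-plane disk of radius 2, no axial
#' erosion), trimming the blurred edge excess the probability
#' transformation includes. Labels never merge or swap; a cell annihilated
#' by erosion is dropped with a warning, not an error. Radius 0 is the
#' identity.
#'
#' @param cells cell `label_volume`.
#' @param radius_vox in-plane erosion radius (voxels).
#' @param radius_z axial erosion radius (planes), default 0.
#' @param shape `"disk"` (Euclidean ball section) or `"diamond"`
#'   (6-connected ball when `radius_vox = radius_z = 1`).
#' @return eroded `label_volume`.
#' @export
erode_cell_edges <- function(cells, radius_vox = 2, radius_z = 0,
                             shape = "disk") {
  if (radius_vox < 0 || radius_z < 0)
    pf_stop("invalid_parameter", "erosion radius must be nonnegative")
  if (radius_vox == 0 && radius_z == 0) return(cells)
  offs <- disk_offsets(radius_vox, radius_z, shape)
  before <- sort(setdiff(unique(as.vector(cells)), 0L))
  lab <- .erode_labels(array(as.integer(cells), dim(cells)),
                       matrix(as.integer(offs), ncol = 3))
  after <- sort(setdiff(unique(as.vector(lab)), 0L))
  lost <- setdiff(before, after)
  if (length(lost))
    warning(sprintf("erosion annihilated %d cell(s): %s", length(lost),
                    paste(lost, collapse = ", ")))
  new_label_volume(lab, attr(cells, "kind"))
}

#' Remove cells touching the lateral field border
#'
#' Deletes any cell with at least one voxel on the row/column boundary of
#' the field. Contact with the first or last plane alone does not trigger
#' removal: confocal stacks routinely truncate cells axially, and the
#' filter's purpose is to drop laterally cropped cells. Survivors keep
#' their labels.
#'
#' @param cells cell `label_volume`.
#' @return filtered `label_volume`.
#' @export
remove_border_cells <- function(cells) {
  d <- dim(cells)
  border_labels <- unique(c(cells[, 1, ], cells[, d[2], ],
                            cells[, , 1], cells[, , d[3]]))
  border_labels <- setdiff(border_labels, 0L)
  if (length(border_labels)) {
    lab <- array(as.integer(cells), d)
    lab[lab %in% border_labels] <- 0L
  } else {
    lab <- cells
  }
  new_label_volume(array(as.integer(lab), d), attr(cells, "kind"))
}
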