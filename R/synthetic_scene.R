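# Synthetic confocal scenes with known ground truth: nuclei (blue),
# cell bodies plus diffraction-limited punctae (green/red), matched
# empty-field calibration stacks, and full per-punctum truth records.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic two-reporter confocal scene
#'
#' Describes a field of cultured cells imaged in three channels: DAPI-style
#' nuclei (blue), and two puncta-bearing fluorescence channels (green, red)
#' with diffuse cell-body signal. Punctae are rendered as Gaussian spots
#' (diffraction-limited appearance); the whole scene is blurred with an
#' anisotropic Gaussian PSF (z SD > xy SD, mimicking confocal optics) and
#' corrupted with Poisson shot noise on signal plus additive Gaussian read
#' noise. Defaults describe a scaled-down field (13 planes of 256 x 256)
#' holding ~30 non-overlapping cells, chosen so a full pipeline run stays
#' cheap while every structural feature of the real data is present.
#'
#' Colocalization model: each green punctum independently receives a
#' coincident red partner (same centroid) with probability
#' `coloc_fraction`; `puncta_per_cell_red` is the Poisson rate of
#' *additional*, independently placed red-only punctae, so the realized
#' fraction of green punctae with a red partner is an honest binomial draw.
#'
#' @param field_shape integer length-3 `(planes, rows, columns)`.
#' @param n_cells number of cells to place.
#' @param nucleus_radius_vox in-plane nucleus radius (voxels); the axial
#'   semi-axis is half of this.
#' @param cell_radius_vox in-plane cell-body radius (voxels).
#' @param cell_halfdepth_vox axial half-extent of the cell body (planes).
#' @param puncta_per_cell_green,puncta_per_cell_red Poisson means of green
#'   punctae and of red-only punctae per cell.
#' @param coloc_fraction probability in `[0, 1]` that a green punctum has a
#'   coincident red partner.
#' @param puncta_radius_vox in-plane Gaussian SD of a rendered punctum.
#' @param psf_sigma_vox per-axis PSF blur SD `(z, y, x)` in voxels.
#' @param bg_mean,bg_sd background (camera offset) mean and read-noise SD.
#' @param signal_amplitude peak punctum intensity above local diffuse
#'   signal, before PSF blur.
#' @param cytoplasm_amplitude diffuse green cell-body intensity above
#'   background (the red channel carries 40% of it).
#' @param nucleus_amplitude blue-channel nucleus intensity above background.
#' @param noise_model `"poisson_gaussian"` (shot noise on signal + Gaussian
#'   read noise), `"gaussian"` (read noise only) or `"none"`.
#' @param max_place_retries rejection-sampling cap for cell placement; a
#'   field too crowded to satisfy the non-overlap constraint fails loudly.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return a validated `scene_spec` list.
#' @export
scene_spec <- function(field_shape = c(13L, 256L, 256L),
                       n_cells = 30L,
                       nucleus_radius_vox = 8,
                       cell_radius_vox = 14,
                       cell_halfdepth_vox = 4,
                       puncta_per_cell_green = 6,
                       puncta_per_cell_red = 1.5,
                       coloc_fraction = 0.5,
                       puncta_radius_vox = 1.0,
                       psf_sigma_vox = c(0.8, 0.5, 0.5),
                       bg_mean = 100,
                       bg_sd = 10,
                       signal_amplitude = 500,
                       cytoplasm_amplitude = 75,
                       nucleus_amplitude = 400,
                       noise_model = c("poisson_gaussian", "gaussian", "none"),
                       max_place_retries = 1000L,
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  spec <- list(field_shape = as.integer(field_shape), n_cells = as.integer(n_cells),
               nucleus_radius_vox = nucleus_radius_vox,
               cell_radius_vox = cell_radius_vox,
               cell_halfdepth_vox = cell_halfdepth_vox,
               puncta_per_cell_green = puncta_per_cell_green,
               puncta_per_cell_red = puncta_per_cell_red,
               coloc_fraction = coloc_fraction,
               puncta_radius_vox = puncta_radius_vox,
               psf_sigma_vox = as.numeric(psf_sigma_vox),
               bg_mean = bg_mean, bg_sd = bg_sd,
               signal_amplitude = signal_amplitude,
               cytoplasm_amplitude = cytoplasm_amplitude,
               nucleus_amplitude = nucleus_amplitude,
               noise_model = noise_model,
               max_place_retries = as.integer(max_place_retries),
               seed = as.integer(seed))
  validate_scene_spec(spec)
  structure(spec, class = "scene_spec")
}

validate_scene_spec <- function(spec) {
  if (length(spec$field_shape) != 3L || any(spec$field_shape < 1L))
    pf_stop("invalid_spec", "field_shape must be 3 positive integers")
  if (spec$coloc_fraction < 0 || spec$coloc_fraction > 1)
    pf_stop("invalid_spec", "coloc_fraction must lie in [0, 1]")
  if (spec$nucleus_radius_vox <= 0 || spec$cell_radius_vox <= 0 ||
      spec$puncta_radius_vox <= 0)
    pf_stop("invalid_spec", "all radii must be positive")
  if (spec$puncta_per_cell_green < 0 || spec$puncta_per_cell_red < 0)
    pf_stop("invalid_spec", "puncta rates must be nonnegative")
  if (spec$bg_sd < 0) pf_stop("invalid_spec", "bg_sd must be nonnegative")
  if (spec$nucleus_radius_vox >= spec$cell_radius_vox)
    pf_stop("invalid_spec", "nucleus must fit inside the cell body")
  invisible(spec)
}

apply_noise <- function(signal, spec) {
  # observed = bg_mean + shot(signal) + read noise; unit camera gain
  out <- signal + spec$bg_mean
  if (spec$noise_model == "poisson_gaussian") {
    shot <- array(rpois(length(signal), pmax(signal, 0)), dim(signal))
    out <- shot + spec$bg_mean
  }
  if (spec$noise_model %in% c("poisson_gaussian", "gaussian") && spec$bg_sd > 0)
    out <- out + array(rnorm(length(out), 0, spec$bg_sd), dim(out))
  out
}

#' Generate an empty calibration field
#'
#' A stack containing only background: the green-channel "empty field"
#' acquisition used to calibrate the cell-mask background model.
#'
#' @param spec a [scene_spec()].
#' @return an [image_stack()] (channel green).
#' @export
generate_empty_field <- function(spec) {
  validate_scene_spec(spec)
  with_seed(spec$seed, {
    sig <- array(0, spec$field_shape)
    image_stack(apply_noise(sig, spec), channel = "green")
  })
}

# place n cell centres by rejection sampling (non-overlapping bodies,
# clear of the lateral field border)
place_cells <- function(spec) {
  nz <- spec$field_shape[1]; ny <- spec$field_shape[2]; nx <- spec$field_shape[3]
  margin <- spec$cell_radius_vox + 5
  if (2 * margin >= min(ny, nx))
    pf_stop("placement_error", "field too small for cell radius %g",
            spec$cell_radius_vox)
  minsep <- 2 * spec$cell_radius_vox + 1
  cy <- numeric(0); cx <- numeric(0); cz <- numeric(0)
  zmid <- (nz + 1) / 2
  for (i in seq_len(spec$n_cells)) {
    placed <- FALSE
    for (try in seq_len(spec$max_place_retries)) {
      y <- runif(1, margin, ny - margin)
      x <- runif(1, margin, nx - margin)
      if (length(cy) == 0 || all((cy - y)^2 + (cx - x)^2 >= minsep^2)) {
        cy <- c(cy, y); cx <- c(cx, x)
        cz <- c(cz, zmid + sample(-1:1, 1))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      pf_stop("placement_error",
              paste("could not place cell %d of %d without body overlap",
                    "(min centre separation %g voxels) within %d retries"),
              i, spec$n_cells, minsep, spec$max_place_retries)
  }
  data.frame(cell = seq_len(spec$n_cells), z = cz, y = cy, x = cx)
}

# place puncta sites inside one cell: distinct xy positions (axially
# stacked spots are unresolvable at confocal z sampling, so the generator
# keeps lateral separation >= min_xy_sep)
place_sites <- function(n, centre, spec, existing_yx, min_xy_sep = 5,
                        edge_margin = 3.5, tries = 200) {
  rmax <- spec$cell_radius_vox - edge_margin
  hz <- spec$cell_halfdepth_vox
  out <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(tries)) {
      r <- rmax * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      y <- centre$y + r * sin(th); x <- centre$x + r * cos(th)
      z <- runif(1, centre$z - hz + 1.2, centre$z + hz - 1.2)
      all_yx <- rbind(existing_yx, out[, 2:3, drop = FALSE])
      if (nrow(all_yx) == 0 ||
          all((all_yx[, 1] - y)^2 + (all_yx[, 2] - x)^2 >= min_xy_sep^2)) {
        out <- rbind(out, c(z, y, x))
        ok <- TRUE
        break
      }
    }
    if (!ok) break  # cell saturated; truth records only placed punctae
  }
  out
}

# add a Gaussian spot in place (bounding-box render)
render_spot <- function(arr, z, y, x, amp, sz, sxy) {
  d <- dim(arr)
  z0 <- max(1, floor(z - 4 * sz)); z1 <- min(d[1], ceiling(z + 4 * sz))
  y0 <- max(1, floor(y - 4 * sxy)); y1 <- min(d[2], ceiling(y + 4 * sxy))
  x0 <- max(1, floor(x - 4 * sxy)); x1 <- min(d[3], ceiling(x + 4 * sxy))
  gz <- exp(-0.5 * ((z0:z1) - z)^2 / sz^2)
  gy <- exp(-0.5 * ((y0:y1) - y)^2 / sxy^2)
  gx <- exp(-0.5 * ((x0:x1) - x)^2 / sxy^2)
  arr[z0:z1, y0:y1, x0:x1] <- arr[z0:z1, y0:y1, x0:x1] +
    amp * (gz %o% gy %o% gx)
  arr
}

#' Generate a ground-truthed synthetic scene
#'
#' Renders the three channels of a [scene_spec()] field and returns both
#' the noisy stacks and the full ground truth: true cell and nucleus label
#' volumes, per-punctum centroids with colocalization partners, and
#' per-cell realized counts.
#'
#' @param spec a [scene_spec()].
#' @return a list with elements `stacks` (named list of [image_stack()]s:
#'   `green`, `red`, `blue`), `empty_field` (matching calibration stack)
#'   and `truth` (list: `cells` data frame with centres and
#'   `border_touching` flags, `puncta` data frame with one row per punctum
#'   — `cell`, `channel`, `z`, `y`, `x`, `punctum_id`, `partner_id` — and
#'   label arrays `cell_labels`, `nucleus_labels`).
#' @export
generate_scene <- function(spec) {
  validate_scene_spec(spec)
  with_seed(spec$seed, {
    d <- spec$field_shape
    centres <- place_cells(spec)
    green <- array(0, d); red <- array(0, d); blue <- array(0, d)
    cell_lab <- array(0L, d); nuc_lab <- array(0L, d)

    # geometry masks per cell (bounding-box loops keep this cheap)
    zc_idx <- seq_len(d[1]); yc_idx <- seq_len(d[2]); xc_idx <- seq_len(d[3])
    for (i in seq_len(nrow(centres))) {
      ct <- centres[i, ]
      r <- spec$cell_radius_vox; hz <- spec$cell_halfdepth_vox
      rn <- spec$nucleus_radius_vox; rnz <- rn / 2
      z0 <- max(1, floor(ct$z - hz)); z1 <- min(d[1], ceiling(ct$z + hz))
      y0 <- max(1, floor(ct$y - r)); y1 <- min(d[2], ceiling(ct$y + r))
      x0 <- max(1, floor(ct$x - r)); x1 <- min(d[3], ceiling(ct$x + r))
      zz <- z0:z1; yy <- y0:y1; xx <- x0:x1
      dy2 <- (yy - ct$y)^2; dx2 <- (xx - ct$x)^2
      inplane <- outer(dy2, dx2, "+") <= r^2          # rows x cols
      body <- outer(rep(TRUE, length(zz)), inplane) & TRUE
      dim(body) <- c(length(zz), length(yy), length(xx))
      sub <- cell_lab[zz, yy, xx, drop = FALSE]
      sub[body] <- i
      cell_lab[zz, yy, xx] <- sub
      gsub <- green[zz, yy, xx, drop = FALSE]
      gsub[body] <- gsub[body] + spec$cytoplasm_amplitude
      green[zz, yy, xx] <- gsub
      rsub <- red[zz, yy, xx, drop = FALSE]
      rsub[body] <- rsub[body] + 0.4 * spec$cytoplasm_amplitude
      red[zz, yy, xx] <- rsub
      # nucleus ellipsoid
      ell <- array(0, c(length(zz), length(yy), length(xx)))
      dz2 <- ((zz - ct$z) / rnz)^2
      for (k in seq_along(zz)) {
        ell[k, , ] <- outer(dy2 / rn^2, dx2 / rn^2, "+") + dz2[k]
      }
      nsub <- nuc_lab[zz, yy, xx, drop = FALSE]
      nsub[ell <= 1] <- i
      nuc_lab[zz, yy, xx] <- nsub
      bsub <- blue[zz, yy, xx, drop = FALSE]
      bsub[ell <= 1] <- bsub[ell <= 1] + spec$nucleus_amplitude
      blue[zz, yy, xx] <- bsub
    }

    # punctae
    sxy <- spec$puncta_radius_vox
    sz <- 0.8
    puncta <- list()
    pid <- 0L
    for (i in seq_len(nrow(centres))) {
      ct <- centres[i, ]
      ng <- rpois(1, spec$puncta_per_cell_green)
      nr <- rpois(1, spec$puncta_per_cell_red)
      gsites <- place_sites(ng, ct, spec, matrix(numeric(0), ncol = 2))
      paired <- if (nrow(gsites) > 0)
        runif(nrow(gsites)) < spec$coloc_fraction else logical(0)
      rsites <- place_sites(nr, ct, spec,
                            gsites[, 2:3, drop = FALSE])
      for (j in seq_len(nrow(gsites))) {
        pid <- pid + 1L; gid <- pid
        green <- render_spot(green, gsites[j, 1], gsites[j, 2], gsites[j, 3],
                             spec$signal_amplitude, sz, sxy)
        rid <- NA_integer_
        if (paired[j]) {
          pid <- pid + 1L; rid <- pid
          red <- render_spot(red, gsites[j, 1], gsites[j, 2], gsites[j, 3],
                             spec$signal_amplitude, sz, sxy)
          puncta[[length(puncta) + 1L]] <-
            data.frame(cell = i, channel = "red", z = gsites[j, 1],
                       y = gsites[j, 2], x = gsites[j, 3], punctum_id = rid,
                       partner_id = gid)
        }
        puncta[[length(puncta) + 1L]] <-
          data.frame(cell = i, channel = "green", z = gsites[j, 1],
                     y = gsites[j, 2], x = gsites[j, 3], punctum_id = gid,
                     partner_id = rid)
      }
      for (j in seq_len(nrow(rsites))) {
        pid <- pid + 1L
        red <- render_spot(red, rsites[j, 1], rsites[j, 2], rsites[j, 3],
                           spec$signal_amplitude, sz, sxy)
        puncta[[length(puncta) + 1L]] <-
          data.frame(cell = i, channel = "red", z = rsites[j, 1],
                     y = rsites[j, 2], x = rsites[j, 3], punctum_id = pid,
                     partner_id = NA_integer_)
      }
    }
    puncta <- if (length(puncta)) do.call(rbind, puncta) else
      data.frame(cell = integer(0), channel = character(0), z = numeric(0),
                 y = numeric(0), x = numeric(0), punctum_id = integer(0),
                 partner_id = integer(0))

    # PSF blur then noise, per channel
    psf <- spec$psf_sigma_vox
    green <- .gaussian_smooth3d(green, psf)
    red <- .gaussian_smooth3d(red, psf)
    blue <- .gaussian_smooth3d(blue, psf)
    stacks <- list(green = image_stack(apply_noise(green, spec), "green"),
                   red = image_stack(apply_noise(red, spec), "red"),
                   blue = image_stack(apply_noise(blue, spec), "blue"))
    empty <- image_stack(apply_noise(array(0, d), spec), "green")

    border <- centres$y - spec$cell_radius_vox < 1 |
      centres$y + spec$cell_radius_vox > d[2] |
      centres$x - spec$cell_radius_vox < 1 |
      centres$x + spec$cell_radius_vox > d[3]
    centres$border_touching <- border
    list(stacks = stacks, empty_field = empty,
         truth = list(cells = centres, puncta = puncta,
                      cell_labels = cell_lab, nucleus_labels = nuc_lab))
  })
}

#' Write a scene's ground truth as plain CSV
#'
#' One file per punctum table and per-cell table, round-trippable with
#' [utils::read.csv()].
#'
#' @param scene result of [generate_scene()].
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_scene_truth_csv <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, "truth_puncta.csv")
  cp <- file.path(dir, "truth_cells.csv")
  write.csv(scene$truth$puncta, pp, row.names = FALSE)
  write.csv(scene$truth$cells, cp, row.names = FALSE)
  invisible(c(puncta = pp, cells = cp))
}
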