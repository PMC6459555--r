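#' Single-channel 3D image stack
#'
#' The unit consumed by all image operations: one fluorescence channel's
#' voxel grid with the package's fixed axis order `(plane, row, column)`,
#' i.e. `dim(voxels) == c(n_planes, n_rows, n_columns)`. Plane `k` of a
#' stack `s` is the matrix `s$voxels[k, , ]`.
#'
#' @param voxels numeric 3D array of finite, nonnegative intensities with
#'   axis order (plane, row, column).
#' @param channel one of `"green"`, `"red"`, `"blue"`.
#' @param voxel_size optional numeric length-3 `(z, y, x)` physical voxel
#'   edge lengths (same arbitrary unit on all axes); used only where
#'   anisotropy matters (distance transforms, watershed step lengths).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(voxels, channel = c("green", "red", "blue"),
                        voxel_size = NULL) {
  channel <- match.arg(channel)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    pf_stop("invalid_input", "voxels must be a 3D array (plane, row, column)")
  if (dim(voxels)[1] < 1L)
    pf_stop("invalid_input", "stack needs at least one plane")
  if (!all(is.finite(voxels)))
    pf_stop("invalid_input", "stack contains non-finite intensities")
  if (!is.null(voxel_size)) {
    stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
    voxel_size <- as.numeric(voxel_size)
  }
  structure(list(voxels = voxels, channel = channel, voxel_size = voxel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> channel=%s  %d planes x %d rows x %d cols\n",
              x$channel, d[1], d[2], d[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Gaussian-smooth an image stack
#'
#' Separable Gaussian filtering with mirror boundary handling; the kernel
#' is sampled out to 4 standard deviations and normalised to unit sum, so
#' constants pass through unchanged and the stack mean is preserved up to
#' boundary-handling error. `sigma = 0` on an axis skips that axis;
#' `sigma = c(0, 0, 0)` returns the input values unchanged.
#'
#' @param stack an [image_stack()] (a bare 3D array is also accepted).
#' @param sigma numeric length-3 per-axis blur SD in voxels `(z, y, x)`,
#'   or one value recycled to all axes.
#' @return an object of the same type as `stack` with filtered voxels.
#' @export
smooth_stack <- function(stack, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  if (length(sigma) != 3L || any(!is.finite(sigma)) || any(sigma < 0))
    pf_stop("invalid_parameter", "sigma must be 3 finite nonnegative values")
  arr <- if (inherits(stack, "image_stack")) stack$voxels else stack
  sm <- .gaussian_smooth3d(arr, as.numeric(sigma))
  if (inherits(stack, "image_stack")) {
    stack$voxels <- sm
    stack
  } else {
    sm
  }
}

#' Write / read a stack as multi-page TIFF
#'
#' One page per plane, plane-major order, 32-bit float samples. Intensities
#' are stored divided by `scale` so arbitrary dynamic ranges survive the
#' TIFF float format round trip exactly.
#'
#' @param stack an [image_stack()].
#' @param path output file.
#' @param scale divisor applied before writing (and re-applied on read).
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, scale = 65535) {
  arr <- stack$voxels
  pages <- lapply(seq_len(dim(arr)[1]), function(k) arr[k, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param channel,voxel_size passed to [image_stack()] on read.
#' @export
read_stack_tiff <- function(path, channel = "green", voxel_size = NULL,
                            scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0, c(length(pages), d[1], d[2]))
  for (k in seq_along(pages)) arr[k, , ] <- pages[[k]] * scale
  image_stack(arr, channel = channel, voxel_size = voxel_size)
}
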