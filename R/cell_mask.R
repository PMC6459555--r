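# Empty-field background modelling and cell-mask construction.
#
# The rule reproduced here: fit a Gaussian to the smoothed empty-field
# green-channel intensity distribution, then call a voxel "cell" when the
# probability that its (identically smoothed) intensity arose from
# background falls below alpha (default 1e-5). The test is one-sided
# upper tail: fluorescent foreground is strictly brighter than background.

#' Fit the empty-field Gaussian background model
#'
#' Smooths the empty-field stack with `smoothing_sigma` and takes the
#' sample mean and SD of the smoothed voxel intensities (method of
#' moments, which for a Gaussian is also the MLE). A robust variant
#' (median / 1.4826 MAD) is available for calibration fields suspected to
#' contain debris.
#'
#' @param empty_field an [image_stack()] of a cell-free field (>= 1000
#'   voxels).
#' @param smoothing_sigma per-axis Gaussian blur SD `(z, y, x)` in voxels,
#'   applied identically during calibration and application; default
#'   `c(1, 2, 2)`.
#' @param alpha upper-tail probability below which a voxel is called cell;
#'   must lie in (0, 0.5).
#' @param robust use median/MAD instead of mean/SD.
#' @return a `background_model` with fields `mu_bg`, `sigma_bg`, `alpha`,
#'   `smoothing_sigma` and the closed-form intensity `cutoff`
#'   `mu_bg + qnorm(1 - alpha) * sigma_bg`.
#' @export
fit_background_gaussian <- function(empty_field, smoothing_sigma = c(1, 2, 2),
                                    alpha = 1e-5, robust = FALSE) {
  arr <- if (inherits(empty_field, "image_stack")) empty_field$voxels
         else empty_field
  if (length(arr) < 1000)
    pf_stop("invalid_input", "empty field must contain at least 1000 voxels")
  if (alpha <= 0 || alpha >= 0.5)
    pf_stop("invalid_parameter", "alpha must lie in (0, 0.5)")
  if (length(smoothing_sigma) == 1L) smoothing_sigma <- rep(smoothing_sigma, 3L)
  sm <- if (all(smoothing_sigma == 0)) arr
        else .gaussian_smooth3d(arr, as.numeric(smoothing_sigma))
  if (robust) {
    mu <- median(sm)
    sg <- mad(sm)
  } else {
    mu <- mean(sm)
    sg <- sd(as.vector(sm))
  }
  if (!is.finite(sg) || sg <= 0)
    pf_stop("degenerate_model",
            "empty field has zero intensity variance; cannot define a tail")
  structure(list(mu_bg = mu, sigma_bg = sg, alpha = alpha,
                 smoothing_sigma = as.numeric(smoothing_sigma),
                 cutoff = mu + qnorm(1 - alpha) * sg,
                 robust = robust),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(
    "<background_model> mu=%.4g sd=%.4g alpha=%g -> cutoff %.4g (sigma %s)\n",
    x$mu_bg, x$sigma_bg, x$alpha, x$cutoff,
    paste(x$smoothing_sigma, collapse = ",")))
  invisible(x)
}

#' Compute the cell mask from a background model
#'
#' Marks every voxel whose upper-tail background probability under
#' `Normal(mu_bg, sigma_bg)` is below `alpha` — equivalently, whose
#' intensity exceeds the closed-form cutoff `mu_bg + z[1-alpha] * sigma_bg`
#' (the equivalence is exercised by the test suite). The stack is smoothed
#' here with the model's own `smoothing_sigma` unless `presmoothed = TRUE`.
#'
#' @param stack green-channel [image_stack()].
#' @param model a `background_model` from [fit_background_gaussian()].
#' @param presmoothed set `TRUE` if `stack` was already smoothed with
#'   `model$smoothing_sigma`.
#' @return a `cell_mask`: logical array congruent with the stack plus a
#'   `provenance` attribute recording the model and filters applied.
#' @export
compute_cell_mask <- function(stack, model, presmoothed = FALSE) {
  arr <- if (inherits(stack, "image_stack")) stack$voxels else stack
  if (!all(is.finite(arr)))
    pf_stop("invalid_input", "stack contains non-finite intensities")
  if (!presmoothed && any(model$smoothing_sigma > 0))
    arr <- .gaussian_smooth3d(arr, model$smoothing_sigma)
  p_bg <- pnorm(arr, mean = model$mu_bg, sd = model$sigma_bg,
                lower.tail = FALSE)
  m <- array(p_bg < model$alpha, dim(arr))
  new_cell_mask(m, list(model = model, filters = character(0)))
}

new_cell_mask <- function(mask, provenance) {
  structure(mask, class = "cell_mask", provenance = provenance)
}

#' @export
print.cell_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<cell_mask> %d x %d x %d, %.2f%% foreground (filters: %s)\n",
              d[1], d[2], d[3], 100 * mean(x),
              paste(attr(x, "provenance")$filters, collapse = " -> ")))
  invisible(x)
}

#' Remove small specks from a binary mask
#'
#' Deletes every 3D connected component (26-connectivity) whose volume is
#' strictly below `min_voxels`; components at or above the boundary are
#' untouched. The default reproduces the debris filter used on full-size
#' confocal fields ("< 100,000 voxels"); scale it with the field.
#'
#' @param mask a `cell_mask` (or logical 3D array).
#' @param min_voxels strict lower volume bound for surviving components.
#' @return filtered mask of the same class.
#' @export
remove_small_specks <- function(mask, min_voxels = 100000) {
  m <- mask
  lab <- .label3d(array(as.logical(m), dim(m)), 26L)
  if (max(lab) > 0) {
    vol <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(vol >= min_voxels)
    m <- array(lab %in% keep, dim(m))
  } else {
    m <- array(FALSE, dim(m))
  }
  prov <- attr(mask, "provenance")
  if (is.null(prov)) prov <- list(filters = character(0))
  prov$filters <- c(prov$filters, sprintf("specks<%g", min_voxels))
  new_cell_mask(m, prov)
}

# ---------------------------------------------------------------------------
# Out-of-focus plane filtering
# ---------------------------------------------------------------------------

#' Per-plane focus features
#'
#' Three features per plane, used both by the trained classifier and the
#' fixed-threshold fallback: the fraction of masked voxels, the mean
#' intensity inside the mask (0 when the plane has no masked voxels), and
#' the mean in-plane gradient magnitude of the intensity image.
#'
#' @param mask a `cell_mask`.
#' @param stack the matching [image_stack()].
#' @return data frame with one row per plane: `plane`, `masked_fraction`,
#'   `mean_masked_intensity`, `mean_gradient`.
#' @export
plane_focus_features <- function(mask, stack) {
  arr <- if (inherits(stack, "image_stack")) stack$voxels else stack
  nz <- dim(arr)[1]
  out <- data.frame(plane = seq_len(nz), masked_fraction = 0,
                    mean_masked_intensity = 0, mean_gradient = 0)
  for (k in seq_len(nz)) {
    pm <- mask[k, , ]
    pi <- arr[k, , ]
    out$masked_fraction[k] <- mean(pm)
    out$mean_masked_intensity[k] <- if (any(pm)) mean(pi[pm]) else 0
    gy <- diff(pi)          # row differences
    gx <- t(diff(t(pi)))    # column differences
    out$mean_gradient[k] <- mean(abs(gy)) + mean(abs(gx))
  }
  out
}

#' Train the focus-plane classifier
#'
#' A linear maximum-margin classifier (linear-kernel support vector
#' machine) on the three [plane_focus_features()], trained on labelled
#' planes from synthetic scenes. Features are standardized internally.
#'
#' @param features data frame from [plane_focus_features()] (rows pooled
#'   over training scenes).
#' @param in_focus logical vector, one element per feature row.
#' @return a `focus_classifier`.
#' @export
train_focus_classifier <- function(features, in_focus) {
  x <- as.matrix(features[, c("masked_fraction", "mean_masked_intensity",
                              "mean_gradient")])
  y <- factor(in_focus, levels = c(FALSE, TRUE))
  if (nlevels(droplevels(y)) < 2L)
    pf_stop("invalid_input", "training planes must include both classes")
  fit <- e1071::svm(x, y, kernel = "linear", scale = TRUE)
  structure(list(kind = "svm", fit = fit), class = "focus_classifier")
}

#' Fixed-threshold fallback focus classifier
#'
#' Declares a plane out of focus when its masked-voxel fraction falls
#' below `f_min`. Used when no trained classifier is available.
#'
#' @param f_min masked-fraction threshold (default 0.001).
#' @return a `focus_classifier`.
#' @export
fallback_focus_classifier <- function(f_min = 0.001) {
  structure(list(kind = "threshold", f_min = f_min),
            class = "focus_classifier")
}

predict_focus <- function(classifier, features) {
  if (classifier$kind == "threshold")
    return(features$masked_fraction >= classifier$f_min)
  x <- as.matrix(features[, c("masked_fraction", "mean_masked_intensity",
                              "mean_gradient")])
  as.logical(predict(classifier$fit, x) == "TRUE")
}

#' Zero out-of-focus planes from the cell mask
#'
#' Classifies each plane with the supplied `focus_classifier` and zeroes
#' the mask on planes called out of focus; in-focus planes are untouched.
#' The per-plane decision and feature vector are attached as the
#' `focus_log` attribute (and written to CSV by the pipeline).
#'
#' @param mask a `cell_mask`.
#' @param stack the matching [image_stack()].
#' @param classifier a `focus_classifier` from [train_focus_classifier()]
#'   or [fallback_focus_classifier()]; `NULL` raises a not-ready error.
#' @return filtered mask with attribute `focus_log`.
#' @export
filter_out_of_focus_planes <- function(mask, stack, classifier) {
  if (is.null(classifier) || !inherits(classifier, "focus_classifier"))
    pf_stop("not_ready", "no focus classifier supplied (train one or use the fallback)")
  feats <- plane_focus_features(mask, stack)
  keep <- predict_focus(classifier, feats)
  m <- mask
  for (k in which(!keep)) m[k, , ] <- FALSE
  prov <- attr(mask, "provenance")
  if (is.null(prov)) prov <- list(filters = character(0))
  prov$filters <- c(prov$filters, sprintf("focus(%s)", classifier$kind))
  out <- new_cell_mask(array(m, dim(mask)), prov)
  attr(out, "focus_log") <- cbind(feats, in_focus = keep)
  out
}

#' @importFrom stats mad predict
NULL
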