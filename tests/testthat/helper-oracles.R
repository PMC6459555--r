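# Independent oracles used to freeze expected values. Each is a direct,
# brute-force formulation kept deliberately separate from the package's
# own implementation path.

# dense 3D Gaussian convolution with mirror boundaries (O(n * k^3))
oracle_gauss3d <- function(arr, sigma) {
  d <- dim(arr)
  r <- ceiling(4 * sigma)
  ax <- lapply(1:3, function(i) {
    k <- exp(-0.5 * ((-r[i]):(r[i]))^2 / sigma[i]^2)
    k / sum(k)
  })
  refl <- function(i, n) {
    if (n == 1) return(rep(1L, length(i)))
    per <- 2 * (n - 1)
    i <- (i - 1) %% per
    i[i < 0] <- i[i < 0] + per
    i[i >= n] <- per - i[i >= n]
    i + 1L
  }
  out <- array(0, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    acc <- 0
    for (a in -r[1]:r[1]) for (b in -r[2]:r[2]) for (cc in -r[3]:r[3]) {
      acc <- acc + ax[[1]][a + r[1] + 1] * ax[[2]][b + r[2] + 1] *
        ax[[3]][cc + r[3] + 1] *
        arr[refl(z + a, d[1]), refl(y + b, d[2]), refl(x + cc, d[3])]
    }
    out[z, y, x] <- acc
  }
  out
}

# brute-force 3D connected components (26- or 6-connectivity)
oracle_label3d <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  nb <- nb[!(nb$dz == 0 & nb$dy == 0 & nb$dx == 0), ]
  if (connectivity == 6)
    nb <- nb[abs(nb$dz) + abs(nb$dy) + abs(nb$dx) == 1, ]
  nxt <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (row in seq_len(nrow(idx))) {
    p <- idx[row, ]
    if (lab[p[1], p[2], p[3]] != 0L) next
    nxt <- nxt + 1L
    stack <- list(p)
    lab[p[1], p[2], p[3]] <- nxt
    while (length(stack)) {
      q <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        z <- q[1] + nb$dz[k]; y <- q[2] + nb$dy[k]; x <- q[3] + nb$dx[k]
        if (z < 1 || z > d[1] || y < 1 || y > d[2] || x < 1 || x > d[3]) next
        if (mask[z, y, x] && lab[z, y, x] == 0L) {
          lab[z, y, x] <- nxt
          stack[[length(stack) + 1L]] <- c(z, y, x)
        }
      }
    }
  }
  lab
}

# Dijkstra geodesic distances from seed voxels within a mask (tiny fixtures)
oracle_geodesic_labels <- function(mask, seeds, step = c(2, 1, 1)) {
  d <- dim(mask)
  nb <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  nb <- nb[!(nb$dz == 0 & nb$dy == 0 & nb$dx == 0), ]
  nb$len <- sqrt((nb$dz * step[1])^2 + (nb$dy * step[2])^2 +
                 (nb$dx * step[3])^2)
  # simple O(n^2) Dijkstra over mask voxels
  done <- array(FALSE, d)
  dist <- array(Inf, d)
  lab <- array(0L, d)
  seedpos <- which(seeds > 0 & mask)
  dist[seedpos] <- 0
  lab[seedpos] <- seeds[seedpos]
  while (TRUE) {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    i <- cand[which.min(dist[cand])]
    done[i] <- TRUE
    ai <- arrayInd(i, d)
    for (k in seq_len(nrow(nb))) {
      z <- ai[1] + nb$dz[k]; y <- ai[2] + nb$dy[k]; x <- ai[3] + nb$dx[k]
      if (z < 1 || z > d[1] || y < 1 || y > d[2] || x < 1 || x > d[3]) next
      if (!mask[z, y, x]) next
      nd <- dist[i] + nb$len[k]
      if (nd < dist[z, y, x] - 1e-12) {
        dist[z, y, x] <- nd
        lab[z, y, x] <- lab[i]
      }
    }
  }
  list(dist = dist, labels = lab)
}

# exhaustive Otsu scan on a fixed histogram of log10 ratios
oracle_otsu_log10 <- function(ratios, n_bins = 256) {
  lr <- log10(ratios)
  br <- seq(min(lr), max(lr), length.out = n_bins + 1)
  h <- tabulate(findInterval(lr, br, rightmost.closed = TRUE), nbins = n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  best <- -Inf; best_k <- NA
  for (k in 1:(n_bins - 1)) {
    w0 <- sum(h[1:k]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:k] * mids[1:k]) / w0
    m1 <- sum(h[(k + 1):n_bins] * mids[(k + 1):n_bins]) / w1
    between <- w0 * w1 * (m0 - m1)^2
    if (between > best) { best <- between; best_k <- k }
  }
  br[best_k + 1]
}

# small scene used by fast unit tests (6 cells, 128 x 128 x 11)
small_scene_spec <- function(seed = 1, n_cells = 6L, ...) {
  scene_spec(field_shape = c(11L, 128L, 128L), n_cells = n_cells,
             seed = seed, ...)
}

default_test_config <- function(...) {
  run_config(speck_min_voxels = 1000, ...)
}

# map segmented nuclei to truth cells by nearest centroid
match_cells_to_truth <- function(nuclei, truth_cells) {
  nt <- label_table(nuclei)
  vapply(seq_len(nrow(nt)), function(i) {
    which.min((nt$centroid_z[i] - truth_cells$z)^2 +
              (nt$centroid_y[i] - truth_cells$y)^2 +
              (nt$centroid_x[i] - truth_cells$x)^2)
  }, integer(1))
}

# per-cell detected-vs-true count MAE (relative to total true count)
puncta_count_mae <- function(result, scene, channel = "green",
                             col = "n_green") {
  map <- match_cells_to_truth(result$nuclei, scene$truth$cells)
  tru_tab <- table(factor(
    scene$truth$puncta$cell[scene$truth$puncta$channel == channel],
    levels = scene$truth$cells$cell))
  det <- result$table$cells[[col]][match(seq_along(map),
                                         result$table$cells$cell)]
  tru <- as.numeric(tru_tab)[map]
  list(abs_err = sum(abs(det - tru), na.rm = TRUE), total = sum(tru))
}

# wrap a bare integer array as a label volume
new_lab <- function(arr, kind) punctaflux:::new_label_volume(arr, kind)
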