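# Puncta segmentation, cell assignment, colocalization counting, CSV I/O.

test_that("blank stacks yield zero punctae and bad params error", {
  spec <- scene_spec(field_shape = c(6L, 64L, 64L), seed = 3)
  blank <- generate_empty_field(spec)
  p <- segment_puncta(blank, NULL, canny_params(), restrict_to_cells = FALSE)
  expect_equal(max(p), 0L)
  expect_error(canny_params(low = 0.99, high = 0.90),
               class = "invalid_parameter")
})

test_that("high-SNR Gaussian spots are recovered with subvoxel centroids", {
  # 20 spots on flat background, far apart
  set.seed(31)
  d <- c(9, 160, 160)
  arr <- array(100, d)
  pos <- expand.grid(y = seq(20, 140, by = 30), x = seq(20, 140, by = 30))
  pos <- pos[1:20, ]
  pos$z <- rep(c(3, 5, 7), length.out = 20)
  for (i in 1:20) {
    for (z in 1:d[1]) for (y in (pos$y[i] - 4):(pos$y[i] + 4))
      for (x in (pos$x[i] - 4):(pos$x[i] + 4))
        arr[z, y, x] <- arr[z, y, x] + 500 *
          exp(-0.5 * (((z - pos$z[i]) / 0.9)^2 + ((y - pos$y[i]) / 1.1)^2 +
                      ((x - pos$x[i]) / 1.1)^2))
  }
  arr <- arr + array(rnorm(length(arr), 0, 10), d)  # SNR 50 wrt read noise
  p <- segment_puncta(image_stack(arr, "green"), NULL,
                      canny_params(sigma = 0.8, low = 180, high = 400,
                                   quantiles = FALSE),
                      restrict_to_cells = FALSE)
  expect_equal(max(p), 20L)
  st <- label_table(p)
  for (i in 1:20) {
    dmin <- min(sqrt((st$centroid_y - pos$y[i])^2 +
                     (st$centroid_x - pos$x[i])^2))
    expect_lt(dmin, 1)
  }
})

test_that("raising the high threshold never increases the count of isolated spots", {
  # hysteresis monotonicity on well-separated objects: the strong-edge
  # seed set shrinks as the high threshold rises, so isolated spots can
  # only drop out, never split
  set.seed(47)
  d <- c(7, 120, 120)
  arr <- array(100, d)
  pos <- expand.grid(y = seq(20, 100, by = 27), x = seq(20, 100, by = 27))
  amp <- seq(200, 650, length.out = nrow(pos))   # graded brightness
  for (i in seq_len(nrow(pos)))
    for (z in 1:d[1]) for (y in (pos$y[i] - 4):(pos$y[i] + 4))
      for (x in (pos$x[i] - 4):(pos$x[i] + 4))
        arr[z, y, x] <- arr[z, y, x] + amp[i] *
          exp(-0.5 * (((z - 4) / 0.9)^2 + ((y - pos$y[i]) / 1.1)^2 +
                      ((x - pos$x[i]) / 1.1)^2))
  arr <- arr + array(rnorm(length(arr), 0, 5), d)
  counts <- vapply(c(200, 400, 800, 1600), function(h) {
    p <- segment_puncta(image_stack(arr, "green"), NULL,
                        canny_params(sigma = 0.8, low = 100, high = h,
                                     quantiles = FALSE),
                        restrict_to_cells = FALSE)
    max(p)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[4])  # the sweep actually bites
})

test_that("plurality assignment matches an exhaustive per-voxel vote", {
  # punctum fully inside cell 3
  d <- c(3, 20, 20)
  cells <- array(0L, d); cells[, 1:10, ] <- 3L; cells[, 11:20, ] <- 1L
  p <- array(0L, d); p[2, 4:6, 4:6] <- 1L
  a <- assign_puncta_to_cells(new_lab(p, "punctae"), new_lab(cells, "cells"))
  expect_equal(a$cell, 3L)

  # 60/40 split between cells 1 and 2 -> plurality cell
  cells2 <- array(0L, d); cells2[, 1:12, ] <- 1L; cells2[, 13:20, ] <- 2L
  p2 <- array(0L, d); p2[2, 8:17, 5] <- 1L   # 5 voxels in 1, 5 in 2 -> tie
  p2b <- array(0L, d); p2b[2, 7:16, 5] <- 1L # 6 in 1, 4 in 2
  a_tie <- assign_puncta_to_cells(new_lab(p2, "punctae"),
                                  new_lab(cells2, "cells"))
  expect_equal(a_tie$cell, 1L)  # tie breaks to smaller label
  a_60 <- assign_puncta_to_cells(new_lab(p2b, "punctae"),
                                 new_lab(cells2, "cells"))
  expect_equal(a_60$cell, 1L)

  # random fixture vs brute-force vote
  set.seed(13)
  cells3 <- array(sample(0:4, 3 * 30 * 30, TRUE), c(3, 30, 30))
  p3 <- array(0L, c(3, 30, 30))
  for (k in 1:12) {
    z <- sample(1:3, 1); y <- sample(1:27, 1); x <- sample(1:27, 1)
    p3[z, y:(y + 2), x:(x + 2)] <- k
  }
  a3 <- assign_puncta_to_cells(new_lab(p3, "punctae"),
                               new_lab(cells3, "cells"))
  for (k in sort(unique(p3[p3 > 0]))) {
    votes <- table(factor(cells3[p3 == k], levels = 0:4))
    incell <- votes[-1]
    want <- if (all(incell == 0)) 0L else as.integer(names(incell)[
      which.max(incell)])
    expect_equal(a3$cell[a3$punctum == k], want)
  }
  # conservation: assigned + unassigned = total
  expect_equal(sum(a3$cell > 0) + sum(a3$cell == 0), max(p3))
})

test_that("colocalization counting is symmetric and boundary-exact", {
  d <- c(3, 20, 20)
  cells <- array(1L, d)
  g <- array(0L, d); g[2, 3:5, 3:5] <- 1L; g[2, 10:12, 10:12] <- 2L
  r_same <- g  # identical volumes -> both fractions 1
  ag <- assign_puncta_to_cells(new_lab(g, "punctae"), new_lab(cells, "cells"))
  tab <- count_colocalization(new_lab(g, "punctae"), new_lab(r_same, "punctae"),
                              ag, ag, new_lab(cells, "cells"))
  expect_equal(tab$cells$frac_green_overlapping, 1)
  expect_equal(tab$cells$frac_red_overlapping, 1)

  # disjoint volumes -> zero overlap; empty-channel fractions are NA
  r_dis <- array(0L, d); r_dis[2, 16:18, 16:18] <- 1L
  ar <- assign_puncta_to_cells(new_lab(r_dis, "punctae"),
                               new_lab(cells, "cells"))
  tab2 <- count_colocalization(new_lab(g, "punctae"),
                               new_lab(r_dis, "punctae"), ag, ar,
                               new_lab(cells, "cells"))
  expect_equal(tab2$cells$n_green_overlapping_red, 0L)
  expect_equal(tab2$cells$n_red_overlapping_green, 0L)

  # min_overlap_vox: exactly 1 shared voxel counts at 1, not at 2
  r_kiss <- array(0L, d); r_kiss[2, 5:7, 5:7] <- 1L  # shares voxel (2,5,5)
  ark <- assign_puncta_to_cells(new_lab(r_kiss, "punctae"),
                                new_lab(cells, "cells"))
  t1 <- count_colocalization(new_lab(g, "punctae"), new_lab(r_kiss, "punctae"),
                             ag, ark, new_lab(cells, "cells"),
                             min_overlap_vox = 1)
  t2 <- count_colocalization(new_lab(g, "punctae"), new_lab(r_kiss, "punctae"),
                             ag, ark, new_lab(cells, "cells"),
                             min_overlap_vox = 2)
  expect_equal(t1$field$n_green_overlapping_red, 1)
  expect_equal(t2$field$n_green_overlapping_red, 0)

  # symmetric accounting: pair counts agree in both directions
  expect_equal(t1$field$n_green_overlapping_red,
               t1$field$n_red_overlapping_green)
})

test_that("puncta CSV round-trips losslessly", {
  d <- c(3, 24, 24)
  cells <- array(0L, d); cells[, 1:12, ] <- 1L; cells[, 13:24, ] <- 2L
  g <- array(0L, d); g[2, 3:5, 3:5] <- 1L; g[2, 15:17, 3:5] <- 2L
  r <- array(0L, d); r[2, 3:5, 3:5] <- 1L
  ag <- assign_puncta_to_cells(new_lab(g, "punctae"), new_lab(cells, "cells"))
  ar <- assign_puncta_to_cells(new_lab(r, "punctae"), new_lab(cells, "cells"))
  tab <- count_colocalization(new_lab(g, "punctae"), new_lab(r, "punctae"),
                              ag, ar, new_lab(cells, "cells"))
  path <- tempfile(fileext = ".csv")
  write_puncta_csv(tab, path)
  back <- read_puncta_csv(path)
  expect_equal(back$cells$n_green, tab$cells$n_green)
  expect_equal(back$cells$frac_green_overlapping,
               tab$cells$frac_green_overlapping, tolerance = 1e-6)
  expect_equal(back$field$n_green_total, tab$field$n_green_total)
  # counts serialized as integers, fractions as decimals
  lines <- readLines(path)
  expect_true(any(grepl("^cell,", lines)))
  expect_false(any(grepl("n_green.*\\.", sub("frac.*", "", lines[2]))))

  # empty table -> header-only CSV body plus field row
  e <- array(0L, d)
  ae <- assign_puncta_to_cells(new_lab(e, "punctae"), new_lab(cells, "cells"))
  tabe <- count_colocalization(new_lab(e, "punctae"), new_lab(e, "punctae"),
                               ae, ae, new_lab(e, "cells"))
  path2 <- tempfile(fileext = ".csv")
  write_puncta_csv(tabe, path2)
  back2 <- read_puncta_csv(path2)
  expect_equal(nrow(back2$cells), 0L)
})

test_that("count conservation holds on a full synthetic scene", {
  sc <- generate_scene(small_scene_spec(seed = 43))
  cfg <- default_test_config()
  res <- run_image_pipeline(sc$stacks, sc$empty_field, cfg)
  ag <- assign_puncta_to_cells(res$puncta_green, res$cells)
  expect_equal(sum(ag$cell > 0) + sum(ag$cell == 0), max(res$puncta_green))
  # every surviving cell is covered by the table
  surv <- sort(setdiff(unique(as.vector(res$cells)), 0L))
  expect_equal(sort(res$table$cells$cell), surv)
})
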