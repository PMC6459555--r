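# Background model fitting, p-value masking, speck removal, focus filter.

test_that("smoothing matches a brute-force convolution oracle", {
  # single bright voxel in an 11^3 stack
  arr <- array(0, c(11, 11, 11))
  arr[6, 6, 6] <- 100
  got <- smooth_stack(arr, c(1, 1, 1))
  want <- oracle_gauss3d(arr, c(1, 1, 1))
  expect_equal(got, want, tolerance = 1e-10)

  # identity at sigma 0, constants invariant under blur
  expect_identical(smooth_stack(arr, c(0, 0, 0)), arr)
  const <- array(7, c(5, 6, 7))
  expect_equal(smooth_stack(const, c(1, 2, 2)), const, tolerance = 1e-12)
  expect_error(smooth_stack(arr, c(-1, 0, 0)), class = "invalid_parameter")
})

test_that("background fit recovers generator parameters and flags degeneracy", {
  spec <- scene_spec(field_shape = c(24L, 64L, 64L), bg_mean = 100,
                     bg_sd = 10, seed = 13)
  ef <- generate_empty_field(spec)
  m <- fit_background_gaussian(ef, smoothing_sigma = 0)
  expect_lt(abs(m$mu_bg - 100) / 100, 0.01)
  expect_lt(abs(m$sigma_bg - 10) / 10, 0.01)

  # smoothing strictly shrinks the fitted SD (variance of an average)
  m_sm <- fit_background_gaussian(ef, smoothing_sigma = c(1, 2, 2))
  expect_lt(m_sm$sigma_bg, m$sigma_bg)

  flat <- image_stack(array(5, c(10, 10, 10)), "green")
  expect_error(fit_background_gaussian(flat, smoothing_sigma = 0),
               class = "degenerate_model")
})

test_that("p-value masking equals the closed-form intensity cutoff", {
  model <- structure(list(mu_bg = 100, sigma_bg = 10, alpha = 1e-5,
                          smoothing_sigma = c(0, 0, 0),
                          cutoff = 100 + qnorm(1 - 1e-5) * 10),
                     class = "background_model")
  # normal CDF oracle at the values worked out by hand:
  # z=5 -> tail 2.9e-7 < 1e-5 (in); z=4 -> tail 3.2e-5 > 1e-5 (out)
  vals <- array(c(150, 140, 100), c(3, 1, 1))
  mk <- compute_cell_mask(image_stack(vals, "green"), model,
                          presmoothed = TRUE)
  expect_identical(as.vector(mk), c(TRUE, FALSE, FALSE))

  # equivalence on 1e6 random voxels, exact to 1e-12 around the cutoff
  set.seed(42)
  v <- array(runif(1e6, 50, 160), c(100, 100, 100))
  mk <- compute_cell_mask(image_stack(v, "green"), model, presmoothed = TRUE)
  closed <- v > model$cutoff
  agree <- as.vector(mk) == as.vector(closed)
  near <- abs(v - model$cutoff) < 1e-12
  expect_true(all(agree | as.vector(near)))
})

test_that("lowering alpha never grows the mask", {
  set.seed(7)
  v <- image_stack(array(rnorm(8000, 100, 10), c(20, 20, 20)), "green")
  alphas <- c(0.2, 0.05, 1e-3, 1e-5)
  masks <- lapply(alphas, function(a) {
    m <- structure(list(mu_bg = 100, sigma_bg = 10, alpha = a,
                        smoothing_sigma = c(0, 0, 0),
                        cutoff = 100 + qnorm(1 - a) * 10),
                   class = "background_model")
    compute_cell_mask(v, m, presmoothed = TRUE)
  })
  for (i in 1:(length(alphas) - 1))
    expect_true(all(masks[[i]] | !masks[[i + 1]]))  # superset relation
})

test_that("speck removal honours the strict volume boundary", {
  # component of 99,999 voxels removed; 100,000 retained
  m <- array(FALSE, c(50, 210, 100))
  m[1:50, 1:100, 1:20] <- TRUE            # 100,000 voxels
  blk <- array(TRUE, c(50, 100, 20)); blk[1, 1, 1] <- FALSE
  m[1:50, 111:210, 41:60] <- blk          # 99,999 voxels
  out <- remove_small_specks(m, 100000)
  expect_equal(sum(out[, 1:100, ]), 100000)
  expect_equal(sum(out[, 111:210, ]), 0)

  # empty mask passes through; filter is idempotent
  e <- array(FALSE, c(4, 4, 4))
  expect_equal(sum(remove_small_specks(e, 10)), 0)
  once <- remove_small_specks(m, 100000)
  twice <- remove_small_specks(once, 100000)
  expect_equal(as.vector(once), as.vector(twice))
})

test_that("speck filter agrees with a brute-force component oracle", {
  set.seed(5)
  m <- array(runif(20 * 20 * 20) < 0.2, c(20, 20, 20))
  lab <- oracle_label3d(m, 26)
  vol <- tabulate(lab[lab > 0])
  want <- array(lab > 0 & vol[pmax(lab, 1)] >= 30, dim(m))
  got <- remove_small_specks(m, 30)
  expect_equal(as.vector(got), as.vector(want))
})

test_that("fallback focus rule zeroes only empty planes", {
  m <- array(FALSE, c(5, 30, 30))
  m[2, 5:20, 5:20] <- TRUE
  m[3, 5:25, 5:25] <- TRUE
  stack <- image_stack(array(100, c(5, 30, 30)), "green")
  out <- filter_out_of_focus_planes(m, stack, fallback_focus_classifier())
  flog <- attr(out, "focus_log")
  expect_equal(flog$in_focus, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(sum(out), sum(m))  # in-focus planes untouched
  expect_error(filter_out_of_focus_planes(m, stack, NULL),
               class = "not_ready")
})

test_that("trained SVM separates blurred planes on held-out scenes", {
  make_labeled <- function(seed) {
    sc <- generate_scene(small_scene_spec(seed = seed,
                                          cell_halfdepth_vox = 3))
    model <- fit_background_gaussian(sc$empty_field)
    mask <- remove_small_specks(compute_cell_mask(sc$stacks$green, model),
                                500)
    feats <- plane_focus_features(mask, sc$stacks$green)
    # truth: a plane is in focus when it holds cell-body voxels
    body <- apply(sc$truth$cell_labels > 0, 1, sum)
    feats$in_focus <- body > 0
    feats
  }
  train <- do.call(rbind, lapply(31:34, make_labeled))
  test <- do.call(rbind, lapply(35:37, make_labeled))
  clf <- train_focus_classifier(train, train$in_focus)
  pred <- punctaflux:::predict_focus(clf, test)
  # score unambiguous planes: those whose label matches both z-neighbours
  # (at the focal transition the mask halo makes either call defensible)
  lab <- test$in_focus
  nz <- max(test$plane)
  prev <- ave(lab, rep(seq_len(nrow(test) / nz), each = nz),
              FUN = function(v) c(v[1], v[-length(v)]))
  nxt <- ave(lab, rep(seq_len(nrow(test) / nz), each = nz),
             FUN = function(v) c(v[-1], v[length(v)]))
  clear <- lab == prev & lab == nxt
  acc <- mean(pred[clear] == lab[clear])
  expect_gte(acc, 0.95)
})
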