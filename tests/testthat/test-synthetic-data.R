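# Generators: empty fields, scenes, flow populations, sorted screens.

test_that("empty field reproduces the requested background statistics", {
  # degenerate: noise disabled -> every voxel equals the offset
  spec0 <- scene_spec(field_shape = c(4L, 16L, 16L), bg_sd = 0,
                      noise_model = "none", seed = 7)
  ef0 <- generate_empty_field(spec0)
  expect_true(all(ef0$voxels == spec0$bg_mean))

  # determinism: same seed, bit-identical
  spec <- scene_spec(field_shape = c(64L, 64L, 64L), bg_mean = 100,
                     bg_sd = 10, seed = 11)
  expect_identical(generate_empty_field(spec)$voxels,
                   generate_empty_field(spec)$voxels)

  # law of large numbers at 64^3 voxels
  ef <- generate_empty_field(spec)
  expect_lt(abs(mean(ef$voxels) - 100), 1)
  expect_lt(abs(sd(as.vector(ef$voxels)) - 10), 1)
})

test_that("empty field rejects invalid field shapes", {
  expect_error(scene_spec(field_shape = c(0L, 16L, 16L)),
               class = "invalid_spec")
  expect_error(scene_spec(coloc_fraction = 1.2), class = "invalid_spec")
})

test_that("scene truth is consistent with its own label volumes", {
  sc <- generate_scene(small_scene_spec(seed = 3))
  tr <- sc$truth
  expect_equal(nrow(tr$cells), 6L)
  # every punctum centroid lies inside its recorded cell label
  for (i in seq_len(nrow(tr$puncta))) {
    p <- tr$puncta[i, ]
    lab <- tr$cell_labels[round(p$z), round(p$y), round(p$x)]
    expect_equal(lab, p$cell)
  }
  # colocalized pairs are symmetric and green x red
  pr <- tr$puncta
  paired <- pr[!is.na(pr$partner_id), ]
  for (i in seq_len(nrow(paired))) {
    mate <- pr[pr$punctum_id == paired$partner_id[i], ]
    expect_equal(mate$partner_id, paired$punctum_id[i])
    expect_false(mate$channel == paired$channel[i])
    expect_equal(mate$z, paired$z[i])  # coincident centroids
  }
  # blue channel carries nuclei: intensity inside nuclei far above bg
  inside <- sc$stacks$blue$voxels[tr$nucleus_labels > 0]
  outside <- sc$stacks$blue$voxels[tr$nucleus_labels == 0 &
                                   tr$cell_labels == 0]
  expect_gt(mean(inside), mean(outside) + 100)
})

test_that("zero green rate yields a puncta-free green channel", {
  sc <- generate_scene(small_scene_spec(seed = 5, puncta_per_cell_green = 0,
                                        puncta_per_cell_red = 0))
  expect_equal(nrow(sc$truth$puncta), 0L)
})

test_that("coloc_fraction 1 pairs every green punctum", {
  sc <- generate_scene(small_scene_spec(seed = 9, coloc_fraction = 1,
                                        puncta_per_cell_red = 6))
  g <- sc$truth$puncta[sc$truth$puncta$channel == "green", ]
  expect_true(all(!is.na(g$partner_id)))
})

test_that("realized colocalized fraction follows the binomial draw", {
  # coloc 0.79 over many punctae: realized fraction within 3 SE
  spec <- scene_spec(field_shape = c(13L, 320L, 320L), n_cells = 50L,
                     puncta_per_cell_green = 8, coloc_fraction = 0.79,
                     seed = 21)
  sc <- generate_scene(spec)
  g <- sc$truth$puncta[sc$truth$puncta$channel == "green", ]
  frac <- mean(!is.na(g$partner_id))
  se <- sqrt(0.79 * 0.21 / nrow(g))
  expect_lt(abs(frac - 0.79), 3 * se)
})

test_that("cell placement fails loudly when the field is too crowded", {
  expect_error(
    generate_scene(scene_spec(field_shape = c(11L, 80L, 80L), n_cells = 30L,
                              max_place_retries = 50L, seed = 1)),
    class = "placement_error")
})

test_that("flow population medians and determinism match the spec", {
  # single mode, zero spread -> identical ratios
  sp0 <- flow_pop_spec(n_events = 2000,
                       modes = list(list(fraction = 1, median_ratio = 3,
                                         log_sd = 0)),
                       channel_noise_sd = 0, seed = 2)
  ev0 <- generate_flow_population(sp0)
  expect_equal(max(abs(ev0$RFP / ev0$GFP - 3)), 0, tolerance = 1e-12)

  # two equal modes at 1 and 10: pooled median strictly between
  sp2 <- flow_pop_spec(n_events = 10000,
                       modes = list(list(fraction = 0.5, median_ratio = 1,
                                         log_sd = 0.05),
                                    list(fraction = 0.5, median_ratio = 10,
                                         log_sd = 0.05)),
                       seed = 3)
  ev2 <- generate_flow_population(sp2)
  med <- median(ev2$RFP / ev2$GFP)
  expect_gt(med, 1); expect_lt(med, 10)

  # Monte-Carlo error on a single-mode median
  sp4 <- flow_pop_spec(n_events = 10000,
                       modes = list(list(fraction = 1, median_ratio = 4,
                                         log_sd = 0.1)),
                       seed = 4)
  ev4 <- generate_flow_population(sp4)
  expect_lt(abs(median(ev4$RFP / ev4$GFP) - 4), 0.1)

  expect_identical(generate_flow_population(sp4), generate_flow_population(sp4))
  expect_error(flow_pop_spec(modes = list(list(fraction = 0.6,
                                               median_ratio = 1,
                                               log_sd = 0.1))),
               class = "invalid_spec")
})

test_that("sorted-screen simulator sorts tertiles and plants hits", {
  spec <- screen_sim_spec(n_genes = 60L, sgrnas_per_gene = 4L,
                          hits = c(gene0007 = 3),
                          cells_per_sgrna = 150L, n_replicates = 2L,
                          mean_reads_per_sgrna = 300, seed = 5)
  sim <- simulate_sorted_screen(spec)
  truth <- attr(sim, "truth")
  n_cells <- truth$n_cells
  # tertile definition and cell conservation
  for (bs in truth$bin_sizes) {
    expect_equal(unname(bs["high"]), floor(n_cells / 3))
    expect_equal(unname(sum(bs)), n_cells)
  }
  # hit sgRNAs enriched in the high bin in every replicate
  hit_rows <- grep("gene0007", rownames(sim$counts))
  for (r in 1:2) {
    hi <- sim$counts[hit_rows, sprintf("high_rep%d", r)]
    lo <- sim$counts[hit_rows, sprintf("low_rep%d", r)]
    expect_true(all(hi > lo))
  }
  # reads scaled to the requested depth
  expect_equal(unname(colSums(sim$counts)[1]), 300 * nrow(sim$counts))
  # unknown hit gene rejected
  expect_error(screen_sim_spec(n_genes = 10, hits = c(nope = 1)),
               class = "unknown_gene")
  # determinism
  sim2 <- simulate_sorted_screen(spec)
  expect_identical(sim$counts, sim2$counts)
})

test_that("null screen log2 ratios center on zero", {
  spec <- screen_sim_spec(n_genes = 100L, sgrnas_per_gene = 4L,
                          cells_per_sgrna = 200L, n_replicates = 1L,
                          seed = 8)
  sim <- simulate_sorted_screen(spec)
  lr <- log2((sim$counts[, "high_rep1"] + 0.5) /
             (sim$counts[, "low_rep1"] + 0.5))
  expect_lt(abs(mean(lr)), 3 * sd(lr) / sqrt(length(lr)))
})
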