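test_that("neuromast mask overlaps ground truth on a high-SNR phantom", {
  ph <- fine_phantom()
  rep_n <- normalize_intensity(get_channel(ph$stack, "reporter"))
  nm <- segment_neuromast(rep_n, voxel_size_um = ph$params$voxel_size_um)
  expect_gte(iou(ph$neuromast$labels > 0, nm$labels > 0), 0.8)
})

test_that("pure noise yields no neuromast", {
  set.seed(9)
  x <- array(runif(12 * 80 * 80), c(12, 80, 80))
  expect_error(segment_neuromast(x), "no neuromast")
})

test_that("the multi-Otsu background excludes every cell voxel", {
  ph <- fine_phantom()
  rep_n <- normalize_intensity(get_channel(ph$stack, "reporter"))
  bg <- background_mask_multiotsu(rep_n, 5, background_classes = 2)
  expect_equal(sum(bg & ph$cells$labels > 0), 0)
  expect_gt(mean(bg), 0.5)
})

test_that("seeded watershed recovers individual cells (IoU >= 0.7)", {
  ph <- fine_phantom()
  rep_n <- normalize_intensity(get_channel(ph$stack, "reporter"))
  gtc <- ph$cells$labels
  cells <- segment_hair_cells(rep_n, gt_seeds(gtc),
                              params = segmentation_params(background_classes = 2),
                              voxel_size_um = ph$params$voxel_size_um)
  expect_equal(max(cells$labels), max(gtc))
  ious <- vapply(seq_len(max(gtc)), function(i) {
    iou(gtc == i, cells$labels == i)
  }, 1)
  expect_gte(mean(ious), 0.7)
})

test_that("watershed splits two touching cells near the midplane", {
  d <- c(10, 40, 60)
  zc <- array(rep(1:10, prod(d[2:3])), d)
  yc <- array(rep(rep(1:40, each = 10), 60), d)
  xc <- array(rep(1:60, each = 10 * 40), d)
  sph <- function(cz, cy, cx, r) ((zc - cz) / (r / 2))^2 +
    ((yc - cy) / r)^2 + ((xc - cx) / r)^2 <= 1
  fg <- sph(5, 20, 22, 12) | sph(5, 20, 38, 12)
  img <- array(0.02, d); img[fg] <- 1
  seeds <- seed_set(data.frame(z = c(5, 5), y = c(20, 20), x = c(22, 38)))
  cells <- segment_hair_cells(img, seeds, background = !fg)
  lab <- cells$labels
  # boundary between the labels lies within 2 px of the x = 30 midplane
  expect_true(all(xc[lab == 1] <= 32))
  expect_true(all(xc[lab == 2] >= 28))
  expect_true(sum(lab == 1) > 0 && sum(lab == 2) > 0)
})

test_that("seeds outside foreground are flagged; none give empty labels", {
  d <- c(6, 30, 30)
  img <- array(0.02, d)
  img[2:5, 10:20, 10:20] <- 1
  bg <- img < 0.5
  expect_warning(
    cells <- segment_hair_cells(img, seed_set(data.frame(z = 3, y = 2, x = 2)),
                                background = bg),
    "outside")
  expect_equal(max(cells$labels), 0)
  expect_warning(
    empty <- segment_hair_cells(img, seed_set(data.frame(z = integer(0),
                                                         y = integer(0),
                                                         x = integer(0))),
                                background = bg),
    "no seeds")
  expect_equal(max(empty$labels), 0)
  expect_error(seed_set(data.frame(z = c(3, 3), y = c(12, 12), x = c(12, 12))),
               "duplicate")
})

test_that("vesicle count is recovered within 10% on a punctate phantom", {
  ph <- vesicle_phantom()
  ag <- normalize_intensity(get_channel(ph$stack, "ag"))
  ves <- segment_vesicles(ag, vesicle_preset("g418"), ph$neuromast)
  n_gt <- max(ph$vesicles$labels)
  expect_lte(abs(max(ves$labels) - n_gt) / n_gt, 0.1)
})

test_that("vesicles wholly outside the neuromast are discarded", {
  d <- c(6, 60, 60)
  img <- array(0, d)
  img[3, 10, 10] <- 1; img[3, 50, 50] <- 1
  img <- lateralline:::gauss_blur3d(img, 1.5, 0) * 12
  nm <- array(FALSE, d); nm[, 40:60, 40:60] <- TRUE
  prm <- segmentation_params(dot_pairs = list(c(4, 0.1)),
                             filament_pairs = list(c(2, 99)))
  ves <- segment_vesicles(img, prm, label_volume(nm, "neuromast"))
  expect_equal(max(ves$labels), 1)        # only the inside spot survives
  all_out <- label_volume(array(c(TRUE, rep(FALSE, prod(d) - 1)), d),
                          "neuromast")
  ves0 <- segment_vesicles(img, prm, all_out)
  expect_equal(max(ves0$labels), 0)
})

test_that("GPN-like phantoms halve vesicle count but conserve signal", {
  run <- function(vpc, seed) {
    p <- stack_phantom_params(seed = seed, vesicles_per_cell = c(vpc, 20),
                              ag_total_per_cell = 200,
                              shape_px = c(14, 110, 110))
    ph <- gen_neuromast_stack(p)
    ag <- normalize_intensity(get_channel(ph$stack, "ag"))
    ves <- segment_vesicles(ag, vesicle_preset("g418"), ph$neuromast)
    tab <- vesicle_table(ves, ph$stack, ph$cells)
    s <- per_neuromast_stats(tab, ph$cells, "ag", ph$stack, ph$neuromast)
    s$gt_count <- max(ph$vesicles$labels)
    s
  }
  seeds <- c(11, 21, 31, 41, 51)
  ctrl <- do.call(rbind, lapply(seeds, function(s) run(5, s)))
  gpn <- do.call(rbind, lapply(seeds, function(s) run(2.5, s + 500)))
  count_ratio <- sum(gpn$n_vesicles) / sum(ctrl$n_vesicles)
  gt_ratio <- sum(gpn$gt_count) / sum(ctrl$gt_count)
  expect_equal(count_ratio, gt_ratio, tolerance = 0.12)
  expect_equal(gt_ratio, 0.5, tolerance = 0.25)  # realized NB draws
  expect_equal(mean(gpn$vesicle_volume_mean_um3) /
                 mean(ctrl$vesicle_volume_mean_um3), 1, tolerance = 0.15)
  expect_equal(mean(gpn$vesicle_fluorescence_mean) /
                 mean(ctrl$vesicle_fluorescence_mean), 1, tolerance = 0.15)
  expect_equal(sum(gpn$total_fluorescence) / sum(ctrl$total_fluorescence),
               1, tolerance = 0.05)
})

test_that("the small-scale detector prefers the small vesicle class", {
  set.seed(6)
  n <- 20
  img <- matrix(0, 300, 300)
  centers <- expand.grid(y = seq(25, 275, by = 50), x = seq(25, 275, by = 50))
  small <- centers[1:18, ]; large <- centers[19:36, ]
  for (i in seq_len(nrow(small)))
    img <- img + outer(1:300, 1:300, function(y, x)
      exp(-((y - small$y[i])^2 + (x - small$x[i])^2) / (2 * 1^2)))
  for (i in seq_len(nrow(large)))
    img <- img + outer(1:300, 1:300, function(y, x)
      exp(-((y - large$y[i])^2 + (x - large$x[i])^2) / (2 * 4^2)))
  mask <- detect_dots_2d(img, list(c(2, 0.2)))
  hit <- function(df) mean(vapply(seq_len(nrow(df)), function(i)
    mask[df$y[i], df$x[i]], TRUE))
  expect_gte(hit(small) - hit(large), 0.3)
})

test_that("cytoplasm and vesicles partition the neuromast exactly", {
  ph <- vesicle_phantom()
  cyto <- make_cytoplasm_mask(ph$neuromast, ph$vesicles)
  nm <- ph$neuromast$labels > 0
  ves <- ph$vesicles$labels > 0
  cy <- cyto$labels > 0
  expect_identical(cy | ves, nm)
  expect_false(any(cy & ves))
  # degenerate cases
  none <- label_volume(array(FALSE, dim(nm)), "vesicles")
  expect_identical(make_cytoplasm_mask(ph$neuromast, none)$labels > 0, nm)
  all_v <- label_volume(nm, "vesicles")
  expect_false(any(make_cytoplasm_mask(ph$neuromast, all_v)$labels > 0))
  expect_error(make_cytoplasm_mask(ph$neuromast,
                                   label_volume(array(FALSE, c(2, 2, 2)),
                                                "vesicles")),
               "grids")
})

test_that("segmentation is deterministic for identical input", {
  ph <- vesicle_phantom()
  ag <- normalize_intensity(get_channel(ph$stack, "ag"))
  prm <- vesicle_preset("g418")
  v1 <- segment_vesicles(ag, prm, ph$neuromast)
  v2 <- segment_vesicles(ag, prm, ph$neuromast)
  expect_identical(v1$labels, v2$labels)
})

test_that("label edits replay merges and deletions", {
  lab <- array(c(1L, 1L, 2L, 2L, 3L, 0L, 0L, 0L), c(2, 2, 2))
  ed <- data.frame(op = c("merge", "delete"), from = c(2, 3), to = c(1, NA))
  out <- lateralline:::apply_label_edits(lab, ed)
  expect_equal(sort(unique(as.vector(out))), c(0L, 1L))
  expect_equal(sum(out == 1), 4)
})
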