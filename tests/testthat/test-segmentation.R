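test_that("a two-tone image is split into its ideal bipartition", {
  img <- uniform_image(64, 64, c(1, 1, 1))
  img[, 1:30, ] <- 0  # black block touching the left edge; border majority white
  m <- cluster_segment(img)
  ideal <- matrix(0L, 64, 64); ideal[, 1:30] <- 1L
  expect_identical(m, ideal)
})

test_that("contrast-free images are rejected", {
  expect_error(cluster_segment(uniform_image(64, 64, c(0.5, 0.5, 0.5))),
               "contrast")
})

test_that("a background-coloured wing spot leaves a hole that repair fills", {
  bg <- 0.82
  img <- uniform_image(80, 80, c(bg, bg, bg))
  spec <- matrix(FALSE, 80, 80)
  spec[20:60, 20:60] <- TRUE   # dark specimen block
  for (k in 1:3) { ch <- img[, , k]; ch[spec] <- 0.2; img[, , k] <- ch }
  hole <- matrix(FALSE, 80, 80)
  hole[35:45, 35:45] <- TRUE   # spot of exact background colour
  for (k in 1:3) { ch <- img[, , k]; ch[hole] <- bg; img[, , k] <- ch }
  raw <- cluster_segment(img)
  hole_core <- matrix(FALSE, 80, 80); hole_core[37:43, 37:43] <- TRUE
  spec_core <- matrix(FALSE, 80, 80); spec_core[22:58, 22:58] <- TRUE
  expect_equal(sum(raw[hole_core]), 0)     # hole present before repair
  fixed <- repair_mask(raw)
  expect_true(all(fixed[hole_core] == 1))  # and absent after
  expect_true(all(fixed[spec_core] == 1))
})

test_that("repair keeps the largest component, fills holes, and is idempotent", {
  ann <- matrix(0L, 60, 60)
  ann[15:45, 15:45] <- 1L
  ann[25:35, 25:35] <- 0L                  # annulus
  disc <- matrix(0L, 60, 60); disc[15:45, 15:45] <- 1L
  expect_identical(repair_mask(ann), disc)

  sat <- disc
  sat[2:4, 2:4] <- 1L                      # satellite stain
  expect_identical(repair_mask(sat), disc)

  expect_identical(repair_mask(disc), disc)            # already simply connected
  expect_identical(repair_mask(repair_mask(ann)), repair_mask(ann))
  expect_error(repair_mask(matrix(0L, 10, 10)), "empty")
  expect_error(repair_mask(matrix(2L, 10, 10)), "binary")
})

test_that("mean IoU matches hand-computed cases and is symmetric", {
  a <- matrix(0L, 10, 10); a[1:5, ] <- 1L
  expect_equal(mean_iou(a, a), 1.0)

  # disjoint equal-area foregrounds: fg IoU 0, bg IoU 0/..; mean from parts
  b <- matrix(0L, 10, 10); b[6:10, ] <- 1L
  expect_equal(mean_iou(a, b), (0 + 0) / 2)  # bg union is everything, inter 0

  # pred covers exactly half of truth's foreground, no false positives
  half <- matrix(0L, 10, 10); half[1:5, 1:5] <- 1L
  got <- mean_iou(half, a)
  # fg: 25/50 = 0.5; bg: 50/75
  expect_equal(got, (0.5 + 50 / 75) / 2)

  set.seed(4)
  for (i in 1:20) {
    p <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
    q <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
    expect_equal(mean_iou(p, q), mean_iou(q, p))
  }
  expect_error(mean_iou(a, matrix(0L, 5, 5)), "mismatch")
})

test_that("segmentation of rendered specimens is accurate and brightness-stable", {
  cfg <- tiny_config(n_species = 5, images_per_species = c(1, 1), seed = 31)
  ds <- generate_dataset(cfg)
  for (id in ds$metadata$image_id) {
    truth <- matrix(as.integer(ds$masks[[id]] > 0), 64, 64)
    m0 <- repair_mask(cluster_segment(ds$images[[id]]))
    iou0 <- mean_iou(m0, truth)
    expect_gte(iou0, 0.95)
    for (f in c(0.9, 1.1)) {
      shifted <- ds$images[[id]] * f
      shifted[shifted > 1] <- 1
      iou <- mean_iou(repair_mask(cluster_segment(shifted)), truth)
      expect_lt(abs(iou - iou0), 0.02)
    }
  }
})

test_that("segment_dataset reports components and mIoU per image", {
  cfg <- tiny_config(n_species = 3, images_per_species = c(1, 1), seed = 33)
  ds <- generate_dataset(cfg)
  seg <- segment_dataset(ds$images, ds$masks)
  expect_equal(nrow(seg$report), 3)
  expect_true(all(seg$report$miou >= 0 & seg$report$miou <= 1))
  expect_true(all(seg$report$n_components_repaired == 1))
  expect_true(all(vapply(seg$masks, function(m) all(m %in% 0:1), logical(1))))
})
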