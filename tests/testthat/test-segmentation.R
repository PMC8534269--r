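blank <- function(ny = 80, nx = 100) matrix(0, ny, nx)

test_that("an all-zero image yields an empty label map", {
  lm <- segment_compartments(blank(), segmentation_params(), 0.2)
  expect_identical(lm$n_objects, 0L)
  expect_true(all(lm$labels == 0))
})

test_that("well-separated Gaussian spots are found with sub-pixel centroids", {
  px <- 0.2
  img <- blank()
  centers <- rbind(c(20.3, 30.6), c(60.8, 25.2), c(45.5, 60.4)) # (x, y) px
  for (i in 1:3)
    img <- add_gaussian(img, centers[i, 1], centers[i, 2], 1.6, 120)
  lm <- segment_compartments(img, segmentation_params(), px)
  expect_identical(lm$n_objects, 3L)
  found <- lm$centroid_weighted_um / px
  for (i in 1:3) {
    d <- sqrt((found[, 1] - centers[i, 1])^2 + (found[, 2] - centers[i, 2])^2)
    expect_lt(min(d), 1) # within 1 px of the seeded centre
  }
})

test_that("fill_holes recovers the full disk area of a bright annulus", {
  px <- 0.2
  img <- blank()
  xs <- matrix(rep(0:99, each = 80), 80) # 0-based x per pixel
  ys <- matrix(rep(0:79, times = 100), 80)
  r <- sqrt((xs - 50)^2 + (ys - 40)^2)
  img[r >= 10 & r <= 14] <- 100
  disk_px <- sum(r <= 14) # oracle: direct pixel count of the filled disk
  params <- segmentation_params(gaussian_sigma_px = 0.5,
                                threshold_method = "fixed",
                                fixed_threshold = 50, closing_radius_px = 0L,
                                fill_holes = TRUE)
  lm <- segment_compartments(img, params, px)
  expect_identical(lm$n_objects, 1L)
  expect_equal(lm$area_px, disk_px, tolerance = 0.02)
  # and without hole filling the hole stays open
  params$fill_holes <- FALSE
  lm2 <- segment_compartments(img, params, px)
  expect_lt(lm2$area_px[1], sum(r >= 9 & r <= 15))
})

test_that("raising the minimum dot area never increases the object count", {
  img <- blank()
  set.seed(11)
  for (i in 1:8)
    img <- add_gaussian(img, runif(1, 10, 90), runif(1, 10, 70),
                        runif(1, 1, 3), 120)
  counts <- vapply(c(1, 4, 10, 25, 60, 200), function(a) {
    segment_compartments(img, segmentation_params(min_dot_area_px = a),
                         0.2)$n_objects
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation is translation-equivariant", {
  img <- blank()
  for (c in list(c(30, 30), c(60, 50))) img <- add_gaussian(img, c[1], c[2], 1.5, 100)
  shifted <- blank()
  for (c in list(c(30, 30), c(60, 50)))
    shifted <- add_gaussian(shifted, c[1] + 7, c[2] + 5, 1.5, 100)
  a <- segment_compartments(img, segmentation_params(), 1)
  b <- segment_compartments(shifted, segmentation_params(), 1)
  expect_identical(a$n_objects, b$n_objects)
  expect_equal(b$centroid_weighted_um - a$centroid_weighted_um,
               matrix(rep(c(7, 5), each = 2), 2,
                      dimnames = list(NULL, c("x", "y"))),
               tolerance = 1e-6)
})

test_that("cell segmentation keeps the largest component and reports um^2", {
  px <- 0.2
  img <- matrix(0, 120, 150)
  img[11:60, 21:120] <- 100   # 50 x 100 px rectangle = 5000 px
  img[100:105, 10:15] <- 100  # a smaller distractor component
  params <- segmentation_params(gaussian_sigma_px = 0.5,
                                threshold_method = "fixed",
                                fixed_threshold = 50)
  cm <- segment_cell(img, params, px)
  expect_equal(cm$area_px, 5000, tolerance = 0.02)
  expect_identical(cm$area_um2, cm$area_px * px^2) # 5000 px * 0.04 = 200 um^2
  expect_equal(cm$area_um2, 200, tolerance = 0.02)
  expect_error(segment_cell(matrix(5, 10, 10)), "constant")
})

test_that("cell mask area tracks the true polygon area on synthetic cells", {
  cfg <- noiseless(tiny_config())
  scene <- generate_timelapse(cfg)
  cm <- segment_cell(get_channel(scene$stack, 1, "GFP"),
                     pixel_size_um = cfg$pixel_size_um)
  truth <- polygon_area(scene$ground_truth$frames[[1]]$polygon)
  expect_lt(abs(cm$area_um2 - truth) / truth, 0.1)
})

test_that("nucleus centroid is recovered and empty frames are flagged", {
  px <- 0.183
  img <- render_nucleus(200, 150, px, cx_um = 18.3, cy_um = 12.2,
                        a_um = 7, b_um = 4.5, amp = 120)
  nuc <- segment_nucleus(img, pixel_size_um = px)
  expect_lt(abs(nuc$centroid_um["x"] - 18.3), px)
  expect_lt(abs(nuc$centroid_um["y"] - 12.2), px)
  expect_error(segment_nucleus(blank(), pixel_size_um = px),
               class = "lc3topo_no_nucleus")
})
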