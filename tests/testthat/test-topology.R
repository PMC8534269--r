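test_that("axis normalization maps the migration direction onto +x", {
  pts <- cbind(c(1, 3, -2), c(0, 4, 5))
  expect_equal(normalize_axis(pts, c(1, 0)), pts) # identity for +x
  flipped <- normalize_axis(pts, c(-1, 0))
  expect_equal(flipped, -pts, tolerance = 1e-12)  # 180 degrees
  # a dot at angle theta from the nucleus ends up at x-offset = its distance
  theta <- 0.7; r <- 5.3
  dot <- c(r * cos(theta), r * sin(theta))
  rot <- normalize_axis(dot, direction = c(cos(theta), sin(theta)))
  expect_equal(rot, c(r, 0), tolerance = 1e-12)
  expect_error(normalize_axis(pts, c(0, 0)), "non-zero")
})

test_that("partition boundaries follow the 5+5 equal-width rule", {
  p <- compute_partition(c(0, 100), nucleus_centroid = 40)
  expect_equal(p$boundaries, c(0, 8, 16, 24, 32, 40, 52, 64, 76, 88, 100))
  expect_equal(p$back_width, 8)
  expect_equal(p$front_width, 12)
  expect_length(p$widths, 10)
  expect_equal(p$boundaries[6], 40) # nucleus centroid sits at position #5
  expect_equal(nucleus_relative_position(p), 0.40)

  mid <- compute_partition(c(0, 80), nucleus_centroid = 40)
  expect_equal(unname(mid$widths), rep(8, 10))
  expect_equal(nucleus_relative_position(mid), 0.5)

  # from a mask matrix: a solid block spanning columns 11..60 at 0.5 um/px
  mask <- matrix(FALSE, 20, 100); mask[5:15, 11:61] <- TRUE
  pm <- compute_partition(mask, nucleus_centroid = 15, pixel_size_um = 0.5)
  expect_equal(pm$x_min, 5)
  expect_equal(pm$x_max, 30)
  expect_error(compute_partition(c(0, 100), nucleus_centroid = 120),
               class = "lc3topo_bad_partition")
})

test_that("portion membership is half-open with the final bin closed", {
  p <- compute_partition(c(0, 100), 40)
  expect_identical(portion_index(40, p), 5L)  # exactly at b5 -> front side
  expect_identical(portion_index(100, p), 9L) # right edge included
  expect_identical(portion_index(0, p), 0L)
  expect_identical(portion_index(c(-1, 101), p), c(NA_integer_, NA_integer_))
})

test_that("portion counts match brute-force binning over random frames", {
  set.seed(5)
  for (rep in 1:25) {
    x_min <- runif(1, 0, 10); len <- runif(1, 30, 120)
    nuc <- x_min + runif(1, 0.2, 0.8) * len
    p <- partition_bins(x_min, x_min + len, nuc)
    n <- sample(0:40, 1)
    comp <- data.frame(
      class = sample(c("autophagosome", "autolysosome"), n, replace = TRUE),
      x_um = runif(n, x_min, x_min + len),
      area_um2 = runif(n, 0.1, 1))
    ap <- assign_portions(comp, p)
    for (cl in rownames(ap$counts)) {
      expect_identical(unname(ap$counts[cl, ]),
                       brute_bin(comp$x_um[comp$class == cl], p$boundaries))
    }
    # conservation: portion sums equal the per-class totals
    expect_identical(unname(rowSums(ap$counts)),
                     as.numeric(table(comp$class)[rownames(ap$counts)]))
  }
})

test_that("a compartment straddling a boundary splits area but not count", {
  p <- partition_bins(0, 100, 50) # all widths 10
  # pixels span x in [28, 32): 2/5 of area in portion 2, 3/5 in portion 3
  px <- cbind(x = c(28, 29, 30, 31, 32), y = rep(1, 5))
  comp <- data.frame(class = "autophagosome", x_um = 30.2, area_um2 = 5)
  comp$pixels <- list(px)
  ap <- assign_portions(comp, p)
  expect_identical(unname(ap$counts["autophagosome", ]),
                   c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(unname(ap$areas_um2["autophagosome", 3:4]), c(2, 3))
  # out-of-mask compartments are excluded and logged
  comp2 <- rbind(comp, transform(comp, x_um = 70))
  comp2$in_cell <- c(TRUE, FALSE)
  ap2 <- assign_portions(comp2, p)
  expect_identical(sum(ap2$counts), 1L)
  expect_identical(nrow(ap2$excluded), 1L)
})

test_that("density modes normalize as documented", {
  counts <- c(0, 0, 0, 0, 0, 0, 10, 0, 0, 0)
  f <- density_profile(counts, "fraction_of_total")
  expect_equal(as.numeric(f), c(rep(0, 6), 1, rep(0, 3)))
  expect_equal(sum(density_profile(rep(3, 10), "fraction_of_total")), 1)
  expect_equal(as.numeric(density_profile(rep(3, 10), "fraction_of_total")),
               rep(0.1, 10))
  z <- density_profile(rep(0, 10), "fraction_of_total")
  expect_true(isTRUE(attr(z, "undefined")))

  # uniform spatial density: per-um profile flat, fraction profile not
  p <- partition_bins(0, 100, 40)
  counts_uniform <- p$widths * 2 # 2 dots per um
  per_um <- density_profile(counts_uniform, "per_um_length", p)
  expect_equal(as.numeric(per_um), rep(2, 10))
  frac <- density_profile(counts_uniform, "fraction_of_total")
  expect_gt(max(frac) / min(frac), 1.4) # front bins are wider
  expect_equal(as.numeric(density_profile(counts, "raw")), counts)
})

test_that("flux ratio follows red/yellow with undefined zero denominator", {
  expect_equal(flux_ratio(0, 5), 0)
  expect_equal(flux_ratio(10, 5), 2)
  expect_true(is.na(flux_ratio(3, 0)))
})

test_that("temporal profiles trace the density peak and frame variability", {
  m <- matrix(rep(c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.3, 0.1, 0.05, 0.05),
                  3), nrow = 3, byrow = TRUE)
  tp <- temporal_profiles(m)
  expect_identical(tp$peak_trace, rep(6L, 3))
  expect_equal(unname(tp$sem), rep(0, 10)) # identical frames: zero variance
  expect_equal(unname(tp$mean), m[1, ])
})

test_that("profiles are invariant under rotation of the whole scene", {
  # rotate a frame's coordinates and its direction annotation together:
  # the normalized partition and counts must be unchanged
  set.seed(8)
  cell_x <- runif(400, 0, 60)
  nuc <- c(25, 0)
  comp <- data.frame(class = "autophagosome", x_um = runif(30, 1, 59),
                     area_um2 = 1)
  comp$y_um <- runif(30, -4, 4)
  p0 <- partition_bins(min(cell_x), max(cell_x), nuc[1])
  c0 <- assign_portions(comp, p0)$counts
  for (theta in c(0.4, 1.57, 2.9)) {
    rot <- function(m) {
      co <- cos(theta); si <- sin(theta)
      cbind(co * m[, 1] - si * m[, 2], si * m[, 1] + co * m[, 2])
    }
    cell_rot <- rot(cbind(cell_x, runif(400, -4, 4)))
    dir_rot <- c(cos(theta), sin(theta))
    cell_norm <- normalize_axis(cell_rot, dir_rot)
    comp_rot <- comp
    cen <- normalize_axis(rot(cbind(comp$x_um, comp$y_um)), dir_rot)
    comp_rot$x_um <- cen[, 1]
    nuc_norm <- normalize_axis(rot(matrix(nuc, 1)), dir_rot)
    p1 <- partition_bins(min(cell_norm[, 1]), max(cell_norm[, 1]),
                         nuc_norm[1])
    expect_equal(p1$boundaries, p0$boundaries, tolerance = 1e-9)
    expect_identical(assign_portions(comp_rot, p1)$counts, c0)
  }
})
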