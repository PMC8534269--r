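test_that("generation is deterministic and ground truth matches the config", {
  cfg <- tiny_config(n_yellow = 8, n_red = 5)
  s1 <- generate_timelapse(cfg)
  s2 <- generate_timelapse(cfg)
  expect_identical(s1$stack$images, s2$stack$images)
  expect_identical(s1$ground_truth$dots, s2$ground_truth$dots)

  for (f in s1$ground_truth$frames) {
    expect_identical(as.vector(table(f$dots$class)[c("autophagosome",
                                                     "autolysosome")]),
                     c(8L, 5L))
  }
  # every dot centre lies inside the true cell polygon (x-monotone shape:
  # |y - midline| below the half-width at that x)
  shp <- cell_shape(cfg)
  for (f in s1$ground_truth$frames) {
    off <- f$partition$x_min
    yc <- f$nucleus_um["y"]
    expect_true(all(abs(f$dots$y_um - yc) <=
                      shp$halfwidth(f$dots$x_um - off)))
  }
})

test_that("front-peaked placement puts the true histogram mode at the peak", {
  cfg <- scene_config(cell_area_um2 = 900, n_frames = 3, n_yellow = 20,
                      n_red = 20, dot_spatial_model = "front_peaked",
                      peak_portion = 6, peak_concentration_bins = 0.8,
                      nucleus_rel_position = 0.45, seed = 7)
  gt <- generate_timelapse(cfg)$ground_truth
  pooled <- integer(10)
  for (f in gt$frames) {
    h <- brute_bin(f$dots$x_um, f$partition$boundaries)
    expect_identical(h, unname(f$histograms$all))
    pooled <- pooled + h
  }
  expect_true((which.max(pooled) - 1) %in% c(6, 7))
})

test_that("yellow dots peak at the same place in GFP and RFP; red dots are GFP-dark", {
  scene <- generate_timelapse(noiseless(tiny_config()))
  px <- scene$stack$pixel_size_um
  f <- scene$ground_truth$frames[[1]]
  gfp <- get_channel(scene$stack, 1, "GFP")
  rfp <- get_channel(scene$stack, 1, "RFP")
  cyto <- scene$ground_truth$config$cytosol_level
  for (i in seq_len(nrow(f$dots))) {
    row <- round(f$dots$y_um[i] / px) + 1
    col <- round(f$dots$x_um[i] / px) + 1
    rows <- (row - 3):(row + 3); cols <- (col - 3):(col + 3)
    wg <- gfp[rows, cols]; wr <- rfp[rows, cols]
    if (f$dots$class[i] == "autophagosome") {
      expect_identical(which.max(wg), which.max(wr))
      expect_gt(max(wg), cyto + 50)
    } else {
      expect_lte(max(wg), cyto + 5) # nothing above the cytosol background
    }
  }
})

test_that("rendered cell area and nucleus motion match the configuration", {
  cfg <- noiseless(tiny_config(speed_um_per_h = 10))
  scene <- generate_timelapse(cfg)
  px <- cfg$pixel_size_um
  gfp <- get_channel(scene$stack, 1, "GFP")
  mask_area <- sum(gfp >= cfg$cytosol_level / 2) * px^2
  expect_lt(abs(mask_area - cfg$cell_area_um2) / cfg$cell_area_um2, 0.05)

  pos <- t(vapply(scene$ground_truth$frames, function(f) f$nucleus_um,
                  numeric(2)))
  step <- cfg$speed_um_per_h * cfg$interval_min / 60
  expect_equal(diff(pos[, 1]), rep(step, cfg$n_frames - 1), tolerance = 1e-12)
  expect_equal(diff(pos[, 2]), rep(0, cfg$n_frames - 1), tolerance = 1e-12)
})

test_that("presets encode the experimental conditions", {
  ns <- scene_preset("normal_static")
  nm <- scene_preset("normal_motile")
  tm <- scene_preset("transformed_motile")
  sv <- scene_preset("starved")
  ly <- scene_preset("lysotracker_motile")
  expect_identical(ns$dot_spatial_model, "isotropic")
  expect_identical(ns$speed_um_per_h, 0)
  expect_identical(scene_preset("transformed_static")$speed_um_per_h, 0)
  expect_gte(tm$speed_um_per_h / nm$speed_um_per_h, 3)
  expect_identical(sv$n_yellow, ns$n_yellow)
  expect_gt(sv$n_red, ns$n_red)
  expect_true("LYSO" %in% ly$channels && !"GFP" %in% ly$channels)
  expect_error(scene_preset("unknown_condition"))
})

test_that("geometrically infeasible dot requests are rejected", {
  expect_error(generate_timelapse(tiny_config(n_yellow = 500, n_red = 500)),
               "infeasible")
})
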