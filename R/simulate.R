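#' Generate a synthetic micro-pattern time lapse with ground truth
#'
#' Renders a single micro-pattern-confined cell over `n_frames` frames.  The
#' cell translates along +x at the configured speed; yellow dots are rendered
#' at identical positions in the GFP and RFP channels, red dots in RFP only;
#' the nucleus is an ellipse in the far-red channel; the cytosol appears as
#' diffuse signal in the fluorescence channels and as an outline in the
#' transmission channel.  Output is a pure function of (config, seed).
#'
#' Dot placement enforces the configured minimum centre separation by
#' rejection sampling; geometrically infeasible requests (too many dots for
#' the available cell area) are rejected with an error.
#'
#' @param config A [scene_config()].
#' @return List with `stack` (a [timelapse_stack()]) and `ground_truth`
#'   (class `ground_truth`): per-frame true cell polygon, nucleus centroid,
#'   dot records, velocity, and per-portion histograms of the true dot centres
#'   under the same partition rule as the analysis; plus a combined `dots`
#'   data frame and the per-portion bin layout.
#' @export
#' @examples
#' sc <- generate_timelapse(scene_config(cell_area_um2 = 300, n_frames = 2,
#'                                       n_yellow = 5, n_red = 5, seed = 3))
#' n_frames(sc$stack)
generate_timelapse <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  n_dots <- config$n_yellow + config$n_red
  if (n_dots * pi * (config$dot_min_separation_um / 2)^2 >
      0.55 * config$cell_area_um2)
    stop("infeasible geometry: ", n_dots, " dots at minimum separation ",
         config$dot_min_separation_um, " um cannot be placed in ",
         config$cell_area_um2, " um^2")
  withr::with_seed(config$seed, generate_timelapse_impl(config))
}

generate_timelapse_impl <- function(config) {
  px <- config$pixel_size_um
  shape <- cell_shape(config)
  L <- shape$length_um
  step_um <- config$speed_um_per_h * config$interval_min / 60
  margin <- 8
  width_um <- L + (config$n_frames - 1) * step_um + 2 * margin
  height_um <- 2 * shape$max_halfwidth_um + 2 * margin
  nx <- as.integer(ceiling(width_um / px)) + 1L
  ny <- as.integer(ceiling(height_um / px)) + 1L
  xs <- (seq_len(nx) - 1) * px
  ys <- (seq_len(ny) - 1) * px
  yc <- (ny - 1) / 2 * px

  nuc_x_local <- config$nucleus_rel_position * L
  nuc_ax <- nucleus_axes(shape, nuc_x_local)
  sig_px <- config$dot_sigma_um / px

  images <- vector("list", config$n_frames)
  gt_frames <- vector("list", config$n_frames)
  all_dots <- list()

  for (t in seq_len(config$n_frames)) {
    offset <- margin + (t - 1) * step_um
    part <- partition_bins(offset, offset + L, offset + nuc_x_local)
    dots <- place_dots(config, shape, part, offset)
    dots$frame <- t

    hw <- shape$halfwidth(xs - offset)
    mask <- outer(abs(ys - yc), hw, "<=") & rep(hw > 0, each = ny)
    cyto <- config$cytosol_level * mask

    chans <- list()
    if (config$single_channel) {
      lyso <- cyto
      for (i in seq_len(nrow(dots)))
        lyso <- add_gaussian(lyso, dots$x_um[i] / px, (dots$y_um[i] + yc) / px,
                             sig_px, config$dot_amplitude)
      chans$LYSO <- lyso
    } else {
      gfp <- cyto; rfp <- cyto
      for (i in seq_len(nrow(dots))) {
        xp <- dots$x_um[i] / px; yp <- (dots$y_um[i] + yc) / px
        rfp <- add_gaussian(rfp, xp, yp, sig_px, config$dot_amplitude)
        if (dots$class[i] == "yellow")
          gfp <- add_gaussian(gfp, xp, yp, sig_px, config$dot_amplitude)
      }
      chans$GFP <- gfp; chans$RFP <- rfp
    }
    chans$NUC <- render_nucleus(nx, ny, px, offset + nuc_x_local, yc,
                                nuc_ax["a"], nuc_ax["b"],
                                config$nucleus_amplitude)
    if ("TRANS" %in% config$channels) {
      band <- abs(outer(abs(ys - yc), hw, "-")) <= 0.4 &
        rep(hw > 0.4, each = ny)
      chans$TRANS <- matrix(100, ny, nx) - 25 * band
    }
    frame <- lapply(config$channels, function(ch) {
      apply_noise(chans[[ch]], config$noise)
    })
    names(frame) <- config$channels
    images[[t]] <- frame

    # ground truth in image coordinates (y relative to top edge)
    dots_img <- dots
    dots_img$y_um <- dots$y_um + yc
    gt_class <- if (config$single_channel) "lysosome"
                else ifelse(dots$class == "yellow", "autophagosome",
                            "autolysosome")
    hist_by <- function(cls) {
      x <- dots$x_um[gt_class == cls] + 0 # local x already includes offset
      tabulate(portion_index(x, part) + 1L, nbins = 10)
    }
    classes <- unique(gt_class)
    hists <- lapply(classes, hist_by)
    names(hists) <- classes
    hists$all <- tabulate(portion_index(dots$x_um, part) + 1L, nbins = 10)
    gt_frames[[t]] <- list(
      polygon = shape_polygon(shape, offset_x = offset, y_center = yc),
      nucleus_um = c(x = offset + nuc_x_local, y = yc),
      dots = transform(dots_img, class = gt_class),
      velocity_um_per_min = c(step_um / config$interval_min, 0),
      partition = part,
      histograms = hists)
    all_dots[[t]] <- gt_frames[[t]]$dots
  }

  stack <- timelapse_stack(images, config$channels, px, config$interval_min,
                           migration_direction = c(1, 0))
  gt <- structure(list(frames = gt_frames,
                       dots = do.call(rbind, all_dots),
                       cell_length_um = L,
                       nucleus_rel_position = config$nucleus_rel_position,
                       cell_area_um2 = config$cell_area_um2,
                       speed_um_per_h = config$speed_um_per_h,
                       config = config),
                  class = "ground_truth")
  list(stack = stack, ground_truth = gt)
}

# Sample dot centres for one frame.  x in image coordinates (offset applied),
# y relative to the cell midline.  Enforces the minimum separation rule.
place_dots <- function(config, shape, part, offset) {
  n <- config$n_yellow + config$n_red
  res <- matrix(NA_real_, n, 2)
  if (n == 0)
    return(data.frame(class = character(0), x_um = numeric(0),
                      y_um = numeric(0), radius_um = numeric(0),
                      frame = integer(0)))
  L <- shape$length_um
  m <- 2 * config$dot_sigma_um + 0.2
  min_sep2 <- config$dot_min_separation_um^2
  model <- config$dot_spatial_model
  if (model == "front_peaked") {
    ctr <- mean(part$boundaries[config$peak_portion + 1:2]) - offset
    sdx <- config$peak_concentration_bins *
      mean(part$widths[config$peak_portion + 1])
  } else if (model == "scattered") {
    ctr <- stats::runif(1, 0.2 * L, 0.8 * L)
    sdx <- config$scatter_sigma_um
  }
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(600)) {
      x <- switch(model,
        isotropic = stats::runif(1, m, L - m),
        front_peaked = stats::rnorm(1, ctr, sdx),
        scattered = stats::rnorm(1, ctr, sdx))
      if (x < m || x > L - m) next
      h <- shape$halfwidth(x)
      if (model == "isotropic" && stats::runif(1) > h / shape$max_halfwidth_um)
        next # area-uniform placement
      if (h <= m) next
      y <- stats::runif(1, -(h - m), h - m)
      if (i > 1) {
        d2 <- (res[seq_len(i - 1), 1] - x)^2 + (res[seq_len(i - 1), 2] - y)^2
        if (min(d2) < min_sep2) next
      }
      res[i, ] <- c(x, y); placed <- TRUE; break
    }
    if (!placed)
      stop("infeasible geometry: could not place dot ", i, " of ", n,
           " without violating the minimum-separation rule")
  }
  data.frame(class = rep(c("yellow", "red"),
                         c(config$n_yellow, config$n_red)),
             x_um = res[, 1] + offset, y_um = res[, 2],
             radius_um = 2 * config$dot_sigma_um)
}

# Add an isotropic Gaussian intensity profile at a (possibly fractional)
# pixel position (0-based x_px, y_px).
add_gaussian <- function(img, x_px, y_px, sigma_px, amp) {
  r <- ceiling(4 * sigma_px)
  cols <- max(1, floor(x_px) - r + 1):min(ncol(img), ceiling(x_px) + r + 1)
  rows <- max(1, floor(y_px) - r + 1):min(nrow(img), ceiling(y_px) + r + 1)
  gx <- exp(-((cols - 1) - x_px)^2 / (2 * sigma_px^2))
  gy <- exp(-((rows - 1) - y_px)^2 / (2 * sigma_px^2))
  img[rows, cols] <- img[rows, cols] + amp * outer(gy, gx)
  img
}

# Soft-edged ellipse for the nuclear stain.
render_nucleus <- function(nx, ny, px, cx_um, cy_um, a_um, b_um, amp) {
  xs <- (seq_len(nx) - 1) * px
  ys <- (seq_len(ny) - 1) * px
  u <- sqrt(outer(((ys - cy_um) / b_um)^2, ((xs - cx_um) / a_um)^2, "+"))
  amp * pmin(pmax((1.05 - u) / 0.1, 0), 1)
}

apply_noise <- function(signal, noise) {
  expected <- signal + noise$background
  out <- if (noise$poisson) {
    matrix(stats::rpois(length(expected), lambda = expected),
           nrow(expected), ncol(expected))
  } else expected
  if (noise$read_noise_sd > 0)
    out <- out + stats::rnorm(length(out), 0, noise$read_noise_sd)
  matrix(as.integer(pmin(pmax(round(out), 0), 65535)),
         nrow(expected), ncol(expected))
}

#' Write a synthetic scene to disk
#'
#' Writes the stack as multi-page TIFF (+ YAML sidecar), the ground-truth dot
#' table as CSV, and an echo of the scene configuration as YAML.
#'
#' @param scene List returned by [generate_timelapse()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(scene$stack, file.path(dir, "stack.tif"))
  write_ground_truth(scene$ground_truth, file.path(dir, "ground_truth.csv"))
  cfg <- scene$ground_truth$config
  cfg$noise <- unclass(cfg$noise)
  yaml::write_yaml(unclass(cfg), file.path(dir, "scene_config.yaml"))
  invisible(dir)
}
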