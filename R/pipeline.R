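#' Analysis run configuration
#'
#' Collects every parameter that affects results, so that a run is fully
#' reproducible from its config echo.  Dot-channel segmentation defaults add
#' difference-of-Gaussian background subtraction (sigma 8 px) so puncta are
#' isolated from the diffuse cytosolic reporter signal; cell and nucleus
#' segmentation use wider blurs and Otsu.
#'
#' @param direction Migration direction as a length-2 vector, or `NULL` to
#'   use the stack's annotation (falling back to +x).
#' @param auto_direction Estimate the direction from the net nucleus
#'   displacement instead (an automated stand-in for the user-drawn line;
#'   flagged in the QC log).
#' @param dot_params,cell_params,nucleus_params [segmentation_params()] for
#'   the three segmentation targets.
#' @param cell_source Channel for cell segmentation (`"GFP"`, `"RFP"`,
#'   `"TRANS"` or `"LYSO"`); `NULL` picks GFP, else LYSO, else RFP.
#' @param overlap_threshold GFP/RFP object overlap fraction at/above which an
#'   RFP object is an autophagosome (see [classify_compartments()]).
#' @param density_mode Density normalization for profiles (see
#'   [density_profile()]).
#' @param min_valid_frames Minimum analysable frames for a per-cell summary.
#' @param turning_tolerance_um Backward-step tolerance of [is_turning()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(direction = NULL,
                       auto_direction = FALSE,
                       dot_params = segmentation_params(
                         background_sigma_px = 8, closing_radius_px = 0L),
                       cell_params = segmentation_params(
                         gaussian_sigma_px = 3, min_dot_area_px = 200L),
                       nucleus_params = segmentation_params(
                         gaussian_sigma_px = 2, min_dot_area_px = 50L),
                       cell_source = NULL,
                       overlap_threshold = 0.3,
                       density_mode = c("fraction_of_total", "per_um_length",
                                        "raw"),
                       min_valid_frames = 3L,
                       turning_tolerance_um = 1) {
  density_mode <- match.arg(density_mode)
  stopifnot(overlap_threshold > 0, overlap_threshold <= 1,
            min_valid_frames >= 1, turning_tolerance_um >= 0)
  structure(list(direction = direction, auto_direction = auto_direction,
                 dot_params = dot_params, cell_params = cell_params,
                 nucleus_params = nucleus_params, cell_source = cell_source,
                 overlap_threshold = overlap_threshold,
                 density_mode = density_mode,
                 min_valid_frames = as.integer(min_valid_frames),
                 turning_tolerance_um = turning_tolerance_um),
            class = "run_config")
}

pick_cell_source <- function(stack, config) {
  if (!is.null(config$cell_source)) return(config$cell_source)
  for (ch in c("GFP", "LYSO", "RFP")) {
    if (ch %in% stack$channel_map) return(ch)
  }
  stop("no suitable channel for cell segmentation")
}

frame_nucleus_centroids <- function(stack, config) {
  t(vapply(seq_len(n_frames(stack)), function(t) {
    tryCatch(segment_nucleus(get_channel(stack, t, "NUC"),
                             config$nucleus_params,
                             stack$pixel_size_um)$centroid_um,
             lc3topo_no_nucleus = function(e) c(NA_real_, NA_real_))
  }, numeric(2)))
}

#' Run the full topology and motility analysis on one cell
#'
#' Per frame: segment nucleus, cell and compartments, classify compartments
#' (tandem-reporter dual channel, or single-channel lysosomes), rotate all
#' coordinates so the migration direction maps to +x, partition the cell into
#' the 10 nucleus-anchored portions, and accumulate per-portion counts, areas
#' and density profiles.  Across frames: track the nucleus centroid and
#' compute speed, d/D, direction autocorrelation and the turning flag.
#' Frames whose nucleus or cell cannot be segmented, or whose nucleus falls
#' outside the cell extent, are flagged and dropped; a per-cell summary is
#' reported only when at least `min_valid_frames` frames survive.
#'
#' @param stack A [timelapse_stack()].
#' @param config A [run_config()].
#' @param cell_id Identifier used in the output tables.
#' @param ground_truth Optional `ground_truth` carried through to the output
#'   (for recovery benchmarking of synthetic scenes).
#' @return A list of class `cell_profile`: per-frame details (`frames`),
#'   per-class T x 10 `counts`/`areas_um2`/`density` matrices, `track` and
#'   `metrics`, per-cell `summary`, a long-format `results` table keyed by
#'   (cell_id, frame, class, portion), and a `qc` log.
#' @export
run_cell <- function(stack, config = run_config(), cell_id = "cell",
                     ground_truth = NULL) {
  stopifnot(inherits(stack, "timelapse_stack"), inherits(config, "run_config"))
  px <- stack$pixel_size_um
  d <- dim(stack$images[[1]][[1]])
  center <- c((d[2] - 1) / 2, (d[1] - 1) / 2) * px
  single <- "LYSO" %in% stack$channel_map
  classes <- if (single) "lysosome" else c("autophagosome", "autolysosome")
  cell_source <- pick_cell_source(stack, config)

  direction <- config$direction
  if (is.null(direction)) direction <- stack$migration_direction
  auto_used <- FALSE
  nuc_raw <- frame_nucleus_centroids(stack, config)
  if (config$auto_direction) {
    ok <- which(stats::complete.cases(nuc_raw))
    if (length(ok) >= 2) {
      net <- nuc_raw[max(ok), ] - nuc_raw[min(ok), ]
      if (sum(net^2) > 0) { direction <- net; auto_used <- TRUE }
    }
  }
  if (is.null(direction)) direction <- c(1, 0)

  T <- n_frames(stack)
  frames <- vector("list", T)
  qc <- data.frame(frame = seq_len(T), valid = FALSE, n_gfp_only = 0L,
                   note = "", stringsAsFactors = FALSE)
  counts <- lapply(c(classes, "all"), function(cl)
    matrix(NA_real_, T, 10, dimnames = list(NULL, paste0("p", 0:9))))
  names(counts) <- c(classes, "all")
  areas <- counts
  dens <- counts
  nuc_norm <- matrix(NA_real_, T, 2)

  for (t in seq_len(T)) {
    if (!stats::complete.cases(nuc_raw)[t]) {
      qc$note[t] <- "no nucleus"; next
    }
    cellm <- tryCatch(
      segment_cell(get_channel(stack, t, cell_source), config$cell_params, px),
      error = function(e) NULL)
    if (is.null(cellm)) { qc$note[t] <- "no cell"; next }
    comp <- if (single) {
      single_channel_compartments(
        segment_compartments(get_channel(stack, t, "LYSO"),
                             config$dot_params, px))
    } else {
      classify_compartments(
        segment_compartments(get_channel(stack, t, "GFP"),
                             config$dot_params, px),
        segment_compartments(get_channel(stack, t, "RFP"),
                             config$dot_params, px),
        config$overlap_threshold)
    }
    qc$n_gfp_only[t] <- attr(comp, "n_gfp_only")
    # in-mask test at the (unrotated) centroid pixel
    if (nrow(comp) > 0) {
      rows <- pmin(pmax(round(comp$y_um / px) + 1, 1), d[1])
      cols <- pmin(pmax(round(comp$x_um / px) + 1, 1), d[2])
      comp$in_cell <- cellm$mask[cbind(rows, cols)]
    } else comp$in_cell <- logical(0)

    # axis normalization of every coordinate set
    nuc_rot <- normalize_axis(nuc_raw[t, ], direction, center)
    idx <- which(cellm$mask, arr.ind = TRUE)
    cell_xy <- cbind((idx[, 2] - 1) * px, (idx[, 1] - 1) * px)
    cell_rot_x <- normalize_axis(cell_xy, direction, center)[, 1]
    if (nrow(comp) > 0) {
      cen <- normalize_axis(cbind(comp$x_um, comp$y_um), direction, center)
      comp$x_um <- cen[, 1]; comp$y_um <- cen[, 2]
      comp$pixels <- lapply(comp$pixels, normalize_axis,
                            direction = direction, center = center)
    }
    part <- tryCatch(
      partition_bins(min(cell_rot_x), max(cell_rot_x), nuc_rot[1]),
      lc3topo_bad_partition = function(e) NULL)
    if (is.null(part)) { qc$note[t] <- "nucleus outside cell extent"; next }

    ap <- assign_portions(comp, part)
    for (cl in classes) {
      cc <- if (cl %in% rownames(ap$counts)) ap$counts[cl, ] else rep(0, 10)
      aa <- if (cl %in% rownames(ap$areas_um2)) ap$areas_um2[cl, ]
            else rep(0, 10)
      counts[[cl]][t, ] <- cc
      areas[[cl]][t, ] <- aa
      dens[[cl]][t, ] <- density_profile(cc, config$density_mode, part)
    }
    call <- colSums(ap$counts)
    aall <- colSums(ap$areas_um2)
    counts$all[t, ] <- call
    areas$all[t, ] <- aall
    dens$all[t, ] <- density_profile(call, config$density_mode, part)
    nuc_norm[t, ] <- nuc_rot
    qc$valid[t] <- TRUE
    frames[[t]] <- list(partition = part, compartments = ap$per_compartment,
                        excluded = ap$excluded, cell_area_um2 = cellm$area_um2,
                        nucleus_um = nuc_rot,
                        nucleus_rel_position = nucleus_relative_position(part))
  }

  track <- tryCatch(track_nucleus(nuc_norm, stack$interval_min),
                    error = function(e) NULL)
  metrics <- list(
    speed_um_per_h = if (is.null(track)) NA_real_ else average_speed(track),
    d_over_D = if (is.null(track)) NA_real_ else directionality_ratio(track),
    turning = if (is.null(track)) NA
              else is_turning(track, config$turning_tolerance_um),
    autocorrelation = if (is.null(track)) NULL else
      tryCatch(direction_autocorrelation(track), error = function(e) NULL))

  valid <- which(qc$valid)
  summary <- NULL
  if (length(valid) >= config$min_valid_frames) {
    mean_counts <- vapply(classes, function(cl)
      mean(rowSums(counts[[cl]][valid, , drop = FALSE])), numeric(1))
    mean_areas <- vapply(classes, function(cl)
      mean(rowSums(areas[[cl]][valid, , drop = FALSE])), numeric(1))
    summary <- list(
      cell_id = cell_id,
      n_valid_frames = length(valid),
      total_count = mean_counts,
      total_area_um2 = mean_areas,
      flux_ratio = if (single) NA_real_ else
        flux_ratio(mean_counts["autolysosome"], mean_counts["autophagosome"]),
      nucleus_rel_position = mean(vapply(frames[valid], function(f)
        f$nucleus_rel_position, numeric(1))),
      cell_area_um2 = mean(vapply(frames[valid], function(f)
        f$cell_area_um2, numeric(1))),
      mean_density = lapply(dens, function(m)
        colMeans(m[valid, , drop = FALSE])))
  }

  results <- do.call(rbind, lapply(valid, function(t) {
    do.call(rbind, lapply(c(classes, "all"), function(cl) {
      data.frame(cell_id = cell_id, frame = t, class = cl, portion = 0:9,
                 count = as.integer(counts[[cl]][t, ]),
                 area_um2 = areas[[cl]][t, ],
                 density = dens[[cl]][t, ],
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(results))
    results <- data.frame(cell_id = character(0), frame = integer(0),
                          class = character(0), portion = integer(0),
                          count = integer(0), area_um2 = numeric(0),
                          density = numeric(0))

  structure(list(cell_id = cell_id, classes = classes, frames = frames,
                 counts = counts, areas_um2 = areas, density = dens,
                 track = track, metrics = metrics, summary = summary,
                 results = results, qc = qc, direction = direction,
                 auto_direction_used = auto_used,
                 config = config, ground_truth = ground_truth),
            class = "cell_profile")
}

#' @export
print.cell_profile <- function(x, ...) {
  cat(sprintf("cell_profile '%s': %d/%d valid frames; classes: %s\n",
              x$cell_id, sum(x$qc$valid), nrow(x$qc),
              paste(x$classes, collapse = ", ")))
  if (!is.null(x$summary))
    cat(sprintf("  mean counts: %s; flux ratio %.3g; speed %.2f um/h\n",
                paste(sprintf("%s %.1f", names(x$summary$total_count),
                              x$summary$total_count), collapse = ", "),
                x$summary$flux_ratio, x$metrics$speed_um_per_h))
  invisible(x)
}

#' Simulate and analyse a cohort of cells under one condition
#'
#' Generates `n_cells` synthetic cells from a preset (or explicit
#' [scene_config()]), with per-cell seeds `base_seed + 0:(n-1)`, runs
#' [run_cell()] on each, and aggregates per-portion density profiles (mean
#' +/- SEM over cells) per compartment class.  Turning cells are excluded
#' from the topology aggregation but kept in the summary table.
#'
#' @param preset Preset name for [scene_preset()] or a `scene_config`.
#' @param n_cells Number of cells.
#' @param base_seed First per-cell seed.
#' @param config A [run_config()].
#' @param keep_cells Keep the individual `cell_profile`s (with ground truth)?
#' @return A list of class `cohort_result`: `profiles` (per class: cells x 10
#'   matrix of per-cell frame-averaged densities), `mean_profile`,
#'   `sem_profile`, `summary` (per-cell data frame), `manifest` (cell ids and
#'   seeds), and optionally `cells`.
#' @export
run_cohort <- function(preset, n_cells, base_seed = 1L,
                       config = run_config(), keep_cells = TRUE) {
  stopifnot(n_cells >= 1)
  name <- if (is.character(preset)) preset else "custom"
  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cfg <- if (is.character(preset)) scene_preset(preset, seed = base_seed + i - 1L)
           else { p <- preset; p$seed <- base_seed + i - 1L; p }
    scene <- generate_timelapse(cfg)
    cells[[i]] <- run_cell(scene$stack, config,
                           cell_id = sprintf("%s_%02d", name, i),
                           ground_truth = scene$ground_truth)
  }
  classes <- c(cells[[1]]$classes, "all")
  keep <- vapply(cells, function(cl)
    !is.null(cl$summary) && !isTRUE(cl$metrics$turning), logical(1))
  profiles <- lapply(classes, function(cl) {
    m <- do.call(rbind, lapply(cells[keep], function(ce)
      ce$summary$mean_density[[cl]]))
    if (is.null(m)) m <- matrix(numeric(0), 0, 10)
    rownames(m) <- vapply(cells[keep], function(ce) ce$cell_id, character(1))
    m
  })
  names(profiles) <- classes
  summary <- do.call(rbind, lapply(cells, function(ce) {
    s <- ce$summary
    data.frame(cell_id = ce$cell_id,
               n_valid_frames = if (is.null(s)) 0L else s$n_valid_frames,
               speed_um_per_h = ce$metrics$speed_um_per_h,
               d_over_D = ce$metrics$d_over_D,
               turning = isTRUE(ce$metrics$turning),
               flux_ratio = if (is.null(s)) NA_real_ else s$flux_ratio,
               nucleus_rel_position = if (is.null(s)) NA_real_
                                      else s$nucleus_rel_position,
               cell_area_um2 = if (is.null(s)) NA_real_ else s$cell_area_um2,
               stringsAsFactors = FALSE)
  }))
  for (cl in cells[[1]]$classes) {
    summary[[paste0("count_", cl)]] <- vapply(cells, function(ce)
      if (is.null(ce$summary)) NA_real_ else ce$summary$total_count[[cl]],
      numeric(1))
    summary[[paste0("area_", cl, "_um2")]] <- vapply(cells, function(ce)
      if (is.null(ce$summary)) NA_real_ else ce$summary$total_area_um2[[cl]],
      numeric(1))
  }
  manifest <- data.frame(cell_id = vapply(cells, `[[`, character(1), "cell_id"),
                         seed = as.integer(base_seed) + seq_len(n_cells) - 1L,
                         included = keep)
  structure(list(condition = name,
                 profiles = profiles,
                 mean_profile = lapply(profiles, colMeans),
                 sem_profile = lapply(profiles, function(m)
                   apply(m, 2, stats::sd) / sqrt(nrow(m))),
                 summary = summary, manifest = manifest,
                 cells = if (keep_cells) cells else NULL),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("cohort_result '%s': %d cells (%d in topology aggregate)\n",
              x$condition, nrow(x$summary), sum(x$manifest$included)))
  cat("  mean 'all' profile:",
      paste(sprintf("%.2f", x$mean_profile$all), collapse = " "), "\n")
  invisible(x)
}

#' Write per-cell analysis outputs to a run directory
#'
#' Writes the long per-portion results table, the track, the motility metrics
#' and the QC log as CSV, plus a YAML echo of the run configuration.
#'
#' @param result A `cell_profile` from [run_cell()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cell_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_results(result$results, file.path(dir, "portions.csv"))
  if (!is.null(result$track)) {
    tr <- result$track
    write_results(data.frame(cell_id = result$cell_id,
                             frame = seq_len(nrow(tr$positions)),
                             x_um = tr$positions[, 1], y_um = tr$positions[, 2]),
                  file.path(dir, "track.csv"))
    if (!is.null(result$metrics$autocorrelation))
      write_results(cbind(cell_id = result$cell_id,
                          result$metrics$autocorrelation),
                    file.path(dir, "autocorrelation.csv"))
  }
  write_results(data.frame(cell_id = result$cell_id,
                           speed_um_per_h = result$metrics$speed_um_per_h,
                           d_over_D = result$metrics$d_over_D,
                           turning = isTRUE(result$metrics$turning)),
                file.path(dir, "metrics.csv"))
  write_results(result$qc, file.path(dir, "qc.csv"))
  cfg <- result$config
  cfg$dot_params <- unclass(cfg$dot_params)
  cfg$cell_params <- unclass(cfg$cell_params)
  cfg$nucleus_params <- unclass(cfg$nucleus_params)
  yaml::write_yaml(unclass(cfg), file.path(dir, "run_config.yaml"))
  invisible(dir)
}
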