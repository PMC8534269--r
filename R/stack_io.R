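#' Multi-channel time-lapse stack
#'
#' Container for a T-frame, C-channel time lapse of one field of view.  Images
#' are stored as integer matrices indexed `[y, x]` (row = y increasing
#' downward, column = x increasing rightward); physical position of pixel
#' `(row, col)` is `(col - 1, row - 1) * pixel_size_um`.
#'
#' @param images List of frames; each frame a named list of 2D non-negative
#'   integer matrices, one per channel, all sharing one shape.
#' @param channel_map Character vector of channel names in storage order,
#'   e.g. `c("GFP","RFP","NUC","TRANS")` or `c("LYSO","NUC")`.
#' @param pixel_size_um Pixel size in micrometres (> 0).
#' @param interval_min Frame interval in minutes (> 0).
#' @param migration_direction Optional length-2 vector giving the annotated
#'   direction of migration in image coordinates (the user-drawn line of the
#'   original workflow); `NULL` if not annotated.
#' @return A list of class `timelapse_stack`.
#' @export
timelapse_stack <- function(images, channel_map, pixel_size_um, interval_min,
                            migration_direction = NULL) {
  stopifnot(length(images) >= 1, pixel_size_um > 0, interval_min > 0)
  channel_map <- as.character(channel_map)
  dims <- dim(images[[1]][[1]])
  for (fr in images) {
    stopifnot(length(fr) == length(channel_map))
    for (ch in fr) {
      stopifnot(is.matrix(ch), identical(dim(ch), dims), all(ch >= 0))
    }
  }
  if (!is.null(migration_direction)) {
    stopifnot(length(migration_direction) == 2)
    if (sum(migration_direction^2) == 0)
      stop("migration_direction must be non-zero")
  }
  images <- lapply(images, function(fr) stats::setNames(fr, channel_map))
  structure(list(images = images, channel_map = channel_map,
                 pixel_size_um = pixel_size_um, interval_min = interval_min,
                 migration_direction = migration_direction),
            class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$images[[1]][[1]])
  cat(sprintf(
    "timelapse_stack: %d frames x %d channels (%s), %d x %d px, %.3f um/px, %g min interval\n",
    n_frames(x), length(x$channel_map), paste(x$channel_map, collapse = ","),
    d[2], d[1], x$pixel_size_um, x$interval_min))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A [timelapse_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) length(stack$images)

#' Total duration of a time lapse in minutes
#'
#' A run from 0 to 120 min at 30-min intervals holds 5 frames, so the duration
#' is `(T - 1) * interval_min`.
#'
#' @param stack A [timelapse_stack()].
#' @return Duration in minutes.
#' @export
duration_min <- function(stack) (n_frames(stack) - 1) * stack$interval_min

#' Extract one channel image of one frame
#' @param stack A [timelapse_stack()].
#' @param frame Frame index (1-based).
#' @param channel Channel name.
#' @return Integer intensity matrix.
#' @export
get_channel <- function(stack, frame, channel) {
  if (!channel %in% stack$channel_map)
    stop("unknown channel: ", channel)
  stack$images[[frame]][[channel]]
}

#' Write a stack as multi-page TIFF plus metadata sidecar
#'
#' Pages are written in TCYX order (frame-major, channels within frame) as
#' 16-bit grayscale; acquisition metadata (channel names, pixel size, frame
#' interval, axis order, optional migration direction) goes to a YAML sidecar
#' `<path>.yaml`, so a written scene is self-describing.
#'
#' @param stack A [timelapse_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  pages <- list()
  for (fr in stack$images)
    for (ch in fr)
      pages[[length(pages) + 1L]] <- ch / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(axis_order = "TCYX",
               n_frames = n_frames(stack),
               channels = as.list(stack$channel_map),
               pixel_size_um = stack$pixel_size_um,
               interval_min = stack$interval_min,
               migration_direction =
                 if (is.null(stack$migration_direction)) NULL
                 else as.list(as.numeric(stack$migration_direction)))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a multi-page TIFF time lapse
#'
#' Reads TCYX-ordered pages back into a [timelapse_stack()].  Metadata is
#' taken from the YAML sidecar written by [write_stack()] when present;
#' otherwise `channel_map`, `pixel_size_um` and `interval_min` must be given.
#' The declared channel count must divide the page count exactly.
#'
#' @param path TIFF path.
#' @param channel_map,pixel_size_um,interval_min,migration_direction Metadata
#'   overrides (required if no sidecar exists).
#' @return A [timelapse_stack()].
#' @export
read_stack <- function(path, channel_map = NULL, pixel_size_um = NULL,
                       interval_min = NULL, migration_direction = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (is.null(channel_map)) channel_map <- unlist(meta$channels)
    if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
    if (is.null(interval_min)) interval_min <- meta$interval_min
    if (is.null(migration_direction) && !is.null(meta$migration_direction))
      migration_direction <- unlist(meta$migration_direction)
  }
  if (is.null(channel_map) || is.null(pixel_size_um) || is.null(interval_min))
    stop("channel_map, pixel_size_um and interval_min are required when no ",
         "sidecar metadata is present")
  if (is.null(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be positive")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  C <- length(channel_map)
  if (length(pages) %% C != 0)
    stop(sprintf("page count (%d) is not a multiple of declared channels (%d)",
                 length(pages), C))
  T <- length(pages) %/% C
  images <- vector("list", T)
  for (t in seq_len(T)) {
    frame <- vector("list", C)
    for (c in seq_len(C)) {
      m <- pages[[(t - 1) * C + c]]
      if (length(dim(m)) == 3) m <- m[, , 1] # tolerate grey written as RGB
      storage.mode(m) <- "double"
      frame[[c]] <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
    }
    images[[t]] <- frame
  }
  timelapse_stack(images, channel_map, pixel_size_um, interval_min,
                  migration_direction)
}

#' Write a results table to CSV
#'
#' Column order is preserved and numeric columns are written with full
#' (round-trippable) precision, so [read_results()] reproduces the table
#' exactly.  Physical quantities carry their units in the column names
#' (`_um`, `_um2`, `_min`).
#'
#' @param table A data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  data.table::fwrite(out, path, quote = "auto")
  invisible(path)
}

#' Read a results table written by [write_results()]
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_results <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write ground-truth dot records to CSV
#'
#' One row per dot per frame with columns
#' `frame, class, x_um, y_um, radius_um`.
#'
#' @param ground_truth A `ground_truth` object from [generate_timelapse()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  write_results(ground_truth$dots[, c("frame", "class", "x_um", "y_um",
                                      "radius_um")], path)
}
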