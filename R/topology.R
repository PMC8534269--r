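#' Rotate coordinates so a migration direction maps onto +x
#'
#' Applies the rigid rotation that sends `direction` to the positive x-axis to
#' a set of 2D points, about `center`.  After normalization the cell front is
#' at larger x than the nucleus centroid and the back at smaller x.
#'
#' @param points Numeric matrix (n x 2) or length-2 vector of (x, y)
#'   coordinates in micrometres.
#' @param direction Non-zero length-2 vector along the direction of migration
#'   (the user-annotated line of the original workflow).
#' @param center Rotation centre, default the origin.
#' @return Rotated coordinates, same shape as `points`.
#' @export
#' @examples
#' normalize_axis(c(0, 2), direction = c(0, 1)) # -> (2, 0)
normalize_axis <- function(points, direction, center = c(0, 0)) {
  stopifnot(length(direction) == 2)
  if (sum(direction^2) == 0) stop("direction vector must be non-zero")
  vec <- is.null(dim(points))
  if (vec) points <- matrix(points, ncol = 2)
  stopifnot(ncol(points) == 2)
  theta <- atan2(direction[2], direction[1])
  co <- cos(theta); si <- sin(theta)
  dx <- points[, 1] - center[1]; dy <- points[, 2] - center[2]
  out <- cbind(center[1] + co * dx + si * dy,
               center[2] - si * dx + co * dy)
  colnames(out) <- colnames(points)
  if (vec) out <- drop(out)
  out
}

partition_bins <- function(x_min, x_max, nucleus_x) {
  if (!(nucleus_x > x_min && nucleus_x < x_max))
    stop(structure(class = c("lc3topo_bad_partition", "error", "condition"),
                   list(message = sprintf(
                     "nucleus centroid x=%.3f outside cell extent [%.3f, %.3f]",
                     nucleus_x, x_min, x_max), call = NULL)))
  b <- c(seq(x_min, nucleus_x, length.out = 6),
         seq(nucleus_x, x_max, length.out = 6)[-1])
  structure(list(boundaries = b, nucleus_x = nucleus_x,
                 x_min = x_min, x_max = x_max,
                 back_width = (nucleus_x - x_min) / 5,
                 front_width = (x_max - nucleus_x) / 5,
                 widths = diff(b)),
            class = "cell_partition")
}

#' Partition a cell into 10 nucleus-anchored back-front portions
#'
#' The cell's x-extent is split into five equal-width back portions (back edge
#' to nucleus centroid, positions #0-#5) and five equal-width front portions
#' (nucleus centroid to front edge, positions #5-#10).  The nucleus centroid
#' always falls on boundary position #5.  Portion k spans
#' `[b_k, b_{k+1})`, half-open, with the final portion right-closed.
#'
#' @param cell_mask Either a logical/numeric mask matrix (`[y, x]`, foreground
#'   > 0) or a numeric vector of foreground x-coordinates in micrometres
#'   (already axis-normalized).
#' @param nucleus_centroid Nucleus centroid: scalar x or (x, y) vector, um.
#' @param pixel_size_um Pixel size, required when `cell_mask` is a matrix.
#' @return A `cell_partition` with 11 boundaries `b_0..b_10` (um), the
#'   nucleus x (= `b_5`), and the per-portion widths.
#' @export
#' @examples
#' p <- compute_partition(c(0, 100), nucleus_centroid = 40)
#' p$boundaries # 0 8 16 24 32 40 52 64 76 88 100
compute_partition <- function(cell_mask, nucleus_centroid,
                              pixel_size_um = NULL) {
  if (is.matrix(cell_mask)) {
    stopifnot(!is.null(pixel_size_um), pixel_size_um > 0)
    cols <- which(colSums(cell_mask > 0) > 0)
    if (length(cols) == 0) stop("empty cell mask")
    xs <- (range(cols) - 1) * pixel_size_um
  } else {
    xs <- range(as.numeric(cell_mask))
  }
  partition_bins(xs[1], xs[2], nucleus_centroid[1])
}

#' @export
print.cell_partition <- function(x, ...) {
  cat("cell_partition: x", sprintf("[%.2f, %.2f] um,", x$x_min, x$x_max),
      sprintf("nucleus at %.2f (position #5),", x$nucleus_x),
      sprintf("back width %.2f, front width %.2f um", x$back_width,
              x$front_width), "\n")
  invisible(x)
}

#' Portion index of x-positions under a partition
#'
#' @param x Numeric x-coordinates (um, axis-normalized).
#' @param partition A `cell_partition`.
#' @return Integer portion indices in 0..9; `NA` outside the cell extent.
#'   A position exactly at `b_5` falls in portion 5 (front side).
#' @export
portion_index <- function(x, partition) {
  idx <- findInterval(x, partition$boundaries, rightmost.closed = TRUE)
  idx[x < partition$x_min | x > partition$x_max] <- NA_integer_
  as.integer(idx - 1L)
}

#' Per-portion counts and areas of classified compartments
#'
#' Counts assign each compartment to the portion holding its centroid; areas
#' assign each compartment pixel to the portion holding that pixel, so a
#' compartment straddling a boundary contributes area to both portions but its
#' count to one.  Compartments whose centroid lies outside the cell mask
#' (column `in_cell` = FALSE) are excluded and returned for QC.
#'
#' @param compartments Data frame with columns `class`, `x_um` (normalized
#'   centroid x), `area_um2`, optionally `in_cell` (logical) and `pixels`
#'   (list column of n x 2 matrices of member-pixel coordinates, um,
#'   normalized).  When `pixels` is absent, each compartment's whole area
#'   falls into its centroid's portion.
#' @param partition A `cell_partition` for the same frame.
#' @return List with `counts` and `areas_um2` (class x 10 matrices; one row
#'   per class present), `per_compartment` (input rows with `portion`), and
#'   `excluded` (out-of-mask or out-of-extent rows).
#' @export
assign_portions <- function(compartments, partition) {
  classes <- intersect(c("autophagosome", "autolysosome", "lysosome"),
                       unique(compartments$class))
  if (length(classes) == 0) classes <- unique(compartments$class)
  counts <- matrix(0L, length(classes), 10,
                   dimnames = list(classes, paste0("p", 0:9)))
  areas <- matrix(0, length(classes), 10,
                  dimnames = list(classes, paste0("p", 0:9)))
  in_cell <- if ("in_cell" %in% names(compartments)) compartments$in_cell
             else rep(TRUE, nrow(compartments))
  portion <- rep(NA_integer_, nrow(compartments))
  if (nrow(compartments) > 0)
    portion <- portion_index(compartments$x_um, partition)
  keep <- in_cell & !is.na(portion)
  for (i in which(keep)) {
    cl <- as.character(compartments$class[i])
    k <- portion[i] + 1L
    counts[cl, k] <- counts[cl, k] + 1L
    if (!is.null(compartments$pixels) &&
        is.matrix(compartments$pixels[[i]])) {
      px <- compartments$pixels[[i]]
      pk <- portion_index(px[, 1], partition)
      pk <- pk[!is.na(pk)]
      if (length(pk) > 0) {
        per_px <- compartments$area_um2[i] / nrow(px)
        tab <- tabulate(pk + 1L, nbins = 10)
        areas[cl, ] <- areas[cl, ] + tab * per_px
      }
    } else {
      areas[cl, k] <- areas[cl, k] + compartments$area_um2[i]
    }
  }
  per_compartment <- compartments
  per_compartment$portion <- portion
  list(counts = counts, areas_um2 = areas,
       per_compartment = per_compartment[keep, , drop = FALSE],
       excluded = per_compartment[!keep, , drop = FALSE])
}

#' Density profile over the 10 portions
#'
#' @param values Numeric 10-vector of per-portion counts or areas.
#' @param mode `"fraction_of_total"` (divides by the total; sums to 1),
#'   `"per_um_length"` (divides each portion by its physical width, which
#'   differs between front and back), or `"raw"`.
#' @param partition `cell_partition` supplying widths (required for
#'   `per_um_length`).
#' @return Numeric 10-vector with attributes `mode` and, for a zero total in
#'   fraction mode, `undefined = TRUE`.
#' @export
density_profile <- function(values, mode = c("fraction_of_total",
                                             "per_um_length", "raw"),
                            partition = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(values) == 10, all(values >= 0))
  out <- switch(mode,
    raw = as.numeric(values),
    fraction_of_total = {
      tot <- sum(values)
      if (tot > 0) as.numeric(values) / tot else rep(0, 10)
    },
    per_um_length = {
      stopifnot(inherits(partition, "cell_partition"))
      as.numeric(values) / partition$widths
    })
  attr(out, "mode") <- mode
  if (mode == "fraction_of_total" && sum(values) == 0)
    attr(out, "undefined") <- TRUE
  out
}

#' Autophagy flux ratio (autolysosomes / autophagosomes)
#'
#' Red-only over yellow dot counts; a larger ratio indicates higher autophagy
#' flux (more reporter delivered to the degradative compartment per
#' autophagosome).
#'
#' @param n_red Autolysosome (red-only dot) count.
#' @param n_yellow Autophagosome (yellow dot) count.
#' @return `n_red / n_yellow`, or `NA` (undefined) when `n_yellow` is 0.
#' @export
flux_ratio <- function(n_red, n_yellow) {
  stopifnot(n_red >= 0, n_yellow >= 0)
  if (n_yellow == 0) return(NA_real_)
  n_red / n_yellow
}

#' Nucleus position relative to normalized cell length
#'
#' `(b_5 - b_0) / (b_10 - b_0)`: 0 at the back edge, 1 at the front edge.
#'
#' @param partition A `cell_partition`.
#' @return Value in (0, 1).
#' @export
nucleus_relative_position <- function(partition) {
  stopifnot(inherits(partition, "cell_partition"))
  len <- partition$x_max - partition$x_min
  if (len <= 0) stop("zero cell length")
  (partition$nucleus_x - partition$x_min) / len
}

#' Stack per-frame density profiles and trace the density peak
#'
#' @param profiles T x 10 matrix (or list of 10-vectors) of per-frame density
#'   profiles for one class.
#' @return List of class `temporal_profile`: `matrix` (T x 10), `peak_trace`
#'   (0-based argmax portion per frame; ties take the lower index), `mean` and
#'   `sem` per portion across frames.
#' @export
temporal_profiles <- function(profiles) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  stopifnot(is.matrix(profiles), ncol(profiles) == 10)
  peak <- apply(profiles, 1, which.max) - 1L
  n <- nrow(profiles)
  sem <- if (n > 1) apply(profiles, 2, stats::sd) / sqrt(n) else rep(NA_real_, 10)
  structure(list(matrix = profiles, peak_trace = as.integer(peak),
                 mean = colMeans(profiles), sem = sem),
            class = "temporal_profile")
}
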