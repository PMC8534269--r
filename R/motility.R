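#' Build a nucleus-centroid track from per-frame positions
#'
#' Positions are the per-frame nucleus centroids in the axis-normalized frame
#' (um).  Gap policy: a single missing frame (NA position) is bridged by
#' linear interpolation and flagged; two or more consecutive missing frames
#' truncate the track at the gap.
#'
#' @param positions T x 2 numeric matrix (or data frame with `x_um`, `y_um`)
#'   of per-frame positions; missing frames as NA rows.
#' @param interval_min Frame interval in minutes.
#' @return List of class `cell_track`: `positions` (T x 2), `interval_min`,
#'   `interpolated` (logical per frame), `truncated` (TRUE if the tail was
#'   dropped).
#' @export
track_nucleus <- function(positions, interval_min) {
  if (is.data.frame(positions))
    positions <- cbind(positions$x_um, positions$y_um)
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2, interval_min > 0)
  missing <- !stats::complete.cases(positions)
  runs <- rle(missing)
  # truncate at the first run of >= 2 consecutive missing frames
  bad <- which(runs$values & runs$lengths >= 2)
  if (length(bad) > 0) {
    cut <- sum(runs$lengths[seq_len(bad[1] - 1)])
    positions <- positions[seq_len(cut), , drop = FALSE]
    missing <- missing[seq_len(cut)]
    truncated <- TRUE
  } else truncated <- FALSE
  if (length(missing) > 0 && missing[length(missing)]) { # trailing single NA
    positions <- positions[-length(missing), , drop = FALSE]
    missing <- missing[-length(missing)]
  }
  if (length(missing) > 0 && missing[1])
    stop("track cannot start with a missing frame")
  if (nrow(positions) < 2)
    stop("need at least 2 frames with detected nuclei")
  for (i in which(missing)) {
    positions[i, ] <- (positions[i - 1, ] + positions[i + 1, ]) / 2
  }
  structure(list(positions = positions, interval_min = interval_min,
                 interpolated = missing, truncated = truncated),
            class = "cell_track")
}

track_steps <- function(track) {
  diff(track$positions)
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("cell_track: %d frames at %g min; speed %.2f um/h, d/D %s\n",
              nrow(x$positions), x$interval_min, average_speed(x),
              format(directionality_ratio(x), digits = 3)))
  invisible(x)
}

#' Average cell speed in micrometres per hour
#'
#' Total path length divided by total elapsed time ("average speed by cell").
#'
#' @param track A `cell_track`.
#' @return Speed in um/h.
#' @export
average_speed <- function(track) {
  v <- track_steps(track)
  path <- sum(sqrt(rowSums(v^2)))
  total_min <- (nrow(track$positions) - 1) * track$interval_min
  path / total_min * 60
}

#' Directionality ratio d/D
#'
#' `d` is the straight-line distance from start to endpoint, `D` the total
#' track distance; the ratio is 1 for perfectly straight motion and 0 for a
#' closed loop.
#'
#' @param track A `cell_track`.
#' @return Value in `[0, 1]`; `NA` (undefined) when `D = 0`.
#' @export
directionality_ratio <- function(track) {
  v <- track_steps(track)
  D <- sum(sqrt(rowSums(v^2)))
  if (D == 0) return(NA_real_)
  p <- track$positions
  d <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  d / D
}

#' Direction autocorrelation over time lags
#'
#' For displacement vectors separated by `lag` frame intervals,
#' `A(lag) = mean(cos(phi_{t+lag} - phi_t))` over all pairs where both steps
#' are non-zero (zero-length steps carry no direction and are excluded).
#' `A(0) = 1` whenever at least one non-zero step exists.
#'
#' @param track A `cell_track`.
#' @param max_lag Largest lag (frame intervals); default all available.
#' @return Data frame with `lag`, `lag_min`, `autocorrelation` (NA at lags
#'   with no valid pair), `n_pairs`.
#' @export
direction_autocorrelation <- function(track, max_lag = NULL) {
  v <- track_steps(track)
  len <- sqrt(rowSums(v^2))
  ok <- len > 0
  if (sum(ok) < 1) stop("track has no non-zero steps")
  phi <- atan2(v[, 2], v[, 1])
  nmax <- nrow(v) - 1
  if (is.null(max_lag)) max_lag <- nmax
  max_lag <- min(max_lag, nmax)
  res <- data.frame(lag = 0:max_lag)
  res$lag_min <- res$lag * track$interval_min
  res$autocorrelation <- NA_real_
  res$n_pairs <- 0L
  res$autocorrelation[1] <- 1
  res$n_pairs[1] <- sum(ok)
  for (l in seq_len(max_lag)) {
    t0 <- seq_len(nrow(v) - l)
    valid <- ok[t0] & ok[t0 + l]
    if (any(valid)) {
      res$autocorrelation[l + 1] <- mean(cos(phi[t0 + l][valid] -
                                               phi[t0][valid]))
      res$n_pairs[l + 1] <- sum(valid)
    }
  }
  res
}

#' Translate tracks to a common origin
#'
#' Each track is translated so its first position is (0, 0); geometry is
#' otherwise unchanged (the classic "plot at origin" visualization transform).
#'
#' @param tracks A `cell_track` or list of them.
#' @return Same structure with translated positions.
#' @export
plot_at_origin <- function(tracks) {
  shift1 <- function(tr) {
    tr$positions <- sweep(tr$positions, 2, tr$positions[1, ])
    tr
  }
  if (inherits(tracks, "cell_track")) shift1(tracks)
  else lapply(tracks, shift1)
}

#' Does a track turn against the annotated migration direction?
#'
#' Cells are only retained if they migrate in one direction for the whole
#' acquisition; in the normalized frame this is operationalized as: a track is
#' "turning" iff any step's x-component is more negative than
#' `-tolerance_um` (backward motion beyond noise).  Turning tracks are
#' excluded from topology aggregation.
#'
#' @param track A `cell_track` in the normalized frame.
#' @param tolerance_um Backward-step tolerance in micrometres (default 1).
#' @return Logical.
#' @export
is_turning <- function(track, tolerance_um = 1) {
  v <- track_steps(track)
  any(v[, 1] < -tolerance_um)
}
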