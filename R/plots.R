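#' Bar plot of a back-front density profile
#'
#' Mean +/- SEM per portion, with the nucleus position (#5) marked; the
#' standard visualization of the per-portion topology.
#'
#' @param x A `cohort_result`, or a numeric 10-vector of means.
#' @param class Compartment class to plot (for cohort input).
#' @param sem Optional 10-vector of SEMs when `x` is a vector.
#' @param ... Passed to [graphics::barplot()].
#' @return Bar midpoints, invisibly.
#' @export
plot_profile <- function(x, class = "all", sem = NULL, ...) {
  if (inherits(x, "cohort_result")) {
    m <- x$mean_profile[[class]]
    s <- x$sem_profile[[class]]
    main <- paste(x$condition, "-", class)
  } else {
    m <- as.numeric(x); s <- sem; main <- class
  }
  mids <- graphics::barplot(m, names.arg = 0:9, xlab = "portion (back -> front)",
                            ylab = "density", main = main,
                            ylim = c(0, max(m + if (is.null(s)) 0 else s) * 1.15),
                            ...)
  if (!is.null(s) && any(s > 0, na.rm = TRUE))
    graphics::arrows(mids, m - s, mids, m + s, angle = 90, code = 3,
                     length = 0.03)
  graphics::abline(v = mids[6] - diff(mids)[1] / 2, lty = 2)
  invisible(mids)
}

#' Plot tracks translated to a common origin
#'
#' @param tracks A list of `cell_track`s (translated internally via
#'   [plot_at_origin()]).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the translated tracks.
#' @export
plot_tracks <- function(tracks, ...) {
  tr0 <- plot_at_origin(tracks)
  lim <- max(1, vapply(tr0, function(tr) max(abs(tr$positions)), numeric(1)))
  graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim),
                 xlab = "x (um)", ylab = "y (um)", asp = 1, ...)
  for (tr in tr0) graphics::lines(tr$positions, col = "#00000080")
  graphics::points(0, 0, pch = 3, col = "red")
  invisible(tr0)
}
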