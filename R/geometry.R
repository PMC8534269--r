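# Cell-shape geometry for the synthetic generator.
#
# Shapes are represented by a half-width profile hw(x) over the local cell
# axis x in [0, L] (symmetric about the cell midline), from which both the
# rasterized mask and the ground-truth polygon derive.  The shape is scaled so
# that the analytic area 2 * integral(hw) equals the configured cell area, so
# polygon area and target area agree to sampling precision.

# Line-confined cell: ellipse clipped to a stripe.  Cells spread somewhat
# beyond the printed line, so the confining stripe is wider than the pattern
# by a fixed overhang factor.
LINE_OVERHANG <- 1.5

cell_shape <- function(config) {
  if (config$pattern_kind == "line") {
    h <- config$pattern_width_um / 2 * LINE_OVERHANG
    b <- 1.2 * h
    # area = a * I with I = int_{-1}^{1} 2*min(b*sqrt(1-u^2), h) du
    I <- stats::integrate(function(u) 2 * pmin(b * sqrt(pmax(0, 1 - u^2)), h),
                          -1, 1, rel.tol = 1e-10)$value
    a <- config$cell_area_um2 / I
    L <- 2 * a
    hw <- function(x) {
      u <- (x - a) / a
      ifelse(x >= 0 & x <= L, pmin(b * sqrt(pmax(0, 1 - u^2)), h), 0)
    }
    max_hw <- h
  } else {
    # Crossbow: teardrop = disk plus tangent wedge to a rear apex.
    d <- 1.8 # apex distance in units of disk radius
    xt <- -1 / d
    yt <- sqrt(1 - xt^2)
    hw_unit <- function(x) { # x in [-d, 1], R = 1
      ifelse(x < xt,
             yt * pmax(0, x + d) / (xt + d),
             sqrt(pmax(0, 1 - pmin(x, 1)^2)))
    }
    area_unit <- stats::integrate(function(x) 2 * hw_unit(x), -d, 1,
                                  rel.tol = 1e-10)$value
    s <- sqrt(config$cell_area_um2 / area_unit)
    L <- (d + 1) * s
    hw <- function(x) {
      ifelse(x >= 0 & x <= L, s * hw_unit(x / s - d), 0)
    }
    max_hw <- s
  }
  list(halfwidth = hw, length_um = L, max_halfwidth_um = max_hw)
}

# Polygon (2-column matrix, um) tracing hw() at a given x-offset and midline.
shape_polygon <- function(shape, offset_x = 0, y_center = 0, n = 200) {
  xs <- seq(0, shape$length_um, length.out = n)
  top <- shape$halfwidth(xs)
  cbind(x = c(xs, rev(xs)) + offset_x,
        y = c(top, -rev(top)) + y_center)
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Nucleus semi-axes (um), shrunk if the cell is locally too narrow.
nucleus_axes <- function(shape, nucleus_x_local) {
  a <- 7; b <- 4.8
  xs <- seq(nucleus_x_local - a, nucleus_x_local + a, length.out = 41)
  room <- min(shape$halfwidth(pmax(pmin(xs, shape$length_um), 0)))
  b <- min(b, max(room - 0.5, 1))
  c(a = a, b = b)
}
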