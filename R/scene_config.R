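#' Noise model for the synthetic generator
#'
#' Photon shot noise is modelled as Poisson resampling of the expected signal
#' (including the flat background); detector read noise as additive Gaussian
#' noise. Defaults give a read-noise SD of 2% of the default dot amplitude.
#'
#' @param background Flat background level added to every pixel (counts).
#' @param read_noise_sd SD of additive Gaussian read noise (counts).
#' @param poisson Apply Poisson shot noise to the expected signal?
#' @return A list of class `noise_model`.
#' @export
#' @examples
#' noise_model(background = 0, read_noise_sd = 0, poisson = FALSE) # noiseless
noise_model <- function(background = 10, read_noise_sd = 3, poisson = TRUE) {
  stopifnot(background >= 0, read_noise_sd >= 0, is.logical(poisson))
  structure(list(background = background, read_noise_sd = read_noise_sd,
                 poisson = poisson), class = "noise_model")
}

#' Configuration of a synthetic micro-pattern time-lapse scene
#'
#' Describes one cell confined to a line or crossbow micro-pattern, imaged for
#' `n_frames` frames at `interval_min` minute intervals, carrying two dot
#' populations: "yellow" dots rendered in both GFP and RFP (autophagosomes of
#' the tandem RFP-GFP-LC3 reporter) and "red" dots rendered in RFP only
#' (autolysosomes, whose GFP moiety is pH-quenched). When `channels` contains
#' `"LYSO"` the scene is single-channel (lysotracker mode) and all dots are
#' lysosomes.
#'
#' Dot x-positions follow one of three spatial models: `isotropic` (uniform
#' over the cell), `front_peaked` (Gaussian around the centre of portion
#' `peak_portion` of the true back-front partition, SD =
#' `peak_concentration_bins` portion widths), or `scattered` (Gaussian with a
#' broad SD `scatter_sigma_um` around a centre resampled uniformly along the
#' cell at every frame, so the density peak wanders).
#'
#' @param pattern_kind `"line"` (directed migration) or `"crossbow"` (static).
#' @param pattern_width_um Printed line width in micrometres.
#' @param crossbow_extent_um Printed crossbow size in micrometres.
#' @param cell_area_um2 Target projected cell area in square micrometres.
#' @param nucleus_rel_position Nucleus centre as a fraction of cell length
#'   measured from the back edge (must lie in (0, 1)).
#' @param n_frames,interval_min Number of frames and frame interval (minutes).
#' @param pixel_size_um Pixel size in micrometres (11 um detector pixel / 60x).
#' @param speed_um_per_h Migration speed along +x, micrometres per hour.
#' @param n_yellow,n_red Dot counts per frame for the two classes.
#' @param dot_sigma_um Gaussian sigma of the rendered dot profile (um).
#' @param dot_min_separation_um Minimum centre-to-centre dot distance (um);
#'   placement failing this after a bounded number of draws is an error.
#' @param dot_spatial_model `"isotropic"`, `"front_peaked"` or `"scattered"`.
#' @param peak_portion Portion index (0-9) of the front-peaked model.
#' @param peak_concentration_bins SD of the front-peaked model, in portion
#'   widths.
#' @param scatter_sigma_um SD of the scattered model (um).
#' @param dot_amplitude,cytosol_level,nucleus_amplitude Rendered intensities
#'   (counts on a 16-bit scale).
#' @param noise A [noise_model()].
#' @param channels Channel names; `c("GFP","RFP","NUC","TRANS")` for the
#'   tandem-reporter mode or `c("LYSO","NUC")` for the lysotracker mode.
#' @param seed Integer seed; output is a pure function of (config, seed).
#' @return A validated list of class `scene_config`.
#' @seealso [scene_preset()], [generate_timelapse()]
#' @export
scene_config <- function(pattern_kind = c("line", "crossbow"),
                         pattern_width_um = 10,
                         crossbow_extent_um = 45,
                         cell_area_um2 = 1380,
                         nucleus_rel_position = 0.5,
                         n_frames = 5,
                         interval_min = 30,
                         pixel_size_um = 0.183,
                         speed_um_per_h = 0,
                         n_yellow = 20,
                         n_red = 25,
                         dot_sigma_um = 0.25,
                         dot_min_separation_um = 1.5,
                         dot_spatial_model = c("isotropic", "front_peaked",
                                               "scattered"),
                         peak_portion = 6,
                         peak_concentration_bins = 1.2,
                         scatter_sigma_um = 15,
                         dot_amplitude = 150,
                         cytosol_level = 30,
                         nucleus_amplitude = 120,
                         noise = noise_model(),
                         channels = c("GFP", "RFP", "NUC", "TRANS"),
                         seed = 1L) {
  pattern_kind <- match.arg(pattern_kind)
  dot_spatial_model <- match.arg(dot_spatial_model)
  stopifnot(
    pattern_width_um > 0, crossbow_extent_um > 0, cell_area_um2 > 0,
    nucleus_rel_position > 0, nucleus_rel_position < 1,
    n_frames >= 1, interval_min > 0, pixel_size_um > 0,
    speed_um_per_h >= 0, n_yellow >= 0, n_red >= 0,
    dot_sigma_um > 0, dot_min_separation_um >= 0,
    peak_portion %in% 0:9, peak_concentration_bins > 0, scatter_sigma_um > 0,
    dot_amplitude > 0, cytosol_level >= 0, nucleus_amplitude > 0,
    inherits(noise, "noise_model"), length(channels) >= 2
  )
  if (!("NUC" %in% channels))
    stop("channels must include 'NUC' (nuclear stain)")
  single <- "LYSO" %in% channels
  if (!single && !all(c("GFP", "RFP") %in% channels))
    stop("channels must include GFP and RFP, or LYSO for single-channel mode")
  cfg <- list(
    pattern_kind = pattern_kind, pattern_width_um = pattern_width_um,
    crossbow_extent_um = crossbow_extent_um, cell_area_um2 = cell_area_um2,
    nucleus_rel_position = nucleus_rel_position, n_frames = as.integer(n_frames),
    interval_min = interval_min, pixel_size_um = pixel_size_um,
    speed_um_per_h = speed_um_per_h, n_yellow = as.integer(n_yellow),
    n_red = as.integer(n_red), dot_sigma_um = dot_sigma_um,
    dot_min_separation_um = dot_min_separation_um,
    dot_spatial_model = dot_spatial_model,
    peak_portion = as.integer(peak_portion),
    peak_concentration_bins = peak_concentration_bins,
    scatter_sigma_um = scatter_sigma_um, dot_amplitude = dot_amplitude,
    cytosol_level = cytosol_level, nucleus_amplitude = nucleus_amplitude,
    noise = noise, channels = channels, single_channel = single,
    seed = as.integer(seed)
  )
  structure(cfg, class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat("scene_config:", x$pattern_kind, "pattern,",
      sprintf("%.0f um^2,", x$cell_area_um2),
      sprintf("%d frames x %g min,", x$n_frames, x$interval_min),
      sprintf("speed %g um/h,", x$speed_um_per_h),
      sprintf("%d yellow + %d red dots (%s)", x$n_yellow, x$n_red,
              x$dot_spatial_model), "\n")
  invisible(x)
}

#' Preset scene configurations for the experimental conditions
#'
#' Six presets mirror the study conditions: normal and Ras-transformed cells,
#' static (crossbow) or motile (line); nutrient starvation of static normal
#' cells (more red-only dots, stable yellow counts, i.e. increased flux); and a
#' single-channel lysotracker mode for lysosome topology in motile cells.
#' Cell areas and nucleus relative positions are the measured per-condition
#' values (1660/1675/1380/1962 um^2; 0.44/0.44/0.51/0.46). The transformed
#' motile speed is more than three times the normal motile speed. Motile
#' normal cells carry a front-peaked dot distribution (peak in portion 6);
#' motile transformed cells a scattered, frame-to-frame wandering one; static
#' cells an isotropic one.
#'
#' @param name One of `"normal_static"`, `"normal_motile"`,
#'   `"transformed_static"`, `"transformed_motile"`, `"starved"`,
#'   `"lysotracker_motile"`.
#' @param seed Integer seed stored in the returned config.
#' @return A [scene_config()].
#' @export
#' @examples
#' # transformed motile cells migrate more than three times faster
#' scene_preset("transformed_motile")$speed_um_per_h /
#'   scene_preset("normal_motile")$speed_um_per_h
scene_preset <- function(name = c("normal_static", "normal_motile",
                                  "transformed_static", "transformed_motile",
                                  "starved", "lysotracker_motile"),
                         seed = 1L) {
  name <- match.arg(name)
  switch(name,
    normal_static = scene_config(
      pattern_kind = "crossbow", cell_area_um2 = 1660,
      nucleus_rel_position = 0.44, speed_um_per_h = 0,
      n_yellow = 20, n_red = 25, dot_spatial_model = "isotropic", seed = seed),
    normal_motile = scene_config(
      pattern_kind = "line", cell_area_um2 = 1380,
      nucleus_rel_position = 0.51, speed_um_per_h = 12,
      n_yellow = 25, n_red = 35, dot_spatial_model = "front_peaked",
      peak_portion = 6, seed = seed),
    transformed_static = scene_config(
      pattern_kind = "crossbow", cell_area_um2 = 1675,
      nucleus_rel_position = 0.44, speed_um_per_h = 0,
      n_yellow = 22, n_red = 27, dot_spatial_model = "isotropic", seed = seed),
    transformed_motile = scene_config(
      pattern_kind = "line", cell_area_um2 = 1962,
      nucleus_rel_position = 0.46, speed_um_per_h = 40,
      n_yellow = 40, n_red = 35, dot_spatial_model = "scattered", seed = seed),
    starved = scene_config(
      pattern_kind = "crossbow", cell_area_um2 = 1660,
      nucleus_rel_position = 0.44, speed_um_per_h = 0,
      n_yellow = 20, n_red = 45, dot_spatial_model = "isotropic", seed = seed),
    lysotracker_motile = scene_config(
      pattern_kind = "line", cell_area_um2 = 1380,
      nucleus_rel_position = 0.51, speed_um_per_h = 12,
      n_yellow = 30, n_red = 0, dot_spatial_model = "front_peaked",
      peak_portion = 6, channels = c("LYSO", "NUC"), seed = seed)
  )
}
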