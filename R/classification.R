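#' Classify LC3 compartments by object-based GFP/RFP colocalization
#'
#' The tandem RFP-GFP-LC3 reporter makes every LC3 compartment RFP-positive,
#' so RFP objects are the reference set.  For each RFP object the overlap
#' fraction is the share of its pixels covered by any GFP object; objects at
#' or above `overlap_threshold` are autophagosomes ("yellow", GFP intact),
#' the rest autolysosomes ("red-only", GFP quenched by the acidic lumen).
#' Ties at exactly the threshold classify as autophagosome.  GFP objects with
#' no RFP counterpart are biologically impossible for this reporter and are
#' counted as segmentation artifacts in the QC attribute, not in the results.
#'
#' @param gfp_labels,rfp_labels `label_map`s from [segment_compartments()] on
#'   the GFP and RFP channels of the same frame (same shape).
#' @param overlap_threshold Overlap fraction at/above which an RFP object is
#'   an autophagosome; in (0, 1], default 0.3.
#' @return Data frame with one row per RFP object: `class`, `x_um`, `y_um`
#'   (weighted centroid), `area_px`, `area_um2`, `overlap_fraction`, and a
#'   `pixels` list column; attribute `n_gfp_only` counts discarded GFP-only
#'   objects.
#' @export
classify_compartments <- function(gfp_labels, rfp_labels,
                                  overlap_threshold = 0.3) {
  stopifnot(inherits(gfp_labels, "label_map"),
            inherits(rfp_labels, "label_map"),
            overlap_threshold > 0, overlap_threshold <= 1)
  if (!identical(dim(gfp_labels$labels), dim(rfp_labels$labels)))
    stop("GFP and RFP label maps must share the same shape")
  K <- rfp_labels$n_objects
  gfp_fg <- gfp_labels$labels > 0
  overlap <- numeric(K)
  if (K > 0) {
    sel <- rfp_labels$labels > 0
    ov <- tapply(gfp_fg[sel], rfp_labels$labels[sel], mean)
    overlap[as.integer(names(ov))] <- as.numeric(ov)
  }
  # GFP objects never touched by an RFP object: QC only
  n_gfp_only <- 0L
  if (gfp_labels$n_objects > 0) {
    rfp_fg <- rfp_labels$labels > 0
    gsel <- gfp_labels$labels > 0
    covered <- tapply(rfp_fg[gsel], gfp_labels$labels[gsel], max)
    n_gfp_only <- sum(covered == 0)
  }
  out <- data.frame(
    class = ifelse(overlap >= overlap_threshold, "autophagosome",
                   "autolysosome"),
    x_um = rfp_labels$centroid_weighted_um[, 1],
    y_um = rfp_labels$centroid_weighted_um[, 2],
    area_px = rfp_labels$area_px,
    area_um2 = rfp_labels$area_um2,
    overlap_fraction = overlap,
    stringsAsFactors = FALSE)
  out$pixels <- rfp_labels$pixels
  attr(out, "n_gfp_only") <- as.integer(n_gfp_only)
  out
}

#' Single-channel (lysotracker) compartment classification
#'
#' In the lysotracker mode there is one fluorescence channel and every
#' detected object is a lysosome; the downstream topology machinery is shared
#' with the dual-channel path.
#'
#' @param labels A `label_map` from [segment_compartments()].
#' @return Data frame in the same layout as [classify_compartments()] with
#'   `class = "lysosome"` and `overlap_fraction = NA`.
#' @export
single_channel_compartments <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  K <- labels$n_objects
  out <- data.frame(
    class = rep("lysosome", K),
    x_um = labels$centroid_weighted_um[, 1],
    y_um = labels$centroid_weighted_um[, 2],
    area_px = labels$area_px,
    area_um2 = labels$area_um2,
    overlap_fraction = rep(NA_real_, K),
    stringsAsFactors = FALSE)
  out$pixels <- labels$pixels
  attr(out, "n_gfp_only") <- 0L
  out
}
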