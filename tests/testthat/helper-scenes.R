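# Shared fixtures: small, fast synthetic scenes and independent oracles.

# A small line cell (fast to render) with a handful of dots.
tiny_config <- function(...) {
  defaults <- list(cell_area_um2 = 300, n_frames = 2, n_yellow = 6, n_red = 5,
                   speed_um_per_h = 8, nucleus_rel_position = 0.45, seed = 42)
  do.call(scene_config, utils::modifyList(defaults, list(...)))
}

noiseless <- function(cfg) {
  cfg$noise <- noise_model(background = 0, read_noise_sd = 0, poisson = FALSE)
  cfg
}

# Independent brute-force binning oracle: explicit loop over half-open bins,
# final bin right-closed.  Deliberately avoids findInterval().
brute_bin <- function(x, boundaries) {
  v <- integer(10)
  for (k in 1:10) {
    v[k] <- if (k < 10) sum(x >= boundaries[k] & x < boundaries[k + 1])
            else sum(x >= boundaries[k] & x <= boundaries[k + 1])
  }
  v
}

# Greedy nearest-neighbour matching of detections to true dots within a
# radius; returns indices into `truth` per detection (NA if unmatched).
match_detections <- function(det, truth, radius_um = 0.5) {
  m <- rep(NA_integer_, nrow(det))
  taken <- logical(nrow(truth))
  if (nrow(det) == 0 || nrow(truth) == 0) return(m)
  for (i in seq_len(nrow(det))) {
    d2 <- (truth$x_um - det$x_um[i])^2 + (truth$y_um - det$y_um[i])^2
    d2[taken] <- Inf
    j <- which.min(d2)
    if (d2[j] <= radius_um^2) { m[i] <- j; taken[j] <- TRUE }
  }
  m
}

# Detection scores of one analysed synthetic cell against its ground truth.
recovery_scores <- function(cell) {
  gt <- cell$ground_truth
  tp <- 0L; n_det <- 0L; n_true <- 0L; confused <- 0L
  for (t in which(cell$qc$valid)) {
    det <- cell$frames[[t]]$compartments
    truth <- gt$frames[[t]]$dots
    m <- match_detections(det, truth)
    tp <- tp + sum(!is.na(m))
    n_det <- n_det + nrow(det)
    n_true <- n_true + nrow(truth)
    ok <- !is.na(m)
    confused <- confused + sum(det$class[ok] != truth$class[m[ok]])
  }
  list(recall = tp / n_true, precision = tp / n_det,
       confusion = confused / tp)
}
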