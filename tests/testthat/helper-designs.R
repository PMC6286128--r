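# Shared, lazily built design objects (the full default run is used by many
# tests; building it once keeps the suite fast).

.design_cache <- new.env(parent = emptyenv())

default_designs <- function() {
  if (is.null(.design_cache$d)) {
    seq <- build_bar_sequence()
    hrf <- hrf_double_gamma(dt_s = seq$dwell_s)
    dm101 <- render_design_matrix(seq, 101)
    dm31 <- render_design_matrix(seq, 31)
    .design_cache$d <- list(
      seq = seq, hrf = hrf, dm101 = dm101, dm31 = dm31,
      reg101 = convolve_design(dm101, hrf),
      reg31 = convolve_design(dm31, hrf),
      ub = unique_bar_frames(dm101))
  }
  .design_cache$d
}

# Closed-form Attend Fixation pRF of a ground-truth voxel table.
fixation_truth <- function(voxels, sigma_fix) {
  t(vapply(seq_len(nrow(voxels)), function(i) {
    g <- gaussian_product(
      list(center = c(voxels$x[i], voxels$y[i]), sigma = voxels$sigma[i]),
      list(center = c(0, 0), sigma = sigma_fix))
    c(x = g$center[1], y = g$center[2], sigma = g$sigma)
  }, numeric(3)))
}

# Parameter-level condition fits generated directly from the gain-field
# model (closed-form product for Attend Fixation, grid prediction for the
# attend-bar conditions), bypassing BOLD simulation. Sizes for attend-bar
# conditions follow the product of the SD with the effective stimulus AF.
model_level_fits <- function(voxels, af, dm, smoothed_color = NULL,
                             smoothed_tf = NULL) {
  ub <- unique_bar_frames(dm)
  if (is.null(smoothed_color))
    smoothed_color <- smooth_bar_frames(ub, af$sigma_stim_color)
  if (is.null(smoothed_tf))
    smoothed_tf <- if (af$sigma_stim_tf == af$sigma_stim_color)
      smoothed_color else smooth_bar_frames(ub, af$sigma_stim_tf)
  fx <- fixation_truth(voxels, af$sigma_fix)
  sdp <- voxels[, c("x", "y", "sigma")]
  pc <- predict_attend_stimulus_position(sdp, af$sigma_stim_color,
                                         smoothed = smoothed_color)
  pt <- predict_attend_stimulus_position(sdp, af$sigma_stim_tf,
                                         smoothed = smoothed_tf)
  bw <- dm$bar_width_dva
  s_att <- function(sk) sqrt(1 / (1 / voxels$sigma^2 + 1 / (sk + bw)^2))
  one <- function(cond, x, y, sigma)
    data.frame(voxel_id = voxels$voxel_id, condition = cond, x = x, y = y,
               sigma = sigma, ecc = sqrt(x^2 + y^2),
               polar_angle = atan2(y, x), amplitude = 1, baseline = 0,
               r2 = 1, converged = TRUE)
  fits <- rbind(
    one("AttendFixation", fx[, 1], fx[, 2], fx[, 3]),
    one("AttendColor", pc[, 1], pc[, 2], s_att(af$sigma_stim_color)),
    one("AttendTF", pt[, 1], pt[, 2], s_att(af$sigma_stim_tf)),
    one("AttendStimulus", (pc[, 1] + pt[, 1]) / 2, (pc[, 2] + pt[, 2]) / 2,
        (s_att(af$sigma_stim_color) + s_att(af$sigma_stim_tf)) / 2))
  fits <- fits[order(fits$voxel_id), ]
  rownames(fits) <- NULL
  class(fits) <- c("prf_fits", "data.frame")
  fits
}
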