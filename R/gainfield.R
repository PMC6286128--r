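# Attentional gain-field model: stimulus-drive estimation by Gaussian
# division, the time-averaged argmax prediction of the attend-stimulus pRF
# position, and the grid fit of the two gain-field sizes against
# quadrant-binned shift vectors.

#' Convolve unique bar frames with a Gaussian stimulus gain-field kernel
#'
#' Separable discrete convolution (zero padding outside the grid) of each
#' unique bar mask with an isotropic Gaussian of size `sigma_k`. The kernel
#' is not normalized: every downstream use rescales each product profile to
#' a maximum of 1, so only the shape matters.
#'
#' @param ub Result of [unique_bar_frames()].
#' @param sigma_k Stimulus gain-field kernel standard deviation, dva.
#' @return List with dense matrix `S` (pixels x unique frames), `wts` (frame
#'   weights, all 1), `sigma_k`, `grid` and the frame `info`.
#' @export
smooth_bar_frames <- function(ub, sigma_k) {
  .stop_if(sigma_k <= 0, "sigma_k must be positive")
  grid <- ub$grid
  n <- grid$n
  cc <- grid$x[seq_len(n)]
  K <- exp(-outer(cc, cc, "-")^2 / (2 * sigma_k^2))
  M <- t(as.matrix(ub$masks))                      # pixels x frames
  F <- ncol(M)
  A <- array(M, c(n, n, F))                        # [x, y, frame]
  A <- array(K %*% matrix(A, nrow = n), c(n, n, F))
  A <- aperm(A, c(2, 1, 3))                        # [y, x, frame]
  A <- array(K %*% matrix(A, nrow = n), c(n, n, F))
  A <- aperm(A, c(2, 1, 3))
  wts <- if (is.null(ub$wts)) rep(1, F) else ub$wts
  list(S = matrix(A, nrow = n * n), wts = wts, sigma_k = sigma_k,
       grid = grid, info = ub$info)
}

#' Estimate the stimulus drive by Gaussian division
#'
#' Inverts the closed-form Gaussian product: the measured Attend Fixation
#' pRF is divided by a Gaussian gain field of size `sigma_fix` centered at
#' `fix_center`, giving the stimulus-drive Gaussian (precision of the
#' measured pRF minus precision of the gain field). The measured size must
#' be smaller than the gain-field size; otherwise the voxel is flagged
#' non-invertible.
#'
#' @param prf_fix List or one-row data.frame with `x`, `y`, `sigma`: the
#'   measured Attend Fixation pRF.
#' @param sigma_fix Fixation gain-field size, dva.
#' @param fix_center Gain-field center (dva).
#' @return List of class `stimulus_drive` with `center`, `sigma` and
#'   `invertible`; `center`/`sigma` are NA when not invertible.
#' @export
estimate_stimulus_drive <- function(prf_fix, sigma_fix, fix_center = c(0, 0)) {
  sm <- prf_fix$sigma
  if (!(sm < sigma_fix)) {
    return(structure(list(center = c(NA_real_, NA_real_), sigma = NA_real_,
                          invertible = FALSE), class = "stimulus_drive"))
  }
  p_meas <- 1 / sm^2
  p_af <- 1 / sigma_fix^2
  p_sd <- p_meas - p_af
  center <- (c(prf_fix$x, prf_fix$y) * p_meas - fix_center * p_af) / p_sd
  structure(list(center = center, sigma = sqrt(1 / p_sd), invertible = TRUE),
            class = "stimulus_drive")
}

#' Predict the Attend Stimulus pRF position from the gain-field model
#'
#' For each unique bar stimulus the mask is convolved with the stimulus
#' gain-field kernel and multiplied pointwise with the stimulus-drive
#' profile on the pixel grid; each product is scaled to a maximum of 1 and
#' the products are averaged over bar stimuli. The grid position of the
#' maximum of this average is the predicted Attend Stimulus pRF center.
#'
#' @param sd A `stimulus_drive`, a list with `center`/`sigma`, or a
#'   data.frame with columns `x`, `y`, `sigma` (one row per stimulus drive).
#' @param sigma_stim_kernel Stimulus gain-field kernel size, dva.
#' @param dm A `design_matrix`; ignored when `smoothed` is supplied.
#' @param smoothed Optional precomputed [smooth_bar_frames()] result for
#'   `sigma_stim_kernel`.
#' @return For a single stimulus drive, a named vector `c(x, y)`; for a
#'   data.frame input, a matrix with one row per stimulus drive.
#' @export
predict_attend_stimulus_position <- function(sd, sigma_stim_kernel,
                                             dm = NULL, smoothed = NULL) {
  if (is.null(smoothed)) {
    .stop_if(is.null(dm), "supply a design_matrix or a smoothed frame stack")
    smoothed <- smooth_bar_frames(unique_bar_frames(dm), sigma_stim_kernel)
  }
  single <- !is.data.frame(sd)
  if (single) sd <- data.frame(x = sd$center[1], y = sd$center[2],
                               sigma = sd$sigma)
  grid <- smoothed$grid
  pos <- cpp_predict_positions(smoothed$S, smoothed$wts, grid$x, grid$y,
                               sd$x, sd$y, sd$sigma)
  .stop_if(single && anyNA(pos),
           "all products are zero: stimulus drive outside the stimulated region")
  colnames(pos) <- c("x", "y")
  if (single) setNames(c(pos[1, 1], pos[1, 2]), c("x", "y")) else pos
}

#' Bin quadrant-mirrored shift vectors over the visual field
#'
#' Bins voxels into an `n_bins` x `n_bins` equal-width grid over
#' `[0, ecc_max]^2` of their (quadrant-mirrored) Attend Fixation positions
#' and computes R2-weighted mean start position/size and end position per
#' occupied bin. Empty bins are omitted and counted.
#'
#' @param records Shift records from [shift_records()] (already mirrored to
#'   the first quadrant).
#' @param n_bins Bins per dimension (8 gives up to 64 vectors).
#' @param ecc_max Upper edge of the binning range, dva.
#' @return data.frame of class `binned_vectors` with one row per occupied
#'   bin; attribute `n_empty` counts empty bins.
#' @export
bin_shift_vectors_quadrant <- function(records, n_bins = 8, ecc_max = 3.3) {
  edges <- seq(0, ecc_max, length.out = n_bins + 1)
  bx <- cut(records$start_x, edges, include.lowest = TRUE, labels = FALSE)
  by <- cut(records$start_y, edges, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(bx) & !is.na(by)
  rec <- records[keep, ]
  bin <- (by[keep] - 1L) * n_bins + bx[keep]
  wmean <- function(v, w) sum(v * w) / sum(w)
  out <- do.call(rbind, lapply(split(seq_along(bin), bin), function(ix) {
    w <- rec$w[ix]
    data.frame(bin = bin[ix][1],
               start_x = wmean(rec$start_x[ix], w),
               start_y = wmean(rec$start_y[ix], w),
               start_sigma = wmean(rec$start_sigma[ix], w),
               end_x = wmean(rec$end_x[ix], w),
               end_y = wmean(rec$end_y[ix], w),
               w_sum = sum(w), n = length(ix))
  }))
  rownames(out) <- NULL
  attr(out, "n_empty") <- n_bins^2 - nrow(out)
  class(out) <- c("binned_vectors", "data.frame")
  out
}

.af_grid_values <- function(range, n, endpoint = FALSE) {
  if (endpoint) seq(range[1], range[2], length.out = n)
  else range[1] + (seq_len(n) - 1) * diff(range) / n
}

#' Fit the two attentional gain-field sizes by grid search
#'
#' Evaluates the gain-field model on an evenly spaced grid of
#' (fixation AF size, stimulus AF kernel size). With
#' `predict_per = "bin"` (default), each binned vector's stimulus drive is
#' derived by Gaussian division of its (bin-averaged) measured Attend
#' Fixation pRF, the Attend Stimulus position is predicted, and the summed
#' squared Euclidean distance to the measured binned end positions is the
#' cell's objective. With `predict_per = "voxel"`, the stimulus drive is
#' derived and the position predicted for every voxel, and the predictions
#' are aggregated into the same weighted visual-field bins as the measured
#' end positions before the distances are summed, so that a voxel-level
#' forward simulation is exactly self-consistent with the fit.
#' Non-invertible inputs (measured size >= fixation AF size) are excluded
#' from that cell; a cell with no usable input gets an infinite objective.
#' Ties are broken toward the smaller fixation size, then the smaller
#' kernel. Reported stimulus AF size follows the convention of adding the
#' bar width to the kernel size.
#'
#' @param vectors A `binned_vectors` data.frame (for `predict_per =
#'   "bin"`), or a `shift_records` data.frame (binned internally; required
#'   for `predict_per = "voxel"`).
#' @param dm A `design_matrix` (101-grid).
#' @param fix_range,stim_range Grid ranges for the fixation AF size and the
#'   stimulus AF kernel size, dva.
#' @param grid_n Grid points per dimension.
#' @param endpoint If FALSE (default) the grid is start-anchored with
#'   spacing `range/grid_n` (0.02 dva at the defaults); if TRUE it is
#'   endpoint-inclusive with spacing `range/(grid_n - 1)`.
#' @param bar_width_dva Bar width added to the kernel size for the reported
#'   effective stimulus AF size.
#' @param predict_per "bin" or "voxel" (see above).
#' @param n_bins,ecc_max Binning of `shift_records` input, as in
#'   [bin_shift_vectors_quadrant()].
#' @return An object of class `gainfield_fit`: best sizes, effective
#'   stimulus size, the full objective `surface` (fixation sizes x kernel
#'   sizes), per-cell usable-input counts, and predicted vs observed binned
#'   end positions at the best cell.
#' @export
fit_af_sizes <- function(vectors, dm, fix_range = c(1.5, 2.5),
                         stim_range = c(0.6, 1.6), grid_n = 50,
                         endpoint = FALSE, bar_width_dva = 0.9,
                         predict_per = c("bin", "voxel"),
                         n_bins = 8, ecc_max = 3.3) {
  predict_per <- match.arg(predict_per)
  records <- NULL
  if (inherits(vectors, "shift_records")) {
    records <- vectors
    vectors <- bin_shift_vectors_quadrant(records, n_bins, ecc_max)
  }
  .stop_if(predict_per == "voxel" && is.null(records),
           "predict_per = 'voxel' needs shift_records input")
  .stop_if(nrow(vectors) < 1, "need at least one binned vector")
  sf_vals <- .af_grid_values(fix_range, grid_n, endpoint)
  sk_vals <- .af_grid_values(stim_range, grid_n, endpoint)
  ub <- unique_bar_frames(dm)
  grid <- ub$grid
  surface <- matrix(NA_real_, grid_n, grid_n,
                    dimnames = list(sigma_fix = sprintf("%.4f", sf_vals),
                                    sigma_stim = sprintf("%.4f", sk_vals)))
  n_used <- surface
  if (predict_per == "voxel") {
    edges <- seq(0, ecc_max, length.out = n_bins + 1)
    bx <- cut(records$start_x, edges, include.lowest = TRUE, labels = FALSE)
    by <- cut(records$start_y, edges, include.lowest = TRUE, labels = FALSE)
    keep <- !is.na(bx) & !is.na(by)
    rec <- records[keep, ]
    bin_full <- (by[keep] - 1L) * n_bins + bx[keep]
    bin_map <- match(bin_full, vectors$bin)
  }
  for (j in seq_along(sk_vals)) {
    sm <- smooth_bar_frames(ub, sk_vals[j])
    res <- if (predict_per == "bin") {
      cpp_af_objective(sm$S, sm$wts, grid$x, grid$y, sf_vals,
                       vectors$start_x, vectors$start_y,
                       vectors$start_sigma,
                       vectors$end_x, vectors$end_y)
    } else {
      cpp_af_objective_binned(sm$S, sm$wts, grid$x, grid$y, sf_vals,
                              rec$start_x, rec$start_y, rec$start_sigma,
                              rec$w, bin_map - 1L,
                              vectors$end_x, vectors$end_y)
    }
    surface[, j] <- res[, 1]
    n_used[, j] <- res[, 2]
  }
  .stop_if(all(!is.finite(surface)),
           "no grid cell has an invertible vector")
  best_val <- min(surface[is.finite(surface)])
  cand <- which(surface == best_val, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  bi <- cand[1, 1]; bj <- cand[1, 2]
  best_sf <- sf_vals[bi]; best_sk <- sk_vals[bj]

  sm_best <- smooth_bar_frames(ub, best_sk)
  src <- if (predict_per == "bin")
    data.frame(x = vectors$start_x, y = vectors$start_y,
               sigma = vectors$start_sigma)
  else data.frame(x = rec$start_x, y = rec$start_y, sigma = rec$start_sigma)
  sds <- lapply(seq_len(nrow(src)), function(v)
    estimate_stimulus_drive(src[v, ], best_sf))
  inv <- vapply(sds, function(s) s$invertible, logical(1))
  pred_raw <- matrix(NA_real_, nrow(src), 2,
                     dimnames = list(NULL, c("x", "y")))
  if (any(inv)) {
    sd_df <- data.frame(
      x = vapply(sds[inv], function(s) s$center[1], 0),
      y = vapply(sds[inv], function(s) s$center[2], 0),
      sigma = vapply(sds[inv], function(s) s$sigma, 0))
    pred_raw[inv, ] <- predict_attend_stimulus_position(sd_df, best_sk,
                                                        smoothed = sm_best)
  }
  pred <- if (predict_per == "bin") pred_raw else {
    ok <- inv & !is.na(pred_raw[, 1])
    t(vapply(seq_len(nrow(vectors)), function(b) {
      ix <- which(bin_map == b & ok)
      if (!length(ix)) return(c(x = NA_real_, y = NA_real_))
      w <- rec$w[ix]
      c(x = sum(pred_raw[ix, 1] * w) / sum(w),
        y = sum(pred_raw[ix, 2] * w) / sum(w))
    }, numeric(2)))
  }
  structure(
    list(sigma_fix = best_sf, sigma_stim_kernel = best_sk,
         effective_stim_size = best_sk + bar_width_dva,
         objective = best_val, surface = surface, n_used = n_used,
         sigma_fix_values = sf_vals, sigma_stim_values = sk_vals,
         predicted = as.data.frame(pred),
         observed = vectors[, c("end_x", "end_y")],
         n_vectors = nrow(vectors), invertible = inv,
         predict_per = predict_per, bar_width_dva = bar_width_dva),
    class = "gainfield_fit")
}

#' @exportS3Method base::print
print.gainfield_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "gainfield_fit: sigma_fix = %.3f dva, stimulus kernel = %.3f dva",
    " (effective %.3f dva)\n  objective %.4g over %d vectors\n"),
    x$sigma_fix, x$sigma_stim_kernel, x$effective_stim_size,
    x$objective, x$n_vectors))
  invisible(x)
}

#' Model-derived eccentricity-change profiles
#'
#' For a population of stimulus-drive Gaussians, computes the change in
#' eccentricity induced by the fixation gain field (closed-form product)
#' and by the traveling stimulus gain field (grid prediction), binned by
#' stimulus-drive eccentricity, together with their difference: the
#' predicted Attend Stimulus - Attend Fixation eccentricity change.
#'
#' @param sd_pop data.frame with columns x, y, sigma (stimulus drives).
#' @param af A fitted `gainfield_fit` or a list with `sigma_fix` and
#'   `sigma_stim_kernel`.
#' @param dm A `design_matrix`.
#' @param n_ecc_bins Number of equal-width eccentricity bins.
#' @param ecc_max Upper edge of the binning range, dva.
#' @param stim_static If TRUE, the stimulus gain field is evaluated as a
#'   static Gaussian at fixation (ablation; with equal sizes the difference
#'   profile is identically zero).
#' @return data.frame with per-bin mean eccentricity changes
#'   (`d_ecc_fix`, `d_ecc_stim`), their difference of means (`d_ecc_diff`),
#'   and the directly computed mean per-voxel difference
#'   (`d_ecc_diff_direct`).
#' @export
condition_shift_profiles <- function(sd_pop, af, dm, n_ecc_bins = 4,
                                     ecc_max = 3.3, stim_static = FALSE) {
  sigma_fix <- af$sigma_fix
  sigma_k <- af$sigma_stim_kernel
  ecc_sd <- sqrt(sd_pop$x^2 + sd_pop$y^2)
  fix_pos <- t(vapply(seq_len(nrow(sd_pop)), function(i) {
    gaussian_product(list(center = c(sd_pop$x[i], sd_pop$y[i]),
                          sigma = sd_pop$sigma[i]),
                     list(center = c(0, 0), sigma = sigma_fix))$center
  }, numeric(2)))
  if (stim_static) {
    stim_pos <- t(vapply(seq_len(nrow(sd_pop)), function(i) {
      gaussian_product(list(center = c(sd_pop$x[i], sd_pop$y[i]),
                            sigma = sd_pop$sigma[i]),
                       list(center = c(0, 0), sigma = sigma_k))$center
    }, numeric(2)))
  } else {
    stim_pos <- predict_attend_stimulus_position(
      sd_pop[, c("x", "y", "sigma")], sigma_k, dm = dm)
  }
  d_fix <- sqrt(rowSums(fix_pos^2)) - ecc_sd
  d_stim <- sqrt(rowSums(stim_pos^2)) - ecc_sd
  bins <- cut(ecc_sd, seq(0, ecc_max, length.out = n_ecc_bins + 1),
              include.lowest = TRUE, labels = FALSE)
  out <- do.call(rbind, lapply(seq_len(n_ecc_bins), function(b) {
    ix <- which(bins == b)
    data.frame(bin = b,
               ecc_lo = (b - 1) * ecc_max / n_ecc_bins,
               ecc_hi = b * ecc_max / n_ecc_bins,
               n = length(ix),
               d_ecc_fix = if (length(ix)) mean(d_fix[ix]) else NA_real_,
               d_ecc_stim = if (length(ix)) mean(d_stim[ix]) else NA_real_)
  }))
  out$d_ecc_diff <- out$d_ecc_stim - out$d_ecc_fix
  out$d_ecc_diff_direct <- vapply(seq_len(n_ecc_bins), function(b) {
    ix <- which(bins == b)
    if (length(ix)) mean(d_stim[ix] - d_fix[ix]) else NA_real_
  }, 0)
  out
}
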