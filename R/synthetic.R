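# Synthetic ground truth: voxel populations and condition-specific BOLD
# time series generated from the multiplicative attentional gain-field
# model, so that every downstream stage can be tested by parameter recovery.

#' Generative attentional gain-field specification
#'
#' The gain-field sizes used to generate condition-specific data: a Gaussian
#' gain field at fixation (`sigma_fix`) shapes the Attend Fixation pRF, and
#' a Gaussian kernel convolved with the bar stimulus (`sigma_stim_*`) shapes
#' the attend-bar pRFs, with separate kernels for the Attend Color and
#' Attend TF conditions. The defaults (fixation 2.5 dva, stimulus kernels
#' 0.65/0.75 dva, color 0.1 dva smaller) lie inside the model's search
#' ranges and jointly reproduce the qualitative findings the generator is
#' meant to emulate: a more precise gain field when color is attended, and
#' an eccentricity-change profile that is positive parafoveally and
#' negative peripherally.
#'
#' @param sigma_fix Fixation gain-field size, dva.
#' @param sigma_stim_color,sigma_stim_tf Stimulus gain-field kernel sizes
#'   for the two attend-bar conditions, dva.
#' @param fix_center Center of the fixation gain field (dva), normally the
#'   origin.
#' @return A list of class `af_spec`.
#' @export
af_spec <- function(sigma_fix = 2.5, sigma_stim_color = 0.65,
                    sigma_stim_tf = 0.75, fix_center = c(0, 0)) {
  .stop_if(sigma_fix <= 0 || sigma_stim_color <= 0 || sigma_stim_tf <= 0,
           "gain-field sizes must be positive")
  structure(list(sigma_fix = sigma_fix, sigma_stim_color = sigma_stim_color,
                 sigma_stim_tf = sigma_stim_tf, fix_center = fix_center),
            class = "af_spec")
}

#' Closed-form product of two isotropic 2D Gaussians
#'
#' The pointwise product of two isotropic Gaussians is a Gaussian with
#' precision equal to the sum of precisions and center at the
#' precision-weighted mean; `scale` is the peak value of the product when
#' both factors have peak 1.
#'
#' @param g1,g2 Lists with elements `center` (length-2 numeric) and `sigma`.
#'   An infinite sigma is allowed and acts as a flat gain.
#' @return List with `center`, `sigma` and `scale`.
#' @export
gaussian_product <- function(g1, g2) {
  .stop_if(g1$sigma <= 0 || g2$sigma <= 0, "sigmas must be positive")
  p1 <- 1 / g1$sigma^2
  p2 <- 1 / g2$sigma^2
  p <- p1 + p2
  center <- (g1$center * p1 + g2$center * p2) / p
  d2 <- sum((g1$center - g2$center)^2)
  list(center = center, sigma = sqrt(1 / p),
       scale = exp(-d2 / (2 * (g1$sigma^2 + g2$sigma^2))))
}

#' Sample a ground-truth voxel population
#'
#' Stimulus-drive pRF centers are drawn uniformly over the disk (or annulus)
#' spanned by `ecc_range`; sizes follow a linear size-eccentricity relation
#' with Gaussian jitter. Optionally the polar-angle distribution is biased
#' toward the horizontal meridian with an axial von Mises density
#' proportional to `exp(kappa * cos(2 * theta))`, emulating the horizontal
#' meridian over-representation of visual cortex; `polar_angle_kappa = 0`
#' gives uniform angles. Feature preference decreases linearly with
#' eccentricity (color preferred near the fovea).
#'
#' @param n Number of voxels.
#' @param ecc_range Eccentricity range (min, max), dva.
#' @param size_intercept,size_slope Linear size-eccentricity relation
#'   (dva, dva/dva); slope must be >= 0.
#' @param size_jitter_sd Gaussian jitter on size, dva.
#' @param amplitude,baseline Response amplitude and baseline, signal units.
#' @param polar_angle_kappa Axial von Mises concentration toward the
#'   horizontal meridian (0 = uniform).
#' @param feature_pref_intercept,feature_pref_slope Linear feature
#'   preference vs eccentricity, clipped to `[-1, 1]`.
#' @param seed Seed; NULL uses the current RNG state.
#' @return data.frame with columns voxel_id, x, y, ecc, polar_angle, sigma,
#'   amplitude, baseline, feature_pref.
#' @export
sample_ground_truth_voxels <- function(n, ecc_range = c(0, 3.3),
                                       size_intercept = 0.25,
                                       size_slope = 0.2,
                                       size_jitter_sd = 0.05,
                                       amplitude = 1, baseline = 0,
                                       polar_angle_kappa = 0,
                                       feature_pref_intercept = 0.5,
                                       feature_pref_slope = -0.3,
                                       seed = NULL) {
  .stop_if(n < 1, "n must be >= 1")
  .stop_if(size_slope < 0, "size_slope must be >= 0")
  .stop_if(diff(ecc_range) <= 0 || ecc_range[2] <= 0,
           "empty eccentricity range")
  .with_seed(seed, {
    ecc <- sqrt(runif(n, max(0, ecc_range[1])^2, ecc_range[2]^2))
    theta <- if (polar_angle_kappa == 0) runif(n, 0, 2 * pi) else {
      k <- polar_angle_kappa
      out <- numeric(0)
      while (length(out) < n) {
        cand <- runif(2 * n, 0, 2 * pi)
        keep <- runif(2 * n) < exp(k * cos(2 * cand) - k)
        out <- c(out, cand[keep])
      }
      out[seq_len(n)]
    }
    sigma <- pmax(0.05, size_intercept + size_slope * ecc +
                    rnorm(n, 0, size_jitter_sd))
    fp <- pmin(1, pmax(-1, feature_pref_intercept + feature_pref_slope * ecc))
    data.frame(voxel_id = seq_len(n),
               x = ecc * cos(theta), y = ecc * sin(theta),
               ecc = ecc, polar_angle = theta, sigma = sigma,
               amplitude = amplitude, baseline = baseline,
               feature_pref = fp)
  })
}

# Isotropic Gaussian profile with peak 1 on a vf_grid.
.gauss_profile <- function(grid, x0, y0, sigma)
  exp(-((grid$x - x0)^2 + (grid$y - y0)^2) / (2 * sigma^2))

# Map per-unique-bar-frame values onto the full frame sequence (zeros on
# pause/blank frames).
.expand_unique_frames <- function(dm, ub, values) {
  fr <- dm$frames
  out <- numeric(nrow(fr))
  bar <- which(fr$frame_type == "bar")
  n_pos <- max(fr$position_index[bar]) + 1L
  dir <- fr$direction_deg[bar] %% 360
  pos <- fr$position_index[bar]
  key_full <- paste(dir %% 180, ifelse(dir >= 180, n_pos - 1L - pos, pos))
  out[bar] <- values[match(key_full, ub$info$key)]
  out
}

#' Generate one voxel's BOLD time series under an attention condition
#'
#' The generative reading of the multiplicative gain-field model. Under
#' Attend Fixation the effective pRF is the closed-form product of the
#' stimulus-drive Gaussian (SD) with the fixation gain field, constant over
#' time. Under Attend Color / Attend TF the per-frame effective pRF is the
#' pointwise product of the SD with the bar mask convolved with the
#' condition's stimulus gain-field kernel, scaled to a maximum of 1; the
#' model summarizes these as one time-averaged ("smeared") profile whose
#' peak is the predicted attend-bar pRF position. `stim_profile` selects
#' how the attend-bar response is generated from this machinery:
#' \describe{
#'   \item{"gaussian" (default)}{a static isotropic Gaussian at the
#'     model-predicted position, sized as the closed-form product of the
#'     SD with the effective stimulus gain field (kernel + bar width).
#'     Fitted attend-bar pRFs then recover exactly the position the
#'     gain-field inversion predicts.}
#'   \item{"smeared"}{the time-averaged normalized product profile itself
#'     (non-Gaussian; Gaussian fits to it land near, but not exactly at,
#'     its peak).}
#'   \item{"traveling"}{the frame-wise products drive each frame's
#'     response directly (attention travels with the bar).}
#' }
#' The neural signal is the overlap of each frame mask with the effective
#' pRF, normalized to a peak of 1 across frames so that `amplitude` sets
#' the peak response, convolved with the HRF, offset by `baseline`, with
#' i.i.d. (optionally AR(1)) Gaussian noise added.
#'
#' @param voxel One-row data.frame or list with x, y, sigma, amplitude,
#'   baseline (the stimulus-drive pRF).
#' @param dm A `design_matrix` (101-grid recommended).
#' @param condition One of "AttendFixation", "AttendColor", "AttendTF".
#' @param af An `af_spec`.
#' @param hrf An `hrf_kernel` sampled at the frame interval.
#' @param noise_sd Gaussian noise standard deviation, signal units.
#' @param ar_rho AR(1) coefficient of the noise (0 = white).
#' @param seed Seed for the noise; NULL uses the current RNG state.
#' @param smoothed Optional precomputed `smooth_bar_frames()` result for the
#'   condition's kernel (avoids re-smoothing when generating many voxels).
#' @param stim_profile Attend-bar effective-pRF variant: "gaussian"
#'   (default), "smeared" or "traveling" (see Details).
#' @return List of class `voxel_timeseries` with `values` (length = frame
#'   count), `neural`, `condition`, `noise_sd`, `seed`.
#' @export
generate_bold_timeseries <- function(voxel, dm, condition, af, hrf,
                                     noise_sd = 0, ar_rho = 0, seed = NULL,
                                     smoothed = NULL,
                                     stim_profile = c("gaussian", "smeared",
                                                      "traveling")) {
  .stop_if(!condition %in% .conditions,
           "unknown condition label: ", condition)
  stim_profile <- match.arg(stim_profile)
  grid <- dm$grid
  sd_g <- list(center = c(voxel$x, voxel$y), sigma = voxel$sigma)
  if (condition == "AttendFixation") {
    eff <- gaussian_product(sd_g, list(center = af$fix_center,
                                       sigma = af$sigma_fix))
    g <- .gauss_profile(grid, eff$center[1], eff$center[2], eff$sigma)
    neural <- as.numeric(dm$masks %*% g)
  } else {
    sk <- .af_kernel_sigma(af, condition)
    ub <- unique_bar_frames(dm)
    if (is.null(smoothed)) smoothed <- smooth_bar_frames(ub, sk)
    if (stim_profile == "traveling") {
      g <- .gauss_profile(grid, voxel$x, voxel$y, voxel$sigma)
      nb <- cpp_neural_attend(Matrix::t(ub$masks), smoothed$S, g)
      neural <- .expand_unique_frames(dm, ub, nb)
    } else {
      A <- cpp_avg_profile(smoothed$S, smoothed$wts, grid$x, grid$y,
                           voxel$x, voxel$y, voxel$sigma)
      .stop_if(max(A) == 0,
               "stimulus drive outside the stimulated region")
      if (stim_profile == "smeared") {
        neural <- as.numeric(dm$masks %*% A)
      } else {
        peak_ix <- which.max(A)
        s_eff <- gaussian_product(
          sd_g, list(center = c(grid$x[peak_ix], grid$y[peak_ix]),
                     sigma = sk + dm$bar_width_dva))$sigma
        g <- .gauss_profile(grid, grid$x[peak_ix], grid$y[peak_ix], s_eff)
        neural <- as.numeric(dm$masks %*% g)
      }
    }
  }
  peak <- max(neural)
  if (peak > 0) neural <- neural / peak
  clean <- voxel$amplitude * as.numeric(.causal_conv(neural, hrf$weights)) +
    voxel$baseline
  values <- .with_seed(seed, {
    eps <- rnorm(length(clean), 0, noise_sd)
    if (ar_rho != 0)
      eps <- as.numeric(stats::filter(eps, ar_rho, method = "recursive")) *
        sqrt(1 - ar_rho^2)
    clean + eps
  })
  structure(list(values = values, neural = neural, condition = condition,
                 noise_sd = noise_sd, seed = seed),
            class = "voxel_timeseries")
}

.af_kernel_sigma <- function(af, condition)
  switch(condition, AttendColor = af$sigma_stim_color,
         AttendTF = af$sigma_stim_tf,
         stop("no stimulus kernel for condition ", condition, call. = FALSE))

#' Simulate a full condition-specific pRF dataset
#'
#' Samples a ground-truth voxel population and generates BOLD time series
#' for the three attention conditions from the gain-field generative model.
#' Noise is specified as a fraction of each voxel's amplitude, per sample.
#' `n_runs` independent repetitions of the traversal sequence are
#' generated per condition and averaged, emulating a session of several
#' mapping runs (for identical regressors, fitting the run average is the
#' exact least-squares equivalent of fitting the concatenation).
#'
#' @param n_voxels Number of voxels.
#' @param dm A `design_matrix` (101-grid).
#' @param hrf An `hrf_kernel`.
#' @param af An `af_spec`.
#' @param noise_frac Noise SD as a fraction of amplitude (0.2 = 20% noise),
#'   per run.
#' @param n_runs Repetitions of the full traversal sequence per condition
#'   (default 2, i.e. 48 bar passes per condition).
#' @param seed Seed controlling both the population and the noise.
#' @param stim_profile Attend-bar generative variant, see
#'   [generate_bold_timeseries()].
#' @param ... Passed to [sample_ground_truth_voxels()].
#' @return List of class `prf_dataset`: `voxels` (ground truth), `ts`
#'   (frames x voxels x 3 conditions array), `af`, `noise_frac`.
#' @export
simulate_prf_dataset <- function(n_voxels, dm, hrf, af = af_spec(),
                                 noise_frac = 0.2, n_runs = 2, seed = 1L,
                                 stim_profile = "gaussian", ...) {
  ub <- unique_bar_frames(dm)
  kernels <- c(AttendColor = af$sigma_stim_color,
               AttendTF = af$sigma_stim_tf)
  sm <- list(AttendColor = smooth_bar_frames(ub, kernels[["AttendColor"]]))
  sm$AttendTF <- if (kernels[["AttendTF"]] == kernels[["AttendColor"]])
    sm$AttendColor else smooth_bar_frames(ub, kernels[["AttendTF"]])
  .with_seed(seed, {
    voxels <- sample_ground_truth_voxels(n_voxels, seed = NULL, ...)
    ts <- array(NA_real_, c(nrow(dm$masks), n_voxels, 3),
                dimnames = list(NULL, NULL, .conditions))
    for (v in seq_len(n_voxels)) {
      vox <- voxels[v, ]
      for (cond in .conditions) {
        runs <- vapply(seq_len(n_runs), function(r)
          generate_bold_timeseries(
            vox, dm, cond, af, hrf,
            noise_sd = noise_frac * vox$amplitude, seed = NULL,
            smoothed = sm[[cond]], stim_profile = stim_profile)$values,
          numeric(nrow(dm$masks)))
        ts[, v, cond] <- rowMeans(runs)
      }
    }
    structure(list(voxels = voxels, ts = ts, af = af,
                   noise_frac = noise_frac, n_runs = n_runs, seed = seed),
              class = "prf_dataset")
  })
}

#' @exportS3Method base::print
print.prf_dataset <- function(x, ...) {
  cat(sprintf("prf_dataset: %d voxels x %d frames x 3 conditions, %.0f%% noise\n",
              dim(x$ts)[2], dim(x$ts)[1], 100 * x$noise_frac))
  invisible(x)
}
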