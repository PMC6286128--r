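# Descriptive attention analyses: quadrant mirroring, shift-direction
# decomposition, polar-angle slope contrast, eccentricity/size change
# profiles, and the (feature) attention modulation index.

#' Mirror pRF positions into the first quadrant
#'
#' Multiplies all conditions' coordinates by the sign of the Attend
#' Fixation coordinates, so fixation positions land in the first quadrant
#' while cross-meridian positions of other conditions keep their relative
#' sign. Zero fixation coordinates count as positive.
#'
#' @param fix data.frame with columns `x`, `y` (Attend Fixation positions).
#' @param ... Further data.frames with `x`, `y` columns (other conditions),
#'   mirrored with the fixation signs.
#' @return List of mirrored data.frames: `fix` first, then the others in
#'   order.
#' @export
mirror_to_quadrant <- function(fix, ...) {
  sx <- ifelse(fix$x < 0, -1, 1)
  sy <- ifelse(fix$y < 0, -1, 1)
  flip <- function(d) { d$x <- d$x * sx; d$y <- d$y * sy; d }
  c(list(fix = flip(fix)), lapply(list(...), flip))
}

#' Build quadrant-mirrored shift records
#'
#' For each voxel, the Attend Fixation -> comparison-condition position
#' shift after quadrant mirroring, with its length and decomposed
#' components. Eccentricity is unchanged by mirroring, so the signed
#' eccentricity change equals the unmirrored one.
#'
#' @param fits A `prf_fits` data.frame.
#' @param comparison Condition compared against Attend Fixation
#'   ("AttendStimulus", "AttendColor" or "AttendTF").
#' @return data.frame of class `shift_records`: voxel_id, mirrored start /
#'   end positions, start/end sizes, dx, dy, shift length `L`, signed
#'   eccentricity change `d_ecc`, `polar_angle` of the start, weight `w`
#'   (R2).
#' @export
shift_records <- function(fits, comparison = "AttendStimulus") {
  fix <- fits[fits$condition == "AttendFixation", ]
  cmp <- fits[fits$condition == comparison, ]
  .stop_if(nrow(cmp) == 0, "comparison condition not present: ", comparison)
  cmp <- cmp[match(fix$voxel_id, cmp$voxel_id), ]
  m <- mirror_to_quadrant(fix[, c("x", "y")], cmp[, c("x", "y")])
  out <- data.frame(
    voxel_id = fix$voxel_id,
    start_x = m$fix$x, start_y = m$fix$y, start_sigma = fix$sigma,
    end_x = m[[2]]$x, end_y = m[[2]]$y, end_sigma = cmp$sigma)
  out$dx <- out$end_x - out$start_x
  out$dy <- out$end_y - out$start_y
  out$L <- sqrt(out$dx^2 + out$dy^2)
  out$d_ecc <- sqrt(cmp$x^2 + cmp$y^2) - sqrt(fix$x^2 + fix$y^2)
  out$polar_angle <- atan2(out$start_y, out$start_x)
  out$w <- fix$r2
  attr(out, "comparison") <- comparison
  class(out) <- c("shift_records", "data.frame")
  out
}

.wmean <- function(v, w) sum(v * w) / sum(w)

#' Decompose pRF shifts into radial, horizontal and vertical components
#'
#' Per-voxel ratios |d_ecc|/L, |dx|/L, |dy|/L, aggregated as R2-weighted
#' means with bootstrap confidence intervals, plus pairwise bootstrap
#' comparisons (radial vs horizontal, horizontal vs vertical). Zero-length
#' shifts are excluded and counted.
#'
#' @param records A `shift_records` data.frame.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return List with `ratios` (component, estimate, ci_low, ci_high),
#'   `comparisons` (pairwise weighted-bootstrap p-values) and `n_excluded`.
#' @export
decompose_shift_directions <- function(records, n_boot = 10000, seed = 1L) {
  keep <- records$L > 0
  .stop_if(!any(keep), "all shifts have zero length")
  r <- records[keep, ]
  comp <- data.frame(ecc = abs(r$d_ecc) / r$L, x = abs(r$dx) / r$L,
                     y = abs(r$dy) / r$L)
  ratios <- do.call(rbind, lapply(names(comp), function(nm) {
    bs <- weighted_bootstrap(comp[[nm]], r$w, n_boot = n_boot, seed = seed)
    data.frame(component = nm, estimate = bs$estimate,
               ci_low = bs$ci[1], ci_high = bs$ci[2])
  }))
  pair <- function(a, b, nm) {
    bs <- weighted_bootstrap(comp[[a]] - comp[[b]], r$w, n_boot = n_boot,
                             seed = seed)
    data.frame(comparison = nm, estimate = bs$estimate, ci_low = bs$ci[1],
               ci_high = bs$ci[2], p = bs$p)
  }
  list(ratios = ratios,
       comparisons = rbind(pair("ecc", "x", "ecc_vs_x"),
                           pair("x", "y", "x_vs_y")),
       n_excluded = sum(!keep))
}

#' Polar-angle dependence of shift components
#'
#' Bins the quadrant polar angle (0 = horizontal meridian, pi/2 = vertical
#' meridian) into `n_bins` equal-width bins and computes R2-weighted mean
#' dx, dy and d_ecc per bin. The slope contrast compares the first-vs-last
#' bin change of dx against that of dy:
#' `contrast = (dx_last - dx_first) - (dy_last - dy_first)`. For radial
#' (foveopetal) shifts dx is most negative at the horizontal meridian and
#' dy at the vertical meridian, so the contrast is positive; a bootstrap
#' over voxels gives its p-value.
#'
#' @param records A `shift_records` data.frame.
#' @param n_bins Number of polar-angle bins.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed.
#' @return List with `bins` (per-bin weighted means), `contrast`,
#'   `p` (two-tailed) and `n_boot`.
#' @export
polar_angle_slope_analysis <- function(records, n_bins = 3, n_boot = 2000,
                                       seed = 1L) {
  ang <- records$polar_angle
  ang <- abs(((ang + pi) %% pi))          # fold to [0, pi)
  ang <- ifelse(ang > pi / 2, pi - ang, ang)
  edges <- seq(0, pi / 2, length.out = n_bins + 1)
  bins <- cut(ang, edges, include.lowest = TRUE, labels = FALSE)
  empty <- setdiff(seq_len(n_bins), unique(bins))
  .stop_if(length(empty) > 0,
           "empty polar-angle bin(s): ", paste(empty, collapse = ", "))
  stat <- function(ix) {
    b <- bins[ix]
    dx1 <- .wmean(records$dx[ix][b == 1], records$w[ix][b == 1])
    dxk <- .wmean(records$dx[ix][b == n_bins], records$w[ix][b == n_bins])
    dy1 <- .wmean(records$dy[ix][b == 1], records$w[ix][b == 1])
    dyk <- .wmean(records$dy[ix][b == n_bins], records$w[ix][b == n_bins])
    (dxk - dx1) - (dyk - dy1)
  }
  tab <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    ix <- which(bins == b)
    data.frame(bin = b, angle_mid = (edges[b] + edges[b + 1]) / 2,
               n = length(ix),
               dx = .wmean(records$dx[ix], records$w[ix]),
               dy = .wmean(records$dy[ix], records$w[ix]),
               d_ecc = .wmean(records$d_ecc[ix], records$w[ix]))
  }))
  obs <- stat(seq_len(nrow(records)))
  boots <- .with_seed(seed, {
    n <- nrow(records)
    vapply(seq_len(n_boot), function(i) {
      ix <- sample.int(n, n, replace = TRUE)
      if (!all(seq_len(n_bins) %in% bins[ix])) return(NA_real_)
      stat(ix)
    }, 0)
  })
  boots <- boots[!is.na(boots)]
  p <- 2 * min(mean(boots <= 0), mean(boots >= 0))
  p <- min(1, max(p, 2 / length(boots)))
  list(bins = tab, contrast = obs, p = p, n_boot = length(boots))
}

#' Eccentricity and size changes across eccentricity
#'
#' Bins voxels by Attend Fixation eccentricity and computes R2-weighted
#' mean changes in eccentricity and size (comparison minus Attend
#' Fixation): an `n_ecc_bins` equal-width profile with bootstrap CIs, and a
#' `n_pct_bins` percentile-bin summary whose bin means feed a Pearson
#' correlation between eccentricity change and size change (with a
#' Fisher-transform CI). Outliers beyond `outlier_k` median absolute
#' deviations are rejected per bin and per measure.
#'
#' @param fits A `prf_fits` data.frame.
#' @param comparison Condition compared against Attend Fixation.
#' @param n_ecc_bins Equal-width bins for the profile.
#' @param n_pct_bins Percentile bins for the correlation (20 = 5-percentile
#'   bins).
#' @param ecc_max Upper edge of the equal-width bins, dva.
#' @param equal_count If TRUE the profile uses equal-count (quantile) bins.
#' @param outlier_k MAD multiplier for per-bin outlier rejection.
#' @param n_boot Bootstrap resamples for the profile CIs.
#' @param seed Seed.
#' @return List with `profile`, `pct_bins`, and `correlation`
#'   (r, ci, p-style flag when undefined).
#' @export
ecc_size_change_analysis <- function(fits, comparison = "AttendStimulus",
                                     n_ecc_bins = 4, n_pct_bins = 20,
                                     ecc_max = 3.3, equal_count = FALSE,
                                     outlier_k = 5, n_boot = 2000,
                                     seed = 1L) {
  rec <- shift_records(fits, comparison)
  d_size <- rec$end_sigma - rec$start_sigma
  ecc0 <- sqrt(rec$start_x^2 + rec$start_y^2)
  .stop_if(nrow(rec) < n_pct_bins,
           "need at least n_pct_bins voxels")
  edges <- if (equal_count)
    quantile(ecc0, seq(0, 1, length.out = n_ecc_bins + 1))
  else seq(0, ecc_max, length.out = n_ecc_bins + 1)
  .stop_if(any(duplicated(edges)), "degenerate eccentricity bins")
  bins <- cut(ecc0, edges, include.lowest = TRUE, labels = FALSE)
  bin_mean <- function(v, w, boot_seed) {
    ok <- if (length(v) >= 3) mad_outlier_mask(v, k = outlier_k)
      else rep(TRUE, length(v))
    bs <- weighted_bootstrap(v[ok], w[ok], n_boot = n_boot, seed = boot_seed)
    c(est = bs$estimate, lo = bs$ci[1], hi = bs$ci[2], n = sum(ok))
  }
  profile <- do.call(rbind, lapply(seq_len(n_ecc_bins), function(b) {
    ix <- which(bins == b)
    if (length(ix) < 3)
      return(data.frame(bin = b, n = length(ix), d_ecc = NA_real_,
                        d_ecc_lo = NA_real_, d_ecc_hi = NA_real_,
                        d_size = NA_real_, d_size_lo = NA_real_,
                        d_size_hi = NA_real_))
    e <- bin_mean(rec$d_ecc[ix], rec$w[ix], seed + b)
    s <- bin_mean(d_size[ix], rec$w[ix], seed + 100 + b)
    data.frame(bin = b, n = length(ix), d_ecc = e["est"],
               d_ecc_lo = e["lo"], d_ecc_hi = e["hi"],
               d_size = s["est"], d_size_lo = s["lo"], d_size_hi = s["hi"])
  }))
  rownames(profile) <- NULL

  qb <- cut(ecc0, quantile(ecc0, seq(0, 1, length.out = n_pct_bins + 1)),
            include.lowest = TRUE, labels = FALSE)
  pct <- do.call(rbind, lapply(seq_len(n_pct_bins), function(b) {
    ix <- which(qb == b)
    no_mask <- rep(TRUE, length(ix))
    oe <- if (length(ix) >= 3) mad_outlier_mask(rec$d_ecc[ix], k = outlier_k)
      else no_mask
    os <- if (length(ix) >= 3) mad_outlier_mask(d_size[ix], k = outlier_k)
      else no_mask
    data.frame(bin = b, n = length(ix),
               ecc = .wmean(ecc0[ix], rec$w[ix]),
               d_ecc = .wmean(rec$d_ecc[ix][oe], rec$w[ix][oe]),
               d_size = .wmean(d_size[ix][os], rec$w[ix][os]))
  }))
  correlation <- if (sd(pct$d_ecc) == 0 || sd(pct$d_size) == 0 ||
                     anyNA(pct$d_ecc) || anyNA(pct$d_size)) {
    list(r = NA_real_, ci = c(NA_real_, NA_real_), defined = FALSE)
  } else {
    r <- cor(pct$d_ecc, pct$d_size)
    ci <- if (abs(r) < 1)
      tanh(fisher_z(r) + c(-1, 1) * 1.96 / sqrt(n_pct_bins - 3))
    else c(r, r)
    list(r = r, ci = ci, defined = TRUE)
  }
  list(profile = profile, pct_bins = pct, correlation = correlation)
}

#' Feature attention modulation index
#'
#' Per voxel and per attend-bar condition, the change vector (eccentricity
#' change, size change) relative to Attend Fixation, with each component
#' normalized by the across-voxel dispersion of the corresponding
#' Attend Stimulus - Attend Fixation difference so that both contribute
#' commensurately. The AMI of a condition is the norm of its normalized
#' vector; the feature AMI is the difference over the sum of the color and
#' TF AMIs. Voxels where both norms are zero are flagged undefined.
#'
#' @param fits A `prf_fits` data.frame (>= 2 voxels).
#' @param norm "sd" (default) normalizes by the standard deviation of the
#'   Attend Stimulus - Attend Fixation differences; "variance" uses the
#'   variance (the literal reading).
#' @return data.frame of class `ami_records`: voxel_id, ami_color, ami_tf,
#'   feature_ami (NA when undefined), defined, weight `w`.
#' @export
compute_feature_ami <- function(fits, norm = c("sd", "variance")) {
  norm <- match.arg(norm)
  wide <- function(cond) {
    d <- fits[fits$condition == cond, ]
    d[match(unique(fits$voxel_id), d$voxel_id), ]
  }
  fix <- wide("AttendFixation")
  col <- wide("AttendColor")
  tf <- wide("AttendTF")
  stim <- wide("AttendStimulus")
  .stop_if(nrow(fix) < 2, "need at least two voxels")
  ds_ecc <- stim$ecc - fix$ecc
  ds_size <- stim$sigma - fix$sigma
  disp <- function(v) if (norm == "sd") sd(v) else var(v)
  s_ecc <- disp(ds_ecc)
  s_size <- disp(ds_size)
  .stop_if(s_ecc == 0 || s_size == 0,
           "zero dispersion of the Attend Stimulus - Attend Fixation differences")
  nrm <- function(cond_df)
    sqrt(((cond_df$ecc - fix$ecc) / s_ecc)^2 +
           ((cond_df$sigma - fix$sigma) / s_size)^2)
  ami_c <- nrm(col)
  ami_t <- nrm(tf)
  denom <- ami_c + ami_t
  out <- data.frame(voxel_id = fix$voxel_id, ami_color = ami_c,
                    ami_tf = ami_t,
                    feature_ami = ifelse(denom > 0,
                                         (ami_c - ami_t) / denom, NA_real_),
                    defined = denom > 0, w = fix$r2)
  class(out) <- c("ami_records", "data.frame")
  out
}

#' Feature preference index
#'
#' Contrast of a voxel's response amplitude to color versus temporal
#' frequency stimulation: `(beta_color - beta_tf) / (|beta_color| +
#' |beta_tf|)`. Positive values indicate color preference. Vectorized;
#' voxels with both betas zero return NA.
#'
#' @param beta_color,beta_tf Response amplitudes.
#' @return Index in `[-1, 1]` (NA where undefined).
#' @export
feature_preference_index <- function(beta_color, beta_tf) {
  denom <- abs(beta_color) + abs(beta_tf)
  ifelse(denom > 0, (beta_color - beta_tf) / denom, NA_real_)
}
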