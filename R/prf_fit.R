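# Three-step pRF estimation: regularized back-projection for a coarse
# center, a joint 2D Gaussian fit over all attention conditions, and a
# per-condition refit with one shared baseline; plus R2 and voxel selection.

#' Isotropic 2D Gaussian pRF parameters
#'
#' @param x,y Center, dva.
#' @param sigma Size (standard deviation), dva; must be positive.
#' @param amplitude,baseline Response scaling and offset, signal units.
#' @return List of class `prf_params` with derived `ecc_dva` and
#'   `polar_angle_rad`.
#' @export
prf_params <- function(x, y, sigma, amplitude = 1, baseline = 0) {
  .stop_if(sigma <= 0, "sigma must be positive")
  structure(list(x = x, y = y, sigma = sigma, amplitude = amplitude,
                 baseline = baseline, ecc_dva = sqrt(x^2 + y^2),
                 polar_angle_rad = atan2(y, x)),
            class = "prf_params")
}

#' @exportS3Method base::print
print.prf_params <- function(x, ...) {
  cat(sprintf("prf_params: center (%.3f, %.3f) dva, sigma %.3f, ecc %.3f, amp %.3g, base %.3g\n",
              x$x, x$y, x$sigma, x$ecc_dva, x$amplitude, x$baseline))
  invisible(x)
}

#' Coefficient of determination of a time-series fit
#'
#' R2 = 1 - sum((m - p)^2) / sum((m - mean(m))^2).
#'
#' @param measured,predicted Numeric vectors of equal length (n >= 2);
#'   `measured` must not be constant.
#' @return R2 in (-Inf, 1].
#' @export
compute_r2 <- function(measured, predicted) {
  .stop_if(length(measured) != length(predicted), "length mismatch")
  .stop_if(length(measured) < 2, "need at least two samples")
  ss_tot <- sum((measured - mean(measured))^2)
  .stop_if(ss_tot == 0, "measured series is constant")
  1 - sum((measured - predicted)^2) / ss_tot
}

# Cached factorization for the ridge back-projection: the regressor matrix
# is identical across conditions, so the stacked Gram matrix is
# n_conditions * X'X + lambda I.
.ridge_solver <- function(reg, lambda, n_conditions) {
  G <- n_conditions * crossprod(reg$W)
  diag(G) <- diag(G) + lambda
  R <- chol(G)
  list(R = R, W = reg$W, grid = reg$grid, n_conditions = n_conditions)
}

.ridge_coef <- function(solver, ysum) {
  b <- crossprod(solver$W, ysum)
  backsolve(solver$R, backsolve(solver$R, b, transpose = TRUE))
}

#' Coarse pRF localization by regularized back-projection
#'
#' L2-penalized (ridge) regression of the voxel's z-scored, concatenated
#' condition time series on the HRF-convolved pixel regressors of the
#' coarse (31 x 31) design. With a very high penalty the coefficient map is
#' a smoothed spatial response profile; the position of its maximum
#' initializes the nonlinear fit. Ties are broken toward the lowest
#' flattened pixel index.
#'
#' @param ts Numeric matrix (frames x conditions) or vector (one
#'   condition). Each condition is z-scored before regression.
#' @param reg A `regressor_stack` from [convolve_design()] on the coarse
#'   grid.
#' @param lambda Ridge penalty (default 1e6).
#' @param solver Optional precomputed solver (internal; reused across
#'   voxels by [fit_prf_dataset()]).
#' @return List with the peak pixel's `x`, `y` (dva) and flattened `index`.
#' @export
ridge_init <- function(ts, reg, lambda = 1e6, solver = NULL) {
  ts <- as.matrix(ts)
  sds <- apply(ts, 2, sd)
  .stop_if(any(sds == 0), "constant (e.g. all-zero) time series")
  z <- sweep(sweep(ts, 2, colMeans(ts)), 2, sds, "/")
  if (is.null(solver)) solver <- .ridge_solver(reg, lambda, ncol(ts))
  coefs <- .ridge_coef(solver, rowSums(z))
  idx <- which.max(coefs)
  list(x = solver$grid$x[idx], y = solver$grid$y[idx], index = idx)
}

# Gaussian profile (peak 1) and its parameter derivatives on the grid,
# mapped through the design: conv(masks %*% g) equals W %*% g by linearity
# but costs one sparse product instead of a dense one.
.overlap_sparse <- function(reg, x0, y0, sigma, derivs = FALSE) {
  gx <- reg$grid$x
  gy <- reg$grid$y
  dx <- gx - x0
  dy <- gy - y0
  g <- exp(-(dx^2 + dy^2) / (2 * sigma^2))
  G <- if (derivs)
    cbind(g, g * dx / sigma^2, g * dy / sigma^2,
          g * (dx^2 + dy^2) / sigma^3)
  else matrix(g)
  .causal_conv(as.matrix(reg$masks %*% G), reg$hrf_weights)
}

# Residuals and analytic Jacobian of the Gaussian-overlap model
# y ~ a * conv(dm %*% g(x0, y0, sigma)) + b, for one or several condition
# blocks with per-block (x0, y0, sigma, a) and one shared baseline b.
.prf_resid <- function(par, y_list, reg, jac = FALSE) {
  k <- length(y_list)
  b <- par[4 * k + 1]
  res <- vector("list", k)
  J <- if (jac) vector("list", k)
  for (c in seq_len(k)) {
    p <- par[(c - 1) * 4 + 1:4]
    O <- .overlap_sparse(reg, p[1], p[2], p[3], derivs = jac)
    res[[c]] <- y_list[[c]] - (p[4] * O[, 1] + b)
    if (jac) {
      Jc <- matrix(0, length(y_list[[c]]), 4 * k + 1)
      Jc[, (c - 1) * 4 + 1:3] <- -p[4] * O[, 2:4]
      Jc[, (c - 1) * 4 + 4] <- -O[, 1]
      Jc[, 4 * k + 1] <- -1
      J[[c]] <- Jc
    }
  }
  if (jac) do.call(rbind, J) else unlist(res, use.names = FALSE)
}

.prf_bounds <- function(k, xy_bound = 5, sigma_bounds = c(0.05, 10)) {
  lower <- c(rep(c(-xy_bound, -xy_bound, sigma_bounds[1], -Inf), k), -Inf)
  upper <- c(rep(c(xy_bound, xy_bound, sigma_bounds[2], Inf), k), Inf)
  list(lower = lower, upper = upper)
}

.run_lm <- function(par, y_list, reg, bounds, maxiter = 100) {
  ctl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-12,
                                    ptol = 1e-10)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = par, lower = bounds$lower, upper = bounds$upper,
      fn = function(p) .prf_resid(p, y_list, reg),
      jac = function(p) .prf_resid(p, y_list, reg, jac = TRUE),
      control = ctl),
    error = function(e) NULL)
  if (is.null(fit)) return(list(par = par, converged = FALSE))
  list(par = pmin(pmax(coef(fit), bounds$lower), bounds$upper),
       converged = fit$info %in% 1:4)
}

#' Joint pRF fit over all attention conditions
#'
#' Fits a single isotropic 2D Gaussian pRF (position, size, amplitude,
#' baseline) to the concatenated condition time series by nonlinear least
#' squares on the fine (101 x 101) convolved design, initialized at the
#' back-projection peak. Size is initialized at the best of a small
#' log-spaced candidate set. Non-convergence is flagged, not raised.
#'
#' @param ts Matrix (frames x conditions) or vector.
#' @param reg `regressor_stack` on the fine grid.
#' @param init_xy Length-2 numeric: initial center (from [ridge_init()]).
#' @param xy_bound,sigma_bounds Box bounds on center (+/- dva) and size.
#' @param sigma_init Candidate initial sizes, dva.
#' @return List of class `prf_fit` with `params` (a `prf_params`), `r2` and
#'   `converged`.
#' @export
fit_prf_joint <- function(ts, reg, init_xy,
                          xy_bound = 5, sigma_bounds = c(0.05, 10),
                          sigma_init = c(0.25, 0.5, 1, 2)) {
  ts <- as.matrix(ts)
  y <- as.numeric(ts)
  # The regressors are identical for every condition block, so fitting the
  # across-condition mean series yields the same least-squares solution as
  # fitting the concatenation, at a third of the cost.
  ybar <- rowMeans(ts)
  best <- NULL
  for (s0 in sigma_init) {
    r <- .overlap_sparse(reg, init_xy[1], init_xy[2], s0)[, 1]
    ab <- lm.fit(cbind(r, 1), ybar)$coefficients
    sse <- sum((ybar - cbind(r, 1) %*% ab)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(sse = sse, par = c(init_xy, s0, ab[1], ab[2]))
  }
  res <- .run_lm(best$par, list(ybar), reg,
                 .prf_bounds(1, xy_bound, sigma_bounds))
  p <- res$par
  pred <- p[4] * .overlap_sparse(reg, p[1], p[2], p[3])[, 1] + p[5]
  structure(list(params = prf_params(p[1], p[2], p[3], p[4], p[5]),
                 r2 = compute_r2(y, rep(pred, ncol(ts))),
                 converged = res$converged),
            class = "prf_fit")
}

#' Per-condition pRF fit with a shared baseline
#'
#' Simultaneously fits one isotropic Gaussian per attention condition
#' (position, size, amplitude each) plus a single baseline shared by all
#' conditions (13 free parameters for three conditions), initialized at the
#' joint fit. R2 is computed on the concatenated prediction. The derived
#' Attend Stimulus parameters are the element-wise means of the Attend
#' Color and Attend TF parameters.
#'
#' @param ts Matrix (frames x 3) with columns in the order AttendFixation,
#'   AttendColor, AttendTF.
#' @param reg `regressor_stack` on the fine grid.
#' @param joint A `prf_fit` from [fit_prf_joint()].
#' @param xy_bound,sigma_bounds Box bounds as in [fit_prf_joint()].
#' @return List of class `condition_fit`: `params` data.frame (one row per
#'   condition plus AttendStimulus), `baseline`, `r2`, `converged`.
#' @export
fit_prf_per_condition <- function(ts, reg, joint,
                                  xy_bound = 5, sigma_bounds = c(0.05, 10)) {
  ts <- as.matrix(ts)
  .stop_if(ncol(ts) != 3, "need three condition time series")
  y_list <- lapply(seq_len(3), function(c) ts[, c])
  jp <- joint$params
  par0 <- c(rep(c(jp$x, jp$y, jp$sigma, jp$amplitude), 3), jp$baseline)
  res <- .run_lm(par0, y_list, reg, .prf_bounds(3, xy_bound, sigma_bounds))
  p <- res$par
  b <- p[13]
  rows <- lapply(1:3, function(c) p[(c - 1) * 4 + 1:4])
  pred <- unlist(lapply(1:3, function(c) {
    q <- rows[[c]]
    q[4] * .overlap_sparse(reg, q[1], q[2], q[3])[, 1] + b
  }))
  pm <- do.call(rbind, rows)
  pm <- rbind(pm, colMeans(pm[2:3, , drop = FALSE]))
  params <- data.frame(condition = c(.conditions, "AttendStimulus"),
                       x = pm[, 1], y = pm[, 2], sigma = pm[, 3],
                       amplitude = pm[, 4])
  params$ecc <- sqrt(params$x^2 + params$y^2)
  params$polar_angle <- atan2(params$y, params$x)
  structure(list(params = params, baseline = b,
                 r2 = compute_r2(as.numeric(ts), pred),
                 converged = res$converged),
            class = "condition_fit")
}

#' @exportS3Method base::print
print.condition_fit <- function(x, ...) {
  cat(sprintf("condition_fit: shared baseline %.3g, R2 %.3f%s\n",
              x$baseline, x$r2,
              if (x$converged) "" else " (not converged)"))
  print(x$params, digits = 3)
  invisible(x)
}

#' Fit pRFs for every voxel of a dataset
#'
#' Runs the full three-step procedure (back-projection, joint fit,
#' per-condition fit) for each voxel of a simulated (or externally loaded)
#' condition time-series array.
#'
#' @param ts Array (frames x voxels x 3 conditions) or a `prf_dataset`.
#' @param reg_coarse,reg_fine `regressor_stack`s on the coarse (31) and
#'   fine (101) grids.
#' @param lambda Ridge penalty for the back-projection.
#' @param ... Passed to the fitting functions (bounds).
#' @return data.frame of class `prf_fits`: one row per voxel x condition
#'   (including the derived AttendStimulus) with columns voxel_id,
#'   condition, x, y, sigma, ecc, polar_angle, amplitude, baseline, r2,
#'   converged.
#' @export
fit_prf_dataset <- function(ts, reg_coarse, reg_fine, lambda = 1e6, ...) {
  if (inherits(ts, "prf_dataset")) ts <- ts$ts
  nv <- dim(ts)[2]
  solver <- .ridge_solver(reg_coarse, lambda, dim(ts)[3])
  out <- vector("list", nv)
  for (v in seq_len(nv)) {
    tsv <- ts[, v, ]
    init <- ridge_init(tsv, reg_coarse, lambda, solver = solver)
    joint <- fit_prf_joint(tsv, reg_fine, c(init$x, init$y), ...)
    cf <- fit_prf_per_condition(tsv, reg_fine, joint, ...)
    df <- cf$params
    df$voxel_id <- v
    df$baseline <- cf$baseline
    df$r2 <- cf$r2
    df$converged <- cf$converged
    out[[v]] <- df
  }
  res <- do.call(rbind, out)
  res <- res[, c("voxel_id", "condition", "x", "y", "sigma", "ecc",
                 "polar_angle", "amplitude", "baseline", "r2", "converged")]
  rownames(res) <- NULL
  class(res) <- c("prf_fits", "data.frame")
  res
}

#' Select voxels by eccentricity, size and fit quality
#'
#' Excludes voxels whose Attend Fixation eccentricity exceeds `ecc_max`
#' (edge of the stimulus region), whose size exceeds `size_max` in any
#' task condition, or whose R2 is below `r2_min`.
#'
#' @param fits A `prf_fits` data.frame.
#' @param ecc_max Maximum Attend Fixation eccentricity, dva.
#' @param size_max Maximum size in any condition, dva.
#' @param r2_min Minimum R2.
#' @return List with `keep` (named logical per voxel), `voxel_ids` (kept),
#'   `fits` (the selected rows) and a rejection `log` (counts per
#'   criterion; a voxel can fail several).
#' @export
select_voxels <- function(fits, ecc_max = 3.3, size_max = 7.2, r2_min = 0.1) {
  sp <- split(fits, fits$voxel_id)
  crit <- t(vapply(sp, function(d) {
    fix <- d[d$condition == "AttendFixation", ]
    c(ecc = fix$ecc[1] > ecc_max,
      size = any(d$sigma[d$condition %in% .conditions] > size_max),
      r2 = fix$r2[1] < r2_min)
  }, logical(3)))
  keep <- !apply(crit, 1, any)
  ids <- as.integer(names(sp))[keep]
  list(keep = setNames(keep, names(sp)), voxel_ids = ids,
       fits = fits[fits$voxel_id %in% ids, ],
       log = data.frame(criterion = c("ecc_gt_max", "size_gt_max", "r2_lt_min"),
                        n_excluded = colSums(crit)),
       n_total = length(sp), n_kept = sum(keep))
}

#' Write a pRF fits table as TSV
#' @param fits A `prf_fits` data.frame.
#' @param path Output path.
#' @export
write_prf_fits <- function(fits, path) {
  write.table(fits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
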