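# Bar-stimulus design: traversal sequence, rasterized design matrices, HRF.

#' Visual-field pixel grid
#'
#' Square pixel grid covering the stimulated region, used for design
#' matrices, pRF profiles and gain-field evaluation. Pixels are ordered with
#' x varying fastest; x increases rightward and y upward. Pixel centers lie
#' at `extent * (i - 0.5) / n - extent / 2`.
#'
#' @param n Number of pixels per side (>= 3).
#' @param extent_dva Side length of the square grid in degrees visual angle.
#' @return A list of class `vf_grid` with elements `n`, `extent_dva`,
#'   `px_dva` (pixel size) and pixel-center coordinate vectors `x`, `y`
#'   (length `n^2`).
#' @export
vf_grid <- function(n, extent_dva = 7.2) {
  .stop_if(n < 3, "grid must have at least 3 pixels per side")
  cc <- extent_dva * (seq_len(n) - 0.5) / n - extent_dva / 2
  structure(
    list(n = as.integer(n), extent_dva = extent_dva, px_dva = extent_dva / n,
         x = rep(cc, times = n), y = rep(cc, each = n)),
    class = "vf_grid")
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.near_integer <- function(x, tol = 1e-8) abs(x - round(x)) < tol

#' Build the bar traversal sequence of one mapping run
#'
#' A run consists of `n_passes` bar passes (each direction occurring equally
#' often, in a seeded random order), a pause after every pass, and blank
#' periods inserted after a configurable subset of passes. All durations
#' must be integer multiples of the frame duration `dwell_s` (one TR).
#'
#' The bar center steps `step_dva` per frame along the traversal direction,
#' symmetric about fixation, so that the traversal span is
#' `n_positions * step_dva` (aperture diameter plus bar width at the default
#' geometry).
#'
#' @param n_passes Total number of bar passes; must be divisible by the
#'   number of directions.
#' @param directions_deg Traversal directions in degrees (counterclockwise
#'   from rightward).
#' @param n_positions Bar positions (frames) per pass.
#' @param step_dva Bar-center step per frame, dva.
#' @param dwell_s Seconds per bar position (the TR).
#' @param pause_s Pause after every pass, seconds.
#' @param blank_s Duration of each blank period, seconds.
#' @param blank_after Pass indices after which a blank period is inserted
#'   (after that pass's pause). Default: evenly spaced, `n_blanks` blanks.
#' @param n_blanks Number of blank periods when `blank_after` is NULL.
#' @param bar_width_dva Bar width, dva.
#' @param aperture_radius_dva Radius of the circular stimulus aperture, dva.
#' @param extent_dva Side of the square modelled region, dva.
#' @param seed Seed for the random pass order.
#' @return An object of class `bar_sequence`: the per-frame table (`frames`)
#'   plus the geometry/timing parameters.
#' @export
build_bar_sequence <- function(n_passes = 24,
                               directions_deg = seq(0, 315, by = 45),
                               n_positions = 24,
                               step_dva = 0.34,
                               dwell_s = 1.6,
                               pause_s = 4.8,
                               blank_s = 38.4,
                               blank_after = NULL,
                               n_blanks = 4,
                               bar_width_dva = 0.9,
                               aperture_radius_dva = 3.6,
                               extent_dva = 7.2,
                               seed = 1L) {
  .stop_if(n_positions < 1, "n_positions must be >= 1")
  .stop_if(step_dva <= 0, "step_dva must be positive")
  .stop_if(n_passes %% length(directions_deg) != 0,
           "n_passes must divide evenly over the requested directions")
  .stop_if(!.near_integer(pause_s / dwell_s) || !.near_integer(blank_s / dwell_s),
           "pause_s and blank_s must be integer multiples of dwell_s")
  per_dir <- n_passes / length(directions_deg)
  if (is.null(blank_after)) {
    blank_after <- if (n_blanks > 0)
      round(seq_len(n_blanks) * n_passes / n_blanks) else integer(0)
  }
  all_dirs <- rep(directions_deg, each = per_dir)
  pass_dirs <- .with_seed(seed, all_dirs[sample.int(length(all_dirs))])

  n_pause <- round(pause_s / dwell_s)
  n_blank <- round(blank_s / dwell_s)
  rows <- vector("list", n_passes)
  for (p in seq_len(n_passes)) {
    blk <- vector("list", 3)
    blk[[1]] <- data.frame(frame_type = "bar", direction_deg = pass_dirs[p],
                           position_index = seq_len(n_positions) - 1L,
                           pass = p)
    if (n_pause > 0)
      blk[[2]] <- data.frame(frame_type = "pause", direction_deg = NA_real_,
                             position_index = NA_integer_, pass = p)[rep(1, n_pause), ]
    if (p %in% blank_after && n_blank > 0)
      blk[[3]] <- data.frame(frame_type = "blank", direction_deg = NA_real_,
                             position_index = NA_integer_, pass = NA_integer_)[rep(1, n_blank), ]
    rows[[p]] <- do.call(rbind, blk[!vapply(blk, is.null, logical(1))])
  }
  frames <- do.call(rbind, rows)
  rownames(frames) <- NULL
  frames$frame <- seq_len(nrow(frames))
  frames$time_s <- (frames$frame - 1L) * dwell_s
  frames$is_blank <- frames$frame_type == "blank"
  frames <- frames[, c("frame", "time_s", "frame_type", "direction_deg",
                       "position_index", "pass", "is_blank")]
  structure(
    list(frames = frames, n_passes = n_passes, directions_deg = directions_deg,
         n_positions = n_positions, step_dva = step_dva, dwell_s = dwell_s,
         pause_s = pause_s, blank_s = blank_s, blank_after = blank_after,
         bar_width_dva = bar_width_dva,
         aperture_radius_dva = aperture_radius_dva, extent_dva = extent_dva,
         pass_directions = pass_dirs, seed = seed),
    class = "bar_sequence")
}

#' @exportS3Method base::print
print.bar_sequence <- function(x, ...) {
  cat(sprintf(
    "bar_sequence: %d passes (%d directions x %d), %d positions/pass, %d frames, %.1f s\n",
    x$n_passes, length(x$directions_deg), x$n_passes / length(x$directions_deg),
    x$n_positions, nrow(x$frames), nrow(x$frames) * x$dwell_s))
  invisible(x)
}

#' Total run duration in seconds
#' @param seq A `bar_sequence`.
#' @export
run_duration <- function(seq) nrow(seq$frames) * seq$dwell_s

# Bar-center offsets along the traversal axis, symmetric about fixation.
.bar_offsets <- function(seq)
  (seq_len(seq$n_positions) - 1 - (seq$n_positions - 1) / 2) * seq$step_dva

#' Rasterize a bar sequence into a binary design matrix
#'
#' Each bar frame becomes a binary strip of width `bar_width_dva`
#' perpendicular to the traversal direction; a pixel is on when its center
#' lies within half a bar width of the bar center line. Pause and blank
#' frames are all-zero. Optionally, pixels outside the circular aperture are
#' masked out.
#'
#' @param seq A `bar_sequence`.
#' @param grid_n Pixels per side of the square grid (e.g. 31 or 101).
#' @param aperture_mask Apply circular aperture masking (default TRUE).
#' @return An object of class `design_matrix`: sparse binary `masks`
#'   (frames x pixels), the `vf_grid`, `frame_times`, and the frame table.
#' @export
render_design_matrix <- function(seq, grid_n = 101, aperture_mask = TRUE) {
  grid <- vf_grid(grid_n, seq$extent_dva)
  offs <- .bar_offsets(seq)
  fr <- seq$frames
  ii <- integer(0); jj <- integer(0)
  in_ap <- if (aperture_mask)
    (grid$x^2 + grid$y^2) <= seq$aperture_radius_dva^2 else TRUE
  bar_rows <- which(fr$frame_type == "bar")
  for (r in bar_rows) {
    th <- fr$direction_deg[r] * pi / 180
    proj <- grid$x * cos(th) + grid$y * sin(th)
    on <- which(abs(proj - offs[fr$position_index[r] + 1L]) <=
                  seq$bar_width_dva / 2 & in_ap)
    ii <- c(ii, rep.int(r, length(on)))
    jj <- c(jj, on)
  }
  masks <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                                dims = c(nrow(fr), grid_n^2))
  structure(
    list(masks = masks, grid = grid, frame_times = fr$time_s,
         frames = fr, bar_width_dva = seq$bar_width_dva,
         aperture_radius_dva = seq$aperture_radius_dva,
         aperture_mask = aperture_mask),
    class = "design_matrix")
}

#' @exportS3Method base::print
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d frames on a %dx%d grid (%.1f dva), %d bar frames\n",
              nrow(x$masks), x$grid$n, x$grid$n, x$grid$extent_dva,
              sum(x$frames$frame_type == "bar")))
  invisible(x)
}

#' Double-gamma hemodynamic response function
#'
#' Canonical two-gamma HRF sampled at `dt_s` and normalized to unit sum.
#' Each gamma component is parameterized by its mode (`*_delay_s`) and
#' dispersion; the undershoot is subtracted scaled by `1/ratio`.
#'
#' @param dt_s Sampling interval in seconds (one TR for convolution with a
#'   design matrix).
#' @param peak_delay_s Time-to-peak of the positive lobe, seconds.
#' @param undershoot_delay_s Time-to-trough of the undershoot, seconds.
#' @param dispersion_1,dispersion_2 Dispersions (width scale) of the two
#'   gamma components, seconds.
#' @param ratio Peak:undershoot amplitude ratio.
#' @param length_s Kernel length, seconds (>= 20).
#' @return An object of class `hrf_kernel` with `dt_s`, unit-sum `weights`
#'   and the parameter list.
#' @export
hrf_double_gamma <- function(dt_s, peak_delay_s = 6, undershoot_delay_s = 16,
                             dispersion_1 = 1, dispersion_2 = 1,
                             ratio = 6, length_s = 32) {
  .stop_if(dt_s <= 0, "dt_s must be positive")
  .stop_if(peak_delay_s <= 0 || undershoot_delay_s <= 0,
           "delays must be positive")
  .stop_if(dispersion_1 <= 0 || dispersion_2 <= 0,
           "dispersions must be positive")
  .stop_if(length_s < 20, "kernel length must be at least 20 s")
  t <- seq(0, length_s, by = dt_s)
  h <- dgamma(t, shape = peak_delay_s / dispersion_1 + 1, rate = 1 / dispersion_1) -
    dgamma(t, shape = undershoot_delay_s / dispersion_2 + 1, rate = 1 / dispersion_2) / ratio
  structure(
    list(dt_s = dt_s, weights = h / sum(h),
         params = list(peak_delay_s = peak_delay_s,
                       undershoot_delay_s = undershoot_delay_s,
                       dispersion_1 = dispersion_1, dispersion_2 = dispersion_2,
                       ratio = ratio, length_s = length_s)),
    class = "hrf_kernel")
}

# Causal FIR convolution of each column of X with kernel w, truncated to
# nrow(X) samples (zero initial conditions).
.causal_conv <- function(X, w) {
  X <- as.matrix(X)
  k <- length(w)
  Xp <- rbind(matrix(0, k - 1, ncol(X)), X)
  out <- stats::filter(Xp, w, method = "convolution", sides = 1)
  out <- out[(k - 1) + seq_len(nrow(X)), , drop = FALSE]
  dimnames(out) <- NULL
  matrix(out, nrow = nrow(X))
}

#' Convolve a design matrix with an HRF
#'
#' Produces the per-pixel predicted regressor stack: each pixel's binary
#' stimulation time course convolved causally with the HRF and truncated to
#' the number of frames.
#'
#' @param dm A `design_matrix`.
#' @param hrf An `hrf_kernel` sampled at the frame interval.
#' @param dense If TRUE (default) the dense convolved regressor matrix `W`
#'   is materialized (needed by the ridge back-projection); the sparse
#'   masks and kernel are kept either way, and by linearity
#'   `W %*% g == conv(masks %*% g)`, which the nonlinear fits exploit.
#' @return An object of class `regressor_stack`: dense matrix `W`
#'   (frames x pixels, or NULL), the sparse `masks`, `hrf_weights` and the
#'   grid.
#' @export
convolve_design <- function(dm, hrf, dense = TRUE) {
  dt <- if (nrow(dm$masks) > 1) diff(dm$frame_times[1:2]) else hrf$dt_s
  .stop_if(abs(hrf$dt_s - dt) > 1e-9,
           "HRF sampling interval does not match the frame interval")
  W <- if (dense) .causal_conv(as.matrix(dm$masks), hrf$weights) else NULL
  structure(list(W = W, masks = dm$masks, hrf_weights = hrf$weights,
                 grid = dm$grid, frame_times = dm$frame_times),
            class = "regressor_stack")
}

#' Unique bar stimulus frames of a design
#'
#' Returns one mask per geometrically unique bar stimulus, with weights
#' counting how many unique (direction, position) bar stimuli it
#' represents. Opposite traversal directions produce identical masks in
#' reversed position order (the traversal is symmetric about fixation), so
#' the default 24 positions x 8 directions = 192 unique bar stimuli reduce
#' to 96 masks of weight 2. Averages weighted this way are identical to
#' averages over all 192 stimuli, each contributing once.
#'
#' @param dm A `design_matrix`.
#' @return List with `masks` (sparse, unique-masks x pixels), `wts`
#'   (stimulus multiplicity per mask), `info` data.frame (canonical
#'   direction_deg, position_index) and the grid.
#' @export
unique_bar_frames <- function(dm) {
  fr <- dm$frames
  bar <- which(fr$frame_type == "bar")
  n_pos <- max(fr$position_index[bar]) + 1L
  dir <- fr$direction_deg[bar] %% 360
  pos <- fr$position_index[bar]
  cdir <- dir %% 180
  cpos <- ifelse(dir >= 180, n_pos - 1L - pos, pos)
  key <- paste(cdir, cpos)
  # weight = number of distinct (direction, position) stimuli per mask
  stim_key <- paste(dir, pos)
  uniq_stim <- !duplicated(stim_key)
  mult <- table(key[uniq_stim])
  first <- bar[!duplicated(key)]
  ckey <- key[!duplicated(key)]
  list(masks = dm$masks[first, , drop = FALSE],
       wts = as.numeric(mult[ckey]),
       info = data.frame(direction_deg = cdir[!duplicated(key)],
                         position_index = cpos[!duplicated(key)],
                         key = ckey),
       grid = dm$grid)
}

#' Write a design matrix's masks in MatrixMarket format
#'
#' Sparse text serialization of the binary frame masks (one row per frame,
#' one column per pixel), readable by [Matrix::readMM()] and by any
#' MatrixMarket-aware tool.
#'
#' @param dm A `design_matrix`.
#' @param path Output path (conventionally `.mtx`).
#' @export
write_design_matrix <- function(dm, path) {
  Matrix::writeMM(dm$masks, path)
  invisible(path)
}

#' Write the per-frame table of a bar sequence as TSV
#' @param seq A `bar_sequence`.
#' @param path Output path.
#' @export
write_frame_table <- function(seq, path) {
  fr <- seq$frames[, c("frame", "time_s", "direction_deg", "position_index",
                       "is_blank")]
  write.table(fr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
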