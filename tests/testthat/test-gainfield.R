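test_that("Gaussian division inverts the Gaussian product analytically", {
  set.seed(1)
  for (i in 1:25) {
    sd0 <- list(center = runif(2, -3, 3), sigma = runif(1, 0.2, 1.5))
    sf <- runif(1, 1.6, 2.5)
    meas <- gaussian_product(sd0, list(center = c(0, 0), sigma = sf))
    back <- estimate_stimulus_drive(list(x = meas$center[1],
                                         y = meas$center[2],
                                         sigma = meas$sigma), sf)
    expect_lt(max(abs(back$center - sd0$center)), 1e-9)
    expect_lt(abs(back$sigma - sd0$sigma), 1e-9)
  }
  # worked example
  b <- estimate_stimulus_drive(list(x = 1.6, y = 0, sigma = sqrt(4 / 5)), 2)
  expect_lt(max(abs(b$center - c(2, 0))), 1e-9)
  expect_lt(abs(b$sigma - 1), 1e-9)
  # boundary: measured size not smaller than the gain field
  flag <- estimate_stimulus_drive(list(x = 1, y = 0, sigma = 2), 2)
  expect_false(flag$invertible)
  expect_true(is.na(flag$sigma))
})

test_that("position prediction respects symmetry and the flat-gain limit", {
  d <- default_designs()
  p0 <- predict_attend_stimulus_position(
    list(center = c(0, 0), sigma = 0.5), 1.0, dm = d$dm101)
  px <- d$dm101$grid$px_dva
  expect_lt(sqrt(sum(p0^2)), px * sqrt(2) + 1e-12)
  # a very wide kernel leaves the stimulus drive in place
  pf <- predict_attend_stimulus_position(
    list(center = c(1.8, -0.9), sigma = 0.6), 60, dm = d$dm101)
  expect_lt(abs(pf["x"] - 1.8), px + 1e-12)
  expect_lt(abs(pf["y"] + 0.9), px + 1e-12)
})

test_that("prediction agrees with a dense independent oracle at 201x201", {
  # independent re-evaluation of the averaged normalized product profile
  # with plain dense R operations on a finer grid
  d <- default_designs()
  seq <- d$seq
  dm201 <- render_design_matrix(seq, 201)
  grid <- dm201$grid
  n <- grid$n
  fr <- dm201$frames
  bar <- which(fr$frame_type == "bar")
  key <- paste(fr$direction_deg[bar], fr$position_index[bar])
  first <- bar[!duplicated(key)]
  cc <- grid$x[seq_len(n)]
  sk <- 1.0
  K <- exp(-outer(cc, cc, "-")^2 / (2 * sk^2))
  oracle_predict <- function(x0, y0, s0) {
    g <- exp(-((grid$x - x0)^2 + (grid$y - y0)^2) / (2 * s0^2))
    acc <- 0
    for (f in first) {
      m <- matrix(as.numeric(dm201$masks[f, ]), n, n)
      sm <- K %*% m %*% K               # separable smoothing, zero padding
      pr <- g * as.vector(sm)
      acc <- acc + pr / max(pr)
    }
    ix <- which.max(acc)
    c(grid$x[ix], grid$y[ix])
  }
  sds <- data.frame(x = c(2, 1.2, 0.6), y = c(0, 0.8, -1.5),
                    sigma = c(1, 0.5, 0.4))
  p101 <- predict_attend_stimulus_position(sds, sk, dm = d$dm101)
  coarse_px <- 7.2 / 31
  for (i in seq_len(nrow(sds))) {
    p201 <- oracle_predict(sds$x[i], sds$y[i], sds$sigma[i])
    expect_lt(sqrt(sum((p101[i, ] - p201)^2)), coarse_px)
  }
  # the worked case: a peripheral SD is pulled toward the fovea
  expect_lt(abs(p101[1, 1]), 2)
})

test_that("narrower static gain fields pull more; the traveling average vanishes in the flat-gain limit", {
  # Gaussian-multiplication property: for a static gain field at fixation,
  # shrinking its size strictly increases the foveal pull
  pulls <- vapply(c(0.6, 1.0, 1.5, 2.5), function(s) {
    g <- gaussian_product(list(center = c(2.6, 0), sigma = 0.8),
                          list(center = c(0, 0), sigma = s))
    2.6 - g$center[1]
  }, 0)
  expect_true(all(diff(pulls) < 0))
  expect_true(all(pulls > 0))
  # the traveling-average prediction still pulls peripheral pRFs inward
  # for every kernel in the search range, and the pull disappears as the
  # kernel flattens
  d <- default_designs()
  sd0 <- list(center = c(2.6, 0), sigma = 0.8)
  shifts <- vapply(c(0.6, 1.0, 1.5), function(k) {
    p <- predict_attend_stimulus_position(sd0, k, dm = d$dm101)
    2.6 - p[["x"]]
  }, 0)
  expect_true(all(shifts > 0))
  p_flat <- predict_attend_stimulus_position(sd0, 60, dm = d$dm101)
  expect_lt(2.6 - p_flat[["x"]], d$dm101$grid$px_dva + 1e-12)
})

test_that("quadrant binning produces weighted vectors and reports empties", {
  set.seed(2)
  n <- 4000
  rec <- data.frame(voxel_id = 1:n,
                    start_x = runif(n, 0, 3.3), start_y = runif(n, 0, 3.3),
                    start_sigma = runif(n, 0.3, 0.9),
                    end_x = runif(n, 0, 3.3), end_y = runif(n, 0, 3.3),
                    w = 1)
  vecs <- bin_shift_vectors_quadrant(rec)
  expect_equal(nrow(vecs), 64)
  expect_equal(attr(vecs, "n_empty"), 0)
  # all voxels in one bin -> a single vector
  rec1 <- rec[1:5, ]
  rec1$start_x <- 0.1; rec1$start_y <- 0.1
  expect_equal(nrow(bin_shift_vectors_quadrant(rec1)), 1)
  # two voxels, uniform weights: the bin vector is their midpoint pair
  rec2 <- data.frame(voxel_id = 1:2, start_x = c(0.1, 0.3),
                     start_y = c(0.2, 0.1), start_sigma = 0.5,
                     end_x = c(1, 2), end_y = c(0.5, 0.7), w = 1)
  v2 <- bin_shift_vectors_quadrant(rec2)
  expect_equal(v2$start_x, 0.2)
  expect_equal(v2$end_x, 1.5)
  expect_equal(v2$n, 2)
})

test_that("grid-search conventions match the stated spacing and tie rule", {
  v <- attnprf:::.af_grid_values(c(0.6, 1.6), 50)
  expect_equal(diff(v)[1], 0.02)
  expect_equal(v[1], 0.6)
  expect_equal(v[50], 1.58)
  ve <- attnprf:::.af_grid_values(c(0.6, 1.6), 50, endpoint = TRUE)
  expect_equal(ve[50], 1.6)
})

test_that("a reduced grid fit is exactly self-consistent on binned vectors", {
  d <- default_designs()
  vox <- sample_ground_truth_voxels(150, seed = 21)
  fx <- fixation_truth(vox, 2.0)
  rec <- data.frame(voxel_id = vox$voxel_id,
                    start_x = abs(fx[, 1]), start_y = abs(fx[, 2]),
                    start_sigma = fx[, 3], end_x = 0, end_y = 0, w = 1)
  class(rec) <- c("shift_records", "data.frame")
  vecs <- bin_shift_vectors_quadrant(rec)
  sm <- smooth_bar_frames(d$ub, 1.0)
  ends <- t(vapply(seq_len(nrow(vecs)), function(b) {
    sd1 <- estimate_stimulus_drive(list(x = vecs$start_x[b],
                                        y = vecs$start_y[b],
                                        sigma = vecs$start_sigma[b]), 2.0)
    predict_attend_stimulus_position(sd1, 1.0, smoothed = sm)
  }, numeric(2)))
  vecs$end_x <- ends[, 1]
  vecs$end_y <- ends[, 2]
  # reduced 9 x 9 grid that contains the generative cell (2.0, 1.0)
  gf <- fit_af_sizes(vecs, d$dm101, fix_range = c(1.92, 2.1),
                     stim_range = c(0.92, 1.1), grid_n = 9)
  expect_equal(gf$sigma_fix, 2.0)
  expect_equal(gf$sigma_stim_kernel, 1.0)
  expect_equal(gf$objective, 0)
  # global-minimum property on the evaluated surface
  expect_true(all(gf$surface >= gf$objective))
  expect_equal(gf$effective_stim_size, 1.9)
})

test_that("model-derived eccentricity profiles are internally consistent", {
  d <- default_designs()
  vox <- sample_ground_truth_voxels(120, ecc_range = c(0.3, 3.3), seed = 5)
  prof <- condition_shift_profiles(vox[, c("x", "y", "sigma")],
                                   list(sigma_fix = 2.0,
                                        sigma_stim_kernel = 0.8),
                                   d$dm101)
  expect_equal(prof$d_ecc_diff, prof$d_ecc_diff_direct, tolerance = 1e-6)
  # both attention sources pull peripheral pRFs toward the fovea
  expect_lt(prof$d_ecc_fix[4], 0)
  expect_lt(prof$d_ecc_stim[4], 0)
  # static stimulus field of equal size: the difference profile vanishes
  prof0 <- condition_shift_profiles(vox[, c("x", "y", "sigma")],
                                    list(sigma_fix = 1.8,
                                         sigma_stim_kernel = 1.8),
                                    d$dm101, stim_static = TRUE)
  expect_equal(max(abs(prof0$d_ecc_diff)), 0)
})
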