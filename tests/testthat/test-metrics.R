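test_that("quadrant mirroring uses the Attend Fixation signs", {
  m <- mirror_to_quadrant(data.frame(x = -1, y = 2),
                          data.frame(x = -1.5, y = 2.5))
  expect_equal(unlist(m$fix), c(x = 1, y = 2))
  expect_equal(unlist(m[[2]]), c(x = 1.5, y = 2.5))
  # cross-meridian positions keep their relative sign
  m2 <- mirror_to_quadrant(data.frame(x = 1, y = -1),
                           data.frame(x = 1.2, y = 0.1))
  expect_equal(unlist(m2$fix), c(x = 1, y = 1))
  expect_equal(unlist(m2[[2]]), c(x = 1.2, y = -0.1))
  # zero coordinates count as positive
  m3 <- mirror_to_quadrant(data.frame(x = 0, y = 2))
  expect_equal(unlist(m3$fix), c(x = 0, y = 2))
})

make_records <- function(start, end, r2 = 1) {
  fits <- rbind(
    data.frame(voxel_id = seq_len(nrow(start)), condition = "AttendFixation",
               x = start[, 1], y = start[, 2], sigma = 0.5, r2 = r2),
    data.frame(voxel_id = seq_len(nrow(start)), condition = "AttendStimulus",
               x = end[, 1], y = end[, 2], sigma = 0.5, r2 = r2))
  shift_records(fits, "AttendStimulus")
}

test_that("shift decomposition reproduces hand-computed ratios", {
  # pure radial inward shift
  r1 <- make_records(cbind(1.5, 1.5), cbind(1, 1))
  expect_equal(abs(r1$d_ecc) / r1$L, 1, tolerance = 1e-12)
  expect_equal(abs(r1$dx) / r1$L, sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(abs(r1$dy) / r1$L, sqrt(2) / 2, tolerance = 1e-12)
  # pure horizontal shift on the horizontal meridian
  r2 <- make_records(cbind(2, 0), cbind(1.4, 0))
  expect_equal(abs(r2$d_ecc) / r2$L, 1)
  expect_equal(abs(r2$dy) / r2$L, 0)
  # pure vertical shift off the meridian: tiny eccentricity component
  r3 <- make_records(cbind(2, 0), cbind(2, 0.2))
  expect_equal(abs(r3$dy) / r3$L, 1)
  expect_equal(abs(r3$d_ecc) / r3$L, abs(sqrt(4.04) - 2) / 0.2,
               tolerance = 1e-9)
  # record invariants on a random population
  set.seed(3)
  rr <- make_records(matrix(runif(100, 0, 3), 50), matrix(runif(100, 0, 3), 50))
  expect_true(all(abs(rr$d_ecc) <= rr$L + 1e-12))
  expect_true(all(abs(rr$dx^2 + rr$dy^2 - rr$L^2) < 1e-12))
  expect_true(all(rr$start_x >= 0 & rr$start_y >= 0))
  dec <- decompose_shift_directions(rr, n_boot = 500, seed = 1)
  expect_true(all(dec$ratios$estimate >= 0 & dec$ratios$estimate <= 1))
  expect_error(decompose_shift_directions(make_records(cbind(1, 1),
                                                       cbind(1, 1))),
               "zero")
})

test_that("polar-angle binning separates radial from axis-aligned shifts", {
  set.seed(5)
  n <- 600
  th <- runif(n, 0.01, pi / 2 - 0.01)
  ecc <- runif(n, 1, 3)
  start <- cbind(ecc * cos(th), ecc * sin(th))
  # pure radial inward shifts
  endr <- start * 0.8
  pr <- polar_angle_slope_analysis(make_records(start, endr), n_boot = 400,
                                   seed = 2)
  expect_lt(pr$bins$dx[1], pr$bins$dx[3])       # dx most negative at 0 deg
  expect_lt(pr$bins$dy[3], pr$bins$dy[1])       # dy most negative at 90 deg
  expect_lt(diff(range(pr$bins$d_ecc)), 0.25 * max(abs(pr$bins$d_ecc)))
  expect_gt(pr$contrast, 0)
  expect_lt(pr$p, 0.05)
  # pure horizontal shifts: dx flat over polar angle
  endh <- cbind(start[, 1] - 0.3, start[, 2])
  ph <- polar_angle_slope_analysis(make_records(start, endh), n_boot = 400,
                                   seed = 2)
  expect_lt(diff(range(ph$bins$dx)), 0.05)
  # x/y-symmetric shift field (noisy diagonal translation): dx and dy are
  # angle-independent in expectation, so the contrast is compatible with 0
  th2 <- c(th, pi / 2 - th)
  start2 <- cbind(2 * cos(th2), 2 * sin(th2))
  end2 <- start2 - 0.1 + matrix(rnorm(4 * length(th), 0, 0.02),
                                ncol = 2)
  ps <- polar_angle_slope_analysis(make_records(start2, end2), n_boot = 400,
                                   seed = 2)
  expect_lt(abs(ps$contrast), 0.02)
  expect_gt(ps$p, 0.05)
  expect_error(polar_angle_slope_analysis(make_records(cbind(2, 0.01),
                                                       cbind(1, 0.01))),
               "empty")
})

make_cond_fits <- function(fix_xy, fix_sigma, delta, r2 = 1) {
  # delta: list of per-condition (dx, dy, dsigma) offsets from fixation
  n <- nrow(fix_xy)
  rows <- lapply(names(delta), function(cc) {
    d <- delta[[cc]]
    data.frame(voxel_id = seq_len(n), condition = cc,
               x = fix_xy[, 1] + d[, 1], y = fix_xy[, 2] + d[, 2],
               sigma = fix_sigma + d[, 3], r2 = r2)
  })
  out <- do.call(rbind, c(list(
    data.frame(voxel_id = seq_len(n), condition = "AttendFixation",
               x = fix_xy[, 1], y = fix_xy[, 2], sigma = fix_sigma,
               r2 = r2)), rows))
  out$ecc <- sqrt(out$x^2 + out$y^2)
  class(out) <- c("prf_fits", "data.frame")
  out
}

test_that("eccentricity/size change analysis recovers a built-in coupling", {
  set.seed(8)
  n <- 200
  th <- runif(n, 0, pi / 2)
  ecc <- runif(n, 0.2, 3.2)
  fix <- cbind(ecc * cos(th), ecc * sin(th))
  # construct Delta size = 2 * Delta ecc exactly (radial shifts)
  d_ecc <- 0.1 * (1.5 - ecc)
  shift <- cbind((ecc + d_ecc) / ecc * fix[, 1] - fix[, 1],
                 (ecc + d_ecc) / ecc * fix[, 2] - fix[, 2])
  fits <- make_cond_fits(fix, 0.5, list(
    AttendStimulus = cbind(shift, 2 * d_ecc)))
  res <- ecc_size_change_analysis(fits, n_boot = 300, seed = 1)
  expect_true(res$correlation$defined)
  expect_gt(res$correlation$r, 0.999)
  # profile reflects the constructed sign change over eccentricity
  expect_gt(res$profile$d_ecc[1], 0)
  expect_lt(res$profile$d_ecc[4], 0)
  # identical conditions: zero changes, correlation flagged undefined
  fits0 <- make_cond_fits(fix, 0.5, list(
    AttendStimulus = cbind(0 * shift, 0 * d_ecc)))
  res0 <- suppressWarnings(ecc_size_change_analysis(fits0, n_boot = 100,
                                                    seed = 1))
  expect_false(res0$correlation$defined)
  expect_true(all(abs(res0$profile$d_ecc) < 1e-12))
})

test_that("feature AMI follows its defining contrast", {
  set.seed(9)
  n <- 60
  fix <- cbind(runif(n, 0.8, 3), runif(n, 0.2, 2))
  base_de <- rnorm(n, 0, 0.05)
  base_ds <- rnorm(n, 0, 0.03)
  radial <- function(k) {
    ecc <- sqrt(rowSums(fix^2))
    cbind((ecc + k * base_de) / ecc * fix[, 1] - fix[, 1],
          (ecc + k * base_de) / ecc * fix[, 2] - fix[, 2], k * base_ds)
  }
  # color changes exactly twice the TF changes -> feature AMI = 1/3
  fits <- make_cond_fits(fix, 0.5, list(AttendColor = radial(2),
                                        AttendTF = radial(1),
                                        AttendStimulus = radial(1.5)))
  ami <- compute_feature_ami(fits)
  expect_equal(ami$feature_ami, rep(1 / 3, n), tolerance = 1e-9)
  # equal changes -> 0
  fits0 <- make_cond_fits(fix, 0.5, list(AttendColor = radial(1),
                                         AttendTF = radial(1),
                                         AttendStimulus = radial(1)))
  expect_equal(compute_feature_ami(fits0)$feature_ami, rep(0, n),
               tolerance = 1e-12)
  # zero color change -> -1
  fits1 <- make_cond_fits(fix, 0.5, list(AttendColor = radial(0),
                                         AttendTF = radial(1),
                                         AttendStimulus = radial(0.5)))
  expect_equal(compute_feature_ami(fits1)$feature_ami, rep(-1, n),
               tolerance = 1e-12)
  # antisymmetry under swapping the conditions
  fits_sw <- make_cond_fits(fix, 0.5, list(AttendColor = radial(1),
                                           AttendTF = radial(2),
                                           AttendStimulus = radial(1.5)))
  expect_equal(compute_feature_ami(fits_sw)$feature_ami,
               -ami$feature_ami, tolerance = 1e-9)
})

test_that("feature preference index is the signed amplitude contrast", {
  expect_equal(feature_preference_index(1, 1), 0)
  expect_equal(feature_preference_index(1, 0), 1)
  expect_equal(feature_preference_index(0.2, 0.6), -0.5)
  expect_true(is.na(feature_preference_index(0, 0)))
  expect_equal(feature_preference_index(c(1, 0.2), c(0, 0.6)), c(1, -0.5))
})
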