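test_that("ground-truth sampler honors the size-eccentricity relation", {
  v0 <- sample_ground_truth_voxels(50, size_slope = 0, size_jitter_sd = 0,
                                   size_intercept = 0.4, seed = 1)
  expect_true(all(v0$sigma == 0.4))
  # OLS on a large sample recovers the generative slope within 5%
  v <- sample_ground_truth_voxels(1000, ecc_range = c(0, 3.3),
                                  size_intercept = 0.25, size_slope = 0.2,
                                  seed = 2)
  sl <- coef(lm(sigma ~ ecc, data = v))[2]
  expect_lt(abs(sl - 0.2) / 0.2, 0.05)
  # determinism and bounds
  expect_identical(sample_ground_truth_voxels(20, seed = 9),
                   sample_ground_truth_voxels(20, seed = 9))
  expect_true(all(v$ecc <= 3.3 & v$sigma > 0))
  expect_error(sample_ground_truth_voxels(10, ecc_range = c(2, 2)), "empty")
})

test_that("polar-angle bias concentrates centers on the horizontal meridian", {
  v <- sample_ground_truth_voxels(2000, polar_angle_kappa = 1, seed = 5)
  ax <- 2 * v$polar_angle                 # axial doubling
  expect_lt(rayleigh_test(ax)$p, 1e-6)
  expect_gt(mean(cos(ax)), 0.2)           # concentration toward 0/180 deg
})

test_that("gaussian product matches the closed form and its limits", {
  g <- gaussian_product(list(center = c(2, 0), sigma = 1),
                        list(center = c(0, 0), sigma = 2))
  expect_lt(max(abs(g$center - c(1.6, 0))), 1e-9)
  expect_lt(abs(g$sigma - sqrt(4 / 5)), 1e-9)
  # flat-gain limit
  gf <- gaussian_product(list(center = c(1, -1), sigma = 0.7),
                         list(center = c(5, 5), sigma = Inf))
  expect_equal(gf$center, c(1, -1))
  expect_equal(gf$sigma, 0.7)
  # identical centers: sigma / sqrt(2)
  gs <- gaussian_product(list(center = c(1, 1), sigma = 0.8),
                         list(center = c(1, 1), sigma = 0.8))
  expect_lt(abs(gs$sigma - 0.8 / sqrt(2)), 1e-12)
  expect_equal(gs$center, c(1, 1))
})

test_that("generative BOLD is linear in amplitude and seed-reproducible", {
  d <- default_designs()
  af <- af_spec()
  v1 <- list(x = 1, y = 0.5, sigma = 0.5, amplitude = 1, baseline = 0)
  v2 <- list(x = 1, y = 0.5, sigma = 0.5, amplitude = 2, baseline = 0)
  t1 <- generate_bold_timeseries(v1, d$dm101, "AttendFixation", af, d$hrf)
  t2 <- generate_bold_timeseries(v2, d$dm101, "AttendFixation", af, d$hrf)
  expect_equal(t2$values, 2 * t1$values, tolerance = 1e-12)
  n1 <- generate_bold_timeseries(v1, d$dm101, "AttendColor", af, d$hrf,
                                 noise_sd = 0.3, seed = 4)
  n2 <- generate_bold_timeseries(v1, d$dm101, "AttendColor", af, d$hrf,
                                 noise_sd = 0.3, seed = 4)
  expect_identical(n1$values, n2$values)
  expect_error(generate_bold_timeseries(v1, d$dm101, "AttendBar", af, d$hrf),
               "condition")
})

test_that("noiseless fixation data are refit exactly as the SD x AF product", {
  d <- default_designs()
  af <- af_spec()
  vox <- list(x = 1.5, y = 0.5, sigma = 0.6, amplitude = 1, baseline = 0.2)
  ts <- vapply(c("AttendFixation", "AttendColor", "AttendTF"), function(cc)
    generate_bold_timeseries(vox, d$dm101, cc, af, d$hrf)$values,
    numeric(nrow(d$dm101$masks)))
  init <- ridge_init(ts, d$reg31)
  jf <- fit_prf_joint(ts, d$reg101, c(init$x, init$y))
  cf <- fit_prf_per_condition(ts, d$reg101, jf)
  tru <- gaussian_product(list(center = c(1.5, 0.5), sigma = 0.6),
                          list(center = c(0, 0), sigma = af$sigma_fix))
  fx <- cf$params[cf$params$condition == "AttendFixation", ]
  expect_lt(abs(fx$x - tru$center[1]), 0.01)
  expect_lt(abs(fx$y - tru$center[2]), 0.01)
  expect_lt(abs(fx$sigma - tru$sigma) / tru$sigma, 0.01)
  expect_lt(abs(cf$baseline - 0.2), 0.01)
  expect_gt(cf$r2, 1 - 1e-6)
})

test_that("attend-bar pRFs of peripheral voxels are pulled toward the fovea", {
  d <- default_designs()
  af <- af_spec()
  for (ex in c(2.3, 2.9)) {
    vox <- list(x = ex, y = 0.6, sigma = 0.25 + 0.2 * sqrt(ex^2 + 0.36),
                amplitude = 1, baseline = 0)
    ts <- vapply(c("AttendFixation", "AttendColor", "AttendTF"), function(cc)
      generate_bold_timeseries(vox, d$dm101, cc, af, d$hrf)$values,
      numeric(nrow(d$dm101$masks)))
    init <- ridge_init(ts, d$reg31)
    cf <- fit_prf_per_condition(ts, d$reg101,
                                fit_prf_joint(ts, d$reg101, c(init$x, init$y)))
    st <- cf$params[cf$params$condition == "AttendStimulus", ]
    expect_lt(st$ecc, sqrt(ex^2 + 0.36))
  }
})

test_that("staircase drives a matched observer to the target accuracy", {
  # flat observer -> chance
  flat <- simulate_staircase_observer(true_threshold = Inf, n_trials = 600,
                                      seed = 2)
  expect_lt(abs(mean(flat$trials$correct) - 0.5), 0.06)
  # standard observer: asymptotic accuracy ~ 83% over the final 500 trials
  sc <- simulate_staircase_observer(true_threshold = 0.3, n_trials = 1000,
                                    target_p = 0.83, seed = 1)
  late <- tail(sc$trials$correct, 500)
  expect_lt(abs(mean(late) - 0.83), 0.03)
  # ML refit of the trial table recovers the true threshold within 10%
  th <- fit_staircase_threshold(sc$trials)
  expect_lt(abs(th - 0.3) / 0.3, 0.1)
  expect_identical(
    simulate_staircase_observer(n_trials = 50, seed = 7)$trials,
    simulate_staircase_observer(n_trials = 50, seed = 7)$trials)
  expect_error(simulate_staircase_observer(target_p = 0.4), "target_p")
})

test_that("gaze generator constructs blinks and spikes as flagged events", {
  g0 <- generate_gaze_trace(10, rate_hz = 100, fixation = c(0.2, -0.1),
                            fixation_noise_sd = 0, pupil_noise_sd = 0)
  expect_true(all(g0$x == 0.2) && all(g0$y == -0.1))
  gb <- generate_gaze_trace(10, rate_hz = 100,
                            blinks = data.frame(onset_s = 2, duration_s = 0.2),
                            seed = 1)
  expect_equal(sum(!gb$valid), 20)
  expect_true(all(is.na(gb$x[!gb$valid])))
  expect_warning(
    generate_gaze_trace(10, rate_hz = 100,
                        blinks = data.frame(onset_s = c(2, 2.1),
                                            duration_s = c(0.3, 0.3))),
    "merged")
  # spike acceleration exceeds the rejection threshold (finite differences)
  gs <- generate_gaze_trace(10, rate_hz = 100, fixation_noise_sd = 0,
                            pupil_noise_sd = 0,
                            spikes = data.frame(time_s = 5, amplitude = 25,
                                                width_s = 0.02))
  acc <- diff(gs$pupil, differences = 2) * 100^2
  expect_gt(max(abs(acc)), 1e5)
})
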