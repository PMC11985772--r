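test_that("identical seed gives bit-identical sessions", {
  cfg <- sim_config(seed = 11, n_sprints = 2)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$streams, b$streams)
  expect_identical(a$decel_trials[[1]]$gyro, b$decel_trials[[1]]$gyro)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("invalid configuration errors name the offending field", {
  expect_error(sim_config(wheel_radius_m = -1), "wheel_radius_m")
  expect_error(sim_config(sample_rate_hz = 0), "sample_rate_hz")
  expect_error(sim_config(asymmetry_gain = 0.9), "asymmetry_gain")
  expect_error(sim_config(fatigue_decay = 0), "fatigue_decay")
  expect_error(sim_config(n_sprints = 0), "n_sprints")
})

test_that("session honours the sprint-protocol structure", {
  ses <- generate_session(sim_config(seed = 3, n_sprints = 6, recovery_s = 20))
  expect_length(ses$streams, 6)
  expect_named(ses$streams[[1]], c("left_wheel", "right_wheel", "frame", "trunk"))
  expect_length(ses$decel_trials, 2)
  # all streams of one sprint share the time base
  t0 <- ses$streams[[1]]$left_wheel$t
  for (s in ses$streams[[1]]) expect_equal(s$t, t0)
})

test_that("velocity_to_gyro implements the construction formula", {
  geom0 <- wheel_geometry(0.3, 0, "left")
  expect_equal(velocity_to_gyro(rep(2, 10), geom0, 0, 0),
               rep(2 / 0.3, 10), tolerance = 1e-12)
  geom <- wheel_geometry(0.3, 0.314, "left")
  expect_equal(velocity_to_gyro(rep(2, 10), geom, 0.5, 0),
               rep(2 / 0.3 + 0.5 * sin(0.314), 10), tolerance = 1e-12)
  expect_error(velocity_to_gyro(rep(2, 10), geom, rep(0.5, 9), 0), "length")
  # reproducible with a fixed seed
  g1 <- velocity_to_gyro(rep(2, 50), geom, 0, noise_sd = 0.05, seed = 9)
  g2 <- velocity_to_gyro(rep(2, 50), geom, 0, noise_sd = 0.05, seed = 9)
  expect_identical(g1, g2)
})

test_that("coast-down trial follows the closed-form deceleration", {
  sys <- system_properties(mt = 85, mu_r = 0, CdA = 0)
  geom <- wheel_geometry(0.3)
  tr <- generate_decel_trial(0.012, 0, sys, v_push = 2.5, geometry = geom)
  v <- abs(tr$gyro[, 3]) * 0.3
  sel <- tr$t > tr$meta$push_end_t + 0.1 & tr$t < tr$meta$stop_t - 0.1
  slope <- unname(coef(lm(v[sel] ~ tr$t[sel]))[2])
  expect_equal(slope, -0.012 * 9.81, tolerance = 1e-6)
  # zero-resistance case: constant velocity during coast
  tr0 <- generate_decel_trial(0, 0, sys, v_push = 2.5, geometry = geom)
  v0 <- abs(tr0$gyro[, 3]) * 0.3
  sel0 <- tr0$t > tr0$meta$push_end_t & tr0$t < tr0$meta$stop_t
  expect_lt(diff(range(v0[sel0])), 1e-9)
  expect_error(generate_decel_trial(0.012, 0, sys, v_push = -1, geometry = geom),
               "v_push")
})

test_that("trunk stream encodes unit quaternions with known per-cycle range", {
  ct <- seq(2, 8, by = 0.5)
  st <- generate_trunk_stream(ct, amplitude_deg = 13.05, baseline_deg = 0,
                              sample_rate = 128)
  expect_true(all(abs(sqrt(rowSums(st$quat^2)) - 1) < 1e-12))
  expect_equal(st$meta$trm_true_deg, 26.1)
  # amplitude 0: constant quaternion stream
  st0 <- generate_trunk_stream(ct, 0, 5, 128)
  expect_equal(max(st0$quat[, 1]) - min(st0$quat[, 1]), 0)
  expect_equal(st0$meta$trm_true_deg, 0)
})

test_that("ground-truth ISI matches the analytic gain closed form", {
  # constant-ratio gain asymmetry, no noise, no wobble, no start enhancement
  g <- 1.2
  cfg <- sim_config(seed = 5, n_sprints = 1, asymmetry_gain = g,
                    start_asym_boost = 1, noise_sd_gyro = 0,
                    yaw_oscillation_amp = 0)
  ses <- generate_session(cfg)
  isi <- ses$ground_truth$sprints[[1]]$isi
  for (w in c("start", "middle", "end", "overall")) {
    expect_equal(isi[[w]], (g - 1) / (g + 1), tolerance = 1e-10)
  }
  # symmetric chair: ISI identically zero
  cfg0 <- sim_config(seed = 5, n_sprints = 1, asymmetry_gain = 1,
                     start_asym_boost = 1, noise_sd_gyro = 0)
  isi0 <- generate_session(cfg0)$ground_truth$sprints[[1]]$isi
  expect_equal(unname(unlist(isi0)), rep(0, 4), tolerance = 1e-12)
})

test_that("phase-mode asymmetry keeps equal wheel means but nonzero ISI", {
  cfg <- sim_config(seed = 6, n_sprints = 1, asymmetry_mode = "phase",
                    asymmetry_phase_frac = 0.15, noise_sd_gyro = 0)
  g <- generate_session(cfg)$ground_truth$sprints[[1]]
  sel <- seq(g$window$start_idx, g$window$end_idx)
  expect_equal(mean(g$v_left[sel]), mean(g$v_right[sel]), tolerance = 0.01)
  expect_gt(g$isi$overall, 0.005)
})
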