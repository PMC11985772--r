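test_that("exact quartic velocity data is recovered to 1e-8 relative", {
  p_true <- c(0.002, -0.05, 0.3, 1.2, 0.4)
  t <- seq(3, 9, by = 1 / 128)  # arbitrary origin; fit re-origins internally
  x <- t - t[1]
  v <- p_true[1] * x^4 + p_true[2] * x^3 + p_true[3] * x^2 + p_true[4] * x + p_true[5]
  fit <- fit_velocity_polynomial(t, v)
  expect_equal(fit$coeffs, p_true, tolerance = 1e-8)
  expect_lt(fit$fit_residual_rms, 1e-10)
  # constant trace: p1..p4 = 0, p5 = 3
  fitc <- fit_velocity_polynomial(t, rep(3, length(t)))
  expect_equal(fitc$coeffs, c(0, 0, 0, 0, 3), tolerance = 1e-10)
})

test_that("noisy-fit residual matches a normal-equations oracle", {
  set.seed(31)
  t <- seq(0, 6, by = 1 / 128)
  v <- 4 * (1 - exp(-t / 1.5)) + rnorm(length(t), 0, 0.1)
  fit <- fit_velocity_polynomial(t, v)
  X <- cbind(t^4, t^3, t^2, t, 1)
  beta <- solve(crossprod(X), crossprod(X, v))
  rms_oracle <- sqrt(mean((v - X %*% beta)^2))
  expect_equal(fit$fit_residual_rms, rms_oracle, tolerance = 1e-10)
  expect_error(fit_velocity_polynomial(c(1, 1, 2, 3, 4), 1:5), "duplicate")
  expect_error(fit_velocity_polynomial(1:4, 1:4), "at least 5")
})

test_that("force model reproduces the constant-velocity closed form", {
  # v = 2 m/s, mt = 100 kg, mu_r = 0.01, kf = 0, CdA = 0.4, rho = 1.22:
  # F = 0 + 100*9.81*0.01 + 0.5*1.22*0.4*4 = 10.786 N; P = 21.572 W
  t <- seq(0, 5, by = 1 / 128)
  poly <- fit_velocity_polynomial(t, rep(2, length(t)))
  sys <- system_properties(mt = 100, mu_r = 0.01, kf = 0, CdA = 0.4)
  fp <- compute_force_power(poly, sys)
  expect_equal(fp$series$F_imu, rep(10.786, length(t)), tolerance = 1e-9)
  expect_equal(fp$series$P_imu, rep(21.572, length(t)), tolerance = 1e-9)
  # at rest: F_aero = 0, P = 0, F = mt g mu_r
  poly0 <- fit_velocity_polynomial(t, rep(0, length(t)))
  fp0 <- compute_force_power(poly0, sys)
  expect_equal(fp0$series$F_aero, rep(0, length(t)), tolerance = 1e-12)
  expect_equal(fp0$series$P_imu, rep(0, length(t)), tolerance = 1e-12)
  expect_equal(fp0$series$F_imu, rep(100 * 9.81 * 0.01, length(t)), tolerance = 1e-9)
})

test_that("linear velocity matches the symbolic force expression", {
  a <- 0.7
  t <- seq(0, 5, by = 1 / 128)
  poly <- fit_velocity_polynomial(t, a * t)
  sys <- system_properties(mt = 85, mu_r = 0.013, kf = 0.002, CdA = 0.35)
  fp <- compute_force_power(poly, sys)
  F_sym <- 85 * a + 85 * 9.81 * (0.013 + 0.002 * (a * t)^2) +
    0.5 * 1.22 * 0.35 * (a * t)^2
  expect_equal(fp$series$F_imu, F_sym, tolerance = 1e-7)
})

test_that("with zero resistances the model is pure Newton", {
  set.seed(5)
  t <- seq(0, 6, by = 1 / 128)
  v <- 4 * (1 - exp(-t / 1.5)) + rnorm(length(t), 0, 0.05)
  poly <- fit_velocity_polynomial(t, v)
  sys <- system_properties(mt = 92, mu_r = 0, kf = 0, CdA = 0)
  fp <- compute_force_power(poly, sys)
  expect_equal(fp$series$F_imu, 92 * fp$series$acc, tolerance = 1e-12)
  # power-force consistency at every sample
  expect_equal(fp$series$P_imu, fp$series$F_imu * fp$series$pV, tolerance = 1e-12)
})

test_that("increasing CdA never decreases force where velocity is positive", {
  t <- seq(0, 6, by = 1 / 128)
  poly <- fit_velocity_polynomial(t, 4 * (1 - exp(-t / 1.5)))
  f_at <- function(cda) {
    compute_force_power(poly, system_properties(85, 0.01, 0, cda))$series$F_imu
  }
  pv <- compute_force_power(poly, system_properties(85, 0, 0, 0))$series$pV
  f1 <- f_at(0.2); f2 <- f_at(0.5)
  expect_true(all(f2[pv > 0] >= f1[pv > 0]))
})

test_that("rolling resistance is recovered from synthetic coast-downs", {
  geom <- wheel_geometry(0.3)
  sys <- system_properties(mt = 85, mu_r = 0, kf = 0, CdA = 0)
  for (mu in c(0.005, 0.01, 0.02)) {
    trials <- list(
      generate_decel_trial(mu, 0, sys, 2.5, 1, geom),
      generate_decel_trial(mu, 0, sys, 2.5, -1, geom))
    est <- estimate_rolling_resistance(trials, geom, sys)
    expect_equal(as.numeric(est), mu, tolerance = 0.02)
  }
})

test_that("direction averaging cancels an incline bias", {
  geom <- wheel_geometry(0.3)
  sys <- system_properties(mt = 85, mu_r = 0, kf = 0, CdA = 0)
  trials <- list(
    generate_decel_trial(0.012, 0, sys, 2.5, 1, geom, slope_grade = 0.004),
    generate_decel_trial(0.012, 0, sys, 2.5, -1, geom, slope_grade = 0.004))
  est <- estimate_rolling_resistance(trials, geom, sys)
  per_trial <- attr(est, "decel") / 9.81
  expect_gt(abs(per_trial[1] - per_trial[2]), 0.004)  # bias visible per trial
  expect_equal(as.numeric(est), 0.012, tolerance = 0.02)
})

test_that("samples within 0.5 s of push end or stop are excluded", {
  # corrupt the trial inside the trimmed margins; the estimate must not move
  geom <- wheel_geometry(0.3)
  sys <- system_properties(mt = 85, mu_r = 0, kf = 0, CdA = 0)
  mk <- function(corrupt) {
    tr <- generate_decel_trial(0.012, 0, sys, 2.5, 1, geom)
    if (corrupt) {
      bad <- tr$t < tr$meta$push_end_t + 0.45 | tr$t > tr$meta$stop_t - 0.45
      tr$gyro[bad, 3] <- tr$gyro[bad, 3] + 5
    }
    tr
  }
  clean <- estimate_rolling_resistance(list(mk(FALSE), mk(FALSE)), geom, sys)
  dirty <- estimate_rolling_resistance(list(mk(TRUE), mk(TRUE)), geom, sys)
  expect_equal(as.numeric(dirty), as.numeric(clean), tolerance = 1e-12)
  # too-short coast is refused
  tr <- mk(FALSE)
  tr$meta$stop_t <- tr$meta$push_end_t + 1.9
  expect_error(estimate_rolling_resistance(list(tr, tr), geom, sys),
               "insufficient coast data")
})

test_that("mu_r recovery tolerates gyro noise", {
  geom <- wheel_geometry(0.3)
  sys <- system_properties(mt = 85, mu_r = 0, kf = 0, CdA = 0)
  for (mu in c(0.005, 0.01, 0.02)) {
    ests <- vapply(1:20, function(i) {
      trials <- list(
        generate_decel_trial(mu, 0, sys, 2.5, 1, geom, noise_sd = 0.05, seed = 100 + i),
        generate_decel_trial(mu, 0, sys, 2.5, -1, geom, noise_sd = 0.05, seed = 200 + i))
      as.numeric(estimate_rolling_resistance(trials, geom, sys))
    }, numeric(1))
    expect_lt(abs(mean(ests) / mu - 1), 0.10)
  }
})

test_that("sprint metrics satisfy the definitional identities", {
  ses <- generate_session(sim_config(seed = 4, n_sprints = 1))
  sa <- analyze_session(ses)
  m <- sa$metrics
  expect_equal(m$V_mean * m$sprint_time, 20, tolerance = 1e-12)
  # V_max recovers the generator's envelope ground truth
  expect_equal(m$V_max, ses$ground_truth$sprints[[1]]$v_max, tolerance = 0.02)
})
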