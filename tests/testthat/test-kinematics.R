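geomL <- function(camber = 18 * pi / 180) wheel_geometry(0.3, camber, "left", 0.6)
geomR <- function(camber = 18 * pi / 180) wheel_geometry(0.3, camber, "right", 0.6)

test_that("camber correction is the identity at zero camber", {
  g <- sin(seq(0, 10, by = 0.01)) + 5
  out <- correct_camber(g, g * 1.1, geomL(0), geomR(0))
  expect_identical(out$spin_left, g)
  expect_identical(out$spin_right, g * 1.1)
})

test_that("camber correction inverts the generator's construction formula", {
  t <- seq(0, 5, by = 1 / 128)
  v_mean <- 4 * (1 - exp(-t / 1.5))
  yaw <- 0.5 * sin(2 * pi * 0.8 * t)
  pair <- consistent_wheel_pair(v_mean, yaw, 0.6)
  gL <- velocity_to_gyro(pair$v_left, geomL(), yaw, 0)
  gR <- velocity_to_gyro(pair$v_right, geomR(), yaw, 0)
  out <- correct_camber(gL, gR, geomL(), geomR())
  expect_lt(max(abs(out$spin_left * 0.3 - pair$v_left)), 1e-6)
  expect_lt(max(abs(out$spin_right * 0.3 - pair$v_right)), 1e-6)
  expect_lt(max(abs(out$yaw - yaw)), 1e-6)
})

test_that("pivoting in place (pure yaw) yields near-zero corrected spin", {
  yaw <- rep(0.8, 100)
  pair <- consistent_wheel_pair(rep(0, 100), yaw, 0.6)
  gL <- velocity_to_gyro(pair$v_left, geomL(), yaw, 0)
  gR <- velocity_to_gyro(pair$v_right, geomR(), yaw, 0)
  out <- correct_camber(gL, gR, geomL(), geomR())
  # mean spin ~ 0: wheels counter-rotate to produce the pivot
  expect_lt(abs(mean(out$spin_left * 0.3 + out$spin_right * 0.3) / 2), 1e-9)
  expect_lt(max(abs(out$yaw - yaw)), 1e-9)
})

test_that("spin_to_velocity is v = spin * r and round-trips", {
  geom <- wheel_geometry(0.3)
  expect_equal(spin_to_velocity(rep(2 / 0.3, 5), geom), rep(2, 5))
  expect_equal(spin_to_velocity(rep(0, 5), geom), rep(0, 5))
  spin <- rnorm(100)
  expect_equal(spin_to_velocity(spin, geom) / 0.3, spin, tolerance = 1e-12)
})

test_that("sprint start/end detection matches analytic crossing and arrival", {
  fs <- 128
  t <- seq(0, 15, by = 1 / fs)
  # ramp v = 0.5 t: threshold 0.06 crossed at t = 0.12 -> first sample after
  v <- 0.5 * t
  w <- detect_sprint_window(v, v, fs, 20, t = t)
  expect_equal(w$start_t, ceiling(0.12 * fs) / fs, tolerance = 1e-9)
  # step to 4 m/s: 20 m in 5.0 s, within one sample
  v2 <- ifelse(t < 1, 0, 4)
  w2 <- detect_sprint_window(v2, v2, fs, 20, t = t)
  expect_lt(abs(w2$duration_s - 5.0), 1.5 / fs)
  expect_gte(w2$distance_m, 20)
  expect_lt(w2$distance_m - 20, 4 / fs)
  # sub-threshold velocity: no start
  expect_error(detect_sprint_window(rep(0.05, 1000), rep(0.05, 1000), fs, 20),
               "no start detected")
  # threshold crossed but track never completed
  v3 <- ifelse(t < 1, 0, 0.5)
  expect_error(detect_sprint_window(v3, v3, fs, 20, t = t), "sprint incomplete")
})

test_that("cycle segmentation counts ripples and partitions 3/middle/5", {
  fs <- 128
  t <- seq(0, 6, by = 1 / fs)
  v <- rep(0, length(t))
  drive <- t >= 0.5
  v[drive] <- 3 + 0.4 * abs(sin(pi * 2 * (t[drive] - 0.5)))  # 10 ripples at 2 Hz
  w <- list(start_idx = which(drive)[1], end_idx = length(t),
            start_t = 0.5, end_t = t[length(t)],
            duration_s = t[length(t)] - 0.5, track_length_m = 20)
  class(w) <- "sprint_window"
  seg <- segment_cycles(v[w$start_idx:w$end_idx], w, fs)
  expect_equal(seg$n_cycles, 10)
  expect_equal(seg$window_start, 1:3)
  expect_equal(seg$window_middle, 4:5)
  expect_equal(seg$window_end, 6:10)
  # 12 cycles -> middle is 4..7 (interior minima at t = 0.5, 1.0, ..., 6.0)
  v12 <- 3 + 0.4 * abs(sin(pi * 2 * seq(0, 6.4, by = 1 / fs)))
  w12 <- w; w12$start_idx <- 1L; w12$end_idx <- length(v12)
  w12$start_t <- 0; w12$end_t <- (length(v12) - 1) / fs
  seg12 <- segment_cycles(v12, w12, fs)
  expect_equal(seg12$n_cycles, 12)
  expect_equal(seg12$window_middle, 4:7)
  expect_equal(seg12$window_end, 8:12)
  # monotone ramp: no minima
  expect_error(segment_cycles(seq(0, 4, length.out = 500), w, fs),
               "insufficient cycles")
})

test_that("windows disjointly cover the detected cycles in order", {
  for (n in c(8, 9, 12, 15)) {
    fs <- 128
    t <- seq(0, (n + 0.9) / 2, by = 1 / fs)
    v <- 3 + 0.4 * abs(sin(pi * 2 * t))
    w <- structure(list(start_idx = 1L, end_idx = length(t), start_t = 0,
                        end_t = t[length(t)], duration_s = t[length(t)],
                        track_length_m = 20), class = "sprint_window")
    seg <- segment_cycles(v, w, fs)
    all_idx <- c(seg$window_start, seg$window_middle, seg$window_end)
    expect_equal(all_idx, seq_len(seg$n_cycles))
  }
})

test_that("full round-trip velocity -> gyro -> correction -> velocity", {
  ses <- generate_session(sim_config(seed = 2, n_sprints = 1, noise_sd_gyro = 0,
                                     yaw_oscillation_amp = 0.3))
  gt <- ses$ground_truth$sprints[[1]]
  gL <- geomL(); gR <- geomR()
  st <- ses$streams[[1]]
  out <- correct_camber(st$left_wheel$gyro[, 3], st$right_wheel$gyro[, 3], gL, gR)
  rel <- max(abs(out$spin_left * 0.3 - gt$v_left)) / max(abs(gt$v_left))
  expect_lt(rel, 1e-9)
})

test_that("cycle count on generated sessions tracks stroke rate", {
  ses <- generate_session(sim_config(seed = 8))
  sa <- analyze_session(ses)
  for (s in seq_len(nrow(sa$metrics))) {
    expected <- round(ses$config$stroke_freq_hz * sa$metrics$sprint_time[s])
    expect_lte(abs(sa$metrics$n_cycles[s] - expected), 1)
  }
})
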