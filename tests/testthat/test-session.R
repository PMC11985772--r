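test_that("symmetric noise-free sprint analyzes to zero ISI and true pace", {
  ses <- generate_session(sim_config(seed = 9, n_sprints = 1,
                                     asymmetry_gain = 1, start_asym_boost = 1,
                                     noise_sd_gyro = 0))
  sa <- analyze_session(ses)
  m <- sa$metrics
  gt <- ses$ground_truth$sprints[[1]]
  expect_equal(m$isi_overall, 0, tolerance = 1e-9)
  expect_equal(m$sprint_time, gt$sprint_time, tolerance = 0.02 * gt$sprint_time)
  expect_equal(m$V_mean, 20 / gt$sprint_time, tolerance = 0.02 * m$V_mean)
})

test_that("missing trunk stream degrades gracefully; missing wheel errors", {
  ses <- generate_session(sim_config(seed = 10, n_sprints = 1))
  sa0 <- analyze_session(ses)
  streams <- ses$streams[[1]]
  streams$trunk <- NULL
  expect_warning(res <- analyze_sprint(streams, sa0$config), "trunk stream absent")
  expect_true(is.na(res$metrics$trm_start))
  expect_false(is.na(res$metrics$isi_start))
  streams$left_wheel <- NULL
  expect_error(analyze_sprint(streams, sa0$config), "left_wheel")
})

test_that("stage errors carry the failing stage name", {
  ses <- generate_session(sim_config(seed = 10, n_sprints = 1))
  cfg <- analyze_session(ses)$config
  streams <- ses$streams[[1]]
  # sub-threshold stream: detection must be named in the error
  quiet <- streams
  n <- length(quiet$left_wheel$t)
  quiet$left_wheel$gyro[, 3] <- rep(0.01, n)
  quiet$right_wheel$gyro[, 3] <- rep(0.01, n)
  expect_error(analyze_sprint(quiet, cfg), "detect_sprint_window")
})

test_that("ST/LT identification uses time extremes with earlier-sprint ties", {
  base <- data.frame(sprint = 1:6, sprint_time = c(5.5, 5.4, 5.6, 5.45, 5.7, 5.65))
  s <- summarize_session(base)
  expect_equal(s$st_index, 2)
  expect_equal(s$lt_index, 5)
  ties <- data.frame(sprint = 1:4, sprint_time = rep(5.5, 4))
  s2 <- summarize_session(ties)
  expect_equal(s2$st_index, 1)
  expect_equal(s2$lt_index, 1)
  expect_error(summarize_session(base[1, , drop = FALSE]), "at least 2")
})

test_that("monotone-slowing session: ST is first sprint, LT the last", {
  ses <- generate_session(sim_config(seed = 14, n_sprints = 6, fatigue_decay = 0.97))
  sa <- analyze_session(ses)
  s <- summarize_session(sa$metrics, group_label = "WR")
  expect_equal(s$st_index, 1)
  expect_equal(s$lt_index, 6)
})

test_that("session round-trips through CSV + manifest and is deterministic", {
  dir1 <- withr::local_tempdir()
  ses <- generate_session(sim_config(seed = 15, n_sprints = 2))
  write_session(ses, dir1)
  back <- read_session(file.path(dir1, "manifest.json"))
  expect_length(back$streams, 2)
  expect_equal(back$streams[[1]]$left_wheel$gyro,
               ses$streams[[1]]$left_wheel$gyro, tolerance = 1e-12)
  expect_equal(back$decel_trials[[1]]$meta$push_end_t,
               ses$decel_trials[[1]]$meta$push_end_t)
  # analysis of the re-read session matches the in-memory analysis
  m1 <- analyze_session(ses)$metrics
  reanalyze <- function() {
    b <- read_session(file.path(dir1, "manifest.json"))
    mu <- estimate_rolling_resistance(b$decel_trials, b$config$geometry_left,
                                      b$config$system)
    b$config$system$mu_r <- as.numeric(mu)
    do.call(rbind, lapply(seq_along(b$streams), function(s) {
      analyze_sprint(b$streams[[s]], b$config, s)$metrics
    }))
  }
  m2 <- reanalyze()
  expect_equal(m1, m2, tolerance = 1e-9)
  # same input files => byte-identical metrics CSV
  f1 <- file.path(dir1, "m1.csv"); f2 <- file.path(dir1, "m2.csv")
  write_metrics_csv(m2, f1); write_metrics_csv(reanalyze(), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("fatigued session shows monotone V_max decline at the decay rate", {
  ses <- generate_session(sim_config(seed = 16, fatigue_decay = 0.97))
  sa <- analyze_session(ses)
  vmax <- sa$metrics$V_max
  expect_true(all(diff(vmax) < 0))
  expect_equal(vmax[6] / vmax[1], 0.97^5, tolerance = 0.03)
})
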