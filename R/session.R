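#' Analysis configuration for a recorded session
#'
#' Bundles the geometric and physical constants the per-sprint analysis
#' needs. `mu_r` typically comes from [estimate_rolling_resistance()] on the
#' session's coast-down trials.
#'
#' @param geometry_left,geometry_right [wheel_geometry()] per wheel.
#' @param system a [system_properties()].
#' @param track_length_m sprint distance, meters.
#' @param static_window optional `c(t1, t2)` still-hold span for the trunk
#'   offset; defaults to the trunk stream's own metadata, else the 2 s before
#'   the detected sprint start.
#' @param cycle_min_spacing_s,cycle_min_prominence_frac cycle-detection
#'   guards (see [segment_cycles()]).
#' @param lowpass_hz optional zero-phase low-pass cutoff for wheel gyro
#'   signals; `NULL` (default) applies no filtering.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(geometry_left, geometry_right, system,
                            track_length_m = 20, static_window = NULL,
                            cycle_min_spacing_s = 0.25,
                            cycle_min_prominence_frac = 0.02,
                            lowpass_hz = NULL) {
  structure(list(geometry_left = geometry_left, geometry_right = geometry_right,
                 system = system, track_length_m = track_length_m,
                 static_window = static_window,
                 cycle_min_spacing_s = cycle_min_spacing_s,
                 cycle_min_prominence_frac = cycle_min_prominence_frac,
                 lowpass_hz = lowpass_hz),
            class = "analysis_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    msg <- conditionMessage(e)
    if (startsWith(msg, stage)) stop(e) else stop_named(stage, msg)
  })
}

#' Analyze one sprint from its sensor streams
#'
#' Runs the full per-sprint pipeline: camber correction of the wheel
#' gyroscopes, conversion to linear velocity, sprint-window detection
#' (0.06 m/s threshold, integrated distance), propulsion-cycle segmentation,
#' 4th-degree velocity polynomial and force/power model, ISI over the
#' start/middle/end windows, and trunk range of motion. Wheel streams are
#' mandatory; the trunk stream is optional (TRM fields are NA with a warning
#' when absent). Errors carry the name of the failing stage.
#'
#' @param streams named list with `left_wheel`, `right_wheel` and optionally
#'   `trunk` [imu_stream()]s on a shared time base.
#' @param config an [analysis_config()].
#' @param sprint_index 1-based sprint number recorded in the output.
#' @return A list of class `sprint_analysis`: `metrics` (one-row data frame
#'   with all per-sprint outcomes) and `details` (window, cycles, polynomial,
#'   force/power series, velocities, symmetry and trunk objects).
#' @export
analyze_sprint <- function(streams, config, sprint_index = 1L) {
  for (nm in c("left_wheel", "right_wheel")) {
    if (is.null(streams[[nm]])) {
      stop_named("analyze_sprint", sprintf("missing mandatory stream '%s'", nm))
    }
  }
  sl <- streams$left_wheel
  sr <- streams$right_wheel
  if (length(sl$t) != length(sr$t) || max(abs(sl$t - sr$t)) > 1e-9) {
    stop_named("analyze_sprint", "wheel streams do not share a time base")
  }
  t <- sl$t
  fs <- sl$sample_rate_hz

  gl <- lowpass_filter(sl$gyro[, 3], fs, config$lowpass_hz)
  gr <- lowpass_filter(sr$gyro[, 3], fs, config$lowpass_hz)
  corr <- with_stage("correct_camber",
                     correct_camber(gl, gr, config$geometry_left, config$geometry_right))
  v_left <- spin_to_velocity(corr$spin_left, config$geometry_left)
  v_right <- spin_to_velocity(corr$spin_right, config$geometry_right)

  window <- with_stage("detect_sprint_window",
                       detect_sprint_window(v_left, v_right, fs,
                                            config$track_length_m, t = t))
  v_mean <- (v_left + v_right) / 2
  win_seq <- seq(window$start_idx, window$end_idx)
  cycles <- with_stage("segment_cycles",
                       segment_cycles(v_mean[win_seq], window, fs,
                                      config$cycle_min_spacing_s,
                                      config$cycle_min_prominence_frac))

  poly <- with_stage("fit_velocity_polynomial",
                     fit_velocity_polynomial(t[win_seq], v_mean[win_seq]))
  fp <- compute_force_power(poly, config$system)
  metrics <- sprint_metrics(poly, fp, window, cycles, t)
  isi <- with_stage("isi_by_window", isi_by_window(v_left, v_right, t, cycles, window))

  trm <- NULL
  if (is.null(streams$trunk)) {
    warning("analyze_sprint: trunk stream absent; TRM fields set to NA")
    trm_vals <- c(NA_real_, NA_real_, NA_real_)
  } else {
    st <- streams$trunk
    flex <- with_stage("quaternion_to_flexion", quaternion_to_flexion(st$quat))
    static_win <- config$static_window
    if (is.null(static_win)) static_win <- st$meta$static_window
    if (is.null(static_win)) static_win <- c(window$start_t - 2, window$start_t - 0.1)
    flex <- with_stage("apply_static_offset",
                       apply_static_offset(flex, st$t, static_win))
    trm <- with_stage("compute_trm", compute_trm(flex, st$t, cycles, window))
    trm_vals <- c(trm$trm_start, trm$trm_middle, trm$trm_end)
  }

  metrics <- cbind(data.frame(sprint = as.integer(sprint_index)), metrics,
                   data.frame(isi_start = isi$isi_start,
                              isi_middle = isi$isi_middle,
                              isi_end = isi$isi_end,
                              isi_overall = isi$isi_overall,
                              trm_start = trm_vals[1],
                              trm_middle = trm_vals[2],
                              trm_end = trm_vals[3]))
  structure(list(metrics = metrics,
                 details = list(window = window, cycles = cycles, poly = poly,
                                force_power = fp, v_left = v_left,
                                v_right = v_right, t = t,
                                symmetry = isi, trunk = trm)),
            class = "sprint_analysis")
}

#' Analyze a whole session
#'
#' Applies [analyze_sprint()] to each sprint of a session (synthetic or read
#' from disk) and binds the per-sprint metric rows.
#'
#' @param session a `synthetic_session` or a list with `streams` (per-sprint
#'   named stream lists) and optionally `decel_trials`.
#' @param config an [analysis_config()]; when `NULL` and the session is
#'   synthetic, a config is built from the session's own parameters, with
#'   `mu_r` estimated from the session's coast-down trials.
#' @return A list of class `session_analysis`: `metrics` (data frame, one row
#'   per sprint), `mu_r_est`, `analyses` (per-sprint detail objects), `config`.
#' @export
analyze_session <- function(session, config = NULL) {
  if (is.null(config)) {
    sc <- session$config
    if (is.null(sc)) stop("analyze_session: config required for non-synthetic sessions",
                          call. = FALSE)
    geom_L <- wheel_geometry(sc$wheel_radius_m, sc$camber_rad, "left", sc$track_width_m)
    geom_R <- wheel_geometry(sc$wheel_radius_m, sc$camber_rad, "right", sc$track_width_m)
    sys0 <- system_properties(mt = sc$athlete_mass_kg + sc$chair_mass_kg,
                              mu_r = 0, kf = sc$kf_true, CdA = sc$CdA_true)
    mu_r <- estimate_rolling_resistance(session$decel_trials, geom_L, sys0)
    sys <- system_properties(mt = sys0$mt, mu_r = as.numeric(mu_r),
                             kf = sc$kf_true, CdA = sc$CdA_true)
    config <- analysis_config(geom_L, geom_R, sys, sc$track_length_m)
  } else {
    mu_r <- config$system$mu_r
    if (!is.null(session$decel_trials) && length(session$decel_trials) == 2L) {
      mu_r <- estimate_rolling_resistance(session$decel_trials,
                                          config$geometry_left, config$system)
      config$system$mu_r <- as.numeric(mu_r)
    }
  }
  analyses <- lapply(seq_along(session$streams), function(s) {
    analyze_sprint(session$streams[[s]], config, sprint_index = s)
  })
  metrics <- do.call(rbind, lapply(analyses, `[[`, "metrics"))
  structure(list(metrics = metrics, mu_r_est = as.numeric(mu_r),
                 analyses = analyses, config = config),
            class = "session_analysis")
}

#' Session summary: fastest/slowest sprint and first-vs-last pairs
#'
#' Identifies the shortest-time (ST) and longest-time (LT) sprints regardless
#' of order (ties broken toward the earlier sprint) and exposes the
#' first-vs-last comparison pair.
#'
#' @param metrics data frame of per-sprint metrics (from [analyze_session()]),
#'   with columns `sprint` and `sprint_time`.
#' @param group_label optional group tag (`"WB"`, `"WR"`, ...).
#' @return A list of class `session_summary`: `metrics`, `st_index`,
#'   `lt_index`, `first_last` (two-row data frame), `group_label`.
#' @export
summarize_session <- function(metrics, group_label = NA_character_) {
  if (nrow(metrics) < 2L) {
    stop("summarize_session: need at least 2 sprints", call. = FALSE)
  }
  st <- metrics$sprint[which.min(metrics$sprint_time)]
  lt <- metrics$sprint[which.max(metrics$sprint_time)]
  structure(list(metrics = metrics,
                 st_index = st, lt_index = lt,
                 first_last = metrics[c(1L, nrow(metrics)), ],
                 group_label = group_label),
            class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("<session_summary> %d sprints  ST = sprint %d (%.2f s)  LT = sprint %d (%.2f s)\n",
              nrow(x$metrics), x$st_index,
              min(x$metrics$sprint_time), x$lt_index, max(x$metrics$sprint_time)))
  invisible(x)
}
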