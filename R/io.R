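#' Write a session to disk (CSV streams + JSON manifest)
#'
#' One CSV per sensor per trial in the `t,gx,gy,gz,ax,ay,az[,qw,qx,qy,qz]`
#' dialect, plus `manifest.json` listing athlete metadata, per-sprint stream
#' paths, coast-down trial paths (with their phase timestamps) and system
#' constants. For synthetic sessions the ground truth is written alongside as
#' `ground_truth.json` (scalar truths only; traces are regenerable from the
#' seed).
#'
#' @param session a `synthetic_session` (or compatible list).
#' @param dir output directory, created if needed.
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- session$config
  sprints <- lapply(seq_along(session$streams), function(s) {
    paths <- list()
    for (sensor in names(session$streams[[s]])) {
      rel <- sprintf("sprint%d_%s.csv", s, sensor)
      write_imu_csv(session$streams[[s]][[sensor]], file.path(dir, rel))
      paths[[sensor]] <- rel
    }
    paths
  })
  decel <- lapply(seq_along(session$decel_trials), function(i) {
    rel <- sprintf("decel_%d.csv", i)
    tr <- session$decel_trials[[i]]
    write_imu_csv(tr, file.path(dir, rel))
    list(path = rel, push_end_t = tr$meta$push_end_t, stop_t = tr$meta$stop_t,
         direction = tr$meta$direction)
  })
  manifest <- list(
    athlete = list(mass_kg = cfg$athlete_mass_kg, chair_mass_kg = cfg$chair_mass_kg,
                   wheel_radius_m = cfg$wheel_radius_m,
                   camber_deg = cfg$camber_rad * 180 / pi,
                   track_width_m = cfg$track_width_m, group_label = "synthetic"),
    protocol = list(n_sprints = cfg$n_sprints, track_length_m = cfg$track_length_m,
                    recovery_s = cfg$recovery_s, sample_rate_hz = cfg$sample_rate_hz,
                    static_hold_s = cfg$static_hold_s),
    system = list(rho = 1.22, kf = cfg$kf_true, CdA = cfg$CdA_true),
    sprints = sprints, decel_trials = decel
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(session$ground_truth)) {
    gt <- session$ground_truth
    gt_small <- list(mu_r = gt$mu_r, kf = gt$kf, CdA = gt$CdA,
                     sprints = lapply(gt$sprints, function(g) {
                       list(v_max = g$v_max, sprint_time = g$sprint_time,
                            n_cycles = g$n_cycles, isi = g$isi, trm_deg = g$trm_deg)
                     }))
    jsonlite::write_json(gt_small, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a session from its JSON manifest
#'
#' @param manifest_path path to a `manifest.json` written by [write_session()]
#'   (or hand-authored in the same dialect).
#' @return A list with `streams`, `decel_trials`, `manifest`, and an
#'   [analysis_config()] assembled from the manifest (`mu_r` left at 0 until
#'   estimated from the coast-down trials).
#' @export
read_session <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  dir <- dirname(manifest_path)
  fs <- m$protocol$sample_rate_hz
  streams <- lapply(seq_along(m$sprints), function(s) {
    out <- list()
    for (sensor in names(m$sprints[[s]])) {
      meta <- if (sensor == "trunk") {
        list(static_window = c(0, m$protocol$static_hold_s))
      } else list()
      out[[sensor]] <- read_imu_csv(file.path(dir, m$sprints[[s]][[sensor]]),
                                    sensor_id = sensor, sample_rate_hz = fs,
                                    meta = meta)
    }
    out
  })
  decel <- lapply(m$decel_trials, function(d) {
    read_imu_csv(file.path(dir, d$path), sensor_id = "left_wheel",
                 sample_rate_hz = fs,
                 meta = list(push_end_t = d$push_end_t, stop_t = d$stop_t,
                             direction = d$direction))
  })
  a <- m$athlete
  geom_L <- wheel_geometry(a$wheel_radius_m, a$camber_deg * pi / 180, "left",
                           a$track_width_m)
  geom_R <- wheel_geometry(a$wheel_radius_m, a$camber_deg * pi / 180, "right",
                           a$track_width_m)
  sys <- system_properties(mt = a$mass_kg + a$chair_mass_kg, mu_r = 0,
                           kf = m$system$kf, CdA = m$system$CdA, rho = m$system$rho)
  cfg <- analysis_config(geom_L, geom_R, sys,
                         track_length_m = m$protocol$track_length_m)
  list(streams = streams, decel_trials = decel, manifest = m, config = cfg)
}

#' Write per-sprint metrics to CSV
#'
#' @param metrics data frame of per-sprint metrics.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
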