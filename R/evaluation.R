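#' Evaluate a tracked session against ground truth
#'
#' Computes the per-frame visual-angle error between estimated and true
#' gaze and aggregates it: per calibration zone (when the manifest carries
#' mark indices), per display axis (horizontal/vertical, each converted
#' through its own pixel pitch), and the overall session mean. Blink
#' frames are excluded from every average.
#'
#' @param gaze Tibble from [track_session()] (`frame`, `gaze_x`, `gaze_y`,
#'   `confidence`).
#' @param manifest Truth manifest (`frame`, `true_gaze_x`, `true_gaze_y`,
#'   optionally `mark_index`, `blink`).
#' @param geometry A [display_geometry()].
#' @return An `eval_report`: list with `per_zone` (tibble `mark`,
#'   `mean_deg`, `n`), `per_axis` (tibble `axis`, `mean_deg`),
#'   `session_mean_deg`, `n_frames`, `n_blinks_excluded`, `frames`
#'   (per-frame tibble).
#' @export
evaluate_session <- function(gaze, manifest, geometry = display_geometry()) {
  unmatched <- setdiff(gaze$frame[!is.na(gaze$gaze_x)], manifest$frame)
  if (length(unmatched)) {
    rlang::abort(sprintf("gaze rows without matching truth rows: %s",
                         paste(utils::head(unmatched, 10), collapse = ", ")))
  }
  joined <- dplyr::inner_join(gaze, manifest, by = "frame")
  blink <- joined$confidence == "blink"
  if ("blink" %in% names(joined)) blink <- blink | joined$blink == 1
  meas <- joined[!blink & !is.na(joined$gaze_x), ]
  if (nrow(meas) == 0) {
    rlang::abort("no measurable (non-blink) frames in the session")
  }
  dx <- meas$gaze_x - meas$true_gaze_x
  dy <- meas$gaze_y - meas$true_gaze_y
  H <- geometry$viewing_distance_cm
  frames <- tibble::tibble(
    frame = meas$frame,
    mark = if ("mark_index" %in% names(meas)) meas$mark_index else NA_integer_,
    error_deg = angular_error_deg(meas$gaze_x, meas$gaze_y,
                                  meas$true_gaze_x, meas$true_gaze_y, geometry),
    error_h_deg = axis_error_deg(dx, geometry$width_cm / geometry$width_px, H),
    error_v_deg = axis_error_deg(dy, geometry$height_cm / geometry$height_px, H)
  )
  per_zone <- if (all(is.na(frames$mark))) {
    tibble::tibble(mark = integer(), mean_deg = numeric(), n = integer())
  } else {
    dplyr::summarise(dplyr::group_by(frames[!is.na(frames$mark), ], .data$mark),
                     mean_deg = mean(.data$error_deg), n = dplyr::n(),
                     .groups = "drop")
  }
  structure(list(
    per_zone = per_zone,
    per_axis = tibble::tibble(axis = c("horizontal", "vertical"),
                              mean_deg = c(mean(frames$error_h_deg),
                                           mean(frames$error_v_deg))),
    session_mean_deg = mean(frames$error_deg),
    n_frames = nrow(frames),
    n_blinks_excluded = sum(blink),
    frames = frames
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d frames (%d blinks excluded)\n",
              x$n_frames, x$n_blinks_excluded))
  cat(sprintf("  session mean error: %.3f deg (H %.3f, V %.3f)\n",
              x$session_mean_deg, x$per_axis$mean_deg[1], x$per_axis$mean_deg[2]))
  if (nrow(x$per_zone)) print(x$per_zone)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) x$per_zone

#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  tibble::tibble(session_mean_deg = x$session_mean_deg,
                 horizontal_deg = x$per_axis$mean_deg[1],
                 vertical_deg = x$per_axis$mean_deg[2],
                 n_frames = x$n_frames,
                 n_blinks_excluded = x$n_blinks_excluded)
}

#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  dat <- object$per_zone
  if (!nrow(dat)) {
    dat <- tibble::tibble(mark = "session", mean_deg = object$session_mean_deg)
  }
  ggplot2::ggplot(dat, ggplot2::aes(factor(.data$mark), .data$mean_deg)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$session_mean_deg, linetype = 2) +
    ggplot2::labs(x = "calibration zone", y = "mean angular error (deg)",
                  title = "Per-zone gaze accuracy")
}

#' Write an evaluation report as YAML (plus an optional per-zone CSV)
#'
#' The CSV mirrors the per-zone table layout: rows = zones, final row =
#' session average.
#'
#' @param report An `eval_report`.
#' @param path Output YAML file.
#' @param zones_csv Optional path for the per-zone CSV.
#' @export
write_eval_report <- function(report, path, zones_csv = NULL) {
  yaml::write_yaml(list(
    session_mean_deg = report$session_mean_deg,
    horizontal_deg = report$per_axis$mean_deg[1],
    vertical_deg = report$per_axis$mean_deg[2],
    n_frames = report$n_frames,
    n_blinks_excluded = report$n_blinks_excluded,
    per_zone = lapply(seq_len(nrow(report$per_zone)),
                      function(i) as.list(report$per_zone[i, ]))
  ), path)
  if (!is.null(zones_csv)) {
    tab <- dplyr::bind_rows(
      dplyr::mutate(report$per_zone, mark = as.character(.data$mark)),
      tibble::tibble(mark = "average", mean_deg = report$session_mean_deg,
                     n = report$n_frames)
    )
    readr::write_csv(tab, zones_csv)
  }
  invisible(path)
}

#' Repeated-use protocol: one calibration, several re-wears
#'
#' Calibrates once on a synthetic session, then simulates `n_sessions`
#' fresh tracking sessions in which the device has been taken off and put
#' back on: each re-wear shifts the true gaze-to-pupil map by a constant
#' pixel offset of magnitude `rewear_offset_px` in a random direction.
#' All sessions are evaluated against the single fixed model.
#'
#' @param config A [scene_config()] (its seed drives everything).
#' @param n_sessions Number of re-wear sessions (default 4).
#' @param rewear_offset_px Magnitude of the constant pupil-center offset
#'   per re-wear (px, default 2).
#' @param marks Mark layout.
#' @param eval_grid Tibble of display points for the tracking sessions;
#'   default 3 x 3 at the mark positions.
#' @param frames_per_point Frames per evaluation point (default 15).
#' @param frames_per_mark Calibration frames per mark (default 60).
#' @param geometry Display geometry.
#' @param params Detector parameters.
#' @param T Optional absolute calibration rejection threshold (px).
#' @return A list: `sessions` (tibble `session`, `mean_deg`, `n`;
#'   session 0 is the no-re-wear baseline), `baseline_mean_deg`,
#'   `overall_mean_deg` (mean over the re-wear sessions), `model`.
#' @export
repeated_use_protocol <- function(config, n_sessions = 4L,
                                  rewear_offset_px = 2,
                                  marks = default_mark_layout(),
                                  eval_grid = NULL,
                                  frames_per_point = 15L,
                                  frames_per_mark = 60L,
                                  geometry = display_geometry(),
                                  params = detect_params(
                                    pupil_radius_px = config$pupil_radius_px),
                                  T = NULL) {
  if (is.null(eval_grid)) eval_grid <- marks[, c("x", "y")]
  calib <- simulate_and_detect(
    config, marks[rep(seq_len(nrow(marks)), each = frames_per_mark), c("x", "y")],
    mark_index = rep(marks$mark, each = frames_per_mark),
    geometry = geometry, params = params)
  cal <- calibrate(calib$observations, calib$manifest, T = T)
  model <- fit_gaze_model(calibration_pairs(cal, marks), geometry)

  path <- eval_grid[rep(seq_len(nrow(eval_grid)), each = frames_per_point), ]
  seeds <- with_local_seed(config$seed + 1L,
                           sample.int(2147483646L, n_sessions + 1L))
  angles <- with_local_seed(config$seed + 2L,
                            stats::runif(n_sessions, 0, 2 * pi))

  run_one <- function(cfg_s) {
    sess <- simulate_and_detect(cfg_s, path, geometry = geometry,
                                params = params)
    gaze <- estimate_from_observations(sess$observations, cal, model, marks)
    rep <- evaluate_session(gaze, sess$manifest, geometry)
    tibble::tibble(mean_deg = rep$session_mean_deg, n = rep$n_frames)
  }

  base_cfg <- config; base_cfg$seed <- seeds[n_sessions + 1L]
  baseline <- run_one(base_cfg)

  rows <- purrr::map(seq_len(n_sessions), function(s) {
    off <- rewear_offset_px * c(cos(angles[s]), sin(angles[s]))
    m <- config$map
    m$px[6] <- m$px[6] + off[1]
    m$py[6] <- m$py[6] + off[2]
    cfg_s <- config; cfg_s$map <- m; cfg_s$seed <- seeds[s]
    dplyr::mutate(run_one(cfg_s), session = s)
  })
  sessions <- dplyr::bind_rows(
    tibble::tibble(session = 0L, mean_deg = baseline$mean_deg, n = baseline$n),
    dplyr::bind_rows(rows)[, c("session", "mean_deg", "n")]
  )
  list(sessions = sessions,
       baseline_mean_deg = baseline$mean_deg,
       overall_mean_deg = mean(sessions$mean_deg[sessions$session > 0]),
       model = model)
}

#' Synthetic accuracy benchmark over several simulated subjects
#'
#' For each seed, builds a distinct synthetic subject (its own ground-truth
#' quadratic gaze-to-pupil map), renders a nine-mark calibration session,
#' calibrates and fits the polynomial gaze model, then evaluates tracking
#' on an evaluation grid spanning the display. Returns per-subject session
#' means and the across-subject mean angular error in degrees.
#'
#' @param seeds Integer vector, one synthetic subject per seed.
#' @param jitter_sigma_px,blink_prob,noise_sigma Generator settings.
#' @param grid_n Evaluation grid is `grid_n` x `grid_n` over the mark
#'   bounding box.
#' @param frames_per_point Frames rendered per grid point.
#' @param frames_per_mark Calibration frames per mark.
#' @param geometry Display geometry.
#' @return A list: `subjects` (tibble `seed`, `mean_deg`, `n`),
#'   `mean_deg` (frame-weighted across-subject mean), `n_frames`.
#' @export
accuracy_benchmark <- function(seeds = 1:8, jitter_sigma_px = 1,
                               blink_prob = 0.05, noise_sigma = 8,
                               grid_n = 5L, frames_per_point = 20L,
                               frames_per_mark = 60L,
                               geometry = display_geometry()) {
  marks <- default_mark_layout()
  gx <- seq(min(marks$x), max(marks$x), length.out = grid_n)
  gy <- seq(min(marks$y), max(marks$y), length.out = grid_n)
  grid <- tidyr::expand_grid(x = gx, y = gy)
  path <- grid[rep(seq_len(nrow(grid)), each = frames_per_point), ]

  subjects <- purrr::map(seeds, function(s) {
    cfg <- scene_config(map = random_true_map(s),
                        jitter_sigma_px = jitter_sigma_px,
                        blink_prob = blink_prob, noise_sigma = noise_sigma,
                        seed = s)
    params <- detect_params(pupil_radius_px = cfg$pupil_radius_px)
    calib <- simulate_and_detect(
      cfg, marks[rep(1:9, each = frames_per_mark), c("x", "y")],
      mark_index = rep(marks$mark, each = frames_per_mark),
      geometry = geometry, params = params)
    cal <- calibrate(calib$observations, calib$manifest)
    model <- fit_gaze_model(calibration_pairs(cal, marks), geometry)
    cfg_t <- cfg; cfg_t$seed <- cfg$seed + 1000L
    sess <- simulate_and_detect(cfg_t, path, geometry = geometry,
                                params = params)
    gaze <- estimate_from_observations(sess$observations, cal, model, marks)
    rep <- evaluate_session(gaze, sess$manifest, geometry)
    tibble::tibble(seed = s, mean_deg = rep$session_mean_deg, n = rep$n_frames)
  })
  subjects <- dplyr::bind_rows(subjects)
  list(subjects = subjects,
       mean_deg = sum(subjects$mean_deg * subjects$n) / sum(subjects$n),
       n_frames = sum(subjects$n))
}

#' Synthetic pupil-detection benchmark
#'
#' Renders non-blink frames at uniformly random gaze points with the
#' default palette and noise, runs the detector on each, and reports the
#' percentage of frames whose detected center lies within `tol_px` of the
#' rendered ground-truth pupil center.
#'
#' @param n_frames Number of frames (default 1000).
#' @param tol_px Center-error tolerance in px (default 5).
#' @param seed RNG seed.
#' @param config A [scene_config()]; defaults to the standard scene with
#'   this seed.
#' @param geometry Display geometry bounding the random gazes.
#' @return A list: `detection_rate_pct`, `median_error_px`, `errors`
#'   (per-frame tibble).
#' @export
detection_benchmark <- function(n_frames = 1000L, tol_px = 5, seed = 1L,
                                config = NULL,
                                geometry = display_geometry()) {
  if (is.null(config)) config <- scene_config(seed = seed)
  params <- detect_params(pupil_radius_px = config$pupil_radius_px)
  gaze <- with_local_seed(seed, tibble::tibble(
    x = stats::runif(n_frames, 0, geometry$width_px),
    y = stats::runif(n_frames, 0, geometry$height_px)
  ))
  cfg <- config; cfg$blink_prob <- 0; cfg$seed <- seed
  sess <- simulate_and_detect(cfg, gaze, geometry = geometry, params = params)
  obs <- sess$observations
  err <- sqrt((obs$pupil_x - sess$manifest$true_pupil_x)^2 +
                (obs$pupil_y - sess$manifest$true_pupil_y)^2)
  err[is.na(err)] <- Inf
  list(detection_rate_pct = 100 * mean(err <= tol_px),
       median_error_px = stats::median(err[is.finite(err)]),
       errors = tibble::tibble(frame = obs$frame, error_px = err,
                               blink = obs$blink))
}
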