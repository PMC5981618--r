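make_gaze <- function(est_x, est_y, blink = NULL) {
  n <- length(est_x)
  if (is.null(blink)) blink <- rep(FALSE, n)
  tibble::tibble(frame = seq_len(n),
                 gaze_x = ifelse(blink, NA_real_, est_x),
                 gaze_y = ifelse(blink, NA_real_, est_y),
                 coarse_zone = ifelse(blink, "blink", "1"),
                 confidence = ifelse(blink, "blink", "ok"))
}

make_truth <- function(x, y, mark = NA_integer_) {
  tibble::tibble(frame = seq_along(x), mark_index = mark,
                 true_gaze_x = x, true_gaze_y = y,
                 blink = 0L)
}

test_that("perfect estimates give an all-zero report", {
  gaze <- make_gaze(c(112, 512, 924), c(60, 360, 660))
  truth <- make_truth(c(112, 512, 924), c(60, 360, 660), mark = c(1L, 5L, 9L))
  rep <- evaluate_session(gaze, truth)
  expect_equal(rep$session_mean_deg, 0)
  expect_equal(rep$per_axis$mean_deg, c(0, 0))
  expect_equal(rep$per_zone$mean_deg, c(0, 0, 0))
  expect_equal(rep$n_frames, 3)
})

test_that("a single 10 px horizontal offset matches the closed form", {
  gaze <- make_gaze(522, 360)
  truth <- make_truth(512, 360)
  rep <- evaluate_session(gaze, truth)
  want <- atan(10 * 35 / 1024 / 50) * 180 / pi
  expect_equal(rep$session_mean_deg, want, tolerance = 1e-12)
  expect_equal(rep$per_axis$mean_deg[1], want, tolerance = 1e-12)
  expect_equal(rep$per_axis$mean_deg[2], 0)
})

test_that("sessions with no measurable frames or unmatched rows are rejected", {
  gaze <- make_gaze(c(100, 200), c(100, 200), blink = c(TRUE, TRUE))
  truth <- make_truth(c(100, 200), c(100, 200))
  expect_error(evaluate_session(gaze, truth), "no measurable")

  gaze2 <- make_gaze(c(100, 200), c(100, 200))
  truth2 <- make_truth(100, 100)   # frame 2 missing
  expect_error(evaluate_session(gaze2, truth2), "matching truth")
})

test_that("blink frames are excluded from every average", {
  gaze <- make_gaze(c(112, 512, 900), c(60, 360, 60),
                    blink = c(FALSE, FALSE, TRUE))
  truth <- make_truth(c(112, 512, 924), c(60, 360, 660), mark = c(1L, 5L, 9L))
  rep <- evaluate_session(gaze, truth)
  expect_equal(rep$n_frames, 2)
  expect_equal(rep$n_blinks_excluded, 1)
  expect_equal(rep$session_mean_deg, 0)
  expect_false(9 %in% rep$per_zone$mark)
})

test_that("per-frame axis errors obey the triangle-type bound", {
  set.seed(13)
  n <- 200
  gaze <- make_gaze(runif(n, 0, 1024), runif(n, 0, 720))
  truth <- make_truth(runif(n, 0, 1024), runif(n, 0, 720))
  rep <- evaluate_session(gaze, truth)
  with(rep$frames, {
    expect_true(all(error_deg >= pmax(error_h_deg, error_v_deg) - 1e-9))
    expect_true(all(error_deg <= error_h_deg + error_v_deg + 1e-9))
  })
})

test_that("report aggregation equals a brute-force recomputation", {
  set.seed(14)
  n <- 120
  gaze <- make_gaze(runif(n, 0, 1024), runif(n, 0, 720))
  truth <- make_truth(runif(n, 0, 1024), runif(n, 0, 720),
                      mark = rep(1:6, each = 20))
  rep <- evaluate_session(gaze, truth)
  geo <- display_geometry()
  # brute force from the raw inputs
  bf <- sapply(seq_len(n), function(i) {
    dx_cm <- (gaze$gaze_x[i] - truth$true_gaze_x[i]) * geo$width_cm / geo$width_px
    dy_cm <- (gaze$gaze_y[i] - truth$true_gaze_y[i]) * geo$height_cm / geo$height_px
    atan(sqrt(dx_cm^2 + dy_cm^2) / geo$viewing_distance_cm) * 180 / pi
  })
  expect_equal(rep$session_mean_deg, mean(bf), tolerance = 1e-12)
  zone_bf <- tapply(bf, truth$mark_index, mean)
  expect_equal(rep$per_zone$mean_deg, as.numeric(zone_bf), tolerance = 1e-12)
  # frame-weighted mean of per-zone errors equals the session mean
  expect_equal(sum(rep$per_zone$mean_deg * rep$per_zone$n) / sum(rep$per_zone$n),
               rep$session_mean_deg, tolerance = 1e-12)
})

test_that("report writers and accessors emit the per-zone layout", {
  gaze <- make_gaze(c(120, 520), c(70, 370))
  truth <- make_truth(c(112, 512), c(60, 360), mark = c(1L, 5L))
  rep <- evaluate_session(gaze, truth)
  expect_equal(nrow(tidy(rep)), 2)
  expect_equal(glance(rep)$n_frames, 2)
  yml <- withr::local_tempfile(fileext = ".yaml")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(rep, yml, csv)
  doc <- yaml::read_yaml(yml)
  expect_equal(doc$session_mean_deg, rep$session_mean_deg, tolerance = 1e-6)
  tab <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(tab$mark, c("1", "5", "average"))
})

test_that("repeated use without re-wear stays near zero error and is reproducible", {
  cfg <- small_config()
  out <- repeated_use_protocol(cfg, n_sessions = 2L, rewear_offset_px = 0,
                               frames_per_point = 2L, frames_per_mark = 3L,
                               params = small_params())
  expect_equal(nrow(out$sessions), 3)   # baseline + 2 re-wears
  expect_true(all(out$sessions$mean_deg < 0.05))
  out2 <- repeated_use_protocol(cfg, n_sessions = 2L, rewear_offset_px = 0,
                                frames_per_point = 2L, frames_per_mark = 3L,
                                params = small_params())
  expect_identical(out$sessions, out2$sessions)
})

test_that("re-wear offsets raise the error but the model keeps tracking", {
  cfg <- small_config(jitter_sigma_px = 0.5, noise_sigma = 8, seed = 17)
  out <- repeated_use_protocol(cfg, n_sessions = 2L, rewear_offset_px = 1,
                               frames_per_point = 3L, frames_per_mark = 8L,
                               params = small_params())
  expect_gt(out$overall_mean_deg, out$baseline_mean_deg)
  # a 1 px pupil offset at this scale stays below ~1 degree of display error
  expect_lt(out$overall_mean_deg, 1)
})
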