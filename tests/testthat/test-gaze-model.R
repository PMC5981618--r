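# independent polynomial evaluation oracle (term-by-term, no shared code)
poly_eval_oracle <- function(k, x, y) {
  k[1] * x^2 + k[2] * y^2 + k[3] * x + k[4] * y + k[5] * x * y + k[6]
}

random_pairs <- function(seed, noise = 0) {
  set.seed(seed)
  kx <- c(runif(2, -1e-4, 1e-4), runif(1, 1.5, 3), runif(1, -0.3, 0.3),
          runif(1, -1e-4, 1e-4), runif(1, -50, 50))
  ky <- c(runif(2, -1e-4, 1e-4), runif(1, -0.3, 0.3), runif(1, 1.5, 3),
          runif(1, -1e-4, 1e-4), runif(1, -50, 50))
  ctr <- tidyr::expand_grid(x = c(150, 320, 490), y = c(130, 240, 350))
  tibble::tibble(
    x = ctr$x + rnorm(9, 0, noise), y = ctr$y + rnorm(9, 0, noise),
    target_x = poly_eval_oracle(kx, ctr$x, ctr$y),
    target_y = poly_eval_oracle(ky, ctr$x, ctr$y)
  )
}

test_that("least-squares fit matches an independent normal-equations solve", {
  for (seed in 1:10) {
    pairs <- random_pairs(seed, noise = 2)
    m <- fit_gaze_model(pairs)
    A <- cbind(pairs$x^2, pairs$y^2, pairs$x, pairs$y, pairs$x * pairs$y, 1)
    cx <- solve(crossprod(A), crossprod(A, pairs$target_x))
    cy <- solve(crossprod(A), crossprod(A, pairs$target_y))
    expect_lt(max(abs(m$coeffs_x - cx) / pmax(abs(cx), 1e-12)), 1e-8)
    expect_lt(max(abs(m$coeffs_y - cy) / pmax(abs(cy), 1e-12)), 1e-8)
  }
})

test_that("a quadratic truth is recovered exactly from noiseless pairs", {
  pairs <- random_pairs(3, noise = 0)
  m <- fit_gaze_model(pairs)
  pred <- predict_gaze(m, pairs$x, pairs$y)
  expect_lt(max(abs(pred$gaze_x - pairs$target_x)), 1e-6)
  expect_lt(max(abs(pred$gaze_y - pairs$target_y)), 1e-6)
  expect_lt(m$fit_residual_px, 1e-6)
})

test_that("an affine truth lies in the model span with negligible residual", {
  ctr <- tidyr::expand_grid(x = c(150, 320, 490), y = c(130, 240, 350))
  pairs <- tibble::tibble(x = ctr$x, y = ctr$y,
                          target_x = 2 * ctr$x + 0.1 * ctr$y + 30,
                          target_y = -0.2 * ctr$x + 1.8 * ctr$y - 12)
  m <- fit_gaze_model(pairs)
  expect_lt(m$fit_residual_px, 1e-6)
  A <- cbind(pairs$x^2, pairs$y^2, pairs$x, pairs$y, pairs$x * pairs$y, 1)
  cx <- solve(crossprod(A), crossprod(A, pairs$target_x))
  expect_lt(max(abs(m$coeffs_x - cx)), 1e-6)
})

test_that("underdetermined or degenerate designs are rejected with a diagnostic", {
  pairs <- random_pairs(1)[1:5, ]
  expect_error(fit_gaze_model(pairs), "at least 6")
  collinear <- tibble::tibble(x = seq(100, 400, length.out = 9),
                              y = 240,
                              target_x = seq(100, 900, length.out = 9),
                              target_y = 360)
  expect_error(fit_gaze_model(collinear), "rank-deficient")
})

test_that("prediction evaluates both polynomials (constant map; random oracle)", {
  const <- structure(list(
    coeffs_x = setNames(c(0, 0, 0, 0, 0, 512), letters[1:6]),
    coeffs_y = setNames(c(0, 0, 0, 0, 0, 360), letters[7:12]),
    geometry = display_geometry(), fit_residual_px = 0, n_pairs = 9,
    condition_number = 1), class = "gaze_model")
  p <- predict_gaze(const, c(0, 123.4, 600), c(0, 77.7, 480))
  expect_equal(p$gaze_x, rep(512, 3))
  expect_equal(p$gaze_y, rep(360, 3))

  set.seed(9)
  for (i in 1:10) {
    kx <- runif(6, -1, 1); ky <- runif(6, -1, 1)
    mdl <- structure(list(coeffs_x = kx, coeffs_y = ky,
                          geometry = display_geometry(),
                          fit_residual_px = 0, n_pairs = 9,
                          condition_number = 1), class = "gaze_model")
    x <- runif(1, 0, 640); y <- runif(1, 0, 480)
    p <- predict_gaze(mdl, x, y)
    expect_equal(p$gaze_x, poly_eval_oracle(kx, x, y), tolerance = 1e-12)
    expect_equal(p$gaze_y, poly_eval_oracle(ky, x, y), tolerance = 1e-12)
  }
})

test_that("tidy and glance expose the twelve coefficients and fit stats", {
  m <- fit_gaze_model(random_pairs(5))
  td <- tidy(m)
  expect_equal(nrow(td), 12)
  expect_equal(td$coefficient, letters[1:12])
  expect_equal(glance(m)$n_pairs, 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_gaze_model(m, path)
  back <- read_gaze_model(path)
  expect_equal(unname(back$coeffs_x), unname(m$coeffs_x), tolerance = 1e-9)
})

test_that("model-level parameter recovery under jitter stays within the error budget", {
  cfg <- scene_config(seed = 1)
  marks <- default_mark_layout()
  # observation-level calibration: mean of 60 jittered centers per mark
  obs <- simulate_observations(cfg$map, marks[rep(1:9, each = 60), c("x", "y")],
                               sigma_x = 1, seed = 2)
  obs$mark <- rep(1:9, each = 60)
  zones <- dplyr::summarise(dplyr::group_by(obs, mark),
                            x = mean(pupil_x), y = mean(pupil_y),
                            .groups = "drop")
  pairs <- dplyr::mutate(zones, target_x = marks$x, target_y = marks$y)
  m <- fit_gaze_model(pairs)
  grid <- tidyr::expand_grid(x = seq(112, 924, length.out = 5),
                             y = seq(60, 660, length.out = 5))
  test_obs <- simulate_observations(cfg$map, grid[rep(1:25, each = 20), ],
                                    sigma_x = 1, seed = 3)
  pred <- predict_gaze(m, test_obs$pupil_x, test_obs$pupil_y)
  truth <- grid[rep(1:25, each = 20), ]
  err <- angular_error_deg(pred$gaze_x, pred$gaze_y, truth$x, truth$y)
  expect_lt(mean(err), 0.53)
})

test_that("mean angular error degrades monotonically with jitter", {
  cfg <- scene_config(seed = 1)
  marks <- default_mark_layout()
  grid <- tidyr::expand_grid(x = seq(112, 924, length.out = 5),
                             y = seq(60, 660, length.out = 5))
  mean_err <- sapply(c(0, 1, 2, 4), function(sigma) {
    runs <- sapply(1:10, function(run) {
      obs <- simulate_observations(cfg$map, marks[rep(1:9, each = 30), c("x", "y")],
                                   sigma_x = sigma, seed = 100 * run + 1)
      obs$mark <- rep(1:9, each = 30)
      zones <- dplyr::summarise(dplyr::group_by(obs, mark),
                                x = mean(pupil_x), y = mean(pupil_y),
                                .groups = "drop")
      m <- fit_gaze_model(dplyr::mutate(zones, target_x = marks$x,
                                        target_y = marks$y))
      tob <- simulate_observations(cfg$map, grid[rep(1:25, each = 8), ],
                                   sigma_x = sigma, seed = 100 * run + 2)
      pred <- predict_gaze(m, tob$pupil_x, tob$pupil_y)
      truth <- grid[rep(1:25, each = 8), ]
      mean(angular_error_deg(pred$gaze_x, pred$gaze_y, truth$x, truth$y))
    })
    mean(runs)
  })
  expect_true(all(diff(mean_err) >= 0))
})

test_that("horizontal error stays at or below vertical under larger vertical noise", {
  cfg <- scene_config(seed = 1)
  marks <- default_mark_layout()
  grid <- tidyr::expand_grid(x = seq(112, 924, length.out = 5),
                             y = seq(60, 660, length.out = 5))
  obs <- simulate_observations(cfg$map, marks[rep(1:9, each = 30), c("x", "y")],
                               sigma_x = 0.5, sigma_y = 2, seed = 5)
  obs$mark <- rep(1:9, each = 30)
  zones <- dplyr::summarise(dplyr::group_by(obs, mark),
                            x = mean(pupil_x), y = mean(pupil_y),
                            .groups = "drop")
  m <- fit_gaze_model(dplyr::mutate(zones, target_x = marks$x,
                                    target_y = marks$y))
  tob <- simulate_observations(cfg$map, grid[rep(1:25, each = 20), ],
                               sigma_x = 0.5, sigma_y = 2, seed = 6)
  pred <- predict_gaze(m, tob$pupil_x, tob$pupil_y)
  truth <- grid[rep(1:25, each = 20), ]
  geo <- display_geometry()
  h_err <- mean(atan2(abs(pred$gaze_x - truth$x) * geo$width_cm / geo$width_px,
                      geo$viewing_distance_cm) * 180 / pi)
  v_err <- mean(atan2(abs(pred$gaze_y - truth$y) * geo$height_cm / geo$height_px,
                      geo$viewing_distance_cm) * 180 / pi)
  expect_lte(h_err, v_err)
})

test_that("estimate gates blinks, checks zone consistency, keeps the fine point", {
  cal <- manual_calibration(mcp_x = rep(c(100, 200, 300), 3),
                            mcp_y = rep(c(100, 200, 300), each = 3))
  marks <- default_mark_layout()
  # identity-ish model mapping centers straight to mark positions
  pairs <- dplyr::mutate(dplyr::select(cal$zones, mark, x = mcp_x, y = mcp_y),
                         target_x = marks$x, target_y = marks$y)
  m <- fit_gaze_model(pairs)
  obs <- tibble::tibble(frame = 1:2,
                        pupil_x = c(100, NA), pupil_y = c(100, NA),
                        quality = c(1, 0), blink = c(FALSE, TRUE))
  est <- estimate_from_observations(obs, cal, m, marks)
  expect_equal(est$confidence, c("ok", "blink"))
  expect_true(is.na(est$gaze_x[2]))
  expect_equal(est$gaze_x[1], 112, tolerance = 1e-6)
  expect_equal(est$coarse_zone, c("1", "blink"))

  # adversarial: coarse says zone 1 (nearest MC'), fine point lands in zone 2
  bad_cal <- manual_calibration(mcp_x = c(105, 400, rep(c(100, 200, 300), 3)[3:9]),
                                mcp_y = rep(c(100, 200, 300), each = 3))
  obs2 <- tibble::tibble(frame = 1L, pupil_x = 200, pupil_y = 100,
                         quality = 1, blink = FALSE)
  est2 <- estimate_from_observations(obs2, bad_cal, m, marks)
  expect_equal(est2$coarse_zone, "1")          # nearest MC' is zone 1 (105 vs 400)
  expect_equal(est2$confidence, "zone_mismatch")
  expect_false(is.na(est2$gaze_x))             # fine point retained
})

test_that("end-to-end: a noiseless frame at mark 5 maps back to mark 5", {
  cfg <- small_config()
  sess <- simulate_calibration_session(cfg, frames_per_mark = 3L)
  obs <- detect_pupils(sess, small_params())
  cal <- calibrate(obs, sess$manifest)
  m <- fit_gaze_model(calibration_pairs(cal))
  fr <- render_frame(cfg, 512, 360)
  est <- estimate(fr, cal, m, params = small_params())
  expect_equal(est$confidence, "ok")
  expect_lt(abs(est$gaze_x - 512), 5)
  expect_lt(abs(est$gaze_y - 360), 5)
  expect_equal(est$coarse_zone, "5")
})
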