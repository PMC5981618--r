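# Small-frame scene used by most unit tests: 160 x 120 px frames with the
# canonical gaze-to-pupil map scaled down 4x, pupil radius 8. Keeps
# per-frame rendering/detection around 5 ms.

small_config <- function(jitter_sigma_px = 0, blink_prob = 0,
                         noise_sigma = 0, seed = 1L, ...) {
  base <- true_map()
  scene_config(frame_width = 160L, frame_height = 120L,
               map = true_map(base$px * 0.25, base$py * 0.25),
               pupil_radius_px = 8, iris_radius_px = 24,
               jitter_sigma_px = jitter_sigma_px, blink_prob = blink_prob,
               noise_sigma = noise_sigma, seed = seed, ...)
}

small_params <- function(...) detect_params(pupil_radius_px = 8, ...)

# place the pupil at an exact image position: identity gaze->pupil map
identity_config <- function(pupil_radius_px = 30, noise_sigma = 0, ...) {
  scene_config(map = true_map(c(0, 0, 1, 0, 0, 0), c(0, 0, 0, 1, 0, 0)),
               pupil_radius_px = pupil_radius_px, jitter_sigma_px = 0,
               blink_prob = 0, noise_sigma = noise_sigma, ...)
}

# calibration set built directly from given mean centers (bypasses detection)
manual_calibration <- function(mcp_x, mcp_y, marks = 1:9) {
  structure(list(
    zones = tibble::tibble(mark = marks, mc_x = mcp_x, mc_y = mcp_y,
                           mcp_x = mcp_x, mcp_y = mcp_y, T = 10,
                           n_kept = 1L, n_rejected = 0L),
    samples = tibble::tibble(mark = marks, frame = marks,
                             x = mcp_x, y = mcp_y),
    n_blinks_excluded = 0L
  ), class = "calibration_set")
}

# observation-level simulator: pupil centers from the true map plus noise,
# no rendering/detection. Used for model-level properties.
simulate_observations <- function(map, gaze, sigma_x, sigma_y = sigma_x,
                                  seed = 1L) {
  ctr <- eval_true_map(map, gaze$x, gaze$y)
  n <- nrow(gaze)
  set.seed(seed)
  tibble::tibble(
    frame = seq_len(n),
    pupil_x = ctr$px + rnorm(n, 0, sigma_x),
    pupil_y = ctr$py + rnorm(n, 0, sigma_y),
    quality = 1, blink = FALSE
  )
}
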