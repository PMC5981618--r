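#' Ground-truth quadratic gaze-to-pupil map
#'
#' The simulator relates the gaze point on the display to the pupil center
#' in the eye-camera image through a smooth, mildly non-linear quadratic
#' map. Each image coordinate is a second-order polynomial in the display
#' coordinates over the basis (x^2, y^2, x, y, x*y, 1) — the same basis the
#' calibration-time gaze model uses in the opposite direction, so that
#' model fitting is a well-posed recovery problem.
#'
#' @param coeffs_px,coeffs_py Numeric length-6 coefficient vectors for the
#'   pupil x and y coordinate, over (gx^2, gy^2, gx, gy, gx*gy, 1).
#' @return An object of class `true_map`.
#' @export
true_map <- function(coeffs_px = c(1.2e-5, 0, 0.42, 0.03, 6e-6, 90),
                     coeffs_py = c(0, 1.0e-5, 0.02, 0.42, 6e-6, 60)) {
  stopifnot(length(coeffs_px) == 6, length(coeffs_py) == 6,
            all(is.finite(c(coeffs_px, coeffs_py))))
  structure(list(px = as.numeric(coeffs_px), py = as.numeric(coeffs_py)),
            class = "true_map")
}

#' @rdname true_map
#' @param map A `true_map`.
#' @param gx,gy Gaze position in display pixels (vectorised).
#' @return `eval_true_map()`: a tibble with pupil-center columns `px`, `py`.
#' @export
eval_true_map <- function(map, gx, gy) {
  basis <- cbind(gx^2, gy^2, gx, gy, gx * gy, 1)
  tibble::tibble(
    px = as.numeric(basis %*% map$px),
    py = as.numeric(basis %*% map$py)
  )
}

#' @rdname true_map
#' @param seed Integer seed; each seed gives a distinct "subject" whose
#'   affine terms are perturbed by a few percent and whose quadratic terms
#'   vary around the defaults, emulating between-subject differences in
#'   eyeball geometry and camera placement.
#' @param scale Multiplier applied to the frame-coordinate range (use < 1
#'   for small test frames).
#' @export
random_true_map <- function(seed, scale = 1) {
  base <- true_map()
  u <- with_local_seed(seed, stats::runif(10, -1, 1))
  # linear gains vary by 5%, quadratic/cross terms by 20%, offsets by 10 px
  px <- base$px * (1 + c(0.2 * u[1], 0, 0.05 * u[2], 0.2 * u[3], 0.2 * u[4], 0))
  py <- base$py * (1 + c(0, 0.2 * u[5], 0.2 * u[6], 0.05 * u[7], 0.2 * u[8], 0))
  px[6] <- base$px[6] + 10 * u[9]
  py[6] <- base$py[6] + 10 * u[10]
  true_map(px * scale, py * scale)
}

#' Scene configuration for the synthetic eye renderer
#'
#' Defines everything the renderer needs: frame size, the ground-truth
#' gaze-to-pupil map, pupil size, the magnitude of per-frame nystagmus
#' jitter, the per-frame blink probability, glints, intensity palette,
#' additive noise, and the RNG seed. Identical configurations and seeds
#' produce bit-identical sessions.
#'
#' @param frame_width,frame_height Eye-camera frame size in px (default
#'   640 x 480).
#' @param map A [true_map()]; defaults to the canonical map for the frame
#'   size (scaled for smaller frames).
#' @param pupil_radius_px Nominal pupil semi-major axis in px.
#' @param jitter_sigma_px Std. dev. (px, per axis) of the Gaussian
#'   per-frame jitter of the pupil center, emulating fixational nystagmus.
#' @param blink_prob Per-frame probability that the frame is a blink.
#' @param glint_count Number of corneal-glint disks (0, 1 or 2).
#' @param noise_sigma Std. dev. of additive Gaussian intensity noise
#'   (8-bit counts).
#' @param palette Named intensities (0-255) for `sclera`, `iris`, `pupil`,
#'   `glint`, `eyelid`.
#' @param iris_radius_px Iris disk radius in px.
#' @param seed Integer RNG seed.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(frame_width = 640L, frame_height = 480L,
                         map = NULL,
                         pupil_radius_px = 30,
                         jitter_sigma_px = 1,
                         blink_prob = 0.05,
                         glint_count = 2L,
                         noise_sigma = 8,
                         palette = c(sclera = 200, iris = 120, pupil = 20,
                                     glint = 250, eyelid = 160),
                         iris_radius_px = 3 * pupil_radius_px,
                         seed = 1L) {
  if (is.null(map)) map <- true_map(true_map()$px * frame_width / 640,
                                    true_map()$py * frame_height / 480)
  stopifnot(jitter_sigma_px >= 0, blink_prob >= 0, blink_prob <= 1,
            pupil_radius_px > 0, noise_sigma >= 0,
            all(c("sclera", "iris", "pupil", "glint", "eyelid") %in% names(palette)))
  structure(list(
    frame_width = as.integer(frame_width), frame_height = as.integer(frame_height),
    map = map, pupil_radius_px = pupil_radius_px,
    jitter_sigma_px = jitter_sigma_px, blink_prob = blink_prob,
    glint_count = as.integer(glint_count), noise_sigma = noise_sigma,
    palette = palette, iris_radius_px = iris_radius_px,
    seed = as.integer(seed)
  ), class = "scene_config")
}

# run code under a private RNG stream without touching the caller's state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  code
}

# fill a disk of given value into an image sub-window (in place)
draw_disk <- function(img, cx, cy, r, value) {
  h <- nrow(img); w <- ncol(img)
  rows <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
  if (!length(rows) || !length(cols)) return(img)
  dy <- rows - cy; dx <- cols - cx
  inside <- outer(dy^2, dx^2, `+`) <= r^2
  sub <- img[rows, cols]
  sub[inside] <- value
  img[rows, cols] <- sub
  img
}

#' Render one synthetic near-eye infrared frame
#'
#' Renders a dark pupil on a brighter iris/sclera background with bright
#' corneal glints, optional additive noise, and (for blinks) an eyelid band
#' that occludes at least 80% of the pupil. The pupil is drawn as a filled
#' ellipse whose minor axis shrinks with eccentricity from the frame center
#' (perspective foreshortening of an off-axis pupil), oriented radially.
#'
#' @param config A [scene_config()].
#' @param gx,gy Gaze position in display pixels; must lie inside the
#'   display rectangle of `geometry`.
#' @param blink Logical: render this frame as a blink?
#' @param seed RNG seed for this frame (jitter + noise); defaults to the
#'   config seed.
#' @param geometry The [display_geometry()] that bounds valid gaze points.
#' @return An `eye_frame`: a list with `image` (numeric matrix, rows = y,
#'   0-255 integers) and `truth` (one-row tibble: `gaze_x`, `gaze_y`,
#'   `pupil_x`, `pupil_y`, `blink`).
#' @export
render_frame <- function(config, gx, gy, blink = FALSE, seed = config$seed,
                         geometry = display_geometry()) {
  if (gx < 0 || gx > geometry$width_px || gy < 0 || gy > geometry$height_px) {
    rlang::abort(sprintf("gaze (%g, %g) lies outside the display", gx, gy))
  }
  with_local_seed(seed, {
    w <- config$frame_width; h <- config$frame_height
    pal <- config$palette
    ctr <- eval_true_map(config$map, gx, gy)
    jit <- if (config$jitter_sigma_px > 0) stats::rnorm(2, 0, config$jitter_sigma_px) else c(0, 0)
    cx <- ctr$px + jit[1]; cy <- ctr$py + jit[2]

    img <- matrix(pal[["sclera"]], h, w)
    img <- draw_disk(img, cx, cy, config$iris_radius_px, pal[["iris"]])

    # foreshortened pupil: minor axis shrinks with distance from frame center,
    # minor direction radial
    ecc <- sqrt((cx - w / 2)^2 + (cy - h / 2)^2) / sqrt((w / 2)^2 + (h / 2)^2)
    a <- config$pupil_radius_px
    b <- a * (1 - 0.15 * ecc)
    theta <- atan2(cy - h / 2, cx - w / 2)
    rows <- max(1, floor(cy - a)):min(h, ceiling(cy + a))
    cols <- max(1, floor(cx - a)):min(w, ceiling(cx + a))
    dy <- rows - cy; dx <- cols - cx
    U <- outer(dy * sin(theta), dx * cos(theta), `+`)      # radial component
    V <- outer(dy * cos(theta), -dx * sin(theta), `+`)     # tangential component
    inside <- (U / b)^2 + (V / a)^2 <= 1
    sub <- img[rows, cols]; sub[inside] <- pal[["pupil"]]
    img[rows, cols] <- sub

    if (config$glint_count >= 1) {
      img <- draw_disk(img, cx + 0.4 * a, cy - 0.33 * a, max(2, a / 10), pal[["glint"]])
    }
    if (config$glint_count >= 2) {
      img <- draw_disk(img, cx - 0.47 * a, cy + 0.27 * a, max(2, a / 10), pal[["glint"]])
    }

    if (blink) {
      # eyelid band from the frame top down to 0.8 of the pupil's semi-minor
      # axis below center: occludes >= 95% of the pupil area
      lid_to <- min(h, ceiling(cy + 0.8 * b))
      img[1:lid_to, ] <- pal[["eyelid"]]
    }

    if (config$noise_sigma > 0) {
      img <- img + stats::rnorm(h * w, 0, config$noise_sigma)
    }
    # quantize to 8-bit (round-half-up, then clamp) in integer arithmetic
    img <- as.integer(img + 0.5)
    img[img < 0L] <- 0L
    img[img > 255L] <- 255L
    dim(img) <- c(h, w)

    structure(list(
      image = img,
      truth = tibble::tibble(gaze_x = gx, gaze_y = gy,
                             pupil_x = cx, pupil_y = cy, blink = blink)
    ), class = "eye_frame")
  })
}

new_session <- function(frames, manifest, config) {
  structure(list(frames = frames, manifest = manifest, config = config),
            class = "eye_session")
}

#' @export
print.eye_session <- function(x, ...) {
  cat(sprintf("<eye_session> %d frames (%d blink), %d x %d px\n",
              nrow(x$manifest), sum(x$manifest$blink),
              x$config$frame_width, x$config$frame_height))
  invisible(x)
}

# Iterate the frames of a session without requiring them to be kept:
# fn(eye_frame, i) is called per frame and its results collected. Seeding
# is identical whether frames are materialized or streamed.
session_scan <- function(config, gaze, mark_index, blink, geometry, fn) {
  n <- nrow(gaze)
  seeds <- with_local_seed(config$seed, sample.int(2147483646L, n + 1L))
  if (is.null(blink)) {
    blink <- with_local_seed(seeds[n + 1L],
                             stats::runif(n) < config$blink_prob)
  }
  results <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- render_frame(config, gaze$x[i], gaze$y[i], blink = blink[i],
                       seed = seeds[i], geometry = geometry)
    results[[i]] <- fn(fr, i)
    truth[[i]] <- fr$truth
  }
  truth <- dplyr::bind_rows(truth)
  manifest <- tibble::tibble(
    frame = seq_len(n),
    frame_path = NA_character_,
    timestamp_ms = (seq_len(n) - 1) * 1000 / 60,
    mark_index = mark_index,
    true_gaze_x = truth$gaze_x, true_gaze_y = truth$gaze_y,
    true_pupil_x = truth$pupil_x, true_pupil_y = truth$pupil_y,
    blink = as.integer(truth$blink)
  )
  list(manifest = manifest, results = results)
}

render_session <- function(config, gaze, mark_index, blink, geometry) {
  out <- session_scan(config, gaze, mark_index, blink, geometry,
                      function(fr, i) fr$image)
  new_session(out$results, out$manifest, config)
}

#' Simulate a nine-mark calibration session
#'
#' For each calibration mark, renders `frames_per_mark` frames at that
#' gaze position with independent jitter and blink draws (emulating a 2 s
#' fixation per mark at 60 frames recorded).
#'
#' @param config A [scene_config()].
#' @param marks Mark layout tibble (`mark`, `x`, `y`); default
#'   [default_mark_layout()].
#' @param frames_per_mark Frames rendered per mark (default 60).
#' @param geometry Display geometry bounding the gaze.
#' @return An `eye_session`: list with `frames` (list of matrices),
#'   `manifest` (tibble), `config`.
#' @export
simulate_calibration_session <- function(config, marks = default_mark_layout(),
                                         frames_per_mark = 60L,
                                         geometry = display_geometry()) {
  if (nrow(marks) == 0) rlang::abort("marks must be non-empty")
  gaze <- marks[rep(seq_len(nrow(marks)), each = frames_per_mark), c("x", "y")]
  mark_index <- rep(marks$mark, each = frames_per_mark)
  render_session(config, gaze, mark_index, blink = NULL, geometry)
}

#' Simulate a free-gaze tracking session
#'
#' Renders one frame per gaze-path point, with truth recorded in the
#' manifest (mark_index is NA for free gaze).
#'
#' @inheritParams simulate_calibration_session
#' @param gaze_path Tibble/data frame with columns `x`, `y` (display px).
#' @export
simulate_tracking_session <- function(config, gaze_path,
                                      geometry = display_geometry()) {
  gaze_path <- tibble::as_tibble(gaze_path)
  if (nrow(gaze_path) == 0) {
    return(new_session(list(), tibble::tibble(
      frame = integer(), frame_path = character(), timestamp_ms = numeric(),
      mark_index = integer(), true_gaze_x = numeric(), true_gaze_y = numeric(),
      true_pupil_x = numeric(), true_pupil_y = numeric(), blink = integer()
    ), config))
  }
  render_session(config, gaze_path[, c("x", "y")],
                 mark_index = rep(NA_integer_, nrow(gaze_path)),
                 blink = NULL, geometry)
}

#' Write / read a session as PNG frames plus a CSV manifest
#'
#' Frames are written as 8-bit grayscale PNGs (`frame_000123.png`) and the
#' manifest as `manifest.csv` with the frame paths filled in.
#'
#' @param session An `eye_session`.
#' @param dir Output directory (created if needed).
#' @return `write_session()`: the manifest (invisibly);
#'   `read_session()`: an `eye_session` (config slot carries only frame size).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("frame_%06d.png", session$manifest$frame))
  for (i in seq_along(session$frames)) {
    png::writePNG(session$frames[[i]] / 255, paths[i])
  }
  manifest <- dplyr::mutate(session$manifest, frame_path = basename(paths))
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  frames <- lapply(manifest$frame_path, function(p) {
    img <- png::readPNG(file.path(dir, p))
    if (length(dim(img)) == 3) img <- img[, , 1]
    round(img * 255)
  })
  cfg <- scene_config(frame_width = ncol(frames[[1]]),
                      frame_height = nrow(frames[[1]]))
  new_session(frames, manifest, cfg)
}
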