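#' Parameters of the pupil detector
#'
#' @param pupil_radius_px Expected nominal pupil semi-axis (px); sets the
#'   minimum usable frame size and the blink area reference.
#' @param blur_sigma Gaussian smoothing sigma (px) applied to the pupil
#'   region before edge extraction; defaults to `pupil_radius_px / 15`
#'   (clamped to \[0.5, 3\]) so smoothing scales with the feature size.
#' @param area_min_frac Blink threshold: a frame is a blink when the dark
#'   pupil area falls below this fraction of the reference pupil area.
#' @param q_min Blink threshold on the ellipse-fit inlier fraction.
#' @param area_ref Reference pupil area in px^2; defaults to
#'   `pi * pupil_radius_px^2`. Calibration can substitute the median
#'   detected area of the session.
#' @param ransac_iter,inlier_tol Consensus-fit settings: number of random
#'   5-point subsets and the inlier distance in px.
#' @param seed Fixed internal seed of the consensus fit (reproducibility).
#' @return A list of class `detect_params`.
#' @export
detect_params <- function(pupil_radius_px = 30, blur_sigma = NULL,
                          area_min_frac = 0.5, q_min = 0.4,
                          area_ref = NULL,
                          ransac_iter = 60L, inlier_tol = 1.5, seed = 42L) {
  if (is.null(blur_sigma)) blur_sigma <- min(3, max(0.5, pupil_radius_px / 15))
  if (is.null(area_ref)) area_ref <- pi * pupil_radius_px^2
  structure(list(pupil_radius_px = pupil_radius_px, blur_sigma = blur_sigma,
                 area_min_frac = area_min_frac, q_min = q_min,
                 area_ref = area_ref, ransac_iter = as.integer(ransac_iter),
                 inlier_tol = inlier_tol, seed = as.integer(seed)),
            class = "detect_params")
}

# adaptive dark threshold: pupil is the darkest structure; clamp guards
# against degenerate histograms. Quantiles come from the 8-bit histogram
# (O(n) tabulate) rather than a sort.
dark_threshold <- function(img) {
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  cs <- cumsum(counts)
  n <- cs[256]
  lo <- which(cs >= 0.002 * n)[1] - 1L
  med <- which(cs >= 0.5 * n)[1] - 1L
  min(90, max(40, lo + 0.3 * (med - lo)))
}

# separable Gaussian blur of a (small) matrix
blur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(2 * sigma))
  k <- stats::dnorm(-r:r, 0, sigma); k <- k / sum(k)
  a <- stats::filter(m, k, sides = 2)
  a[is.na(a)] <- m[is.na(a)]
  b <- t(stats::filter(t(a), k, sides = 2))
  b[is.na(b)] <- a[is.na(b)]
  matrix(b, nrow(m), ncol(m))
}

# boundary pixels of a logical mask (mask & not 4-neighbour-interior)
mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  up <- rbind(mask[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, mask[-h, , drop = FALSE])
  lf <- cbind(mask[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, mask[, -w, drop = FALSE])
  mask & !(up & dn & lf & rt)
}

blank_observation <- function() {
  tibble::tibble(pupil_x = NA_real_, pupil_y = NA_real_,
                 semi_major = NA_real_, semi_minor = NA_real_,
                 angle = NA_real_, area_px = 0, quality = 0, blink = TRUE)
}

#' Detect the pupil center in one near-eye frame
#'
#' Pipeline: adaptive dark thresholding and connected-component labelling
#' locate the pupil as the largest dark region; the region is smoothed,
#' re-thresholded and its boundary pixels extracted; a consensus
#' (RANSAC-style) ellipse fit with least-squares refinement on the inliers
#' gives the sub-pixel center. Glint disks and stray edge points are
#' rejected by the consensus step. Quality is the final inlier fraction of
#' the edge points; the blink flag comes from [blink_test()].
#'
#' @param frame An `eye_frame` or a plain numeric matrix (0-255, rows = y).
#' @param params A [detect_params()].
#' @return A one-row tibble: `pupil_x`, `pupil_y`, `semi_major`,
#'   `semi_minor`, `angle`, `area_px`, `quality`, `blink`.
#' @export
detect_pupil <- function(frame, params = detect_params()) {
  img <- if (inherits(frame, "eye_frame")) frame$image else frame
  if (!is.matrix(img) || length(img) == 0) {
    rlang::abort("frame must be a non-empty single-channel matrix")
  }
  if (min(dim(img)) < 4 * params$pupil_radius_px) {
    rlang::abort(sprintf(
      "frame (%d x %d) smaller than twice the expected pupil diameter (%g px)",
      ncol(img), nrow(img), 2 * params$pupil_radius_px))
  }

  # coarse dark-region localization on a strided subsample (the pupil is
  # far larger than the stride, so the bounding box survives subsampling)
  stride <- max(1L, min(dim(img)) %/% 160L)
  sub <- img[seq(1, nrow(img), stride), seq(1, ncol(img), stride), drop = FALSE]
  thr <- dark_threshold(sub)
  mask <- sub < thr
  if (!any(mask)) return(blank_observation())

  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0L])
  main <- which.max(sizes)
  if (sizes[main] * stride^2 < 9) return(blank_observation())

  idx <- which(lab == main, arr.ind = TRUE)
  r0 <- (range(idx[, 1]) - 1L) * stride + 1L
  c0 <- (range(idx[, 2]) - 1L) * stride + 1L
  m <- ceiling(3 * params$blur_sigma) + 2L + stride
  rows <- max(1, r0[1] - m):min(nrow(img), r0[2] + m)
  cols <- max(1, c0[1] - m):min(ncol(img), c0[2] + m)

  roi <- blur_mat(img[rows, cols], params$blur_sigma)
  roi_mask <- roi < thr
  # keep only the main component inside the ROI
  roi_lab <- EBImage::bwlabel(roi_mask)
  roi_sizes <- tabulate(roi_lab[roi_lab > 0L])
  if (!length(roi_sizes)) return(blank_observation())
  roi_mask <- roi_lab == which.max(roi_sizes)
  area <- sum(roi_mask)
  # fill glint holes so only the outer pupil contour reaches the fit
  roi_mask <- EBImage::fillHull(roi_mask) > 0

  bnd <- which(mask_boundary(roi_mask), arr.ind = TRUE)
  # x = column, y = row, in full-frame coordinates
  ex <- bnd[, 2] + cols[1] - 1
  ey <- bnd[, 1] + rows[1] - 1

  el <- fit_ellipse_robust(ex, ey, n_iter = params$ransac_iter,
                           inlier_tol = params$inlier_tol, seed = params$seed)
  if (is.null(el)) {
    obs <- blank_observation()
    obs$area_px <- area
    obs$blink <- TRUE
    return(obs)
  }
  blink <- blink_test(area, el$quality, params)
  tibble::tibble(pupil_x = el$cx, pupil_y = el$cy,
                 semi_major = el$a, semi_minor = el$b, angle = el$theta,
                 area_px = area, quality = el$quality, blink = blink)
}

#' Blink test from dark area and fit quality
#'
#' A frame is declared a blink when the dark pupil area falls below
#' `area_min_frac * area_ref` (the eyelid has occluded the pupil) or when
#' the ellipse-fit inlier fraction falls below `q_min` (no coherent
#' elliptical boundary).
#'
#' @param area_px Dark-region area in px^2.
#' @param quality Ellipse-fit inlier fraction in \[0, 1\].
#' @param params A [detect_params()].
#' @return Logical.
#' @export
blink_test <- function(area_px, quality, params = detect_params()) {
  area_px < params$area_min_frac * params$area_ref || quality < params$q_min
}

#' Render and detect a synthetic session frame by frame
#'
#' Streams a synthetic session through the detector: each frame is
#' rendered, detected, and discarded, so arbitrarily long sessions run in
#' constant memory. Seeding matches [simulate_calibration_session()] /
#' [simulate_tracking_session()]: the same config yields the same frames.
#'
#' @param config A [scene_config()].
#' @param gaze Tibble with display-gaze columns `x`, `y`, one row per
#'   frame.
#' @param mark_index Optional mark labels per frame (recycled).
#' @param geometry Display geometry.
#' @param params A [detect_params()].
#' @return A list: `manifest` (truth tibble) and `observations` (the
#'   [detect_pupils()] tibble).
#' @export
simulate_and_detect <- function(config, gaze, mark_index = NA_integer_,
                                geometry = display_geometry(),
                                params = detect_params()) {
  gaze <- tibble::as_tibble(gaze)
  mark_index <- rep(mark_index, length.out = nrow(gaze))
  out <- session_scan(config, gaze, mark_index, NULL, geometry,
                      function(fr, i) detect_pupil(fr$image, params))
  obs <- dplyr::bind_cols(tibble::tibble(frame = out$manifest$frame),
                          dplyr::bind_rows(out$results))
  list(manifest = out$manifest, observations = obs)
}

#' Detect pupils over a whole session
#'
#' Runs [detect_pupil()] on every frame of an `eye_session` and returns the
#' observations joined to the frame ids.
#'
#' @param session An `eye_session`.
#' @param params A [detect_params()].
#' @return A tibble with one row per frame: `frame`, plus the
#'   [detect_pupil()] columns.
#' @export
detect_pupils <- function(session, params = detect_params()) {
  obs <- purrr::map(session$frames, detect_pupil, params = params)
  dplyr::bind_cols(
    tibble::tibble(frame = session$manifest$frame),
    dplyr::bind_rows(obs)
  )
}
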