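quad_basis <- function(x, y) cbind(x^2, y^2, x, y, x * y, 1)

#' Fit the second-order pupil-to-display gaze mapping
#'
#' Fits, for each display axis, a second-order polynomial in the pupil
#' center coordinates
#' `D(x) = a*x^2 + b*y^2 + c*x + d*y + e*x*y + f` (and `g..l` for D(y))
#' by ordinary least squares over the calibration pairs: the filtered mean
#' pupil centers MC' against the known display positions of the marks.
#' With the default nine-mark layout this solves two 9-equation, 6-unknown
#' systems.
#'
#' @param pairs Tibble with pupil-center columns `x`, `y` and display
#'   target columns `target_x`, `target_y`; at least 6 rows. A
#'   `calibration_set` plus `marks` may be given instead.
#' @param geometry The [display_geometry()] the targets live in.
#' @return A `gaze_model`: list with `coeffs_x` (named a..f), `coeffs_y`
#'   (named g..l), `geometry`, `fit_residual_px` (RMS residual over the
#'   pairs), `n_pairs`, `condition_number`.
#' @export
fit_gaze_model <- function(pairs, geometry = display_geometry()) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) < 6) {
    rlang::abort(sprintf(
      "need at least 6 calibration pairs to fit 6 coefficients per axis, got %d",
      nrow(pairs)))
  }
  A <- quad_basis(pairs$x, pairs$y)
  qrA <- qr(A)
  if (qrA$rank < 6) {
    dropped <- c("x^2", "y^2", "x", "y", "x*y", "1")[-qrA$pivot[seq_len(qrA$rank)]]
    rlang::abort(sprintf(
      "rank-deficient design (rank %d of 6): pupil centers are degenerate in term(s) %s",
      qrA$rank, paste(dropped, collapse = ", ")))
  }
  kappa_A <- kappa(A, exact = TRUE)
  if (kappa_A > 1e8) {
    rlang::inform(sprintf(
      "gaze-model design matrix is ill-conditioned (condition number %.3g)",
      kappa_A))
  }
  cx <- qr.coef(qrA, pairs$target_x)
  cy <- qr.coef(qrA, pairs$target_y)
  pred <- A %*% cbind(cx, cy)
  res <- sqrt(mean((pred[, 1] - pairs$target_x)^2 +
                     (pred[, 2] - pairs$target_y)^2))
  structure(list(
    coeffs_x = stats::setNames(as.numeric(cx), letters[1:6]),
    coeffs_y = stats::setNames(as.numeric(cy), letters[7:12]),
    geometry = geometry, fit_residual_px = res,
    n_pairs = nrow(pairs), condition_number = kappa_A
  ), class = "gaze_model")
}

#' Pair a calibration set with its mark layout
#'
#' @param cal A `calibration_set`.
#' @param marks Mark layout (`mark`, `x`, `y`); default
#'   [default_mark_layout()].
#' @return A tibble suitable for [fit_gaze_model()].
#' @export
calibration_pairs <- function(cal, marks = default_mark_layout()) {
  dplyr::inner_join(
    dplyr::select(cal$zones, "mark", x = "mcp_x", y = "mcp_y"),
    dplyr::select(marks, "mark", target_x = "x", target_y = "y"),
    by = "mark"
  )
}

#' Predict display gaze positions from pupil centers
#'
#' Evaluates both fitted polynomials at the given pupil centers. Results
#' are not clamped to the display: out-of-display predictions are legal
#' and flagged downstream.
#'
#' @param model A `gaze_model`.
#' @param x,y Pupil-center coordinates (image px, vectorised).
#' @return A tibble with columns `gaze_x`, `gaze_y`.
#' @export
predict_gaze <- function(model, x, y) {
  A <- quad_basis(x, y)
  tibble::tibble(gaze_x = as.numeric(A %*% model$coeffs_x),
                 gaze_y = as.numeric(A %*% model$coeffs_y))
}

#' Estimate gaze for frames: detection, blink gating, zone check
#'
#' The full per-frame runtime path: detect the pupil; blink frames get no
#' gaze point; otherwise the polynomial model output is the gaze estimate
#' and the coarse zone label only annotates confidence: `"ok"` when the
#' nearest calibration mark to the fine gaze point agrees with the coarse
#' (nearest-MC') zone, `"zone_mismatch"` otherwise. The fine point is
#' always the returned gaze.
#'
#' @param session An `eye_session` (or a single `eye_frame` for
#'   [estimate()]).
#' @param calibration A `calibration_set`.
#' @param model A `gaze_model`.
#' @param marks Mark layout used for the zone-consistency check.
#' @param params Detector parameters.
#' @return A tibble: `frame`, `gaze_x`, `gaze_y`, `coarse_zone`,
#'   `confidence`.
#' @export
track_session <- function(session, calibration, model,
                          marks = default_mark_layout(),
                          params = detect_params()) {
  obs <- detect_pupils(session, params)
  estimate_from_observations(obs, calibration, model, marks)
}

#' @rdname track_session
#' @param obs Observations tibble from [detect_pupils()].
#' @export
estimate_from_observations <- function(obs, calibration, model,
                                       marks = default_mark_layout()) {
  coarse <- classify_coarse(obs, calibration)
  pred <- predict_gaze(model, obs$pupil_x, obs$pupil_y)
  # nearest display mark to the fine gaze point
  dx <- outer(pred$gaze_x, marks$x, `-`)
  dy <- outer(pred$gaze_y, marks$y, `-`)
  fine_zone <- as.character(marks$mark[max.col(-(dx^2 + dy^2),
                                               ties.method = "first")])
  blink <- obs$blink
  tibble::tibble(
    frame = obs$frame,
    gaze_x = ifelse(blink, NA_real_, pred$gaze_x),
    gaze_y = ifelse(blink, NA_real_, pred$gaze_y),
    coarse_zone = coarse,
    confidence = dplyr::case_when(
      blink ~ "blink",
      coarse == fine_zone ~ "ok",
      TRUE ~ "zone_mismatch"
    )
  )
}

#' @rdname track_session
#' @param frame A single `eye_frame` or frame matrix.
#' @export
estimate <- function(frame, calibration, model,
                     marks = default_mark_layout(),
                     params = detect_params()) {
  obs <- dplyr::bind_cols(tibble::tibble(frame = 1L),
                          detect_pupil(frame, params))
  estimate_from_observations(obs, calibration, model, marks)
}

#' @export
print.gaze_model <- function(x, ...) {
  cat(sprintf("<gaze_model> %d pairs, RMS residual %.4g px\n",
              x$n_pairs, x$fit_residual_px))
  cat("D(x):", paste(sprintf("%s=%.4g", names(x$coeffs_x), x$coeffs_x),
                     collapse = " "), "\n")
  cat("D(y):", paste(sprintf("%s=%.4g", names(x$coeffs_y), x$coeffs_y),
                     collapse = " "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gaze_model <- function(x, ...) {
  terms <- c("x^2", "y^2", "x", "y", "x*y", "1")
  tibble::tibble(
    axis = rep(c("x", "y"), each = 6),
    term = rep(terms, 2),
    coefficient = rep(letters[1:12], 1),
    estimate = c(unname(x$coeffs_x), unname(x$coeffs_y))
  )
}

#' @exportS3Method generics::glance
glance.gaze_model <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, fit_residual_px = x$fit_residual_px,
                 condition_number = x$condition_number)
}

#' Write / read a gaze model as structured text (YAML)
#'
#' @param model A `gaze_model`.
#' @param path Output file.
#' @param checksum Optional calibration checksum to embed.
#' @export
write_gaze_model <- function(model, path, checksum = NULL) {
  yaml::write_yaml(list(
    coeffs_x = as.list(model$coeffs_x), coeffs_y = as.list(model$coeffs_y),
    geometry = unclass(model$geometry),
    fit_residual_px = model$fit_residual_px, n_pairs = model$n_pairs,
    calibration_checksum = checksum
  ), path, precision = 15)
  invisible(path)
}

#' @rdname write_gaze_model
#' @export
read_gaze_model <- function(path) {
  doc <- yaml::read_yaml(path)
  structure(list(
    coeffs_x = unlist(doc$coeffs_x), coeffs_y = unlist(doc$coeffs_y),
    geometry = do.call(display_geometry, doc$geometry),
    fit_residual_px = doc$fit_residual_px, n_pairs = doc$n_pairs,
    condition_number = NA_real_
  ), class = "gaze_model")
}
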