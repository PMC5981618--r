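#' Display and viewing geometry of the near-eye device
#'
#' Describes the virtual image presented by the near-eye display: its pixel
#' resolution, the physical size of the virtual image, and the viewing
#' distance from the eye to that image. These three quantities are all that
#' is needed to convert a pixel offset on the display into a physical offset
#' (cm) and then into a visual angle.
#'
#' The defaults describe a 1024 x 720 px display whose virtual image spans
#' 35 x 25 cm at a viewing distance of 50 cm.
#'
#' @param width_px,height_px Display resolution in pixels.
#' @param width_cm,height_cm Physical size of the virtual image in cm.
#' @param viewing_distance_cm Distance from the eye to the virtual image (cm).
#' @return An object of class `display_geometry`.
#' @examples
#' geo <- display_geometry()
#' px_offset_to_cm(1024, 0, geo)  # full display width = 35 cm
#' @export
display_geometry <- function(width_px = 1024L, height_px = 720L,
                             width_cm = 35, height_cm = 25,
                             viewing_distance_cm = 50) {
  g <- list(
    width_px = as.numeric(width_px), height_px = as.numeric(height_px),
    width_cm = as.numeric(width_cm), height_cm = as.numeric(height_cm),
    viewing_distance_cm = as.numeric(viewing_distance_cm)
  )
  vals <- unlist(g)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    rlang::abort("all display_geometry fields must be finite and strictly positive")
  }
  structure(g, class = "display_geometry")
}

#' @export
print.display_geometry <- function(x, ...) {
  cat(sprintf(
    "<display_geometry> %g x %g px, %g x %g cm virtual image at %g cm\n",
    x$width_px, x$height_px, x$width_cm, x$height_cm, x$viewing_distance_cm
  ))
  invisible(x)
}

#' Read a display geometry from a YAML config file
#'
#' Recognised keys: `width_px`, `height_px`, `width_cm`, `height_cm`,
#' `viewing_distance_cm`. Missing keys fall back to the defaults of
#' [display_geometry()].
#'
#' @param path Path to a YAML file.
#' @return A `display_geometry`.
#' @export
read_geometry <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  keys <- c("width_px", "height_px", "width_cm", "height_cm", "viewing_distance_cm")
  args <- formals(display_geometry)
  for (k in intersect(keys, names(cfg))) args[[k]] <- cfg[[k]]
  do.call(display_geometry, lapply(args, eval))
}

#' Nine-mark calibration layout
#'
#' The standard nine-mark calibration grid: a 3 x 3 array of fixation
#' targets placed at x in \{112, 512, 924\} and y in \{60, 360, 660\}
#' display pixels, indexed 1..9 row-major (top-left to bottom-right).
#'
#' @return A tibble with columns `mark` (1..9), `x`, `y` (display px).
#' @export
default_mark_layout <- function() {
  tibble::tibble(
    mark = 1:9,
    x = rep(c(112, 512, 924), times = 3),
    y = rep(c(60, 360, 660), each = 3)
  )
}

#' Convert a display-pixel offset to a physical offset in cm
#'
#' The pixel pitch is anisotropic (width_cm/width_px horizontally,
#' height_cm/height_px vertically); the planar offset is the Euclidean
#' distance on the display plane after converting each axis.
#'
#' @param dx_px,dy_px Pixel offsets (vectorised).
#' @param geometry A [display_geometry()].
#' @return Numeric vector of offsets in cm.
#' @export
px_offset_to_cm <- function(dx_px, dy_px, geometry = display_geometry()) {
  dx_cm <- dx_px * geometry$width_cm / geometry$width_px
  dy_cm <- dy_px * geometry$height_cm / geometry$height_px
  sqrt(dx_cm^2 + dy_cm^2)
}

#' Angular gaze error between estimated and true display positions
#'
#' The error is measured as the visual angle alpha subtended at the eye by
#' the planar offset h between the two display points:
#' `tan(alpha) = h / H`, with `h` the Euclidean offset on the display plane
#' in cm and `H` the viewing distance.
#'
#' @param est_x,est_y Estimated gaze position (display px, vectorised).
#' @param true_x,true_y True gaze position (display px).
#' @param geometry A [display_geometry()].
#' @return A tibble with columns `offset_cm` and `degrees`.
#' @export
angular_error <- function(est_x, est_y, true_x, true_y,
                          geometry = display_geometry()) {
  h <- px_offset_to_cm(est_x - true_x, est_y - true_y, geometry)
  tibble::tibble(
    offset_cm = h,
    degrees = atan2(h, geometry$viewing_distance_cm) * 180 / pi
  )
}

#' @rdname angular_error
#' @details `angular_error_deg()` is a convenience wrapper returning the
#'   angle in degrees as a bare numeric vector.
#' @export
angular_error_deg <- function(est_x, est_y, true_x, true_y,
                              geometry = display_geometry()) {
  angular_error(est_x, est_y, true_x, true_y, geometry)$degrees
}

# per-axis angular error (degrees) from a one-axis pixel offset
axis_error_deg <- function(d_px, cm_per_px, H) {
  atan2(abs(d_px) * cm_per_px, H) * 180 / pi
}
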