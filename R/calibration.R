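#' Group per-frame pupil observations by calibration mark
#'
#' Joins observations to the session manifest, drops blink-flagged frames
#' (blinks never enter the calibration sample lists) and groups the
#' remaining pupil centers by calibration mark.
#'
#' @param observations Tibble from [detect_pupils()] (columns `frame`,
#'   `pupil_x`, `pupil_y`, `quality`, `blink`).
#' @param manifest Session manifest with columns `frame`, `mark_index`.
#' @return A tibble of samples: `mark`, `frame`, `x`, `y`.
#' @export
collect_samples <- function(observations, manifest) {
  joined <- dplyr::inner_join(
    dplyr::select(manifest, "frame", mark = "mark_index"),
    observations, by = "frame"
  )
  joined <- dplyr::filter(joined, !is.na(.data$mark))
  marks <- sort(unique(joined$mark))
  samples <- dplyr::filter(joined, !.data$blink)
  empty <- setdiff(marks, unique(samples$mark))
  if (length(empty)) {
    rlang::abort(sprintf(
      "no non-blink observations for calibration mark(s): %s",
      paste(empty, collapse = ", ")))
  }
  dplyr::select(samples, "mark", "frame", x = "pupil_x", y = "pupil_y")
}

#' Threshold-filtered mean pupil center for one mark
#'
#' Implements the outlier-rejected mean: compute the raw mean center MC of
#' the samples, drop every sample whose Euclidean distance to MC strictly
#' exceeds the threshold T, and recompute the mean of the survivors (MC').
#' Filtering is single-pass: one rejection round, one re-mean. If every
#' sample is rejected, the single sample closest to the raw mean is kept.
#'
#' @param x,y Sample pupil-center coordinates (image px), non-empty.
#' @param T Rejection threshold in px (> 0).
#' @return A list: `mc` (raw mean, length-2), `mcp` (filtered mean),
#'   `kept` (logical vector), `n_kept`, `n_rejected`.
#' @export
filter_and_mean <- function(x, y, T) {
  stopifnot(length(x) >= 1, length(x) == length(y), T > 0)
  mc <- c(mean(x), mean(y))
  d <- sqrt((x - mc[1])^2 + (y - mc[2])^2)
  kept <- d <= T
  if (!any(kept)) kept[which.min(d)] <- TRUE   # degenerate guard
  list(mc = mc, mcp = c(mean(x[kept]), mean(y[kept])),
       kept = kept, n_kept = sum(kept), n_rejected = sum(!kept))
}

#' Calibrate: filtered mean pupil centers for all nine marks
#'
#' Runs [collect_samples()] and [filter_and_mean()] per mark. The default
#' threshold is scale-adaptive: `T = 3 * median distance` of the mark's
#' samples to their raw mean, so it tracks the jitter magnitude without
#' tuning; pass `T` to use an absolute pixel threshold instead.
#'
#' @param observations,manifest As in [collect_samples()].
#' @param T Optional absolute rejection threshold (px) applied to every
#'   mark; `NULL` (default) uses the adaptive rule per mark.
#' @return A `calibration_set`: list with `zones` (tibble: `mark`, `mc_x`,
#'   `mc_y`, `mcp_x`, `mcp_y`, `T`, `n_kept`, `n_rejected`), `samples`,
#'   `n_blinks_excluded`.
#' @export
calibrate <- function(observations, manifest, T = NULL) {
  samples <- collect_samples(observations, manifest)
  n_blinks <- sum(observations$blink[observations$frame %in%
                                       manifest$frame[!is.na(manifest$mark_index)]])
  zones <- lapply(split(samples, samples$mark), function(s) {
    Ti <- T
    if (is.null(Ti)) {
      mc <- c(mean(s$x), mean(s$y))
      d <- sqrt((s$x - mc[1])^2 + (s$y - mc[2])^2)
      Ti <- max(3 * stats::median(d), 1e-9)
    }
    fm <- filter_and_mean(s$x, s$y, Ti)
    tibble::tibble(mark = s$mark[1], mc_x = fm$mc[1], mc_y = fm$mc[2],
                   mcp_x = fm$mcp[1], mcp_y = fm$mcp[2], T = Ti,
                   n_kept = fm$n_kept, n_rejected = fm$n_rejected)
  })
  structure(list(zones = dplyr::arrange(dplyr::bind_rows(zones), .data$mark),
                 samples = samples, n_blinks_excluded = n_blinks),
            class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("<calibration_set> %d zones, %d samples, %d blinks excluded\n",
              nrow(x$zones), nrow(x$samples), x$n_blinks_excluded))
  print(x$zones)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.calibration_set <- function(x, ...) x$zones

#' @exportS3Method generics::glance
glance.calibration_set <- function(x, ...) {
  tibble::tibble(n_zones = nrow(x$zones), n_samples = nrow(x$samples),
                 n_blinks_excluded = x$n_blinks_excluded,
                 n_rejected = sum(x$zones$n_rejected))
}

#' @exportS3Method ggplot2::autoplot
autoplot.calibration_set <- function(object, ...) {
  ggplot2::ggplot(object$samples, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_point(data = object$zones,
                        ggplot2::aes(.data$mcp_x, .data$mcp_y),
                        colour = "red", shape = 3, size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~mark, scales = "free") +
    ggplot2::labs(x = "pupil x (px)", y = "pupil y (px)",
                  title = "Per-mark pupil centers and filtered means")
}

#' Write / read a calibration result as structured text (YAML)
#'
#' @param cal A `calibration_set`.
#' @param path Output file.
#' @param checksum Optional source-session checksum to embed.
#' @export
write_calibration <- function(cal, path, checksum = NULL) {
  doc <- list(zones = lapply(seq_len(nrow(cal$zones)), function(i) {
    as.list(cal$zones[i, ])
  }), n_blinks_excluded = cal$n_blinks_excluded,
  session_checksum = checksum)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  doc <- yaml::read_yaml(path)
  zones <- dplyr::bind_rows(lapply(doc$zones, tibble::as_tibble))
  structure(list(zones = zones,
                 samples = tibble::tibble(mark = integer(), frame = integer(),
                                          x = numeric(), y = numeric()),
                 n_blinks_excluded = doc$n_blinks_excluded %||% 0L),
            class = "calibration_set")
}
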