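#' Coarse gaze-zone / blink classification
#'
#' The coarse stage maps each frame to one of ten classes: the nine display
#' zones anchored at the calibration marks, or `"blink"`. The default
#' backend is geometric: a blink-flagged observation is `"blink"`; any
#' other observation is assigned the zone whose filtered mean pupil center
#' (MC') is nearest in the image plane, ties broken toward the lowest mark
#' index.
#'
#' @param observations Tibble with columns `pupil_x`, `pupil_y`, `blink`
#'   (one or more rows).
#' @param calibration A `calibration_set` covering all zones.
#' @return Character vector (`"1"`..`"9"` or `"blink"`), one per row.
#' @export
classify_coarse <- function(observations, calibration) {
  if (is.null(calibration) || !nrow(calibration$zones)) {
    rlang::abort("calibration with a mean center for every zone is required")
  }
  z <- dplyr::arrange(calibration$zones, .data$mark)
  out <- rep(NA_character_, nrow(observations))
  out[observations$blink] <- "blink"
  open <- which(!observations$blink)
  if (length(open)) {
    dx <- outer(observations$pupil_x[open], z$mcp_x, `-`)
    dy <- outer(observations$pupil_y[open], z$mcp_y, `-`)
    d2 <- dx^2 + dy^2
    # max.col on negated distances with ties.method "first" = lowest index
    out[open] <- as.character(z$mark[max.col(-d2, ties.method = "first")])
  }
  out
}

# block-mean downsample of a frame matrix to size x size features in [0,1]
frame_features <- function(img, size = 16L) {
  h <- nrow(img); w <- ncol(img)
  ri <- pmin(size, ceiling(seq_len(h) / h * size))
  ci <- pmin(size, ceiling(seq_len(w) / w * size))
  # two-pass block mean: rows then columns
  m1 <- rowsum(img, ri) / as.vector(table(ri))
  m2 <- t(rowsum(t(m1), ci) / as.vector(table(ci)))
  as.numeric(m2) / 255
}

#' Train the optional learned coarse-classification backend
#'
#' A deliberately small learned stand-in for the 10-class stage: frames are
#' normalized to a fixed grid by block-mean downsampling and a single
#' hidden-layer neural network (multinomial output over the 10 classes) is
#' trained from scratch on synthetic frames. Requires every class
#' (all labelled zones plus blink) in the training data.
#'
#' @param session An `eye_session` of labelled calibration frames.
#' @param labels Character labels per frame (`"1"`..`"9"` or `"blink"`);
#'   defaults to the manifest's mark index with blinks relabelled.
#' @param feature_size Downsampled grid side (default 16).
#' @param hidden Hidden units (default 8).
#' @param holdout_frac Fraction held out for the reported accuracy.
#' @param seed RNG seed for the split and the weight initialization.
#' @return A `coarse_classifier`: list with the fitted net, `levels`,
#'   `feature_size`, `holdout_accuracy`, `train_accuracy`.
#' @export
train_learned_backend <- function(session, labels = NULL, feature_size = 16L,
                                  hidden = 8L, holdout_frac = 0.25,
                                  seed = 7L) {
  man <- session$manifest
  if (is.null(labels)) {
    labels <- ifelse(man$blink == 1, "blink", as.character(man$mark_index))
  }
  needed <- c(as.character(1:9), "blink")
  missing <- setdiff(needed, unique(labels))
  if (length(missing)) {
    rlang::abort(sprintf("training data lacks class(es): %s",
                         paste(missing, collapse = ", ")))
  }
  X <- t(vapply(session$frames, frame_features, numeric(feature_size^2),
                size = feature_size))
  yf <- factor(labels, levels = needed)
  fit <- with_local_seed(seed, {
    n <- nrow(X)
    holdout <- sample.int(n, max(1L, round(holdout_frac * n)))
    net <- nnet::nnet(X[-holdout, , drop = FALSE], nnet::class.ind(yf[-holdout]),
                      size = hidden, softmax = TRUE, maxit = 200,
                      MaxNWts = 1e5, trace = FALSE)
    pred_h <- needed[max.col(stats::predict(net, X[holdout, , drop = FALSE]))]
    pred_t <- needed[max.col(stats::predict(net, X[-holdout, , drop = FALSE]))]
    list(net = net,
         holdout_accuracy = mean(pred_h == as.character(yf[holdout])),
         train_accuracy = mean(pred_t == as.character(yf[-holdout])))
  })
  structure(list(net = fit$net, levels = needed, feature_size = feature_size,
                 holdout_accuracy = fit$holdout_accuracy,
                 train_accuracy = fit$train_accuracy),
            class = "coarse_classifier")
}

#' @rdname train_learned_backend
#' @param classifier A `coarse_classifier`.
#' @param frames List of frame matrices (or an `eye_session`).
#' @return `predict_learned()`: character labels, one per frame.
#' @export
predict_learned <- function(classifier, frames) {
  if (inherits(frames, "eye_session")) frames <- frames$frames
  X <- t(vapply(frames, frame_features, numeric(classifier$feature_size^2),
                size = classifier$feature_size))
  classifier$levels[max.col(stats::predict(classifier$net, X))]
}
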