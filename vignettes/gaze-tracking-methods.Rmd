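---
title: "Methods: near-eye gaze tracking with a calibrated polynomial model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: near-eye gaze tracking with a calibrated polynomial model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A head-mounted eye tracker pairs a near-eye display (a millimeter-scale
OLED whose virtual image spans 35 x 25 cm at a viewing distance of
H = 50 cm, at 1024 x 720 display pixels) with an infrared eye camera
(640 x 480 px) that images the eye under IR illumination. Under this
dark-pupil geometry the pupil is the darkest structure in the frame.
Gaze tracking means mapping the pupil center in camera coordinates to
the point on the display the subject is fixating.

`neargaze` implements the complete pipeline — synthetic frame rendering,
pupil-center detection, nine-mark calibration with outlier-rejected mean
centers, a second-order polynomial gaze mapping, coarse zone/blink
classification, and angular-accuracy evaluation — so that every stage is
testable end to end without recorded eye data.

## Pupil detection

`detect_pupil()` runs: adaptive dark thresholding (from the 8-bit
histogram: threshold = low quantile + 0.3 x (median - low), clamped to
[40, 90] counts), connected-component labelling to find the largest dark
region, ROI-limited Gaussian smoothing, hole filling (corneal glints
punch bright holes into the pupil mask), boundary extraction, and a
consensus ellipse fit: random 5-point conic fits, the candidate with the
largest inlier support (radial distance <= 1.5 px) kept, followed by two
rounds of least-squares refinement on the inlier set. The fitted ellipse
center is the sub-pixel pupil center; quality is the final inlier
fraction of the boundary points. The consensus step runs under a fixed
private RNG seed, so detection is a pure function of the frame.

Numerical notes:

* Conic fitting minimizes the algebraic residual over the unit-norm
  coefficient vector (smallest eigenvector of the 6 x 6 normal matrix),
  in a centered, isotropically scaled frame for conditioning. This
  handles both the 5-point minimal case and the least-squares refit.
* The smoothing sigma defaults to `pupil_radius_px / 15` (clamped to
  [0.5, 3] px) so smoothing scales with the feature: a fixed sigma that
  suits a 30 px pupil visibly erodes an 8 px one.
* The coarse stage runs on a strided subsample of the frame (stride
  `min(height, width) %/% 160`); the pupil is far larger than the
  stride, so the bounding box survives subsampling and full-resolution
  work is confined to the pupil ROI.

## Blink gating

A frame is declared a blink when the dark area falls below 50% of the
reference pupil area (`pi * pupil_radius_px^2` by default) or the
ellipse-fit inlier fraction falls below 0.4. The area rule is the one
that fires in practice: the simulator's eyelid occludes at least 80% (in
practice ~95%) of the pupil, and a half-occluded pupil also falls under
the 50% line. Foreshortening at extreme gaze angles reduces the visible
pupil area by at most ~15%, leaving a comfortable margin above the
threshold for open eyes. Blink frames never enter calibration and are
excluded from every evaluation average.

## Calibration: outlier-rejected mean centers

During calibration the subject fixates nine marks at display positions
(112, 60), (512, 60), (924, 60), (112, 360), (512, 360), (924, 360),
(112, 660), (512, 660), (924, 660); 60 frames are recorded per mark.
Fixational nystagmus and residual detection error scatter the per-frame
pupil centers, so each mark's center is estimated by a threshold-filtered
mean: compute the raw mean MC of the centers, reject every sample whose
Euclidean distance to MC strictly exceeds a threshold T, and re-average
the survivors to get MC'. Filtering is single-pass by design (one
rejection round, one re-mean); re-applying it to its own survivors is
not guaranteed to be a no-op in pathological configurations, and the
tests document this as intended behavior of the single-pass rule.

T defaults to 3 x the median distance of the mark's samples to their raw
mean. The median is robust to the contamination the filter is meant to
remove, so the rule adapts to the jitter magnitude without tuning; an
absolute pixel threshold can be supplied instead. If every sample is
rejected (tiny T), the single sample closest to the raw mean is kept.

## The gaze model

Each display axis is a full second-order polynomial in the pupil center
(x, y):

    D_x = a x^2 + b y^2 + c x + d y + e xy + f
    D_y = g x^2 + h y^2 + i x + j y + k xy + l

The twelve coefficients are fitted by ordinary least squares of the nine
(MC', mark position) pairs — two 9-equation, 6-unknown systems solved by
QR. Rank-deficient designs (e.g. collinear centers) are rejected with a
diagnostic naming the degenerate term; a condition number above 1e8
triggers a warning but not a failure (raw pixel coordinates are used
without normalization, and the default geometry stays well below that).
At runtime the polynomial output is always the reported gaze point; the
coarse zone label (nearest MC', or "blink") only gates blinks and
annotates confidence (`ok` / `zone_mismatch`), because the polynomial
stage is the accurate one and any stronger fusion would be invented
behavior.

## Coarse classification backends

The default backend is geometric nearest-mean-center over the nine MC'
with ties broken toward the lowest mark index, plus the blink gate: a
deterministic realization of the 10-class contract (9 zones + blink)
that needs no training. An optional learned backend
(`train_learned_backend()`) trains a single-hidden-layer network
(multinomial softmax over the 10 classes) on block-mean downsampled
frames, from scratch, on synthetic sessions only; it must reach 90%
held-out accuracy or training reports failure. Deep fine-tuned
classifiers on real eye data are out of scope here.

## Evaluation in degrees of visual angle

The error between an estimated and a true gaze point is the visual angle
`alpha = atan(h / H)`, where h is the planar offset on the display in cm
and H = 50 cm. The pixel pitch is anisotropic (35/1024 cm/px
horizontally, 25/720 cm/px vertically), so each axis is converted
separately and h is the Euclidean offset in cm. Reports aggregate per
calibration zone (attributed by the session's true mark index), per axis
(each axis offset converted through its own pitch, then the same arctan
model), and per session; blink frames are excluded everywhere.

`repeated_use_protocol()` models calibration-free reuse: calibrate once,
then re-wear the device `n` times, each re-wear displacing the
ground-truth pupil positions by a constant offset (default magnitude
2 px, random direction) before tracking fresh sessions against the fixed
model.

## The synthetic scene

`scene_config()` + `render_frame()` emulate the recording conditions:

* a dark elliptical pupil (intensity ~20) on an iris disk (~120) and
  sclera background (~200), with bright corneal glints (~250) and an
  eyelid band (~160) during blinks — all configurable;
* perspective foreshortening: the pupil's minor axis shrinks with
  eccentricity from the frame center (down to 0.85 of the major axis),
  oriented radially;
* per-frame Gaussian jitter of the pupil center (default sigma 1 px per
  axis) standing in for fixational nystagmus;
* per-frame blink probability (default 0.05) with >= 80% eyelid
  occlusion of the pupil;
* additive Gaussian intensity noise (default sigma 8 counts) with 8-bit
  quantization.

The ground-truth gaze-to-pupil relation is a 12-coefficient quadratic
over the same basis the gaze model uses, mildly non-linear (quadratic
terms a few percent of the affine ones) and invertible over the display
rectangle. Its inverse is therefore only approximately inside the
fitted model class; the mismatch is kept well below the accuracy band so
that parameter recovery is a well-posed test. Distinct "subjects" are
drawn by perturbing the map (linear gains +-5%, quadratic terms +-20%,
offsets +-10 px). Sessions are bit-reproducible: all randomness flows
from the config seed, expanded into per-frame seeds.

What the simulator does not model: eyelashes and eyebrows, glasses
reflections, photorealistic iris texture, head slippage within a
session, and pupil-size changes with illumination. Passing tests
therefore demonstrate the correctness and internal accuracy of the
algorithmic chain under the stated conditions, not performance on real
recordings.

Sixty frames per mark are generated directly (rather than recording a
2 s dwell at 60 Hz and subsetting), since any subset rule would be
arbitrary.

## Benchmark problem sizes

The package's accuracy benchmark uses 8 synthetic subjects (distinct
true maps), a 9-mark calibration of 60 frames per mark, and a 5 x 5
evaluation grid spanning the mark bounding box with 20 frames per point;
the detection benchmark uses 1,000 frames at uniformly random gazes.
These sizes keep a full run in the minutes range on one CPU while the
resulting means are stable to well under the tolerances being checked.

## Known limitations

* The detector assumes dark-pupil polarity; there is no bright-pupil
  mode.
* The radial inlier distance used in the consensus fit is exact for
  circles and an approximation for ellipses; at the mild eccentricities
  produced by foreshortening (axis ratio >= 0.85) the approximation
  error is far below the 1.5 px inlier tolerance.
* Zone attribution in per-zone reports requires mark-labelled sessions;
  free-gaze sessions report only session-level means.
* The polynomial model compensates neither head movement relative to the
  device nor 3-D eyeball kinematics; a constant re-wear offset is the
  only cross-session perturbation modelled.
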