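---
title: "fluokernel: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fluokernel: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluokernel)
```

## The problem

Multi-control sterility (MCS) maize breeding tags the kernels of the
fertile maintainer line with a red fluorescent protein (mCherry or
DsRed). Under a suitable excitation light and camera filter,
maintainer-line kernels glow red against a near-black background while
sterile-line kernels stay dark; an automated sorter must separate the
two classes in real time on a conveyor. `fluokernel` provides the
classical machine-vision building blocks of such a sorter — synthetic
scene generation with ground truth, segmentation, colour-moment
features, detector-style augmentation and losses, evaluation metrics,
and a belt-sorting simulator — as small, individually tested units.
The deep detector itself (a YOLO-family network) is deliberately out of
scope: nothing here trains or runs a neural network, but every
component that surrounds one is implemented and testable without a
camera or dataset.

## Synthetic scenes as a stated world

No public dataset of fluorescent kernel images exists, so every
downstream stage is tested against `generate_scene()`. A scene is a
640×640 frame (the standard detector input size) containing elliptical
kernels of three classes — `mCherry-1` (bright red-magenta), `DsRed-2`
(dim red), `Non-3` (near-background) — on a dark background.

Fixed modelling choices, made once:

* **Geometry.** Kernels are filled ellipses, major semi-axis drawn
  uniformly from 16–26 px, minor semi-axis 0.75–1 of the major (aspect
  ratio at most ~1.35, maize-like). The mild eccentricity guarantees a
  single dominant ridge peak in the distance transform, which is what
  the watershed marker logic assumes.
* **Rendering.** Radial brightness falloff from 100% at the centre to
  65% at the rim, mimicking the glow of a translucent kernel; the
  per-class emission triples default to (0.85, 0.12, 0.40),
  (0.50, 0.10, 0.14) and (0.24, 0.22, 0.20), giving the strict
  R-channel ordering mCherry-1 > DsRed-2 > Non-3 that the class-
  separation invariant asserts per scene.
* **Background.** Mean 0.02, additive Gaussian noise with sd 0.01 per
  channel, clipped to [0, 1]. The source imaging rig publishes no pixel
  statistics, so these values are calibrated only for internal
  separability: they are chosen (once) so that Otsu thresholding
  cleanly separates all three kernel classes from the background. An
  earlier candidate with `Non-3` at gray level ~0.07 demonstrably broke
  Otsu — the dominant background mode pushed the threshold between the
  dim and bright kernel classes — which is why the non-fluorescent
  class sits at gray ~0.22, visibly above background but far below the
  fluorescent classes in the R channel.
* **Placement.** Rejection sampling, at most 1000 attempts per kernel,
  failing loudly with the attempt count. The minimum-gap constraint is
  enforced against an exact Euclidean distance transform of the
  already-occupied raster, so `min_gap_px` is a true pixel distance;
  `min_gap_px = 0` permits touching but never overlapping kernels.
* **Determinism.** Scenes are a pure function of (config, seed). Each
  kernel draws from its own seeded substream, so changing one
  parameter does not reshuffle unrelated kernels, and the caller's RNG
  state is never touched.

What the generator does **not** emulate: fluorescence spectra, filter
transmission, sensor noise structure (it uses i.i.d. Gaussian noise),
specular reflection from the endosperm, or kernel shape irregularity.
A green segmentation or classification test therefore establishes that
the algorithms are implemented correctly on separable input, not that
any particular camera configuration achieves a given accuracy.

## Segmentation chain

`segment_scene()` is the classical chain: BT.601 grayscale → median
filter (window 3) → Laplacian sharpening → Otsu binarization with disk
opening/closing → marker-controlled watershed → per-instance crops.
Design points where the procedure description left freedom:

* **Otsu** for the threshold rule: parameter-free and standard; the
  source procedure names no rule.
* **4-neighbour Laplacian, subtractive sharpening**
  (`out = clip(img − strength·∇²img)`): the canonical "Laplace
  differential" form.
* **Watershed markers** are greedy peaks of the exact Euclidean
  distance transform: a candidate must equal the maximum of its
  `(2r+1)²` neighbourhood (`r = min_sep_px`) and lie at least
  `min_sep_px` from any accepted peak; every connected component is
  guaranteed at least one marker. `min_sep_px` should be set to the
  smallest expected kernel radius (default 20 for the default
  generator). Flooding runs on the negated distance transform with
  FIFO tie-breaking, so results are deterministic.
* **Edge handling** is reflect padding everywhere, avoiding dark-border
  artifacts on dark scenes.
* **Coordinates** are 0-based, row-major, boxes half-open `[min, max)`.

Morphology radii default to 2 px and are exposed, not claimed faithful
to any rig. Impurity screening by aspect ratio/area is out of scope.

## Colour moments and the H/V rule

`color_moments()` returns 18 features per kernel: {R, G, B, H, S, V} ×
{mean, second moment, third moment}, with the second moment defined as
the standard deviation and the third as the signed cube root of the
third central moment (Stricker–Orengo). With these root definitions
all three moments carry the channel's units, so scaling a channel by
`k > 0` scales the whole triple by `k` — a property the suite checks.
Moments are computed on [0, 1] channels by default (`scale_255` flag
for byte-scale comparability) over the kernel mask by default; the mask
argument accepts the whole frame where that is wanted.

Published tables of such moments from real rigs are not reproducible
here — capture conditions (exposure, gain, filter) are unknowable, and
printed magnitudes cannot be reverse-engineered — so absolute moment
values are explicitly not targets. What is testable is separability:
fluorescent and non-fluorescent kernels differ most strongly in the H
and V means, so `moment_classify()` uses exactly those two features
with strict `>` thresholds (a tie is non-fluorescent), and
`fit_threshold_rule()` places each threshold at the midpoint of class
means. On the default synthetic benchmark (fixed seeds, scene-level
train/test split) the fitted rule must reach ≥ 95% held-out accuracy.

## Augmentation

* **Gamma transform** `s = c·rᵞ` on [0, 1] intensities, so `c = 1`
  keeps the range closed; γ < 1 brightens (the working point γ = 0.7
  lifts dim DsRed kernels off the dark background), γ > 1 darkens.
  The suite asserts identity at γ = 1, pixel-wise monotone
  brightening for γ < 1, and the composition law γ₁∘γ₂ = γ₁·γ₂ to
  1e-9. An `on_v` flag applies the curve to the HSV value channel only.
* **HSV jitter** draws one `U(−1, 1)` per channel per image: hue shifts
  mod 1, saturation and value scale by `1 + u·gain` with clipping.
  Default gains (0.0138, 0.664, 0.464) are the hue/saturation/value
  hyperparameters used alongside γ = 0.7 in the target pipeline.
* **Mosaic** composes four labelled images around a random centre point
  drawn in the middle half of the canvas; images are placed at native
  scale anchored at the centre and cropped to their quadrant. Boxes
  are kept when at least 20% of their area survives the crop — the
  cutoff is a config choice, as no box-filtering rule is published.

## Box losses

Boxes are corner-format floats; centre/width/height are always derived,
never stored. `ciou_terms()` implements the complete-IoU loss

`L = 1 − IoU + ρ²/c² + α·v`,
`v = (4/π²)(atan(w_t/h_t) − atan(w/h))²`,
`α = v / ((1 − IoU) + v)`,

with `α ≔ 0` when `v = 0` to avoid 0/0 at perfect overlap. The printed
source formulas flatten two fractions typographically (`α=v(1−IOU)+v`,
and a bare `+α` in the loss); they are implemented per the standard
CIoU definition, which is the only dimensionally consistent reading.
The property the loss exists to provide — among equal-IoU candidates,
nearer centres rank first; among coincident centres, matching aspect
ratio ranks first — is asserted on constructed families, and
`rank_candidates()` exposes the induced ordering with deterministic
tie-breaks (centre distance, then aspect penalty, then input order).

## Evaluation metrics

Matching is greedy PASCAL-style in descending score (ties: input
order), with the per-kernel classification framing used by sorting
experiments: matched fluorescent truth → TP, unmatched fluorescent
truth → FN, detection not matched to a fluorescent truth → FP,
untouched non-fluorescent truth → TN. TN is only meaningful in this
framing; the PR curve and AP use detection-level counts over
fluorescent truths only. AP uses all-points interpolation (precision
envelope, rectangle sum over recall increments) — the modern
convention, since only the integral definition is published. Zero
denominators in precision/recall/accuracy/F1 raise errors rather than
returning silent zeros. The implementation is checked against a
brute-force threshold-enumeration oracle on all instances with ≤ 8
detections.

## CBAM forward pass

`cbam_forward()` is the standard convolutional block attention module
as a plain-array forward pass: channel attention
`σ(MLP(avgpool) + MLP(maxpool))` with a shared bias-free two-layer
MLP (ReLU hidden, bottleneck `C/r`, default r = 16), then spatial
attention `σ(conv₇ₓ₇[mean map; max map])`, each applied
multiplicatively in sequence. The published prose conflates the
CBAM-internal sum-then-sigmoid with the composition of the two
modules; the standard formulation is implemented rather than a hybrid,
and the sequential-order contract (channel before spatial, computed on
the intermediate feature) is verified on inputs where the two orders
differ. The spatial convolution uses reflect padding so a spatially
constant input yields a constant map. Because both weight stages are
strict sigmoids, every non-zero activation is strictly attenuated —
an invariant the suite asserts. No gradients, no training, no claim
about where the block should sit inside a detector backbone.

## Sorting simulator

`simulate_sorting()` reproduces the structure of a mixed 500 + 500
kernel sorting run: kernels are shuffled into a drop order; each drop
is a double drop with probability `p_double(interval_s)`; a
double-dropped pair shares one classification decision (the tail kernel
is routed wherever the head was sent); single kernels classify
correctly with probability `p_correct`. Counts conserve the sample
size by construction, and mechanical misroutes are reported separately
from model errors, since published sorting tables do not distinguish
them. `belt_speed()` is exact kinematics
(`spacing/1000/interval`): 30 mm spacing at 0.5/0.45/0.4 s gives
0.060/0.067/0.075 m/s.

The default `p_double` curve interpolates (0.5 s, 0.036),
(0.45 s, 0.057), (0.4 s, 0.093): with a 0.96-accurate classifier the
expected accuracies bracket the observed 94.4% → 92.1% degradation
across those intervals. This calibration is illustrative — the real
failure mode is only described qualitatively — and was fixed before the
acceptance tests were written, not tuned afterwards.

## Numerical and I/O choices

* Images are `H×W×3` arrays in [0, 1]; PNG I/O via the `png` package,
  plus plain-text PGM/PPM so test fixtures stay text. Label maps are
  16-bit text PGM (the available PNG writer is 8-bit only and would
  collide instance indices).
* YOLO-txt is the canonical label format (normalized centre geometry,
  9-decimal output so round trips hold to 1e-6); Pascal-VOC XML is
  supported with pixel corners. Readers reject malformed lines with
  line numbers and out-of-range normalized values.
* Bilinear resize uses pixel-centre alignment, making same-size resize
  the exact identity.
* The Otsu histogram uses 256 bins; counts are accumulated as doubles
  (an integer accumulation overflows on 640×640 frames).
* All CLI subcommands are deterministic given `--seed` and write a
  provenance header (package version, seed, config hash) above their
  CSV output.

## Known limitations

* The generator's separability is by construction; no claim is made
  about real imaging rigs, and absolute colour-moment magnitudes from
  published tables are not reproducible.
* Headline detection metrics of trained networks (AP50 ≈ 95.7%,
  F1 ≈ 96.3%, end-to-end 96% sorting accuracy as an empirical result)
  require the trained models and a 5000-image dataset that does not
  exist publicly; the toolkit reproduces their *arithmetic* from
  printed confusion counts instead.
* The watershed marker heuristic assumes roughly convex, mildly
  eccentric kernels; long thin objects would need a different marker
  policy.
* The sorting simulator ignores steering-gate latency and any spatial
  interaction between channels.
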