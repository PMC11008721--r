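---
title: "Methods: low-light enhancement, crop-row fitting and evaluation in rownav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-light enhancement, crop-row fitting and evaluation in rownav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rownav)
```

rownav is a toolkit for vision-guided navigation between two crop rows
(typically maize at the 3–5 leaf weeding stage). It covers four stages of
that pipeline — low-light image enhancement, conversion of plant detections
into fitted row lines and a central navigation line, training-free reference
implementations of the detector building blocks and losses, and the
evaluation metrics — plus a synthetic scene generator that makes every stage
testable with exact ground truth. This vignette explains the models, their
assumptions, the tunable parameters, and the design decisions taken where
the methods left genuine freedom.

## Retinex decomposition and adaptive gamma correction

A field image illuminated by a nearby floodlight is modelled as the
pixel-wise product of a smooth illumination field and an
illumination-independent reflectance,

$$ I_c(x, y) = R_c(x, y)\, L(x, y), \qquad c \in \{r, g, b\}. $$

Enhancement alters only $L$. The corrected luminance is
$L_{en}(x,y) = L(x,y)^{\gamma(l(x,y))}$ where $l$ is the luminance level
after quantisation to $B$ bins and the per-level exponent is one minus a
weighted cumulative distribution,

$$ \gamma(l) = 1 - \frac{\sum_{v \le l} P_w(v)}{s_p}, \qquad
   P_w(l) = \frac{P(l) - P_{\min}}{P_{\max} - P_{\min}}, \qquad
   P(l) = n_l / n_p, $$

with $s_p = \sum_l P_w(l)$ the global normaliser. Because
$\gamma \in [0, 1]$ and $L \le 1$, the transform can only brighten
($L_{en} \ge L$ elementwise), and levels where the histogram mass has
already accumulated are pushed hardest toward white. The enhanced image is
$R_c \cdot L_{en}$, clamped to $[0, 1]$ (reflectance exceeds 1 wherever a
channel is brighter than the luminance estimate).

Choices the model itself does not fix:

* **Luminance estimation.** Only the decomposition is specified, not how
  $L$ is obtained from a single image. We use the single-scale Retinex
  convention: a Gaussian low-pass (default `blur_sigma = 15` px, reflected
  borders, truncated at $3\sigma$) of the per-pixel channel maximum. The
  channel maximum avoids hue bias; the blur scale should exceed the plant
  diameter so that plants read as reflectance, not illumination.
* **Quantisation.** `bins = 256` over $[0, 1]$, with
  $l(x) = \lfloor \min(x, 1 - \epsilon) B \rfloor$, matching 8-bit imagery.
* **Normaliser.** $s_p$ is read as the sum of $P_w$ over *all* levels. The
  running-sum alternative would make $\gamma(l) \equiv 0$ identically, i.e.
  an all-white output, so the global sum is the only reading that yields
  valid exponents.
* **Degenerate histograms.** The min–max normalisation of $P_w$ is
  undefined on a flat histogram, and with a single occupied level the
  formula would send the whole image to white. Both cases fall back to the
  identity transform ($\gamma \equiv 1$): a uniform image passes through
  `enhance()` unchanged.
* **Floor.** $L$ is clamped to `eps_floor = 1e-6` from below so the
  reflectance division is always defined.

A property worth knowing before applying the transform: the brightest
occupied level always maps to exactly 1 (its $\gamma$ is 0 whenever the
histogram is non-degenerate). If the luminance histogram is spread thin —
for example under a strictly linear illumination ramp — the darkest levels
keep $\gamma \approx 1$ and barely move while the bright end saturates, so
the dark-to-bright spread can *widen*. The transform genuinely evens out
illumination when the dark mass is concentrated in few levels, which is what
a real floodlight falloff produces (most of the frame near a dark floor);
the synthetic night fixture therefore uses a concentrated falloff profile
(`illum_profile = 6`) and 64 bins, where the per-row brightness ratio
demonstrably shrinks. The tests assert exactly that, and nothing stronger.

## Gap-aware weighted row fitting and the navigation line

Detected plant boxes are reduced to their centre points
$((x_1 + x_2)/2,\,(y_1 + y_2)/2)$. Points in the outer 5% border of the
image are discarded and the rest split at the vertical midline into the left
and right row (polygon regions may be supplied instead). Within each row,
points are ordered by $y$ (ties by $x$) and the separation
$D_{i,i+1} = |y_{i+1} - y_i|$ is compared with a threshold $D_{thresh}$;
the downstream point of each exceeding pair is flagged as the start of a
missing-plant gap. Flagged points are *retained* in the fit by default — a
gap start is a real plant — with `drop_gap_points = TRUE` available. When
`d_thresh = NULL` the threshold defaults to $1.8\times$ the row's median
spacing, which flags a single missing plant (a doubled spacing) without
tripping on sowing irregularity.

Each row line minimises the weighted least-squares objective

$$ S = \sum_i w_i\,\bigl(y_i - (m x_i + b)\bigr)^2 $$

via its closed-form $2 \times 2$ normal equations. Weights implement
"closer to the row centre counts more": a preliminary unweighted fit stands
in for the row centre, and

$$ w_i = \exp\!\left(-\frac{d_i^2}{2\sigma^2}\right), \qquad
   \sigma = \max(1.4826\,\mathrm{median}(|d_i|),\ \sigma_{\min}), $$

with $d_i$ the perpendicular distance to that reference and
$\sigma_{\min} = 1$ px. Only monotone decrease with distance is demanded by
the method; the Gaussian kernel with a median-absolute-deviation scale is
our choice because it is smooth, parameter-light and ignores up to half the
points being corrupted. One weighting pass suffices in all validation
suites; no iteration is performed.

Two numerical decisions matter in forward-facing imagery, where rows are
near-vertical:

* **Fitting axis.** $y = mx + b$ is ill-conditioned for near-vertical
  point sets, so the fit runs internally as $x$ on $y$ whenever the squared
  robust spread (MAD) of $x$ falls below 10% of that of $y$, and the
  parameters are converted back for reporting. The *robust* spread, not the
  raw variance, makes the choice: a handful of weed false-positives can
  inflate the raw $x$-variance enough to flip a vertical row onto the wrong
  axis, which we observed to produce navigation errors of tens of degrees
  before weighting can repair anything. An exactly vertical fit
  ($x = c$) has no finite slope and is reported as an error. Callers can
  force either axis through the `form` argument.
* **Parallel rows.** Lines with $|m_1 - m_2| < 10^{-9}$ take the parallel
  branch: the navigation line is the midline with the shared slope.

The central navigation line passes through the intersection of the two row
lines, with slope the tangent of the mean of the two line angles,

$$ m_c = \tan\!\left(\frac{\arctan m_1 + \arctan m_2}{2}\right), \qquad
   b_c = y_i - m_c x_i . $$

This is the angle-bisector construction (despite sometimes being described
as a "harmonic mean" of slopes — it is not; the formula, not the name, is
implemented). It is symmetric in the two rows, and in angle space the
navigation angle is exactly the mean of the two row angles — both properties
are tested directly.

`fit_crop_rows()` packages the whole pipeline as a fitted-model object of
class `crop_row_fit` with `print`, `summary`, `coef`, `predict`, `plot` and
`residuals` methods.

## Reference network blocks and losses

These are deterministic, training-free forwards whose structural properties
can be tested; no parameter is learned and the package never assembles a
full detector.

* **ECA.** Kernel size $k$ is the odd integer nearest to
  $(\log_2 C_{in} + 1)/2$ (minimum 1, midpoints to the larger odd);
  channel means pass through a circular 1-D convolution and a sigmoid, and
  scale their channels.
* **Coordinate attention.** Axis-wise average pooling to $C \times H$ and
  $C \times W$ descriptors, concatenation, a $1 \times 1$ mixing
  convolution down to $\lceil C/r \rceil$ channels with ReLU, per-branch
  expansion with sigmoids, and multiplicative reapplication
  $out = in \odot a_h \odot a_w$. Parameters are seeded draws
  (`ca_params()`) or zeros (`ca_identity_params()`, giving the closed-form
  output $in \times 0.25$).
* **SPPF.** Stride-1 max pooling at receptive fields 5, 9 and 13 with
  same-size ($-\infty$) padding, channel concatenation to $4C$ and an
  optional $1 \times 1$ projection. Two successive 5-pools equal a 9-pool
  and three equal a 13-pool *exactly*; the tests rely on that identity.
* **Focus.** $2 \times 2$ space-to-depth: $C \times H \times W \to
  4C \times H/2 \times W/2$, sub-grids ordered TL, TR, BL, BR.
* **CIoU loss.** $L = 1 - IoU + \rho^2/c^2 + \alpha v$ with centre distance
  $\rho$, enclosing-box diagonal $c$, aspect term
  $v = (4/\pi^2)(\arctan(w^{gt}/h^{gt}) - \arctan(w/h))^2$ and
  $\alpha = v / ((1 - IoU) + v)$, defined as 0 at the $0/0$ point (identical
  boxes). Non-overlapping boxes have $IoU = 0$.
* **Composite loss.** Categorical cross-entropy for class scores over
  positives, binary cross-entropy for IoU-aware objectness over positives
  and negatives (every non-positive anchor is treated as a negative),
  CIoU summed over positives, and an optional late-stage L1 offset term,
  weighted by $\lambda_{1..3}$ and divided by $N_{pos}$. The weights are
  unspecified by the method; defaults are $\lambda = (1, 5, 1)$, the
  convention of anchor-free single-stage detectors, and configurable.

## Evaluation metrics

Detection counts use greedy one-to-one matching in descending confidence at
an IoU threshold (default 0.5) — the Pascal-VOC convention; the matching
rule itself is a choice, and tests verify the greedy count never exceeds the
exhaustive optimal assignment and agrees with it in ≥95% of random
instances. Precision, recall and F1 are reported as percentages with a
zero-denominator-gives-0 convention. Average precision integrates the
monotone precision envelope over recall (all-points interpolation; a
101-point variant is available). Line quality is the angular error
$\Delta\theta = |\arctan a_1 - \arctan a_2|$, averaged over rows
($n_a$), and fit time is wall-clock around the fitting pipeline, averaged
over images — reported but never asserted against, being
hardware-dependent.

## The synthetic scene generator

`generate_scene()` emulates what drives the algorithms above — geometry and
photometry — and nothing else. Two row lines are set by their top/bottom
x-anchors (defaults converge toward a vanishing point above a 640×480
frame, slopes ±6.84 in y-of-x form); plants are isotropic Gaussian-profile
green blobs at fixed y-spacing with optional placement jitter; gaps remove
indexed plants; weeds are smaller off-row blobs; a multiplicative axial
illumination falloff (range and profile exponent) is applied last. Ground
truth (boxes, lines, navigation line, gap indices) is exact, and every
output is a pure function of the configuration and seed.
`perturb_detections()` turns ground truth into detector-like output: centre
jitter, missed boxes, uniform clutter, confidences in (0.3, 1).

What the generator does **not** model: leaf morphology and occlusion, straw
residue, soil texture beyond weak white noise, perspective foreshortening of
blob size, curved rows, or more than two rows. Passing tests therefore
demonstrate the geometric and photometric correctness of the algorithms
under controlled conditions — not detector performance on real field
imagery, which depends on a trained model outside this package's scope.

Augmentation follows the six-way convention (colour shift, brightness
offset, contrast gain, additive Gaussian noise, rotation, mirror), each
deterministic given its seed, expanding N originals to exactly 7N images;
mosaic compositing is provided as an operation but excluded from the
expansion count, since the ×7 arithmetic implies exactly the six
single-image transforms. Default magnitudes (hue shift ±10/255, brightness
±0.15, contrast gain 0.8–1.2, noise sd 0.02, rotation ±10°) are modest
values typical for field imagery; the operations, not the magnitudes, are
prescribed. `split_dataset()` apportions 8:1:1 by largest remainder.

## Validation problem sizes

The test suite validates at sizes chosen to exercise every code path while
keeping the whole suite fast to run routinely: gamma tables against an
explicit-loop oracle on fifty 16×16 maps; weighted least squares against a
grid-refinement minimiser and `stats::lm` on one hundred ≤10-point
instances; pooling identities on one hundred tensors up to 8×32×32; the
kernel-size rule exhaustively for 1–4096 channels; CIoU invariances on one
thousand random box pairs; AP against threshold enumeration on five hundred
≤6-detection instances; dataset expansion on 800 stand-in 64×64 scenes; and
navigation-line recovery on one hundred seeded scenes (20 plants/row, one
gap per row, 2 px centre jitter, 3 clutter boxes), where the mean angular
error is a fraction of a degree and weighting beats plain least squares in
well over 90% of seeds. `scripts/acceptance.R` recomputes these headline
numbers from scratch.

## Known limitations

* Straight rows only; curvature would need a different line model.
* The fitting form conversion cannot represent exactly vertical rows
  (infinite slope); real forward-facing cameras are slightly off-axis, so
  this arises only in synthetic edge cases.
* The enhancement operates on a global histogram; spatially varying colour
  casts and mixed lighting are out of scope, as is any denoising.
* Fit-time measurements are environment-dependent and intentionally never
  part of any correctness claim.

## A worked example

```{r example, eval = FALSE}
cfg <- scene_config(gap_left = 7, weeds = 4, jitter = 0.5, seed = 42)
scene <- generate_scene(cfg)
dets <- perturb_detections(scene, sigma_center = 2, n_false = 3, seed = 43)
fit <- fit_crop_rows(dets, cfg$width, cfg$height)
summary(fit)
angular_difference(fit$nav$mc, scene$nav$mc)$degrees
```
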