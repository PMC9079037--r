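---
title: "Methods: RGB/IRT camera fusion for neonatal cpTD monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RGB/IRT camera fusion for neonatal cpTD monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neotherm)
```

## The measurement problem

Neonates in intensive care are monitored with adhesive skin sensors that can
injure immature skin. Contactless alternatives combine an RGB camera — on
which modern pose estimators can locate body landmarks — with an infrared
thermography (IRT) camera, whose pixels encode surface temperature. Because
the two sensors differ in optics, resolution (here 1920 x 1200 RGB vs
1024 x 768 IRT) and field of view, landmarks found in the RGB frame must be
*registered* into IRT coordinates before temperatures can be read off.

The clinical quantity of interest is the central–peripheral temperature
difference (cpTD): the mean skin temperature over central landmarks (face,
neck, shoulders) minus the mean over peripheral ones (elbows, wrists, hips,
knees, ankles). A rising cpTD accompanies centralization of circulation and
is a recognized early marker in neonatal sepsis screening. `neotherm`
implements the full chain — registration, keypoint transfer, ROI
temperature extraction, cpTD — together with the evaluation machinery
(OKS-based AP/AR, point-transformation error, cpTD error statistics,
Bland–Altman agreement) and a synthetic phantom generator that makes every
stage testable without clinical data.

## Registration model

The RGB-to-IRT mapping is a symmetric field-of-view crop followed by an
affine transform,

$$p' = A\,(p - c) + t, \qquad
A = R(\theta)\,\mathrm{diag}(s_x, s_y),$$

where $c = (c_x, c_y)$ are crop margins removed from each left/right and
top/bottom RGB border, so the crop contributes exactly two parameters. All
coordinates are 0-based pixel centers (x = column, y = row, origin
top-left); this convention is fixed package-wide because crop/affine
composition is meaningless without one. Points are transformed exactly and
only rounded when indexing ROI windows; images are resampled with bilinear
interpolation.

Alignment quality is scored by mutual information (MI) in nats,

$$I(X,Y) = \sum_{x,y} p(x,y)\,\log\frac{p(x,y)}{p(x)\,p(y)},
\qquad 0 \log 0 \equiv 0,$$

estimated from the joint histogram of the warped (grayscale) RGB frame and
the thermogram over the validity mask — the IRT pixels whose inverse-mapped
source falls inside the cropped RGB frame. MI is the standard criterion for
multimodal registration because it rewards statistical dependence rather
than equal intensities. Defaults that the data do not dictate and that we
therefore fixed once:

* **Grayscale conversion** — Rec. 601 luma (0.299 R + 0.587 G + 0.114 B).
* **Histogram bins** — 64 equal-width bins per image, ranges from the
  observed min–max over the overlap mask; 64 balances bias and variance at
  IRT resolution.
* **Overlap guard** — candidates whose valid overlap covers less than
  `min_overlap_fraction = 0.25` of the IRT frame have their MI scaled by
  `overlap / 0.25`. MI is notorious for spurious maxima on tiny overlaps;
  the proportional penalty removes them without a hard wall.
* **Search bounds** — scale in [0.3, 1.5] (the sensor-size ratio of the two
  cameras is about 0.6), rotation within ±15° (the cameras share a rig),
  translation within ±200 IRT px, crop margins in [0, 400] px.

## The optimizer

The fit is a seeded, derivative-free search with a hard budget of
`n_evals = 500` objective evaluations (matching the original studies'
optimization budget), run on block-mean downsampled images (factor 4 by
default) purely for speed — the in-basin optimum of the coarse objective
sits within 1 px of the full-resolution one on phantom pairs, and the
returned map and MI are always expressed at full resolution.

The budget is split into:

1. **Global stage** (30%): a Latin-hypercube sample of the seven-parameter
   box, augmented with a *moment-matching initial guess* — foreground
   pixels (intensity above 30% of the range) of both images are summarized
   by their centroid and covariance; aligning centroids, principal axes
   and axis variances gives closed-form estimates of $t$, $\theta$, $s_x$,
   $s_y$ — plus a cloud of 30 jittered copies of it.
2. **Local stage** (70%): Nelder–Mead simplex descent on bound-normalized
   parameters from the best global candidate, restarted once (restarting
   rebuilds the simplex around the incumbent and reliably escapes premature
   convergence), then a short Gaussian polish with decaying step width.

We first implemented the local stage as a pure random walk with fixed
Gaussian steps of 10% of each bound range. That design recovers sampled
ground-truth maps to only ~30–50 px keypoint error within 500 evaluations —
an order of magnitude short of what ROI extraction tolerates — because a
fixed-width walk neither travels far enough from a mediocre incumbent nor
resolves the optimum finely. The moment initializer plus restarted
Nelder–Mead brings all ten benchmark seeds below 5 px (most below 1 px)
within the same budget, so that design was adopted. The crop margins and
the translation are partially redundant for point transfer (only
$t - A\,c$ matters geometrically; the crop additionally moves the field of
view), which is why keypoint transfer can be accurate even when crop and
translation individually trade off against each other.

Registration is fitted once per subject and reused for all of that
subject's frames, mirroring per-patient calibration in practice.

## Keypoints, OKS, and the mock detector

The landmark vocabulary is the 17 COCO person keypoints plus a derived
`neck` (midpoint of the shoulders; its visibility is the minimum of the two
shoulder flags, and it is absent whenever either shoulder is). The
central/peripheral split assigns the facial points, shoulders and neck to
the central group and everything else — including the hips — to the
peripheral group; the hip assignment is a judgment call on "upper body
region" and is therefore configurable rather than hard-coded.

Detection quality is scored by object keypoint similarity,

$$\mathrm{OKS} = \frac{\sum_i \exp\!\big(-d_i^2 / (2 s^2 k_i^2)\big)\,
[v_i \ge 1]}{\sum_i [v_i \ge 1]},$$

with $d_i$ the landmark distance, $s^2$ the annotated mask area, $v_i$ the
ground-truth visibility and $k_i$ the published COCO per-keypoint
constants (the neck inherits the shoulder constant). AP/AP75/AR follow the
COCO protocol: greedy per-frame matching in descending confidence at each
OKS threshold 0.50:0.05:0.95, 101-point interpolated precision–recall, at
most 20 detections per frame for recall.

Training a pose network is out of scope; the package instead ships a
seeded *mock detector* that drops each landmark with a configurable
probability, jitters survivors with isotropic Gaussian noise, assigns
confidences decreasing with realized jitter (so precision–recall curves
are non-degenerate), and can hallucinate spurious landmarks on empty
slots. Any real detector can be plugged in as a function returning a
`keypoint_set`.

## Temperature extraction

Around each transformed landmark a square ROI (default 10 x 10 px; the
source studies quote both 10 px and 20 px windows, so the size is exposed
as a parameter rather than silently resolved) is read with the half-open
center-rounded convention `lo = round(c) - size %/% 2`,
`hi = lo + size - 1`; windows are clipped at the frame border and the
remaining pixels used, because limbs legitimately reach the image edge.
The landmark reading is the ROI *maximum* — the warmest pixel is the most
likely bare-skin pixel and absorbs small registration errors. Group means
are unweighted arithmetic means of the ROI maxima, and
`cptd = central_mean - peripheral_mean`. A negative cpTD is a legitimate
output (clothing can warm the periphery above the face); only an *empty*
group makes the record undefined, which is flagged rather than raised.
Error summaries use the sample standard deviation (n − 1). Bland–Altman
differences are ground truth minus estimate, so a positive mean difference
reads as underestimation.

Thermograms are carried as °C float matrices; on disk they are 16-bit
TIFFs with a linear centikelvin code, `raw = round((T + 273.15) * 100)`,
whose 0.01 °C step is finer than the 20 mK sensor sensitivity and bounds
round-trip error by 0.005 °C.

## The phantom: what it emulates and what it does not

The generator renders a supine neonate-like figure — head and trunk
ellipses plus capsules along the skeleton — in skin tones on a dark
background (background ≈ 10/255, skin ≈ 175–230/255, emulating recordings
under dim OLED-only illumination), and the *same* geometry as a
temperature field in the IRT frame. The thermal render is the exact
pull-back of the RGB-space geometry through the inverse of the known
ground-truth map, so the two silhouettes correspond perfectly under that
map and registration recovery can be judged against analytic truth.

Surface temperature is `t_central` (default 37.0 °C) over head and trunk
and falls linearly along each limb to `t_peripheral` (default 33.5 °C) at
the wrists and ankles; the background sits at `t_background` (default
22.0 °C) and Gaussian sensor noise (default SD 0.05 °C IRT, 2 intensity
units RGB) is added last. Defaults were chosen once as physiologically
plausible NICU values and are not tuned.

A monotone limb gradient alone cannot make each landmark's ROI maximum
analytically exact — a window centered mid-limb always contains a warmer,
more proximal pixel. Each landmark therefore carries a small flat-topped
warm spot (`kp_bump`, default 0.5 °C, plateau radius 1.5 px, outer radius
6 px, rendered in IRT coordinates): some pixel center always lies on the
plateau, so the noiseless ROI maximum *equals* the analytic
`kp_peak_temp = base + kp_bump` exactly, and the bump height cancels
between the central and peripheral means, leaving the closed-form cpTD of
`analytic_cptd()` untouched. The bump must exceed the thermal gradient
across one ROI reach (about 0.2 °C at default scale); the test suite's
small phantoms raise it to 1 °C for the same reason. Clothing is modeled
as axis-aligned rectangles (in RGB coordinates) that overwrite the surface
temperature in IRT, recolor the RGB frame, and mark covered landmarks
occluded — enough to reproduce the negative-cpTD clothing scenario, and
deliberately no more.

Passing tests on the phantom therefore demonstrate geometric and
arithmetic correctness of the chain, not clinical performance: the phantom
has no pose articulation, no specular or emissivity effects, no moving
staff hands, and its intensity structure is far cleaner than clinical
video. Quantities like the phantom-study cpTD MAE are expected to be
*better* than published clinical figures.

## Numerical and degenerate-input choices

* Identical configuration + seed reproduces byte-identical images, CSVs
  and fitted maps; every stochastic component receives a seed derived from
  the one global seed.
* Constant images are rejected by `fit_registration()` with an explicit
  degenerate-input error; a non-invertible candidate inside the search
  returns an objective of −Inf instead of raising.
* An empty central or peripheral group flags the `cptd_record`
  (`defined = FALSE`) and frames with undefined cpTD are excluded pairwise
  from MAE/Bland–Altman but counted in the report.
* "Total" rows in evaluation tables pool all frames (or point pairs)
  across subjects; they are not averages of per-subject means.
* Problem sizes used by the validation suite were chosen for quick
  iteration: unit tests run on 640 x 400 / 320 x 240 phantoms, the
  registration-recovery and acceptance studies on the full
  1920 x 1200 / 1024 x 768 geometry with 10 recovery pairs and a
  6-subject x 5-frame study.

## Known limitations

* The affine-plus-crop model cannot express lens distortion; like the
  clinical registration errors it emulates, residual error grows toward
  the frame borders under anisotropic optics. Deformable registration is
  explicitly out of scope.
* OKS constants are the adult COCO sigmas; no neonate-specific constants
  exist in the literature.
* The mock detector's error model (isotropic Gaussian + uniform false
  positives) is a caricature of a CNN's failure modes; AP numbers on the
  phantom say nothing about any real network.
* Absolute radiometric calibration (emissivity, reflected temperature) is
  not modeled; the package measures *relative* temperature differences.

## Worked example

```{r example, eval = FALSE}
library(neotherm)

# one phantom subject with a known ground-truth map
pose <- phantom_pose()
map  <- sample_registration_map(pose, c(1024, 768), seed = 1)
gp   <- generate_phantom_pair(phantom_config(true_map = map, pose = pose, seed = 1))

# registration by MI maximization (500 evaluations, seeded)
fit <- fit_registration(gp$pair$rgb, gp$pair$irt, optimizer_settings(seed = 1))

# transfer landmarks and extract the cpTD
kps_irt <- transform_points(derive_neck(gp$truth$kps_rgb), fit$map, c(1024, 768))
compute_cptd(gp$pair$irt, kps_irt)
```
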