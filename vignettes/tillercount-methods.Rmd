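---
title: "Counting grass tillers from tip-painted bunch images: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting grass tillers from tip-painted bunch images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Tillering — the number of above-ground shoots a single grass plant produces —
is a standard trait in breeding trials and ecology, and the manual protocol
(separating and counting every shoot of a bunch) takes minutes per plant. The
imaging protocol this package implements replaces it: the bunch is cut at
about 5 cm, the fresh cut tips are painted white with a roller, and a camera
photographs the bunch perpendicular to the soil from about 1.5 m, covering
roughly a 50 × 50 cm field of view. Painted tip cross-sections become bright
compact objects on a dull soil background; counting tillers becomes counting
those objects.

The pipeline has four stages, each an exported function family:
segmentation (`to_blue_band()`, `max_contrast_threshold()`,
`open_and_label()`), morphometry (`compute_feature_table()`), classification
(`vif_prune()`, `fit_lda()`, `classify_objects()`, `count_tillers()`), and
method agreement (`error_metrics()`, `r_squared()`,
`identity_regression_test()`, `agreement_report()`).

## Segmentation

**Band choice.** Soil reflects red, green and blue in nearly equal
proportions, green vegetation peaks in green, and white paint is bright in
all bands — so the blue band maximises paint/background contrast and is the
default (`band = "blue"`; red and green remain available).

**Automatic threshold.** We use the maximum-average-contrast criterion
(Köhler 1981): a candidate threshold $s$ *separates* a 4-adjacent pixel pair
$(p, q)$ when $\min(I_p, I_q) \le s < \max(I_p, I_q)$, and earns contrast
$\min(|I_p - s|, |I_q - s|)$ from it; the selected threshold maximises the
mean contrast over the pairs it separates, with ties broken toward the lower
threshold. For a two-level image with levels $a < b$ this lands at the
midpoint $\lfloor (a+b)/2 \rfloor$. A constant image has no separating pair
and is an error: no threshold separates it. The implementation aggregates
identical $(\text{lo}, \text{hi})$ pairs, so the exhaustive scan over all 255
candidates is exact, and the test suite checks it against an independently
coded brute-force evaluator.

**Opening and the area filter.** The threshold mask is opened with a digital
disk (radius 1 by default — the 4-neighbour cross), then 8-connected
components below `min_area = 200` px are removed. The published protocol
states only that opening "removes objects smaller than 200 pixels"; whether
that was a structural opening, an area opening, or both is not recoverable,
so we implement the conservative combination — a small structural opening for
speckle plus an exact area filter, each independently configurable — which
guarantees the stated 200-px contract exactly. Foreground connectivity is
8-connected (background 4-connected), and objects touching the image border
are kept: border tips are real shoots.

## The eleven morphometric parameters

For each object we compute area $A$; Crofton perimeter $P_{Crof}$;
compactness $SF_{comp} = 16A/P_{Crof}^2$; equivalent-ellipse axis lengths
$l_{max}, l_{min}$ and elongation
$SF_{elong} = |l_{max} - l_{min}|/(l_{max} + l_{min})$; convex-hull area
$A_{conv}$, perimeter $P_{conv}$ and minimum interior angle $CMA$; convexity
$SF_{conv} = A/A_{conv}$; symmetry mean difference $SMD$; Feret diameters
$FD_{max}, FD_{min}$; and Pentland sphericity
$SF_{sfer} = 4A/(\pi FD_{max}^2)$. Shoot tips are compact, nearly convex and
nearly centrally symmetric (low $SF_{elong}$, $SF_{conv}$ and $SF_{sfer}$
near 1, low $SMD$); cut leaf fragments are long and thin; debris is small and
ragged.

Estimator choices the source protocol leaves open:

* **Crofton perimeter.** Chord counts $c_\theta$ along scan lines in 4
  directions with $P = (\pi/4)\,(c_0 + c_{90} + (c_{45} + c_{135})/\sqrt 2)$
  (diagonal lines are $1/\sqrt2$ apart). This calibration is unbiased for a
  disk — $P(\text{disk } r) = 2\pi r$ within 0.3 % at $r = 100$ — which also
  fixes $SF_{comp}(\text{disk}) = 4/\pi$. A 2-direction variant is available
  for comparison. A single pixel evaluates to $(\pi/4)(2 + \sqrt2) \approx
  2.68$.
* **Axes.** $l_{max}, l_{min}$ are the full axes of the ellipse with the same
  second central moments as the pixel set (plus the $1/12$ unit-square
  moment), the standard rotation-invariant estimator.
* **Hulls.** The convex hull is taken over the pixel *corner* points, i.e.
  the hull of the union of unit squares. This makes $A_{conv} \ge A$ an exact
  invariant and makes Feret diameters the true caliper widths of the drawn
  object (a 120 × 40 px rectangle gives $FD_{min} = 40$, $FD_{max} = 126.5$
  exactly). The one exception is $CMA$, computed on the pixel-*centre* hull:
  corner clouds blunt every sharp vertex with half-pixel micro-edges, pushing
  a true 60° corner to ~90°, while the centre hull preserves it.
* **Feret diameters.** Exact rotating-calipers on the hull ($FD_{max}$ = hull
  diameter; $FD_{min}$ = minimal width over hull edges), with a 1° direction
  grid available as a cross-check (they agree within 0.5 %).
* **SMD.** The printed definition pairs "two opposite boundary points" but
  fixes no pairing rule. We resample the boundary to $2N = 360$
  centroid-to-boundary radii at equal polar angles (circular linear
  interpolation over the boundary-pixel radii) and pair $i$ with $i + N$. The
  text calls the statistic a *mean* while the displayed formula is a bare
  sum; we report the mean as `SMD` and keep the raw sum as `SMD_sum`, so
  either convention can be reproduced.
* **Sphericity at pixel resolution.** Because corner-hull Feret diameters
  measure the union of squares, $SF_{sfer}$ of a rasterized disk carries an
  $O(1/r)$ negative bias ($\approx (2r/(2r+1))^2$ times the lattice-count
  ratio); at $r = 100$ it is 0.990. Tests anchor sphericity at the top of the
  50–100 px tip-scale range, where discretisation bias is smallest.

Units are pixels; `mm_per_px` rescales lengths and areas to calibrated units
without touching the dimensionless factors.

## Classification

**Collinearity pruning.** The dimensional features are strongly collinear
(area, convex area, Feret diameters and convex perimeter all track object
size). `vif_prune()` repeatedly deletes the feature with the largest variance
inflation factor $VIF_j = 1/(1 - R_j^2)$ until all survive at or below 10,
the conventional cut; exact collinearity reports an infinite VIF, and ties
delete the later column so the procedure is deterministic.

**LDA.** `fit_lda()` is a two-class Fisher discriminant:
$w = W^{-1}(\mu_{shoot} - \mu_{non})$ with pooled within-class covariance
$W$, cut point at the midpoint of the projected class means shifted by the
log prior ratio (empirical priors by default — non-shoots can outnumber
shoots in debris-heavy images — equal priors optional). Per-variable
diagnostics are always reported: tolerance $T_j$ (1 − $R^2$ of $j$ on the
other model variables, computed from the pooled *within-class* scatter, the
discriminant-analysis convention, since class separation should not count as
collinearity); Wilks' $\Lambda_{-j}$ of the model with $j$ removed, via the
two-class identity $\Lambda = 1/(1 + D^2 n_1 n_2 / (n(n-2)))$ on Mahalanobis
$D^2$; and the partial F-to-remove
$F_j = (n - p - 1)(\Lambda_{-j}/\Lambda - 1)$ on $(1, n - p - 1)$ degrees of
freedom. The selection rule of the original software is not documented, so we
adopt classical backward elimination: repeatedly drop the variable with the
smallest F-to-remove while it is below `f_remove = 1`. Objects exactly on the
decision boundary are assigned to *shoot*: in breeding use, under-counting is
the costlier error. Different species need different feature sets (stem
sections differ in size and flatness), so models carry a species key and are
stored per species as JSON.

## Agreement statistics

`error_metrics()` reports RMSE, MAE, the *signed* mean bias error
MBE $= \overline{E - O}$, and MSE $= \overline{(E-O)^2}$. MSE is reported
explicitly alongside MBE because agreement tables in this literature
sometimes print the squared form under a bias-error label; keeping both,
clearly keyed, removes the ambiguity (and $MSE = RMSE^2$ is asserted in the
tests). `r_squared()` is the identity-line form
$R^2 = 1 - \sum(O_i - E_i)^2 / \sum(O_i - \bar O)^2$ — *not* the squared
correlation; it penalises bias and is 1 only for exact agreement.
`identity_regression_test()` fits E on O and F-tests the slope against 1 and
the intercept against 0 (squared-t on $n-2$ df); with zero residual variance
the p-values are 1 by convention. Reports always print exact p-values.

## The synthetic world

`render_scene()` emulates the acquisition protocol, not its photorealism:

* **Soil**: correlated Gaussian texture (bilinear upsampling of a coarse iid
  grid, correlation length 8 px) around intensity 90 ± 12, identical in the
  three bands up to iid noise of sd 2 — matching soil's near-equal RGB
  reflectance — plus a linear illumination gradient of ±10 levels in a random
  direction.
* **Painted tips**: near-white (235–255) filled ellipses. Stems are 2–6 px
  wide at the default 0.33 mm/px (50 cm field over ~1500 px), far below the
  200-px filter, but the roller spreads paint well beyond the stem section,
  so the rendered blobs use equivalent diameters of 18–30 px (≥ ~254 px²),
  clearing the filter by construction. Species profiles set the eccentricity:
  `round` (axis ratio 1–1.4), `flattened` (1.8–3, emulating flattened stem
  bases), `thin` (smaller, rounder). Placement enforces a separation margin
  except for an explicit overlap budget (2 % of tips by default), so touching
  tips can merge and the pipeline's under-counting mode is exercised.
* **Distractors**: leaf fragments as curved ribbons 60–220 px long and
  3–7 px wide at intensity 190–225 (bright enough to segment, so the
  classifier — not the threshold — must reject them), and debris as ragged
  multi-lobed blobs, mostly below 200 px.

All randomness flows from one mandatory seed; rendering is bit-reproducible.
`generate_dataset()` draws true counts O uniformly from 15–356 (the span
observed across species in breeding bunches), renders and segments each
image, labels segmented objects against the ground-truth painted raster
(shoot when ≥ 50 % of the object's pixels are painted), and emits a training
table of ~20 % of objects per image, mirroring the field protocol's labelled
fraction.

**What a green test establishes — and what it does not.** The generator
reproduces the *geometry* of the task (bright compact tips, elongated leaf
distractors, sub-filter debris, merged neighbours, illumination drift) but
not field photography: no specular paint highlights, motion blur, JPEG
artefacts, standing stubble seen obliquely, or species-specific leaf
textures. End-to-end results on synthetic scenes therefore validate the
pipeline's internal consistency and its statistical machinery, not the
field-accuracy figures of the original study, which depended on photographs
that are not available. Tip intensity must sit clearly above the soil range
(the `scene_spec()` constructor refuses non-separable settings), so the synthetic world
states — rather than discovers — segmentability; the interesting questions it
answers are about morphometric separation and counting calibration.

## Numerical choices and degenerate inputs

* Threshold ties go to the lower threshold; images with a single grey level
  are an error, and a blank (soil-only) image yields zero objects after the
  area filter rather than an error.
* Degenerate objects (area < 2 px, collinear pixel sets, hulls with < 3
  vertices) are dropped from feature tables with a warning naming their ids;
  direct calls to the individual estimators raise errors instead.
* A centroid outside a non-convex object (crescents) logs a warning and
  computes SMD anyway.
* Exactly collinear features give an infinite VIF sentinel; a singular
  pooled covariance in LDA is an error advising stronger pruning, never a
  silent pseudo-inverse.
* All simulation seeds are 32-bit integers; per-image seeds are drawn from
  the master seed, so datasets are reproducible image by image.
* Default constants — 200 px area filter, VIF threshold 10, 20 % training
  fraction, blue band — are the protocol's stated values and are configurable
  everywhere they appear.

## Known limitations

* Merged touching tips under-count by design (the overlap budget makes this
  visible); no watershed or concavity-based splitting is attempted.
* Debris that is simultaneously larger than 200 px, bright, compact and
  convex is morphometrically indistinguishable from a tip and will be
  counted; the original protocol had the same failure mode.
* TIFF input is not supported in this build (no decoder available); PNG and
  JPEG are.
* Label maps are written as two-channel 8-bit PNGs (`label = R + 256·G`)
  because the available PNG writer cannot emit true 16-bit samples; the
  encoding is lossless up to 65535 objects and `read_label_map()` inverts it.
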