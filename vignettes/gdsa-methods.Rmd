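---
title: "Gradient dose segmented analysis of transit EPID images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient dose segmented analysis of transit EPID images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidGDSA)
```

## The problem

Pre-treatment patient-specific QA verifies that a VMAT plan is deliverable;
it says nothing about what happens to the patient over the six or seven
weeks of a course. Head-and-neck patients in particular lose weight and
tumour volume continuously, and the dose actually delivered drifts away
from the plan. Transit EPID dosimetry watches this for free: the portal
imager integrates the treatment beam after it has passed through the
patient, every fraction, with no extra imaging dose. The difficulty is
reducing a pair of 1280 × 1280 dose images to a number that tracks a
clinically meaningful quantity. Gamma passing rates correlate poorly with
DVH changes; the gradient dose segmented analysis (GDSA) mean statistic
was designed as a surrogate for the change in PTV mean dose, and that is
what this package computes, together with the two measurements used to
explain its excursions: body-separation change and rotational setup error.

## The model

### Composites and normalization

All arcs of one fraction are summed pixel-wise into a composite
(`buildComposite()`), mirroring the integrating panel. The first
fraction's composite is the reference; it is normalized to percent of its
own maximum (`normalizeToPercent()`), with the division done before the
multiplication by 100 so the maximum is exactly 100 in floating point.

### The generalized gradient and the ROI

On the normalized reference, the generalized gradient at pixel $i$ is

$$G_i = \sqrt{\sum_{j \in N_4(i)} \left(\frac{\Delta d_{ij}}{\Delta x_{ij}}\right)^2},$$

the root of the summed squared dose differences to the four nearest
neighbours, each divided by the pixel pitch $\Delta x_{ij}$ (0.336 mm at
the imager plane for a 43 cm panel read out at 1280 pixels;
`derivePixelPitch(430, 1280)`). Units are %/mm. Two details are fixed by
design rather than by any authoritative definition:

* **Sum versus mean inside the root.** Summing the (up to four) squared
  neighbour terms is the default; `gradientMap(..., agg = "mean")`
  averages them instead, for sensitivity checks. For a locally linear
  dose the sum form gives $|\nabla d|\sqrt{2}$, the mean form
  $|\nabla d|/\sqrt{2}$ along an axis-aligned ramp; either is a
  consistent %/mm gradient magnitude, and the segmentation threshold is
  what gives the number meaning.
* **Edges.** Border pixels use only their existing neighbours (three at
  an edge, two at a corner). Padding by replication would zero the
  border gradient artificially; leaving the terms out keeps the border
  classification honest.

Pixels are then segmented (`segmentRegions()`) by a dose threshold
(default 5% of the reference maximum) and a gradient threshold (default
3 %/mm) into four disjoint, exhaustive regions. Tie-breaking is fixed and
documented: *high dose* is inclusive (dose ≥ 5%), *low gradient* is
exclusive (gradient < 3 %/mm), so masks are bit-reproducible. The GDSA
region of interest is the high-dose low-gradient cell — plateau pixels
away from penumbra, where a small anatomical change produces a coherent
dose shift rather than a geometric artefact.

### The statistic and the flag

For fraction $n$, the signed difference map normalized to the reference
maximum is $100\,(D_n - D_{\mathrm{ref}})/\max(D_{\mathrm{ref}})$
(`doseDifferencePercent()`; positive = hotter = increased transmission,
as with weight loss). GDSA$_\mu$ is its arithmetic mean over the ROI;
the accompanying spread is the standard deviation of the same pixel
distribution, population form (divide by $n$) by default and switchable
to the sample form (`gdsaStatistic(..., sdType)`). A fraction is flagged
when $|\mathrm{GDSA}_\mu| \ge 3\%$ — inclusive, matching the 3%
dose-delivery accuracy tolerance — while the separation flag below is a
strict inequality; the two tie rules are deliberate and tested.

An empty ROI raises an error rather than returning zero: a fraction whose
reference has no analyzable plateau is unanalyzable, not perfect.

`analyzeSeries()` computes the gradient map and masks once per reference
segment and evaluates every other fraction against the reference of its
segment. Passing several `referenceFractions` re-baselines the analysis
mid-course, the standard handling of a replan: the new plan's first
fraction becomes the new reference and the trend restarts at zero.
Geometry-mismatched fractions are warned about and skipped rather than
aborting a course.

### Separation change

On the axial CBCT slice through the treatment isocentre, the body mask is
extracted by thresholding at −300 HU (a conventional external-contour
level, configurable), keeping the largest 4-connected component (this
removes couch and immobilization hardware) and filling internal air
cavities (`extractBodyMask()`). Separations are the bounding-box extents
of that mask along the fixed image axes — rows for anterior-posterior,
columns for lateral — converted to cm. Extents rather than chords through
the isocentre were chosen because they are insensitive to the exact
isocentre position within the slice and are directly testable against
rasterized phantoms; a rotated structure therefore measures as its
bounding box, not its side lengths.

Per-fraction changes are absolute differences against the reference
fraction's separations, and the effective separation change diameter is
their geometric mean,

$$\Delta d_{\mathrm{eff}} = \sqrt{\Delta d_{\mathrm{lat}}\,\Delta d_{A\text{-}P}},$$

which keeps cm units, is symmetric and monotone in both arguments, and is
zero whenever either axis is unchanged. A fraction's anatomy flag uses a
strict 1 cm threshold on $\Delta d_{\mathrm{eff}}$, below which uniform
body-contour change is unlikely to matter dosimetrically.

Because extents are pixel counts, each measured separation carries up to
one pixel of quantization and a *difference* of two extents up to two
pixels in unfavourable schedules; at the 1 mm slice grid this is 0.1–0.2
cm, negligible against the 1 cm flag threshold.

### Rotational setup errors

Patient setup rotations are read from the daily rigid registration
matrix. The convention is fixed and documented once: pitch $\theta$ about
the patient left-right axis, roll $\zeta$ about the superior-inferior
axis, yaw $\varphi$ about the anterior-posterior (vertical) axis,
composed extrinsically as
$R = R_{\mathrm{yaw}} R_{\mathrm{roll}} R_{\mathrm{pitch}}$. The
decomposition (`anglesFromMatrix()`) is closed-form
($\zeta = \arcsin R_{21}$, $\theta = \mathrm{atan2}(-R_{23}, R_{22})$,
$\varphi = \mathrm{atan2}(-R_{31}, R_{11})$), exact away from
$|\zeta| = 90°$ — far outside the few-degree regime of patient setup —
and is covered by round-trip tests so a convention change stays
localized. Matrices whose rotation block is not orthonormal with unit
determinant (within 1e-6) are rejected as non-rigid. Cohort summaries
report per-axis maximum, mean and standard deviation of the *absolute*
angles; signed values are retained in the per-fraction records.

## File formats

DICOM RT Image and DICOM Spatial Registration objects are read (and, for
fixture generation, written) by a small built-in codec restricted to the
explicit-VR little-endian transfer syntax and the tags this package
needs; pixel values are mapped to Calibrated Units through the stored
rescale slope/intercept, and the pixel pitch comes from the image-plane
pixel spacing. A portable plain-text format (whitespace-delimited array
plus a JSON sidecar with pitch, fraction index and arc label) and
plain-text 4×4 matrices are accepted everywhere DICOM is, so analyses and
tests can run on human-readable inputs. Results leave the package as
plain CSV (`writeResultsTable()`, `exportTimeseries()`).

## The synthetic-patient generator

`generatePatient()` produces, from one seed, a full course with known
ground truth; its defaults are the package's standing study conditions:

* **EPID composite**: a centred flat plateau of 100 CU covering 40% of a
  256 × 256 image at 0.336 mm pitch, with Gaussian shoulders of width
  3 mm playing the penumbra. The flat interior guarantees a non-empty
  high-dose low-gradient ROI and makes closed-form expectations exact.
* **Weight loss**: a spatially uniform multiplicative transmission gain
  of 0.002 per fraction. Under this model
  $\mathrm{GDSA}_\mu = 100\,\alpha_n \cdot
  \overline{D_{\mathrm{ref,ROI}}}/\max(D_{\mathrm{ref}})$ exactly, which
  is what the parameter-recovery tests assert to 1e-9. Over 30 fractions
  the gain reaches ~6%, crossing the 3% flag threshold around fraction
  16 — the late-course drift typical of head-and-neck weight loss. An
  optional left-right gain ramp (`alpha_ramp`) spreads the ROI
  distribution to produce realistic non-zero error bars without moving
  the mean.
* **Body contour**: an axis-aligned ellipse of 20 cm (A-P) × 28 cm
  (lateral) on a 1 mm grid, shrinking 0.13 cm per fraction per axis —
  about 3.8 cm over a course, the magnitude of a pronounced clinical
  weight-loss case.
* **Rotations**: deterministic drifts (0.1°, 0.05°, 0.05° per fraction
  for pitch/roll/yaw in the drift scenarios, staying within ±4° over a
  course) plus optional Gaussian jitter.
* **Noise**: additive Gaussian in CU, default 0 so exact tests stay
  exact (negative values are clipped at zero dose). No claim is made
  that this is a physical EPID noise model; at 0.336 mm pitch even
  sub-percent white noise produces apparent gradients of several %/mm,
  which is why noisy references can shed a small fraction of their ROI.
  The GDSA mean is insensitive to this (it is an ROI average), and the
  noisy-recovery test asserts agreement with the closed form within
  Monte-Carlo error rather than exactly.
* **Replan**: the `"replan"` scenario restarts the transmission gain at
  zero at the replan fraction (default two thirds through the course),
  and the analysis is re-baselined there — flags appear before the
  replan, none after.

What the generator does *not* emulate: real anatomical deformation (the
gain is spatially uniform or linearly ramped, not anatomy-driven),
scatter and beam-hardening, EPID sag or calibration drift, and any
coupling between the rotation ground truth and the EPID image (rotations
enter only through the registration matrices). Passing tests therefore
demonstrate that the pipeline recovers the parameters of this model
exactly, not that the 3% threshold has any particular sensitivity or
specificity on clinical images.

## Numerical choices and problem sizes

* Gradient maps are computed vectorized from shifted differences and are
  tested against an explicit per-pixel double-loop oracle to 1e-12
  relative on random images.
* The plateau profile is exactly flat inside the field (so the centre
  pixel equals the nominal dose bit-exactly and the interior gradient is
  exactly zero) with a $C^1$ Gaussian shoulder; the shoulder's maximum
  slope (~20 %/mm at the defaults) safely exceeds the 3 %/mm threshold,
  so the penumbra is always high-gradient.
* Population standard deviations are used throughout (ROI pixels,
  |angle| summaries, cohort GDSA spread); the sample form is available
  where it matters and the choice is documented at each site.
* Test and example images are 64–128 pixels and synthetic courses 5–30
  fractions, keeping the full suite under ten seconds while every
  assertion is resolution-independent (closed forms carry the pixel
  pitch explicitly).

## Known limitations

* The reference fraction is itself an in-vivo measurement; setup error or
  atypical anatomy on day one contaminates every later comparison. The
  package mitigates this only by making the reference settable.
* No image registration is applied between reference and comparison EPID
  images; a large in-plane shift would read as a dose change.
* The cohort summary reports the exact computed percentages; rounded
  shares of small sites may not sum to exactly 100.
* The DICOM codec is deliberately minimal (explicit VR little endian
  only); compressed or implicit-VR exports must be converted upstream.
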