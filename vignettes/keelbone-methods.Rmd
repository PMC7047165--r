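---
title: "Methods: radiographic keel bone quantification and its verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiographic keel bone quantification and its verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keelbone)
```

This vignette documents the models and procedures the package
implements, the defaults and why they were chosen, what the synthetic
generators do and do not emulate, and the numerical conventions that a
re-implementation would need to reproduce the same numbers.

## 1. Step-wedge densitometry

A radiograph's gray values depend on exposure, detector gain and
processing, so they are not comparable across images. Imaging an
aluminium step wedge of known thicknesses alongside each hen anchors
the gray scale: after calibration, a keel's mean gray is expressed in
millimetres of aluminium equivalent (mm Al eq), a within-study proxy
for bone mineral density.

The default wedge has 17 steps from 0.5 to 4.5 mm in 0.25 mm
increments, and the unattenuated background provides an 18th point at
thickness 0. `fit_calibration()` fits the least-squares cubic

$$ t(g) = c_0 + c_1 g + c_2 g^2 + c_3 g^3 $$

to the 18 (gray, thickness) pairs. Three conventions here are genuine
design choices rather than field-imposed facts, and are therefore
worth stating:

* **Fit direction.** The cubic expresses thickness as a function of
  gray, not the reverse, so evaluation on keel grays is direct and no
  polynomial inversion is needed. Either detector polarity works; the
  package only requires gray to be strictly monotone in thickness and
  reports the direction it found.
* **Background as a fitted point.** The background gray enters the fit
  as a genuine (gray, 0 mm) observation; the fitted curve is checked to
  map the background to within 0.1 mm of zero and warns otherwise.
* **ROI statistic.** Step and background grays are trimmed means
  (central 80% of ROI pixels), which guards against dust and edge
  pixels without assuming any noise model.

Numerically, the Vandermonde system of raw 16-bit grays (values up to
65535 cubed) is ill-conditioned, so the fit runs on a centred and
scaled gray variable and the coefficients are expanded back exactly.
Monotonicity of the fitted cubic is verified on a 256-point grid over
the calibrated gray range; a wiggling fit is flagged, not silently
accepted. Because cubic tails are unbounded, grays outside the
calibrated range are clamped to the endpoints and flagged
(`attr(x, "clamped")`) rather than extrapolated.

## 2. Polygon scoring: POD and density

Deviations are annotated as an open polyline along the deformed
boundary. `close_deviation_outline()` joins the two extremes by a
straight chord — the first and last annotated vertices define the
extremes, which is the only workable convention when the outline is
hook-shaped — and the severity measure is

$$ \mathrm{POD} = 100 \cdot \frac{A(\text{deviation})}{A(\text{keel})}, $$

with shoelace areas, the keel outline being traced up to the insertion
of the trabecula intermedia. The chord-closed deviation polygon is an
area *estimate* and may protrude beyond the keel outline; its full area
is used by default (clipping to the keel mask is available as an
option). POD is a ratio, so it is invariant to pixel spacing and to
rigid motions of the annotation frame; the tests assert both.

Radiographic density rasterizes the keel outline to a pixel mask,
subtracts exclusion regions (callus formation and legs overlapping the
keel inflate the measure and are excluded), averages the remaining
grays and maps the mean through the calibration. Conventions: 0-based
pixel coordinates with x rightward and y downward, polygon vertices at
pixel centres, even-odd fill evaluated at pixel centres with a
half-open scanline rule (a vertex lying exactly on a scanline counts
once). Shoelace and pixel-count areas then agree to
O(perimeter × spacing), which the suite checks on random polygons.

A radiograph whose fracture status cannot be judged (legs overlapping
the caudal keel) carries `fracture_flag = NA`. That excludes the
(hen, period) from fracture analyses only; deviations scored on the
same radiograph remain usable, because deviations sit mostly in the
cranial and middle keel.

## 3. Cohort structure and inclusion rules

The longitudinal design has seven sampling periods at weeks
12–15, 19–22, 26–29, 32–35, 39–42, 49–52 and 60–62 of age
(radiographs at weeks 13, 20, 27, 33, 40, 50, 61); `period_of_week()`
maps a week of age into this schedule. Period-level values are
arithmetic means over the repeated measurements within the period
(2–3 weighings; assay duplicates averaged per day, day values averaged
per period). Assay quality control follows the standard duplicate/pool
definitions: per-pair CV = 100·sd/mean with the sample (n−1) standard
deviation, intra-assay CV = mean of per-pair CVs, inter-assay CV =
CV of a pool sample run on every kit. Locomotor activity is the count
of a hen's transponder registrations inside the lighting windows
divided by the total lighting hours (crossings/h).

The survival dataset applies the study's inclusion rules: hens not
alive at the end are dropped; for a given outcome, hens with any
non-evaluable flag for that outcome are dropped; the first period
scored positive defines the event regardless of later scores (new
hairline fractures can be missed later, so scores are not forced to be
monotone), and event-free hens are censored at period 7. Survival time
is the period index; any monotone relabelling (e.g. to weeks of age)
leaves the rank-based Cox fit unchanged, which the tests verify to
1e-8.

## 4. The two model families

**Time-to-first-damage.** `fit_cox()` fits a proportional-hazards
model on the period grid. Event times are heavily tied (seven distinct
values), so the Efron approximation is the default. The pen is the
clustering unit; "pen as a random effect" is ambiguous between a
frailty and a cluster-robust variance, so both are offered: a gamma
frailty by default, `pen_effect = "cluster"` for robust variances.
Per-term hazard ratios carry Wald confidence intervals; the global
Wald statistic pools all estimable fixed terms. A treatment level with
all-or-no events yields an unbounded coefficient; such terms are
flagged (`separation`), excluded from the global Wald, and left to the
caller — the package does not silently drop model terms.
`hr_to_percent()` converts hazard ratios to the percent risk changes
used in prose: (1−HR)·100 below 1, (HR−1)·100 above, rounded to the
nearest integer for reporting with the exact value retained.

**Longitudinal outcomes.** `fit_longitudinal()` fits Gaussian linear
mixed models by REML with line × treatment × period fixed effects
(all two-way interactions and the three-way term, no model
simplification) and random intercepts for hen nested in pen. POD,
estradiol-17β and activity are right-skewed and positive and are
log-transformed by default; weight and density are analysed untransformed.
POD is only defined for deviated hens, and deviations are scarce in the
first two periods, so POD models use deviated hens in periods 3–7. Each
term gets a marginal F test (conditional on all other terms) from the
full model; denominator degrees of freedom follow the containment
convention of `nlme::lme`, and the output records this, since df
conventions differ across software. A design with an empty
line × treatment × period cell is reported as an error naming the
cell, and the caller decides which terms to drop — mirroring how
overspecified models must be handled in practice. `random = "none"`
fits the identical fixed-effects model by ordinary least squares, the
degenerate case with both variance components at zero; the suite
checks it coincides with `lm()`.

## 5. What the generators emulate

**Phantoms.** `generate_phantom()` renders a zero-thickness
background, one rectangle per wedge step at its exact thickness, and a
blade-shaped keel polygon (28 vertices) of uniform aluminium-equivalent
thickness. If a deviation is requested, a vertical chord position is
found by root-finding so that the caudal piece of the keel polygon
holds exactly the requested shoelace-area fraction; the boundary arc of
that piece becomes the open deviation outline, exactly as an annotator
would trace it. Thickness maps to gray through a monotone detector
response:

* *linear* (default) — the case under which the cubic calibration is
  exact;
* *cubic* — a response whose **inverse** is an exact degree-3
  polynomial in gray, inverted numerically for rendering. This stresses
  the calibration while keeping its ground truth inside the cubic model
  space, so noise-free ladder recovery to below 1e-6 mm is a
  well-defined check (a gray-as-cubic-of-thickness response has no
  exact cubic inverse, and failing to fit it would say nothing);
* *saturating* — an exponential approach to the detector cap, outside
  the model space on purpose: the tests only require the fit to track
  the ladder within a few RMS residuals.

Noise is additive Gaussian on gray values; noisy images are rounded to
the integer gray grid and clipped to the bit range (8- or 16-bit),
while noise-free phantoms keep exact response values so that
calibration checks are exact. The generator makes no attempt at
physically accurate X-ray transport, breast-muscle shadowing, scatter,
heel effect or bone texture; consequently, passing truth-recovery
tests shows the *measurement code* is correct, not that the method is
robust to anatomy — robustness to real images rests on the exclusion
machinery and the human annotations, as it does in practice.

**Cohorts.** `generate_cohort()` reproduces the study's structure: two
layer lines (G11 low-performing, WLA high-performing) × four treatment
groups (C control, E estradiol implant, S deslorelin acetate implant
suppressing lay, SE both) with 19/6/19/6 hens per pen and two pens per
line (200 hens). First-fracture and first-deviation periods follow a
discrete proportional-hazards process, hazard_p = baseline_p ×
hr_treatment × hr_line (optionally × a log-normal pen frailty). The
default treatment and line factors are the fracture hazard ratios the
design emulates (E 1.17, S 0.20, SE 0.06; WLA 1.66). Baseline
per-period hazards are not published anywhere; the package fixes them
once at c(0.005, 0.005, 0.02, 0.13, 0.18, 0.12, 0.10), i.e. virtually
no fractures before the onset of lay and the steepest rise between
weeks 33 and 40, which reproduces the control-arm cumulative
prevalence pattern. Numeric outcomes are group mean curves plus pen
and hen random intercepts plus residual noise (log-normal for POD,
estradiol and activity); the curves encode the study's qualitative
patterns (S/SE density overtaking C/E late, estradiol collapse under
S, activity decline in S/SE), with variance components set to
magnitudes a field scientist would call realistic (e.g. hen-level sd
80 g for weight, 0.15 mm Al eq for density). Death before study end
and period-wise fracture non-evaluability are missing-at-random flags
(5% each by default) so the inclusion rules are exercised. The
transponder log realizes each hen's activity rate as a Poisson stream
over the lighting windows (14/14/14/14/14/13/10 recording days at
10–14 h/d); it is generated on demand (`include_event_log`) since the
large statistical simulations do not need it.

## 6. Verification design and problem sizes

Every stated number in the pipeline is tested against an independent
oracle: hand shoelace values and a subpixel rasterization oracle for
areas; the generator's ground truth for density and POD; a grid-search
maximiser of the Cox partial likelihood on a six-subject untied toy
dataset (coefficient agreement to 1e-3); and closed-form CV values.
The statistical calibration checks run at sizes chosen to keep the
suite fast while leaving the conclusions sharp:

* hazard-ratio recovery: 100 simulated two-arm cohorts of 500 hens per
  arm with a generative HR of 0.20; the fitted HR must land in
  [0.13, 0.30] (about ±2.8 standard errors at this event count) in at
  least 90% of seeds;
* null coverage: 200 two-arm null cohorts (HR = 1, 100 hens/arm); the
  95% CI must cover 1 at its nominal rate;
* type-I error: 1,000 null cohorts (48 hens, 4 periods, no treatment
  effects anywhere); the three-way-interaction F test must reject at
  5% ± 1.5 points;
* truth recovery: 20 randomized noise-free phantoms (density within
  ±0.02 mm Al eq, POD within ±0.5 points) plus five 8-bit phantoms at
  noise sd 2 (density within ±0.1 mm Al eq);
* hazard conservation: 10,000 simulated hens, per-period empirical
  hazards within 3 binomial standard errors of specification.

## 7. Known limitations

* Fracture and deviation *detection* is out of scope by design; the
  package quantifies what a human annotated.
* The cubic calibration is only as good as the wedge's coverage of the
  keel's gray range; out-of-range keels are clamped and flagged, and a
  saturating detector is approximated, not matched.
* The frailty and cluster-robust treatments of the pen effect agree on
  point estimates but not exactly on variances; with only four pens,
  neither estimates the pen variance well — that is a property of the
  design, not of the implementation.
* Containment denominator df are one convention among several; F
  statistics from software using Satterthwaite or Kenward-Roger df
  will differ slightly in small samples.
* The generators define *a* plausible data-generating process with the
  study's structure. Parameter recovery under that process validates
  the estimation code; it cannot validate the biological model.
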