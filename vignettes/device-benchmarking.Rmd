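---
title: "Simulating and benchmarking terrestrial laser scanning for forest inventory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and benchmarking terrestrial laser scanning for forest inventory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlsbench)
```

## What this package models

Ground-based laser scanners — survey-grade tripod instruments, handheld
mobile scanners and smartphone depth sensors — are routinely compared on two
forest-inventory variables: the diameter at breast height (DBH, the stem
diameter 1.3 m above ground) and the tree height (TH). `tlsbench` implements
the full comparison pipeline as tested code: a ray-casting scan simulator
with per-device profiles, the DBH estimator (breast-height slice, circle
fit, outer-perimeter polygon), the TH estimator (DTM/DSM/nDSM rasters), a
cross-section noise statistic, and the error/comparison layer (RMSE, bias,
detection rate, paired t, one-way ANOVA, Tukey HSD).

Because the interesting failure modes of real devices — range noise,
censoring of thin targets, limited range, unregistered scans — are exactly
the quantities the simulator parameterises, the package can reproduce the
*structure* of a device comparison end to end, and its estimators can be
validated against known ground truth rather than against another
implementation.

## The scan simulator

`simulate_scan()` ray-casts a device's direction sequence from a scan pose
against a scene of analytic surfaces: a flat ground plane, upright cylinders
(calibration tubes), and trees modelled as a tapered conical stem plus a
conical crown. For each emitted direction the first surface hit within the
device's maximum range is kept; its range is then perturbed with Gaussian
noise of standard deviation `range_sigma` (the 1-sigma range precision of
the device), Bernoulli dropout is applied, and objects thinner than the
device's `detection_floor_diameter` return no hits at all — the mechanism by
which a smartphone sensor misses a 2.6 cm tube entirely.

Three beam-steering patterns are available:

* **rosette** — a two-frequency non-repetitive pattern: each angular axis is
  a sum of two cosines whose frequency ratio is irrational (sqrt(2)), so the
  pattern never retraces itself and angular coverage keeps growing with
  dwell time. This is a deliberately *qualitative* stand-in for prism-pair
  scanners: the true prism kinematics of such sensors are not public, so the
  model is validated only through the property that matters downstream —
  coverage monotonicity (`coverage_fraction()` grows strictly with dwell
  time) — and through its field-of-view confinement.
* **raster_lines** — a single azimuth sweep with a fast vertical triangle
  wave, the idealised behaviour of a rotating line scanner.
* **uniform** — solid-angle-uniform directions in the angular window, a
  good default for dense well-mixed sampling and for devices without a
  published pattern.

Registration of multi-scan surveys is out of scope by design: scans are
assumed to share the scene frame, and *registration error* is modelled as a
per-scan rigid perturbation (`jitter_t`, `jitter_r` on `scan_pose`). The
smartphone profile is the one device that carries a nonzero default jitter
(3 cm translation, 0.5 degrees rotation) in its survey plan: its scans are
merged without SLAM, so residual alignment error is a property of the
device workflow, not of the pose plan. The tripod and SLAM devices default
to zero jitter.

### Device profiles

`default_profiles()` encodes the four device classes compared throughout:

| profile | points/s | FOV (deg) | sigma (mm) | max range | pattern | floor |
|---|---|---|---|---|---|---|
| riegl   | 122,000 | 360 x 100   | 5  | 1400 m | raster_lines | — |
| stonex  | 976,000 | 360 x 100   | 12 | 120 m  | uniform | — |
| lca_tls | 240,000 | 70.4 x 77.2 | 20 | 190 m  | rosette | — |
| iphone  | 50,000  | 120 x 90    | 8  | 5 m    | uniform | 5 cm |

Point rates and fields of view follow the manufacturers' published figures.
Only the rosette sensor's range precision is published (2 cm, 1 sigma at
20 m — reproduced by the simulator's noise-calibration property); the other
sigma values are calibration defaults chosen once to reflect the accepted
accuracy ranking of the device classes, and are ordinary arguments if you
want to explore alternatives.

## Synthetic scenes

`make_lab_scene()` builds the indoor calibration scene: twelve tubes with
reference diameters from 2.6 to 50.5 cm (mean 17.78 cm, population SD
11.93 cm) and lengths from 100 to 290 cm (mean 156.58 cm, SD 70.13 cm) on a
flat floor. The tube sizes are the packaged reference values; the layout (a
4 x 3 grid inside 7 x 7 m) is the package's own, chosen to keep footprints
well separated.

`make_plantation_scene()` emulates a fast-growing plantation: a rectangular
grid at 4 m spacing, lognormal DBH (default mean 25.6 cm, SD 4 cm — the SD
is not part of the reference conditions and was set once to a plausible
plantation spread) and heights from the standard allometric form
`TH = a + b log(DBH) + noise` with `b = 6` m per log-cm and the intercept
solved so the mean height is 15.7 m. Trees are a tapered conical stem
(base diameter 1.2 x DBH, shrinking linearly so the diameter at 1.3 m is
exactly DBH) plus a conical crown from half the tree height to the apex
(default crown radius 1.5 m at 4 m spacing). With this taper the stem cone
vanishes at 7.8 m regardless of size; the apex that the height pipeline
needs is supplied by the crown cone, which always reaches the tree top.
This is the simplest geometry that exposes both a circular breast-height
cross-section and a well-defined apex.

What the generator does *not* emulate: branches and foliage (crowns are
opaque cones, so occlusion is harsher than in a leaf-off stand), wind
movement, understory, terrain relief, bark texture, and multi-return
physics. Passing tests therefore demonstrate correctness of the estimators
under the stated geometric and noise model, not performance on real forests.

## DBH from a breast-height slice

`extract_dbh_slice()` keeps points whose height above local ground falls in
a half-open band — by default `[1.30, 1.35)` m, a 5 cm slice centred at
1.325 m spanning the two conventional breast-height thresholds; both centre
and thickness are arguments, since reference diameters are sometimes taped
at other heights (the packaged tube diameters were taped at 1 m, and the
worked examples slice there). The slice is partitioned into stems by
connected-component clustering on a 0.3 m planar grid — safe at 4 m
spacing — and each section then flows through:

1. `fit_circle()` — the Taubin algebraic circle fit, a non-iterative
   eigenvalue method that is exact on noiseless circles and has negligible
   bias at the noise levels involved here. Collinear sections are rejected.
2. `perimeter_polygon()` — a deterministic surrogate for manually tracing
   the outer contour: points are grouped into 72 angular bins about the
   circle centre, each bin is represented by the 90th percentile of its
   point radii (the *outer* contour), empty bins are filled by circular
   interpolation, and the bin-radius sequence is low-pass smoothed to its
   first 8 harmonics before the polygon is closed. The smoothing step is
   what makes the surrogate behave like a human tracing: a raw
   quantile-per-bin polygon is jagged under sensor noise and its length
   systematically overstates the perimeter, while a harmonic cutoff at 8
   retains genuine low-order shape (ellipticity, lobes, even a square
   cross-section to within 1%).
3. `dbh_from_perimeter()` — perimeter / pi, in cm. A useful calibration
   fact: tracing a regular hexagon instead of a circle biases the diameter
   by -4.5% (6R/pi vs 2R), which bounds the coarseness error of polygonal
   tracing at low vertex counts.

The pipeline is exact to 0.05% on dense noiseless cylinders and is
translation-equivariant exactly; under rotation the angular binning
re-aligns, which on noisy sections moves the estimate by a small
discretization term (noiseless sections are rotation-exact too).

## The cross-section noise band

The per-device quality statistic works in the unwrapped domain:
`unwrap_to_polar()` expresses a section as azimuth theta (0–360 degrees)
versus radial deviation from the fitted reference circle (mm);
`fit_fourier()` fits a global harmonic contour model (default K = 8,
at least 2K + 1 points required), which is periodic by construction and so
has no boundary discontinuity — the reason a global model is preferred over
local smoothers for closed contours; `residual_band95()` reports the width
of the interval containing 95% of the residuals. Systematic shape (ovality,
lobes) is absorbed by the harmonics, so the band width isolates random
sensor noise: for Gaussian noise it converges to 3.92 sigma, and the
package's calibration properties hold for any K from 4 to 12.

The 95% interval is the *central* (equal-tail 2.5–97.5 percentile)
interval by default; a shortest-interval variant is available via
`method = "shortest"` for heavy-tailed residual sets. Below 40 residuals
the quantiles are unstable and the function warns but still computes.

## Tree height from rasters

`rasterize()` grids a cloud into half-open cells (origin snapped to whole
cells at the floor of the cloud bounds — a reproducible binning convention;
boundary points belong to the higher-index cell) and aggregates per-cell
minimum (DTM) or maximum (DSM) elevation. `ndsm()` subtracts congruent
grids; DTM nodata under dense crowns is filled from the nearest defined
ground cell by default, which is benign on the flat terrain the generator
produces. `sample_height_at()` reads the nDSM cell containing each stem
centroid. The default cell size of 0.5 m is a crown-scale compromise: the
sampling error of reading the apex from the stem cell is bounded by the
crown surface slope times the cell diagonal (about 0.17 m at the default
geometry), and the package's height-recovery property holds across cell
sizes 0.25–1.0 m.

For tube scenes, `tube_length_from_segments()` mirrors the manual
vertical-segment procedure: two diametrically opposed strips on the tube
surface, length = mean of the strips' vertical extents (falling back to one
strip, and flagging estimates below 90% of a supplied prior as probable
range truncation).

`simulate_canopy_survey()` packages the acquisition design used by the
height-recovery checks: perimeter tripod scans (which see the ground under
the opaque crowns) plus a 3 x 3 grid of overhead scans extending beyond the
plot corners (so every apex is seen from opposing azimuths — with opaque
cone crowns, a single-sided view leaves the far half of an apex cell
empty). The merged cloud is clipped to the plot plus margin before
rasterization, as plot-based workflows do.

## The evaluation layer

Errors are signed, `estimate - reference`, so overestimates are positive;
`rmse()` uses the divisor-n root mean square, `bias()` the plain mean.
Undetected objects carry no estimate and are excluded from RMSE and bias
but counted by `detection_rate()` — separating measurement accuracy from
detection capability. `summary_stats()` reports the population (divisor-n)
standard deviation as its "variability", matching the convention of the
packaged reference tables; the sample form is a flag away. Relative forms
(`rrmse()`, `rbias()`) are percentages of the mean reference value.

Device comparison follows standard practice: `paired_t()` per device
against the reference, `anova_tukey()` across devices — one-way ANOVA with
Tukey's HSD run only when the ANOVA is significant at the chosen alpha. The
statistical machinery is delegated to R's `stats` (`t.test`, `aov`,
`TukeyHSD`); the test suite cross-checks all of it against hand-computed
closed forms (explicit sums of squares, studentized-range half-widths, and
the two-group identity F = t^2) at 1e-9.

Display rounding follows the reporting conventions (2 decimals for cm
values, 1 for percentages); all internal computation is at full precision.

## Problem sizes and numerical choices

The simulation-based checks use problem sizes chosen to make their
statistical bounds sharp while staying comfortably interactive: 3-tube
noiseless scenes (2 x 10^5 rays per pose) for exact recovery, 4000-point
sections for the noise band, an 8 x 8 plantation for height recovery, and
twenty 2 x 2 plots for the four-device RMSE ordering, with per-device ray
budgets proportional to realistic per-plot acquisition times (scaled by
`time_scale = 200`). Determinism is strict throughout: a single master seed
is split into per-scan seeds, identical inputs give bit-identical clouds,
and the RNG state of the caller is never disturbed.

Degenerate inputs are contracts, not surprises: zero-duration scans return
empty direction sets (negative durations are errors), empty height bands
return empty slices, collinear sections and single-bin angular coverage are
errors, sections with fewer than three points are flagged undetected, and
zero-variance paired differences refuse to produce a t statistic.

## Known limitations

* The rosette model reproduces coverage behaviour, not true prism
  kinematics; per-second coverage fractions should not be compared against
  real devices quantitatively.
* Opaque cone crowns overstate occlusion; the canopy survey design works
  around this rather than modelling foliage transmission.
* The outer-quantile perimeter inherits a positive bias under noise (an
  upper quantile of noisy radii exceeds the true radius); this is a
  property of outer-contour tracing itself, and it is why simulated
  absolute errors are interpreted via the device *ordering* rather than
  compared numerically to field studies.
* LAS IO covers uncompressed point format 0 at millimetre scale — the
  format the simulator needs — not the full LAS zoo, and no compressed LAZ.
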