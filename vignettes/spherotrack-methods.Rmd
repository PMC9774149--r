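---
title: "spherotrack: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spherotrack: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherotrack)
```

## The problem

A tumor spheroid embedded in a basement-membrane hydrogel grows and — if the
line is invasive — sends cellular protrusions into the matrix. Daily
brightfield images of one spheroid per well, across a drug dose grid and two
oxygen conditions (21% vs 1.5% O2), plus a resazurin (Alamar Blue)
absorbance readout, are the raw data. spherotrack turns them into the
standard endpoints of such a screen: equivalent diameter and spherical
volume, boundary shape descriptors that quantify invasion, relative tumor
volume (RTV), tumor growth inhibition (TGI), control-normalized viability,
an invasiveness classification, and a four-parameter logistic (4PL)
dose-response summary.

## Shape metrics

All shape metrics are computed from a single closed sub-pixel contour per
image.

* Area `S`: shoelace integral of the contour polygon (um^2). A pixel-count
  area is also available from the mask; the contour integral is the default
  because the two agree within 2% on all tested shapes and only the contour
  generalizes to sub-pixel precision.
* Actual perimeter `P_o`: polygon arc length. Perimeter must come from the
  sub-pixel contour, not from counting pixel edges — edge counting
  overestimates a circle's perimeter by up to ~27%, which would corrupt
  every isoperimetric statistic downstream. This is the single most
  consequential numerical decision in the package.
* Equivalent perimeter `P_e = 2*sqrt(pi*S)`: perimeter of the circle with
  the same area.
* Excess perimeter index `EPI = (P_o - P_e)/P_e`: 0 for a circle, >= 0 for
  every simple closed curve (isoperimetric inequality), rising as the
  boundary grows protrusions. The rasterized pipeline carries a small
  positive bias (~0.004 on ideal disks) and a tolerance band of +/- 0.02 on
  circles; both are asserted, not hidden, in the test suite.
* Equivalent diameter `d = 2*sqrt(S/pi)`. The upstream instrument reports a
  "diameter" without defining it; the equal-area circle diameter is chosen
  because it is consistent with `P_e` and well-behaved for non-convex
  invasive outlines.
* Roughness: the coefficient of variation `sd(r)/mean(r)` of
  centroid-to-vertex radii. The instrument's roughness formula is unknown;
  this substitute is scale-invariant, vanishes for circles, and increases
  monotonically with protrusion amplitude, which is all the downstream
  analysis relies on. Whether the original statistic is radial, curvature-
  or fractal-based cannot be determined from its outputs, so no attempt is
  made to mimic it numerically.
* Volume `V = (4/3)*pi*(d/2)^3`: the sphere approximation. No z-information
  is used anywhere.

## Boundary detection

The reference instrument locates boundaries with a proprietary
deep-learning system. spherotrack substitutes a documented classical
pipeline: Gaussian smoothing (sigma 2 um), Otsu's between-class-variance
threshold on the inverted image (the spheroid is dark on a bright field),
morphological closing (disk radius 5 um), hole filling, and retention of
the largest connected component. Rationale: reproducible, dependency-light,
and adequate for high-contrast brightfield spheroids; the module interface
(image in, mask out) permits swapping in a learned segmenter later. The
minimum accepted area is 2000 um^2; all three parameters are configurable.

The contour is the 0.5 iso-level of the mask after a 1-px Gaussian — a
marching-squares trace via `grDevices::contourLines`. The light smoothing
suppresses staircase noise without eroding protrusions wider than ~3 px.
Coordinates are pixel-centered (integers at centers, origin top-left, y
down); the stored orientation is normalized so the shoelace area of the
stored coordinates is positive. Masks touching the frame raise a
boundary-clipped error rather than returning a truncated contour.

## Growth, drug effect and the phantom world

No image data were deposited with the source study, so the package ships a
synthetic phantom generator as a first-class, tested module; every
downstream stage is validated against its analytic ground truth.

The growth law is the minimal model reproducing the qualitative regimes a
G12C-inhibitor screen shows (growth, stasis, shrinkage): discrete-daily
logistic growth of the equivalent radius with multiplicative Hill
inhibition,

    r[t+1] = r[t] + g * r[t] * (1 - r[t]/r_max) * (1 - I),
    I = Emax * C^h / (C^h + EC50^h),

and linear accretion of the protrusion amplitude `a[t+1] = a[t] +
nu*(1 - I)`. Hypoxia multiplies `g`, `nu` and `Emax` by three independent
factors because only the direction of those effects is known, not their
magnitude. The scaled effective `Emax` may exceed 1: inhibition then flips
the growth increment negative, which is the shrinking-spheroid regime seen
at high doses under potentiating hypoxia. Radius and amplitude are floored
at 0.

Default parameters (one choice, stated here, not revisited): starting
radius 150 um (a 4-day-old aggregate), logistic rate 0.3/day, carrying
radius 400 um, invasion rate 0.02/day, 6 boundary lobes, Emax 0.9, EC50
0.02 uM, Hill 1, hypoxia factors 0.6 (growth), 0.6 (invasion), 1.5 (drug),
2.5 um/px on a 480 px field, image noise sd 0.02. The dose design is the
9-level grid 0 (vehicle), 0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1, 5 uM with
at least 6 replicates per group, imaged daily.

The boundary is the polar curve `r(theta) = R * (1 + a *
sum_j cos(k_j theta + phi_j)/m)` with modes `k_j = j + 2` and seeded random
phases, so the maximal radial deviation is bounded by `a` and the
ground-truth polygon is analytic — the oracle for every raster-path test.
Viable volume assumes a 150 um diffusion rim (the oxygen limit commonly
cited for avascular tissue); the necrotic core is also rendered as a darker
central disk, but as an intensity feature only, since all reported metrics
are boundary metrics. The absorbance model is linear:
`A570 - A600 = viability_per_volume * V_viable + noise` on a 0.15 baseline
per channel. Replicate variability is lognormal jitter (sd 3%) on starting
radius and growth rate — a typical seeding CV for centrifuged aggregates;
per-well seeds are an FNV-1a hash of (master seed, well id), so any well
regenerates in isolation.

What the phantom does *not* emulate: detached single cells in the matrix,
optical blur and vignetting, debris, focus drift, multi-spheroid wells, and
any coupling between invasion and viability. A green test therefore
establishes correctness of the measurement and aggregation code on
well-formed single-spheroid images — not robustness to every real-world
artifact.

## Endpoints

* `RTV = V_terminal / V_original` per well; the terminal day defaults to 7
  (a configuration knob — longer courses exist in practice) and the
  baseline to day 1.
* `TGI = (RTV_control - RTV_treatment)/RTV_control * 100`, computed with
  the vehicle group of the *same oxygen condition* as control. Negative TGI
  (treated grew more than control) is legal and preserved. Because RTV is a
  ratio, TGI is invariant to volume units, and TGI from volumes equals
  `100*(1 - mean((d7/d1)^3)_t / mean((d7/d1)^3)_c)` identically — both are
  asserted to machine precision.
* Viability: the reduction signal is background-subtracted `A570 - A600`
  (any linear signal is equivalent once control-normalized, so the
  molar-extinction reduction formula is deliberately not used; the signal
  function is swappable). Normalization is to the mean vehicle signal of
  the same condition and day; replicate SEM is propagated through the
  ratio. Vehicle is treated as a label (dose 0), not a DMSO concentration.
* Invasiveness: `less-invasive` iff terminal EPI < 0.5 (strict inequality;
  0.5 itself classifies as invasive); the threshold is configurable.
* Dose response: 4PL on log dose by least squares (Nelder-Mead on
  `(bottom, top, log10 IC50, log slope)`), vehicle excluded and anchoring
  100% upstream. If neither observations nor fit cross 50%, the status is
  `ic50-not-reached` and no IC50 is invented — the expected outcome for
  weakly responsive lines. A positive dose-viability association is flagged
  as anomalous rather than silently fitted.

## Numerical choices and degenerate inputs

* Otsu's threshold is computed on a 256-bin histogram of the
  min-max-normalized inverted image, making segmentation exactly invariant
  to global intensity shifts.
* Images with < 0.05 intensity range, masks below the minimum area, and
  frame-touching masks raise typed conditions (`no_spheroid_found`,
  `boundary_clipped`) that carry well/day context; the pipeline records
  them per well and continues.
* Degenerate polygons (< 3 vertices, zero area), non-positive areas or
  perimeters, and non-finite inputs raise `invalid_argument`.
* All randomness flows through locally scoped seeds (`with_seed`), so
  identical inputs and configuration reproduce byte-identical images,
  tables and result CSVs; the session RNG state is never clobbered.

## Testing scale-downs

The acceptance suite runs on one CPU; where a criterion allows, simulation
sizes are reduced without touching the stated world: the raster-path
isoperimetric check uses 25 rendered phantoms (the exact-polygon path keeps
all 1000), the TGI plate images only days 1 and 7 (the only days TGI
uses), and the determinism check uses a 2-dose, 2-replicate, 3-day plate.
Generator parameters, thresholds and tolerances are never adjusted to test
outcomes.

## Known limitations

* Volume is always the equal-area-sphere approximation; strongly
  anisotropic spheroids will be biased.
* The classical segmenter assumes one dark spheroid on a bright field;
  dense debris or gel artifacts can capture the largest component.
* Roughness and EPI are resolution-stable only down to protrusions a few
  pixels wide; at 2.5 um/px, sub-5-um filopodia are invisible.
* Hypoxia effect sizes in the phantom are direction-calibrated
  placeholders, not fits to any measured magnitudes.
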