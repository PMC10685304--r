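---
title: "Methods: film-based QA of multi-fraction adaptive treatments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: film-based QA of multi-fraction adaptive treatments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`filmqa` compares a measured film dose distribution (the *reference*)
against a calculated dose distribution (the *evaluated* plane) on a
common 2D grid, for a single fraction or for a five-fraction total in
which one film physically accumulated all fractions. The choice of the
measured film as reference follows the usual QA convention and the
"measurements versus calculations" ordering of the quantities we report;
it matters only for asymmetric metrics (γ, DTA) and is therefore fixed,
not configurable.

The chain is: batch calibration → daily rescale → landmark registration
→ response-to-dose conversion → film-plane extraction of the calculated
grids → fraction summation → edge trimming → relative normalization →
bounded shift correction → γ / dose deviation / DTA / profiles →
summary row.

### Film calibration

Net response $x$ maps to dose through the monotone rational form

$$ D(x) = \frac{a + b\,x}{1 + c\,x}, $$

a standard saturating parametrization for radiochromic film. After
clearing the denominator the fit is linear least squares in $(a, b, c)$;
the fitted curve is then verified to be strictly monotone and pole-free
over the calibrated response range (dense sampling at 512 points), and
non-monotone input point sets are rejected outright. The daily
correction is a single multiplicative *dose-scale* factor $s$ minimizing
$\sum_k (d_k - s\,D(x_k))^2$ over the 3–5 daily films; this closed-form
choice is deliberate — with only three to five points a one-parameter
correction is all the data supports. A response-axis rescaling variant
was considered and rejected: for our curve family the two are locally
equivalent, and the dose-axis scale is directly interpretable as the
day's sensitivity drift. Conversion flags pixels whose response leaves
the calibrated range (±2% of the response span) as invalid and aborts if
more than 5% of pixels do, which in practice signals film saturation or
a wrong daily set.

### Registration and geometry

The three cassette-pin landmarks give a rigid (rotation + translation,
no scaling) transform by orthogonal Procrustes/SVD, which is exact,
label-invariant, and degenerate only for collinear pins (rejected). The
scan is resampled bilinearly onto the film-frame grid; landmark
*detection* is out of scope — landmarks enter as coordinates, and the
simulator mimics manual selection with 0.3 mm Gaussian jitter.

All planes live on a voxel-centre 1×1 mm grid of 61×166 voxels covering
the 60×165 mm film; one voxel is trimmed from every border (edge
effects of film cutting and interpolation roll-off), leaving the 59×164
analysis grid. Film-plane extraction from the 3D calculated grid is
trilinear; all resampling is bilinear; out-of-support samples are marked
invalid and excluded from every downstream statistic (never
extrapolated), with excluded-voxel counts carried into the report.

### Normalization, shift correction and metrics

Relative dose is obtained by dividing each plane by the **median** dose
within a 10 mm-radius disk centred on the high-dose centre. The centre
is the centroid of the largest 8-connected component of voxels ≥ 90% of
the plane maximum — a centroid rule chosen because it is stable under
noise and plateau ties; the centre is located on the calculated plane
and reused for the measured plane so both normalizations sample the same
anatomy. The median (not the mean) makes the normalization robust to
single-pixel film artefacts.

Residual setup/post-processing displacements are removed by a grid
search over ±1.5 mm per axis in 0.1 mm steps, minimizing the mean
squared relative dose difference over voxels ≥ 10% of $D_{max}$;
candidates are visited in order of increasing $|s|$ and only strict
improvements are accepted, so ties break toward the smaller shift. No
sub-step refinement is attempted — the 0.1 mm step is already far below
the 1 mm grid and the film positioning accuracy.

The global γ at 2%/2 mm uses the normalization dose (relative value 1)
for the dose tolerance. The evaluated plane is interpolated bilinearly
on a fine lattice (0.2 mm by default; any divisor of the grid pitch),
and the search walks displacement offsets sorted by radius with exact
early termination once the distance term alone exceeds the current
best; the search radius caps at 3× the distance tolerance (6 mm), which
bounds reported γ values at 3 — above any pass/fail decision point.
Pass rates are reported over voxels at or above 10% and 90% of
$D_{max}$, where $D_{max}$ is taken from the **calculated** relative
plane by default (configurable to the measured plane): the calculated
plane is noise-free, so thresholds do not jitter with film noise. The
90%-threshold voxel set is by construction a subset of the
10%-threshold set.

DTA is the smallest displacement at which the evaluated dose matches
the reference voxel's dose within 0.5% of that voxel's *own* dose (the
one deliberately local tolerance in the chain), searched on the same
fine lattice with a 10 mm cap; voxels with no match inside the cap
carry the cap value with a saturation flag and are *included* in the
band statistics — silently dropping them would bias the DTA mean low
exactly where agreement is worst. Summary statistics are taken over the
10–90% of $D_{max}$ band. Dose deviations and profile differences are
global (percent / percentage points of the normalization dose), which
avoids inflating relative errors in the low-dose tail.

Chamber comparisons average the calculated dose over a 3 mm-radius
sphere (the chamber's active volume) using trilinear samples on a
0.5 mm sub-lattice, and report the measured-minus-calculated difference
in percent of the calculated value.

## The synthetic experiment

The simulator replaces the physical phantom measurement with a
parametric stand-in so the full chain runs at desk scale with known
ground truth. It emulates:

* a water-equivalent elliptical-cylinder body (semi-axes 100×75 mm)
  with an air-filled lung cylinder and a coronal film cassette with
  three pins;
* a 13-beam plan delivering five fractions of 1.2 Gy (6.0 Gy total).
  Each beam contributes a flat-top field with error-function penumbra
  (σ = 3 mm) in both lateral directions and exponential attenuation
  (μ = 0.005 /mm, ×0.25 through lung) along its axis; beams are summed
  and the grid is scaled so the prescription point receives 1.2 Gy
  exactly. The prescription point sits on the inline field edge where
  the dose falls to 70% of the target-centre value, mirroring
  stereotactic prescriptions to a covering isodose line — this
  reproduces the ~1.7 Gy per-fraction and ~8.6 Gy total maximum dose of
  a plan of this class without modelling an optimizer;
* online re-planning (adapt-to-shape), modelled as the dose
  distribution rigidly following the varied target for translations and
  rotations, and as recomputed attenuation paths for body
  modifications. The optimizer itself is out of scope: QA compares
  delivered against calculated dose, both of which exist *after*
  adaptation;
* the three inter-fraction variation families, five fractions each.
  The exact experimental magnitudes are not published, so defaults were
  chosen once as what a physicist would call realistic for this
  phantom: in-plane translations up to 6 mm, rotations up to 4° about
  the anterior–posterior axis, body contour rescaling ±5%;
* the measurement chain: film response through the inverse of a "true"
  physical curve (a = 10, b = −0.25, c = 0.25 — steepest response at
  low dose, saturating toward 10 Gy, as for real radiochromic film),
  0.3% multiplicative per-pixel response noise, a uniform 0.96–1.04
  daily dose-scale drift recovered by the daily films (totals: five
  films 0–10 Gy; singles: three films up to 2/2.2/2.5 Gy), scanner
  placement (±3°, ±2 mm) and 0.3 mm landmark jitter, and optional
  per-fraction delivery errors (dose scale, residual shift), all drawn
  from one seeded generator and recorded in the ground-truth ledger;
* the fourteen-dataset layout: three accumulated totals plus eleven
  singles (the unvaried plan, all five translations, rotations 1/3/5,
  body modifications 1/5), with chamber readings for the unvaried plan
  and the translation singles.

What the simulator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: Monte-Carlo dose
calculation and its statistical noise, magnetic-field effects on film
response, scanner lateral-response nonuniformity, film artefacts and
spatially correlated noise, irradiation-to-scan-time kinetics, MRI
acquisition and contouring. The null experiment shows that the
*analysis chain* is unbiased under a well-controlled measurement model;
it cannot certify a clinical workflow.

## Numerical choices and problem sizes

Interpolation is bilinear/trilinear throughout; interpolating the
*response* image before dose conversion (rather than converting first)
matches the physical order of the scanner chain, and the difference is
far below film noise for smooth fields. Degenerate inputs fail loudly:
all-zero planes have no high-dose centre, empty shift overlaps, ramp
poles and rank-deficient calibration designs all raise typed errors
rather than returning numbers.

The validation suite runs the γ/DTA kernels against independent
brute-force oracles on 50 random smooth 15×15 planes at a shared
0.05 mm evaluation lattice (agreement to 10⁻¹⁴ observed; 10⁻⁶
asserted), recovers injected shifts (100 seeds, ≤ one 0.1 mm step),
scanner rotations (2° ± 0.2° under jitter, 100 seeds), daily scale
(1.05 within 0.5%, 100 seeds) and calibration round trips (bias < 0.5%
over 0.3–8.6 Gy, 50 seeds), and runs the full fourteen-dataset null
experiment (zero delivery error, default measurement noise), requiring
γ pass ≥ 99% at the 10% threshold everywhere and total-dose rows within
0.5 percentage points of the single-fraction mean — the package's
concrete reading of "totals match singles". These sizes keep the whole
suite within a few minutes on one core while leaving each property
well over-determined.

## Known limitations

* The beam model is parametric: no scatter, no buildup, no MLC
  structure. It produces realistic gradients and penumbra, which is
  what the 2D metrics exercise, but its absolute depth-dose shape is
  schematic.
* Daily rescaling assumes a pure dose-scale drift; a drift that bends
  the curve (e.g. temperature-dependent saturation) would leave a
  residual the single factor cannot absorb.
* DICOM RT-Dose I/O is not provided; grids exchange through the
  portable float64+JSON container and film scans through 16-bit TIFF
  with a JSON sidecar (16-bit quantization ≈ 1.5·10⁻⁵ of the response
  range).
* DTA saturation (cap 10 mm) is reported, not resolved; in very flat
  low-dose regions the 0.5% local tolerance can be unmatchable within
  the cap and the statistics inherit the cap value by design.
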