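---
title: "Measuring cardiac-pulsatility-induced vessel dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cardiac-pulsatility-induced vessel dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archpulse)
```

## The measurement problem

Retrospectively ECG-gated CT resolves the cardiac cycle into 10 volumes at
0–90% of the R–R interval. Deformable registration of those volumes against
a phase-averaged volume produces 10 displacement vector fields ("deformation
fields"), each mapping a phase-averaged position to its position in one
cardiac phase. The attraction of this representation is that *one* manual
measurement — a labeled point, a centerline, a segmented lumen surface — made
once in the phase-averaged volume can be carried into every phase
automatically, removing most of the observer dependence of per-phase
measurement.

`archpulse` implements the measurement side of this workflow. Image
registration itself is out of scope: the fields are inputs (MetaImage or
NIfTI volumes, 3 components, mm), or are generated analytically by the
phantom module.

## Data model and conventions

* Grids are axis-aligned: voxel index `(i,j,k)` (zero-based) maps to world
  mm as `origin + (i,j,k) * spacing`. Non-identity direction matrices are
  rejected rather than silently mishandled — scanner-axis data is the
  intended regime, and a wrong-handed measurement is worse than an error.
* All coordinates and displacements are mm; curvature is reported in m⁻¹
  (×1000 from mm⁻¹), the customary unit for vascular curvature.
* Axis semantics (x lateral, y ventral–dorsal, z caudal–cranial) are those
  of the volume grid; the supine, feet-first orientation is the caller's
  responsibility.
* Interpolation of displacement fields is component-wise trilinear.
  Queries outside the voxel-center bounding box are errors, never
  extrapolations — an extrapolated displacement is clinically meaningless.
  Trilinear interpolation is exact for fields affine in position, and its
  error on smooth fields is second order in the grid spacing; on a 1.5 mm
  grid with 60 mm-wavelength sinusoidal motion the tracking error is
  ~0.01 mm, far inside the ≤0.3 mm accuracy with which this class of
  field-based tracking has been validated.

## Motion

A tracked point's 10 positions are `p_k = p + u_k(p)`. Per-axis amplitude
(pulsatility) is the max−min range over phases; pathlength is the summed
distance between subsequent phase positions. Two pathlength closures are
offered because the literal reading ("subsequent phases", 9 steps) differs
from the physical one (the cycle is periodic, 10 steps): `"open"` is the
default, `"cyclic"` adds the wrap step. With the phantom's sinusoidal phase
weights `w_k = sin(2πk/10)` and unit amplitude these have the exact
enumerable values 1.9021 (amplitude), 3.2166 (open) and 3.8044 (cyclic) mm,
which the test suite pins.

## Centerline geometry

Centerlines are piecewise-linearly resampled at exactly 1 mm arc steps
(the final sub-millimeter gap keeps the endpoint; marks snap to the nearest
resampled index). A Savitzky–Golay filter of polynomial order 4 and window
33 then fits each coordinate locally by least squares; the fitted
polynomial supplies the smoothed value and its first two derivatives at
every sample. Key numerical choices:

* **Derivatives come from the local fit**, not from finite differences of
  the smoothed curve: the curvature formula needs a *consistent* pair of
  first and second derivatives, and the fit provides both under a single
  smoothing choice.
* **Boundary handling.** Within the first/last half-window the polynomial
  fitted to the first/last *full* window is evaluated at off-center
  offsets. No mirroring or zero padding: padding fabricates geometry
  exactly where stent ends are read off. The projection matrices
  (including the off-center rows) come from `signal::sgolay`; the suite
  verifies they reproduce degree-≤4 polynomial centerlines, boundaries
  included, to 1e-9.
* **Units.** Derivatives are with respect to the sample index; at 1 mm
  resampling this *is* arc length, so the general non-unit-speed curvature
  formula is evaluated in mm⁻¹ directly.
* **Short segments.** Centerlines shorter than 33 samples get the largest
  odd window that fits (minimum 5) with a logged warning — a 33 mm support
  cannot be honored on a 25 mm branch stent, and silently refusing to
  measure would be worse. The warning makes the changed smoothness
  auditable.
* **Degenerate tangents** (speed³ below 1e-9, e.g. at a cusp of a corrupt
  centerline) flag the point: κ is set to `NA`, excluded from summaries,
  and counted in the output rather than dropped silently.

Length is the sum of consecutive distances; TI = length / chord (an error
if the endpoints coincide); both accept mark names so the stented segment
of a longer centerline can be summarized. The full centerline is smoothed
*first* and cut at marks afterwards, keeping filter boundaries away from
the region of interest.

### Per-phase geometry

The phase-averaged centerline is translated into each phase by adding the
interpolated displacements to its points. The translated polylines are
**not** re-resampled or re-smoothed before derivative computation — the
Savitzky–Golay fit is recomputed on the translated points. This preserves
exact per-point correspondence across phases, which the per-point curvature
range (max−min over the cycle) depends on; re-resampling would decorrelate
point identities between phases. The per-point ranges are then averaged
(mean curvature change) and maximized (maximal curvature change) over the
segment; length and TI are evaluated per phase and their max−min over the
cycle reported. "Mid cardiac cycle" summaries are the phase-averaged
centerline's values.

Under a pure rigid translation per phase, every one of these dynamic
changes is exactly zero (curvature, length and TI are rigid-motion
invariants, and constant fields interpolate exactly); the suite asserts
this null to 1e-6.

### Known accuracy limit of the smoothing filter

An order-4/window-33 local fit at 1 mm sampling attenuates curvature
according to its frequency response; the relative bias grows as `(1/R)⁴`.
It is below 0.13% for radii ≥ 20 mm but reaches ≈1.85% at R = 10 mm
(κ = 100 m⁻¹) — confirmed both by the pipeline and by an independent
direct least-squares fit. Aortic-arch and supra-aortic curvatures of
interest are well below 80 m⁻¹, where the filter is accurate to <1%; but
users measuring sub-centimeter radii of curvature should know the fixed
33 mm support is the limiting factor there.

## Diameters

Cross-section frames `{tangent, e1, e2}` are placed at 1 cm arc-length
levels (indexed from the proximal stent mark when marks are given, with
flagged native-vessel levels upstream/downstream). The tangent comes from
the Savitzky–Golay first derivative; the in-plane pair is propagated by
rotation-minimizing transport, seeded with the in-plane projection of
global +x (falling back to +y when the tangent is near +x). The
workstation convention this emulates does not document its in-plane
directions, so continuity along the arch was chosen as the design
criterion — transported frames never flip sign between adjacent levels,
keeping the two-diameter "spread" band smooth; the seed is configurable.

From each frame origin, rays are cast in ±e1 and ±e2 against the lumen
surface; the *nearest* hit in each direction is used, so an adjacent
vessel's lumen can never contaminate a diameter. Mesh input uses exact
ray–triangle intersection; mask input marches at 0.2 mm steps along the
ray through trilinearly sampled occupancy and interpolates the 0.5
crossing. A ray without a hit flags the level "open surface" and excludes
it, with a warning count. The two diameters per level are averaged into
the level's mean; their min/max forms the spread band (with only two
values per level, the band edges *are* the pair).

Pulsatile diameter change translates the four marked boundary points —
not the surface — through each phase field and recomputes the two
diameters as distances between translated point pairs, per the marked-point
workflow it reproduces; the change is the max−min of the per-phase mean.
This choice means wall points are followed materially, and a rigid
translation gives exactly zero change.

## The phantom generator

The phantom module is the package's ground truth: arc, helix and straight
tubes (optionally elliptical cross-section) whose centerline, curvature,
tortuosity, diameters and per-phase trajectories all have closed forms.
The motion model is a sum of modes scaled by the phase weights
`w_k = sin(2πk/10)` — periodic, zero-sum, and chosen so amplitude and
pathlength oracles are simple enumerations:

* rigid translation `(Ax, Ay, Az)·w_k`;
* radial pulsation: the cross-sectional offset from the centerline is
  scaled linearly so the surface radius becomes `r + Δr·w_k` while the
  field stays smooth (zero) on the centerline itself;
* bending (arc only): the arc radius oscillates such that per-phase
  curvature is `κ₀ + Δκ·w_k` with arc length preserved, implemented as a
  closed-form polar remapping (the polar branch cut is placed opposite the
  arc midpoint so the displacement field is continuous over the whole
  tube);
* spatially sinusoidal displacement of configurable wavelength — the
  regime for tracking-accuracy experiments; a warning fires if the field
  grid is coarser than a quarter wavelength.

Default grid spacing is 1.5 mm (fields) and 0.75 mm (masks, between
typical ECG-gated CT in-plane pixel sizes). Gaussian centerline jitter
(`add_noise`, seeded) emulates centerline-extraction inaccuracy — the
thing the Savitzky–Golay filter exists to suppress; the suite shows
smoothing recovers κ of a noisy 40 mm arc within 5% while naive finite
differences are off by far more.

What the phantoms deliberately do **not** emulate: CT intensities and
noise texture, registration error in the fields (phantom fields are the
analytic motion sampled on a grid), branch ostia or non-tubular anatomy,
and direction-cosine-rotated grids. Passing tests therefore demonstrate
the *measurement* chain is correct given faithful fields, not that
registration of any particular scanner's data is accurate.

## Problem sizes and determinism

The test suite and the acceptance script run phantoms with tube radii
6–15 mm, arc radii 10–80 mm and field grids of 1.5–3 mm — sizes chosen so
every oracle comparison is well-resolved while a full run stays
interactive on a laptop. All randomness (interior-point sampling, noise)
is routed through explicit seeds; `run_all()` writes byte-identical CSVs
for identical config and inputs, and records the full configuration JSON
next to its outputs.

## Limitations

* Axis-aligned grids only; no direction-cosine resampling.
* Curvature bias at radii ≲ 12 mm (above), inherent to the fixed filter.
* Torsion and inner/outer-wall curvature are not computed; curvature is a
  centerline property here.
* Diameters are ray-pair diameters, not maximal-inscribed-sphere or
  area-equivalent diameters; for strongly non-convex sections the pair
  understates asymmetry.
* The pathlength of a cycle that does not return to its start (open
  closure) depends on which phase is labeled 0; the cyclic closure is
  provided for rotation-invariant comparisons.
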