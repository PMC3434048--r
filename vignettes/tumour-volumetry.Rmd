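---
title: "Tumour volumetry from small-animal MR images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumour volumetry from small-animal MR images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumourvol)
```

## The measurement problem

Subcutaneous xenograft tumours in mice are routinely followed by their
size. External caliper ("gauge block") measurement of three perpendicular
diameters gives a mass via the ellipsoid model,
$m_{GB} = \rho\,\frac{\pi}{6}\,l\,w\,h$, but is blind to irregular shape
and inaccessible for orthotopic tumours. T2-weighted MRI shows these
tumours as hyperintense regions and supports volumetry down to about
$10^{-2}$ g — at which point single voxels matter: a 3 mm tumour imaged
with 250 µm voxels is only 12 voxels across, and the shell of voxels
straddling its rim holds a volume comparable to a third of the tumour
itself. Every design choice in this package traces back to that fact.

Units are fixed internally throughout: spacing in µm, volumes in mm³,
masses in g, densities in g/cm³, with all conversions centralised in the
core module. Arrays are ordered `(slice, row, column)` with the spacing
stored in the same order; file readers perform the reordering. Thick-slice
multi-slice ("2D", e.g. 700 µm slices over ~150 × 200 µm pixels) and
isotropic 3D acquisitions (160–240 µm voxels) share one representation and
differ only in their spacing vector.

## The segmentation pipeline

`segment_tumour()` composes five stages, each available separately:

1. **Threshold estimation** (`estimate_threshold`): the mean intensity over
   a polygonal ROI outlined to contain approximately equal amounts of
   tumour and background. For a balanced two-class region the mean is
   exactly the class midpoint, which is the optimal threshold for a
   bimodal, noise-symmetric image.
2. **Thresholding** (`apply_threshold`): voxel → tumour iff intensity ≥
   the effective threshold of its slice. The comparison direction follows
   from T2 hyperintensity; ties go to tumour. Per-slice *absolute*
   replacement thresholds support adjustment where the global value fails
   (a replacement, rather than a multiplicative factor, is the simplest
   semantics consistent with per-image adjustment, and is what the
   `threshold_plan` records).
3. **Polygon exclusion** (`exclude_polygons`): failed regions (bright
   structures outside the tumour) are removed by polygons drawn on single
   slices. Membership is by voxel-centre test; a voxel whose centre falls
   exactly on the polygon line follows an explicit `boundary_policy`
   (default: background). The policy is a parameter precisely because
   rim-voxel assignment is where the asymmetric over/under volume errors
   live.
4. **Interior conversion** (`fill_interior`): necrotic tumour interior is
   dark on T2 and falls below threshold; a growing-seed pass relabels it.
   Automatic mode fills every background component not connected to the
   image border; seeded mode converts only enclosed components containing
   a seed (a seed in tumour, or in border-connected background, warns and
   does nothing — flooding the exterior from a misplaced seed would be
   silently catastrophic). Connectivity is face-connectivity: 6-neighbour
   in 3D, or 4-neighbour independently per slice for thick-slice stacks,
   where 700 µm slices are thick relative to in-plane resolution and
   through-slice continuity of thin structures is not trustworthy. Face
   connectivity is the conservative choice (no diagonal bridges); it is
   configurable.
5. **Mass conversion** (`mask_to_mass`): voxel count × voxel volume ×
   density, default 1.0 g/cm³. The density is an assumption, not a
   measurement; it scales all masses linearly and is recorded in every
   `mass_estimate`.

The original workflow behind this design is interactive; this package is
deliberately batch-oriented. ROIs, exclusion polygons and seeds arrive as
JSON (0-based voxel coordinates, voxel centre = integer coordinate), so
every run is scriptable and replayable, and each stage appends to the
mask's provenance record.

## The partial-volume error bound simulation

`simulate_pve()` superimposes a sphere of diameter $d$ on an isotropic
grid of edge $s$ with coinciding origins and classifies every element
exactly: *inside* iff the farthest corner of the element lies within the
radius, *outside* iff the nearest point of the element to the centre lies
beyond it, *intersected* (a PVE element) otherwise. The nearest-point /
farthest-corner test is exact for axis-aligned boxes; corner-counting is
not (a rim can graze a face without enclosing a corner), which is why the
classifier is implemented this way and cross-checked in the tests against
a dense supersampling oracle.

The two extreme segmentations bracket every real segmentation: counting
all PVE elements as tumour overestimates, discarding them all
underestimates, and the signed relative errors
$100\,(\tilde V - V)/V$ with $V = \frac{\pi}{6}d^3$ depend only on the
voxels-per-diameter ratio $d/s$. The defaults sweep 3–9 mm tumours against
100–250 µm voxels (ratios 12–90); at ratio 12 the bounds are
+42 % / −32 %, at ratio 70 they shrink to ±6–7 %, with the overestimate
always at least as large in magnitude as the underestimate (convexity of
the sphere). Within a fixed voxel size the bounds shrink strictly with the
ratio; across interleaved voxel sizes, commensurability of the sphere with
the lattice adds fluctuations of a couple of points between near-equal
ratios, so trend statements across the whole sweep are rank statements.

Two numerical choices deserve a note:

* **Origin convention.** "Coinciding origins" can place the sphere centre
  at a grid vertex or at an element centre. Both are implemented
  (`origin_mode`); the default is `element_center`, fixed by calibrating
  both modes against reference tabulations of this simulation — the two
  conventions differ by 1–2 points at small ratios (e.g. +44/−31 vertex
  vs +42/−32 centre at ratio 12) and converge as the ratio grows.
* **Exactness vs approximation.** Approximate rim tests (corner counting,
  sampled occupancy, per-slice circle tests) systematically *thin* the rim
  shell and can understate the overestimate bound at small ratios by
  several points; published tabulations of this kind of simulation
  commonly reflect an effective rim shell of roughly ±0.7 voxel. The
  package keeps the exact test — the quantity of interest is the *maximum
  possible* error, and an exact rim is the only defensible definition —
  and reports full-precision errors, rounding to integer percent only in
  report tables.

Enumeration is whole-volume rather than slice-by-slice; since
classification is per-element the two are mathematically identical. A
sphere whose diameter does not exceed one element edge can contain no
element (under-error −100 %); ratios below 1 compute with a degeneracy
warning.

## The phantom generator

No deposited image data accompanies the class of study this package
serves, so the generator is first-class, tested code, not a fixture. It
emulates what matters for volumetry on T2-weighted images of subcutaneous
tumours and nothing more: a hyperintense ellipsoid (default intensities
100 over a background of 20, chosen for clear bimodality at the default
noise level) with partial-volume intensities at the rim, optional enclosed
low-signal cores, optional Gaussian PSF blur, and additive noise
(Gaussian by default; Rician available, since magnitude-MR noise is Rician
— at the default SNR of 16 the distinction is immaterial for thresholds).
It does *not* emulate anatomy, coil-sensitivity inhomogeneity, sequence
point-spread detail, or real tumour texture; a passing phantom test
therefore validates the geometry and arithmetic of the pipeline, not its
robustness to anatomical confounders — that is exactly the scope
of an exclusively in-silico verification.

Occupancy fractions are computed by conservative banding (exact interior /
exterior classification via the 1-Lipschitz normalised radius, then
supersampling only in the rim band, default 4³ sub-voxels, raised to 8³
for tumours under 6 voxels across). Rendered volume agrees with the
analytic $V = \frac{4\pi}{3}abc$ to well under 1 % at ratio 12. The
ground-truth mask binarises occupancy at 0.5 (unbiased for symmetric
bodies); the analytic volume is the primary truth, the mask secondary.
Necrotic cores change intensities only — the tumour includes its necrotic
interior, so neither analytic volume nor ground truth moves.

By default the field of view is sized to odd dimensions with ≥ 2-voxel
margins, placing the tumour centre on a voxel centre — the same
convention as the PVE simulator's default origin, so segmented sphere
phantoms are bound by `pve_bounds()` *exactly*, not statistically: the
threshold mask always contains every fully-inside voxel and never an
outside one.

The cohort emulated by `phantom_suite()` spans 0.01–2.28 g (17 log-spaced
masses, the size range and count of the small-animal study design it
mirrors) across four acquisition geometries: isotropic 160, 200 and
240 µm, and the 700 × 150 × 200 µm thick-slice protocol. All randomness
derives from a recorded per-case seed.

## Agreement statistics

The coefficient of variation uses the sample (n−1) standard deviation —
the convention matters at n = 10 (≈ 5 % relative) and is therefore fixed
and documented rather than left to chance. Interobserver deviations are
signed percentages against the reference observer's mean. Regression is
ordinary least squares of estimate on reference with Pearson $R^2$;
when the predictor is the analytic phantom truth there is no
regression-attenuation toward zero, so the fitted slope on a noise-free
suite must itself sit within the PVE bounds of the worst-case ratio — a
cross-module consistency check the acceptance tests exercise.

`simulate_observer_study()` emulates observer subjectivity as Gaussian
perturbations of the midpoint threshold (default SD: 10 % of the
tumour–background contrast), the mechanism through which manual ROI and
threshold choices actually move volumes. Because a thick-slice geometry
concentrates ~5× more volume in each rim voxel than a 160 µm isotropic
one, the same threshold jitter moves more volume in 2D: on small (< 0.2 g)
phantoms the emulation shows larger interobserver deviations and larger
intraobserver CV for the 2D geometry than for 3D — a directional
statement, which is all an in-silico emulation can honestly support.

## Problem sizes and degenerate inputs

The test and acceptance workloads use the full 17-mass cohort at the three
isotropic geometries (ratios ≈ 11–102, largest volume ≈ 109³ voxels) —
sizes chosen as representative of real acquisitions of this tumour range.
Degenerate inputs are rejected early with specific errors: non-positive
spacing or density, empty ROIs, self-intersecting polygons, out-of-range
slices or seeds, geometry exceeding the field of view, constant-x
regression. Threshold ties, polygon boundary centres, and the
sub-element-sphere case are all governed by the explicit rules above
rather than floating-point accident.

## Known limitations

* The PVE simulator treats spheres only; elongated tumours have thinner
  worst-case bounds per unit volume than the sphere of equal volume in
  some orientations and thicker in others.
* No DICOM input, no bias-field correction, no registration, no
  multi-tumour instance labelling, no automatic (ROI-free) threshold
  selection.
* Phantom realism is limited to geometry, contrast, blur and noise; claims
  about observer behaviour on real anatomy cannot be settled here.
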