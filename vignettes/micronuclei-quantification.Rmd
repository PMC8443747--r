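---
title: "Quantifying micronuclei in 3D: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying micronuclei in 3D: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mn3d)
```

## The measurement problem

A micronucleus is a small chromatin-containing body outside the main
nucleus, operationally defined here as a segmented object with equivalent
radius of at most 2.0 µm; regular nuclei of neurons and astrocytes have
major axes of roughly 12–15 µm (equivalent radius 6–7.5 µm). In a single
confocal section the two are not distinguishable: an optical slice through
the cap of a large nucleus presents a small, round, brightly stained
cross-section with exactly the geometry of a micronucleus. The package's
central commitment is therefore to measure in 3D: connected-component
labelling links the sections of one nucleus across slices, so its volume —
not any single section's area — determines its size class.

`edge_slice_scenario()` constructs this confound exactly: a 6 µm-radius
nucleus whose top slice cuts ~5.75 µm above centre, a cross-section of
radius √(36 − 33.06) ≈ 1.71 µm, inside the micronucleus band. Slice-wise 2D
analysis reports it as a micronucleus; 3D analysis reports one nucleus and
zero micronuclei. This property is asserted in the test suite.

## Size model

For a 3D component with volume $V$ (voxel count × dx·dy·dz), the
equivalent radius is that of the sphere of equal volume,

$$R_{cal} = \left(\frac{3V}{4\pi}\right)^{1/3},$$

and in area mode that of the circle matching the maximum per-slice
cross-sectional area, $R_{cal} = \sqrt{A_{max}/\pi}$. Both modes are exposed
(`dim_cell_radius` 3 or 2) because dense-tissue counting is usually run with
3D components but area-based radii; the combination `dim_cell_analyze = 3`,
`dim_cell_radius = 2` is fully supported. Anisotropic voxels are handled
exactly: volumes use dx·dy·dz, slice areas dx·dy.

Size bands are inclusive at both ends: micronucleus 0.2–2.0 µm, nucleus
4.0–10.0 µm. The 2.0 µm ceiling is the field's operational micronucleus
cutoff; the 0.2 µm floor excludes single-voxel noise at typical spacings;
the nucleus band brackets the 6–7.5 µm equivalent radius of 12–15 µm nuclei.
The bands are deliberately disjoint (validated) so classification is
unambiguous; objects in the gap are reported as `unclassified` rather than
silently absorbed. Inclusive bounds make the 2.0 µm boundary exact: a
digitized 2.0 µm sphere at 0.1 µm spacing measures $R_{cal} = 1.997$ µm and
is classified micronucleus; a 2.1 µm sphere measures 2.100 µm and is not.

## Binarization

Each channel is smoothed with a slice-wise bilateral filter (spatial
Gaussian of sigma `spatial_sigma` voxels × intensity Gaussian of variance
`degree_of_smoothing`; either 0 disables). Smoothing and morphology run in
2D within slices even for 3D stacks: at a 1 µm z-interval the axial sampling
is several times coarser than the lateral one, and isotropic 3D kernels
would smear across sections. Whether the original workflow filtered in 2D or
3D is not documented; slice-wise is our choice and is flagged here.

Thresholding is discriminant analysis (Otsu): the cut maximizing the
between-class intensity variance, computed per local window rather than
globally. Windows are overlapping squares (default 65 px, 50 % overlap)
whose thresholds are bilinearly interpolated to every voxel — tiles with
interpolation avoid visible seams; the window size is an exposed parameter
because the original local-area geometry is unknown. The `sensitivity`
parameter multiplies each local threshold (effective = sensitivity ×
t_local, default 1.0), the simplest monotone contract; foreground is
intensity ≥ threshold, inclusive so boundary tests are exact.

Otsu returns a cut even for unimodal input (it will happily split pure
noise down the middle). A window's threshold is therefore only trusted when
its two classes separate by at least 4 within-class standard deviations;
for one Gaussian the two "classes" sit ~2.7 within-class SDs apart, while
genuine stain/background mixtures separate far more widely, so 4 cleanly
rejects unimodal windows without discarding sparse signal (a window with
1–2 % foreground at 10 SD contrast still passes). Rejected windows fall
back to the slice-global threshold, then the stack-global one; if no level
of the image shows two-class structure the channel is all background. This
is what makes constant and pure-noise inputs produce empty masks instead of
half-foreground garbage.

Two morphology passes follow on the binary mask: closing with a disk of
radius w₁ reconnects fragments of one object separated by gaps < 2·w₁;
opening with radius w₂ deletes specks of radius < w₂. Both default to 0
(off). The structuring element is a disk because each "scaling size" is a
single number, implying an isotropic in-plane element.

## Components, borders, edits

3D labelling uses 26-connectivity, 2D (per-slice) labelling 8-connectivity:
maximal connectivity is deliberate, since merging z-adjacent sections of one
nucleus is the point of 3D analysis. In 2D mode slices are labelled
independently, so one physical nucleus yields one label per slice — the
behaviour that produces the grazing-section confound on purpose.

Border clearing removes components with any voxel on the lateral x/y faces
(their extent is unknowable) but keeps components touching only the top or
bottom z face (a stack rarely spans whole nuclei, and discarding every
z-clipped nucleus would empty most images). It runs after labelling and
before measurement.

Interactive correction of the binarized result is replaced by a replayable
edit script (CSV: channel, op, label, merge partner, split seeds): delete,
merge, and split by geodesic nearest-seed assignment *within* the label —
splitting operates on binary data, so seeded geodesic partition is used
rather than intensity watershed. Edits are applied to label maps (the
delete/merge/split operations are defined on labels, not raw masks), in
script order, then labels are renumbered consecutively.

## Overlap classification

The overlap rate of a region with another channel's mask is the covered
voxel fraction |region ∩ mask| / |region|, computed volumetrically in the
analysis dimensionality (per-slice overlap would reintroduce exactly the
section-sampling artifact the 3D analysis removes). Cell-marker (red)
regions are *objective* when their overlap with the green∪blue union
reaches `rate_cover_r_min` (default 0.5); the union is used — not the
maximum of the per-channel rates — though both per-channel rates are
reported in the table. The comparison is inclusive (≥): the default is
glossed as "50 % of the area overlapped", which reads as attainment, and
inclusivity makes the 0.5 boundary exactly testable. `non_overlapped` mode
is the strict complement, so the two modes partition regions exactly.

Envelope status of a micronucleus (e.g. Lamin B1 ±) is its overlap with the
green mask against the same threshold. An envelope stain marks a shell, so
the pipeline fills ring holes slice-wise before computing envelope and
objective overlaps — "inside the envelope" is the biologically meaningful
condition, and without filling, a perfectly enveloped micronucleus would
score an overlap near zero.

## Ellipse-fitting separation

In dense tissue adjacent nuclei fuse into one binarized component. Only two
knobs of the separation procedure are documented anywhere: the maximum
major/minor axis ratio (0 = off, 1 = circles, > 1 = ellipses) and the
discrete rotation grid of N orientations with step 180/N degrees (default
N = 30, i.e. 6°). The covering algorithm is this package's own
interpretation, chosen to be deterministic and parameter-light while
honouring both knobs:

* per slice, seed an ellipse at the maximum of the region's Euclidean
  distance transform, semi-minor axis = inscribed radius − 0.5 voxel;
* search all N orientations, growing the semi-major axis in 0.25-voxel
  steps until the footprint leaves the uncovered region or hits the ratio
  limit; keep the orientation admitting the longest axis;
* subtract the footprint and recurse on the remaining fragments.

Two floors stop the recursion: an absolute one (inscribed radius
≥ 1.5 voxels — anything thinner cannot seat a meaningful ellipse) and a
relative one (≥ 0.35 × the first placement's semi-minor axis). The relative
floor exists because the crescent-shaped residuals between overlapping
nuclei are large enough in area to pass any absolute test, and seeding
ellipses on them fragments the labelling and inflates the micronucleus
count. Voxels of unseated fragments are not discarded: every voxel of a
split label is assigned to the chain of its nearest ellipse (normalised
ellipse-frame distance within its slice, 3D Euclidean distance as fallback),
so the output labels partition the input foreground exactly.

Per-slice ellipses are linked across z into nucleus chains by centroid
proximity (consecutive-slice displacement < `fitting_link_radius`, default
4 µm = the nucleus band minimum, well below the ≥ 8 µm centre spacing of
distinct touching nuclei and well above the sub-µm slice-to-slice drift of
one nucleus). Fitting runs before measurement so separated nuclei are
measured individually, and labels receiving at most one chain pass through
unchanged. Whether the original workflow fits before or after size
classification is undocumented; fitting-before-measurement is fixed here.

## Synthetic phantoms

`phantom_spec()`/`make_phantom()` render ellipsoids (voxel centre inside the
surface) at the imaging regime the tool targets: 1 µm z-interval, 10–15
slices, nuclei with semi-axes ~5–6.75 µm, micronuclei 0.8–1.9 µm, lateral
spacing 0.25–0.5 µm. Channel patterns mirror the stains: chromatin core
(blue), optional 1-voxel envelope shell (green), optional cell-marker coat
(red, a 1 µm dilation of the object). Noise is additive Gaussian clipped to
[0, 255], drawn in a fixed channel order under the spec's seed, so phantoms
are bit-reproducible; the acceptance noise level is σ = 10 % of the
foreground–background contrast. Not emulated: the optical PSF,
photobleaching, Poisson statistics, intensity gradients within nuclei, and
chromatin texture. Passing tests therefore demonstrate correctness of the
reconstruction, classification and separation logic under realistic
geometry and additive noise — not robustness to every optical artifact of
real tissue.

`dense_scenario(n, f, seed)` places n ~5 µm nuclei in a row with
consecutive centres 2R(1 − f) apart, so any f > 0 guarantees fusion (at
f = 0 they are placed fully disjoint); seeded jitter perturbs radii by ±5 %
and lateral positions by ±0.5 µm.

## Numerical choices and degenerate inputs

* Axis order is (z, y, x), ascending page index = ascending z, physical
  coordinate = (index − 1) × spacing. 8/16-bit integer TIFF only; float
  samples are rejected so thresholds stay well-defined. Label images are
  written as 16-bit.
* Ties in the distance transform and orientation search resolve to the
  first candidate in array/grid order; all stages are deterministic, and
  identical runs produce byte-identical CSV output (asserted in the tests).
* Constant images, empty masks, empty region tables and missing channels
  are all defined: empty masks give zero labels, empty tables export
  header-only files, a missing green channel makes envelope status
  `not_applicable`.
* Problem sizes in the test suite (stacks of roughly 14 × 100 × 150 voxels,
  spheres digitized at 0.1–0.4 µm spacing, 26-radius sweeps) were chosen so
  every documented accuracy claim (e.g. R_cal within 3 % at 0.2 µm spacing)
  is exercised at realistic resolution while the whole suite stays fast.

## Known limitations

* Slice-wise filtering and fitting assume square lateral pixels
  (`dx == dy`) for the ellipse stage; anisotropic xy grids are rejected
  there.
* Chain linking is greedy nearest-centroid; pathological configurations
  (nuclei stacked exactly above one another closer than the link radius)
  would merge.
* The 2D analysis mode labels every slice independently; it does not
  attempt within-slice tracking and is intended for single-section data or
  for demonstrating the sectioning confound.
* Overlap rates are voxel-count ratios; partial-voxel coverage at object
  boundaries is not modelled.
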