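---
title: "Quantitative micro-CT and histomorphometry of primary teeth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative micro-CT and histomorphometry of primary teeth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dentomorph` implements a quantitative pipeline for dental hard tissues in
micro-computed tomography, of the kind used to characterize mineralization
defects (e.g. in X-linked hypophosphatemia, where renal phosphate wasting
leaves dentin hypomineralized, interglobular dentin expanded and acellular
cementum thinned). Patient scans of this kind are rarely shareable, so the
package pairs every analysis stage with a synthetic tooth-phantom generator
whose voxel-level ground truth makes each stage verifiable by parameter
recovery.

This vignette documents the model behind each stage, the tunable parameters
with their defaults and units, the numerical conventions, and the design
choices that were genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Coordinate and indexing conventions

Volumes are isotropic 3-D arrays (nominally 10 µm voxels). After orientation,
slice 1 is the most coronal axial slice and the z index increases apically
(crown → root). All slice ranges are 1-based and inclusive, the natural R
idiom; µm-to-slice conversions use `ceiling`, so a 0.5 mm extent is exactly 50
slices at 10 µm. Lattice points outside a volume count as background for
distance transforms.

## Density calibration

Scanner grey values are mapped to hydroxyapatite-equivalent mineral density
(mg/cm³ HA) through an affine standard curve fitted by ordinary least squares
to the mean grey values of a multi-rod HA standard
(`fit_calibration()`, `apply_calibration()`):

$$\rho = a \cdot g + b$$

A linear model is the µCT densitometry convention; the vendor's curve form is
not public, and nothing downstream depends on more than monotone affinity over
the dental density range. Degenerate standards (duplicate grey values) are
rejected. On a noiseless synthetic standard the fit is exact to machine
precision with r² = 1 (acceptance criterion 1).

## Tissue segmentation

Segmentation is by density windows on the calibrated volume:

| tissue | rule | boundary semantics |
|---|---|---|
| enamel | > 1600 mg/cm³ HA | strict |
| dentin | 650–1600 | closed interval |
| interglobular dentin | < 650 inside the crown dentin territory | strict |
| acellular cementum | 450–1050 on the median-filtered volume, then mask-back | closed window |

The window bounds come from the source protocol; their open/closed semantics
are not stated there, so the package fixes them as above — enamel strictly
above 1600 and dentin closed at both ends — making enamel and dentin masks
disjoint by construction. Thresholds are recorded verbatim in each mask's
provenance.

### The cementum filter-and-mask-back procedure

Thin acellular cementum cannot be windowed directly at full noise, so the
pipeline (i) median-filters the volume with an 11×11×11 kernel (a per-slice
11×11 mode is available), (ii) windows the filtered volume at 450–1050,
(iii) removes the pulp-adjacent highlight, and (iv) masks back onto the
original volume. Quantification always uses original-volume densities.

Two details were fixed by experiment on phantoms:

* **Pulp-adjacent exclusion.** The manual step this replaces erased softer
  dentin highlighted next to the pulp. A pure connected-component rule
  ("drop candidate components contacting the pulp") fails at the apical
  foramen, where the filtered transition halo around the canal connects to
  the outer cementum sheath and would drag the entire sheath along. The
  implemented rule first erases candidate voxels within `pulp_margin_um`
  (default 50 µm) of the pulp cavity, then drops any component still touching
  it. Both mechanisms are unit-tested.
* **Two-sided mask-back.** "Cementum with a density over 650" is interpreted
  as original density in (650, 1050]: since cementum is itself defined by the
  450–1050 window, a lower bound alone would keep 1–2 voxels of adjacent
  dentin (~1200 mg/cm³) that the filtered transition band drags into thin
  sheaths, biasing thin-layer thickness upward by ~2 voxels.

The median filter runs on values quantized to 4096 uniform levels across the
volume's range (~0.6 mg/cm³ bins on a calibrated dental volume) using a
sliding-histogram algorithm; the quantization is negligible against the
segmentation windows. The filter has a resolution floor: a sheath thinner
than about half the kernel (55 µm at 10 µm voxels) is erased by the median
and is not measurable by this procedure at all. Cohort simulations therefore
keep the thinned case cementum above that floor (see below).

### Pulp cavity

`pulp_cavity_mask()` takes sub-450 voxels that are enclosed in-plane (per
axial slice, components not reaching the slice border). A 3-D connectivity
rule fails here because the canal opens into the background at the apical
foramen, fusing pulp and air into one component.

### Interglobular dentin and the dentin territory

Interglobular dentin is the sub-650 volume inside the *crown dentin
territory*: the dentin mask with its internal cavities closed by 3-D hole
filling of the full-volume mask, cropped to the ROI afterwards so voids
bisected by an ROI face still count. The pulp is never filled because it
always communicates with the exterior (foramen or volume boundary), whereas
interglobular voids are fully enclosed — this exact, radius-free rule replaces
a morphological closing, which would have needed an arbitrary structuring
element.

## Anatomical landmarks and regions of interest

* **CEJ** (`detect_cej()`): scanning from the root end toward the crown, the
  first slice on which enamel forms a topologically complete ring. "Complete
  ring" is operationalized as the slice's non-enamel pixels (4-connectivity)
  containing a component fully enclosed by enamel. On noisy data, landmark
  detection runs on the despeckled enamel cap (`largest_component()`), since
  at realistic noise a handful of dentin voxels clear the enamel threshold.
* **Apical enamel** (`detect_apical_enamel()`): the most apical slice
  containing enamel.
* **Crown ROI** (`build_crown_roi()`): the `ceiling(500/voxel)` slices (0.5
  mm) extending coronally from, and including, the CEJ slice.
* **Root ROI** (`build_root_roi()`): skip `ceiling(150/voxel)` slices
  apically from the apical enamel slice, then span `ceiling(500/voxel)`.
* **Apical cementum ROI** (`build_cementum_roi()`): from the most apical
  slice on which cementum forms a complete ring, the consecutive coronal run
  of ring slices, clamped to 50; fewer than 25 is an error (insufficient root
  structure). The source protocol chose 25–50 slices "depending on whether
  sufficient root structure remained" — a subjective call; the greedy maximal
  run is this package's fixed reading.

**Dentin zones** (`subdivide_dentin()`): within the root ROI, mantle dentin is
the outermost 150 µm measured as Euclidean distance from the outer dentin
surface after cementum exclusion; proximal pulpal dentin the innermost 150 µm
from the pulp surface; circumpulpal dentin the remainder. The distance metric
is not stated in the source; the Euclidean distance transform is the natural
choice. Where a thin wall makes the shells overlap, mantle assignment wins
(the outermost anatomy is never diluted) and the overlap is flagged; walls at
or below 300 µm leave the circumpulpal zone empty with a warning. Because the
650–1600 window alone puts cementum inside the dentin mask, the pipeline
subtracts the segmented cementum before zoning.

**Orientation** (`orient_volume()`): a rigid rotation (trilinear resampling,
voxel size unchanged) aligning the root axis with +z; the axis is either
supplied via landmarks or estimated as the principal axis of the mineralized
voxel cloud, with the sign fixed by the enamel centroid (crown coronal). With
mesial/distal CEJ landmarks the CEJ chord is additionally brought into an
axial plane. Rotations numerically indistinguishable from the identity skip
resampling entirely, so re-orienting an aligned volume is exact.

## Morphometry

* **Mean density** (`mean_density()`): arithmetic mean of original calibrated
  densities over a mask.
* **Local thickness** (`local_thickness()`): model-independent
  maximal-inscribed-sphere thickness — each foreground voxel gets the
  diameter of the largest sphere containing it that fits in the mask, and the
  ROI value is the mean over the z-stack, in mm. Sphere radii are the
  Euclidean distance-transform values (distance to the nearest background
  voxel centre), the classic convention; it overestimates thin structures by
  up to one voxel, a discretization bias that is documented rather than
  corrected. The implementation (separable exact EDT, neighbour-domination
  pruning, sphere painting) is validated against an exhaustive brute-force
  sphere-fitting reference (`reference = TRUE`) that shares only the
  definition, and the two agree exactly on every mask tested (acceptance
  criterion 3). An early half-voxel-offset radius convention was abandoned:
  diagonal background voxels make it underestimate digital spheres beyond the
  one-voxel band.
* **Interglobular volume** (`interglobular_volume()`): voxel count × voxel
  volume, and the fraction of the dentin territory.
* **Crown length** (`crown_length()`): axial distance from the CEJ plane to
  the most coronal enamel slice. The source software's operational rule is
  unrecorded; this axial definition is the package's documented choice,
  isolated in one function.

`analyze_tooth()` chains all of the above into a long-format per-tooth record.

## 2-D histomorphometry

* **Mineralized area fraction** (`mineralized_area_fraction()`): binarize a
  grayscale section and report the percentage of dark (mineralized) pixels.
  The manual histogram adjustment of classic section analysis is replaced by
  a deterministic Otsu threshold with a numeric override — reproducibility
  over fidelity to an undocumented hand step. Constant images are rejected.
* **Layer thickness** (`layer_thickness_2d()`): for a band with two opposing
  boundaries, the per-pixel thickness is the sum of Euclidean distances to
  the two adjacent complement regions minus one pixel (centre-to-centre
  distances overshoot a straight band's width by exactly one pixel), averaged
  over the band. Exact on straight bands, within 5% on annuli.
* **Replicates** (`section_replicate_summary()`): per-tooth means over
  replicate sections (typically n = 3).

## Cohort statistics

The statistical layer is deliberately descriptive, matching small-cohort
practice for rare disease: no hypothesis tests, only control-derived bands.

* `reference_interval()`: the default band is the t-based 95% CI of the
  control mean, mean ± t(0.975, n−1)·SD/√n — consistent with one shaded band
  per metric in a control-referenced dot plot. Whether such bands are CIs of
  the mean or population tolerance bands is often ambiguous in source
  figures; both modes ship (`type = "reference"` gives mean ± 1.96 SD), CI of
  the mean is the default.
* `classify_within_limits()`: strict comparison against the band edges;
  values on an edge are within.
* `fold_change()` / `percent_change()`: case-over-control ratios of group
  means; a non-positive control mean is an error for fold changes, with
  guidance to report absolute differences.
* `cohort_report()`: per metric, the control band, per-value classification,
  and fold/percent change; values are per tooth by default (matching plots of
  individual teeth), with per-patient aggregation as an option. Metrics
  missing a group are skipped with a warning.

## The phantom: a stated world

`phantom_spec()` / `generate_tooth_phantom()` build an axisymmetric
single-rooted tooth as a solid of revolution: a flat-topped enamel cap over
crown dentin, a pulp chamber narrowing into a canal open at the apical
foramen, root dentin under an acellular cementum sheath, and a gentle conical
taper of the apical root half to 60% of the cervical radius (steep cones make
the sheath obliquely thin and are unrealistic for single-rooted primary
teeth). Real teeth are irregular; axial symmetry is enough to exercise every
downstream operator while keeping every geometric truth analytic.

Defaults (all overridable): 10 µm voxels; crown 0.9 mm high, radius 0.8 mm;
root 1.0 mm, radius 0.7 mm; enamel 0.2 mm; dentin wall 0.45 mm; cementum
100 µm; densities enamel/dentin/cementum/pulp/background =
2000/1200/900/200/0 mg/cm³ HA, chosen to sit centrally in the segmentation
windows (generator conventions, not biological claims). The miniature
geometry keeps a full phantom near 200³ voxels; real primary teeth are
larger, but tooth size scales no operator — only runtimes. The default
cementum sits at the thick end of reported acellular/apical cementum so the
sheath spans about the median kernel's half-width.

Interglobular voids are non-overlapping spheres (default radius 30 µm)
rendered at pulp density, placed by seeded rejection sampling with an
occupancy stamp until the requested volume fraction of crown dentin is
reached. Centres lie in crown dentin; spheres must fit inside dentin with a
one-voxel dentin shell (so voids never abut pulp or enamel, and hole-filling
always recognizes them), and may dip just past the CEJ plane (so the crown
ROI is not depleted near the CEJ). Placement failure after exhausting
candidates reports the realized (lower) fraction with a warning rather than
looping forever. Noise is additive Gaussian in grey units, applied after the
affine density-to-grey map; scanner physics (beam hardening, scatter, partial
volume) is out of scope.

**What a green test does and does not establish.** Phantom recovery shows the
operators implement their definitions and the pipeline recovers known effects
at realistic noise. It does not validate against real anatomy: real teeth
have irregular CEJs, attrition, resorbing roots, partial-volume boundaries
and spatially correlated noise, none of which the generator emulates.

The 2-D histology generator mirrors this for sections: a mineralized dentin
field (dark) with unmineralized blobs at a requested area fraction, flanked
by cementum and predentin bands inside a bright empty-slide margin, plus an
exact checkerboard mode for the 50% case.

## Cohort simulation

`simulate_cohort()` generates control and case teeth and runs the full
pipeline on each. The default case phenotype is the characteristic
mineralization-disorder triad: dentin density ×0.9, interglobular void
fraction ×10 (from a control fraction of 0.005), cementum thickness ×0.5.
Between-tooth variability is Gaussian jitter of nominal dentin density (SD 10
mg/cm³) on top of within-scan noise (SD 50). The control cementum for the
simulation is 160 µm so the halved case sheath (80 µm) stays above the median
filter's ~55 µm resolution floor — inside the validity domain of the method
being exercised. One tooth per patient is the default; teeth can be blocked
into patients for per-patient analysis.

## Numerical choices and degenerate inputs

* Exact squared Euclidean distance transforms (separable parabolic lower
  envelopes); distances to features are centre-to-centre.
* Median filtering uses replicate borders and ≤4096-level quantization.
* The thickness map is exactly reproducible: the pruning step provably
  preserves the sphere-painting maximum (domination chains terminate at a
  retained sphere).
* Empty masks are errors for measurements (`mean_density`,
  `local_thickness`) but a warning for cementum segmentation, where an empty
  result is a real phenotype (aplastic cementum); `analyze_tooth()` degrades
  to `NA` cementum metrics when no apical hollow-cylinder run of 25 slices
  exists.
* Ties and bounds: values exactly at window bounds follow the table above;
  classification at a band edge is "within"; the Otsu threshold is a bin
  edge, deterministic for a given image.
* File I/O: volumes are written/read as uncompressed little-endian NIfTI-1
  (no R package in the supported toolchain provides this, so the single-file
  format is implemented directly); curves, ROI manifests and phantom truth
  serialize to JSON. NIfTI orientation metadata (qform/sform) is left unset;
  the axial convention above is authoritative. Voxel sizes round-trip
  through NIfTI's float32 `pixdim`.

## Known limitations

* Single-rooted, axisymmetric phantoms only; no furcations, attrition or
  root-resorption modelling, and no automatic mesial/distal labelling.
* The cementum procedure cannot measure sheaths thinner than ~half the
  median kernel; that is a property of the method, reproduced faithfully.
* Local thickness carries the classic ≤1-voxel overestimation on thin
  structures.
* The CLI-style entry points of the original protocol description are
  provided as R functions and the `scripts/acceptance.R` driver rather than a
  shell tool; the package is an analysis library.
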