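---
title: "Models and methods behind clearbrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clearbrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clearbrain)
```

`clearbrain` analyses light-sheet recordings of optically cleared mouse
brains. This vignette is the package's own account of the models it
implements, the conventions it fixes where the underlying procedures are
ambiguous, and what its synthetic-data tests do and do not demonstrate.

## Geometry and containers

Volumes are stored as plain 3D arrays in (z, y, x) order inside a
`brain_volume`, with a physical voxel pitch per axis in micrometres. The
axis convention is fixed package-wide: the light sheet propagates along
**+y** (lateral illumination) and the camera faces **+z** (dorsal
detection). The default pitch, 1.61 µm in-plane with a 3.23 µm z-step, is a
typical high-resolution LSFM sampling of a cleared hemisphere; camera
intensities live on a 12-bit scale (0–4095).

## Depth-dependent attenuation correction

Within tissue, both the excitation and the emitted fluorescence are
attenuated approximately exponentially. The model is single-coefficient
Beer–Lambert per axis:

$$I_\mathrm{obs} = I_\mathrm{true}\; e^{-k_y \Delta y}\, e^{-k_z \Delta z},$$

with correction factor $1/(e^{-k_y\Delta y} e^{-k_z\Delta z})$ applied
multiplicatively inside the tissue mask. The pipeline order is: compute the
factor field, clamp it, smooth it with a 3D Gaussian, multiply. Design
choices a user should know:

* **Background threshold.** The mask threshold is the 99th percentile of a
  background-only window, i.e. the level that the brightest 1% of
  background voxels exceed. "Upper 1%" is ambiguous between percentile
  definitions, so the linear-interpolation convention between order
  statistics (R's type 7) is fixed and tested; the percentile is computed
  over the 3D window (all z-planes of the footprint), not per-plane. For
  real recordings the window should be at least 500 × 500 px; the bound is
  configurable because synthetic test volumes are far smaller.
* **Mask hygiene.** Thresholding keeps everything brighter than background;
  by default only the largest 6-connected component is retained (isolated
  bright specks outside the sample are not tissue) and fully enclosed
  background cavities are closed, up to a configurable size.
* **Path lengths.** $\Delta y$ at a voxel is the cumulative in-mask path
  from the illumination-side (−y) tissue entry; $\Delta z$ from the
  detection-side (+z) boundary, since that is the tissue the emission must
  cross to reach the camera. A half-voxel convention puts the entry face at
  zero path, the n-th tissue voxel at $(n - \tfrac12)\times$ pitch; it is
  symmetric and exactly testable. Mask holes contribute zero path — cleared
  cavities do not attenuate under the tissue model taken literally.
* **Coefficient estimation.** The original workflow tuned $k_y, k_z$ by eye
  against intensity gradient profiles. Here the estimate is a documented
  regression: bin in-mask voxels by depth while holding the other axis's
  depth in its lowest tercile, regress log mean intensity on depth, negate
  the slope. Two refinement passes then divide out the other axis's current
  estimate and re-fit over the full range, removing the residual cross-axis
  bias of the tercile restriction; on noise-free phantoms the estimates
  converge to the true coefficients to well below 1%. Negative estimates
  are clamped to zero with a warning, and per-axis R² of the profile fit is
  reported. Manual override (`ky`, `kz` as numbers) remains available,
  since hand-tuned values may be preferred for display work.
* **Smoothing and clamping.** Smoothing (σ = 2 voxels per axis by default)
  operates on the factor field itself, not its logarithm, matching the
  pipeline order stated above; a constant field is a fixed point of the
  filter (nearest-edge padding). Factors are clamped at 20× by default:
  deep voxels below the noise floor would otherwise be amplified without
  bound. The clamp and the number of voxels that hit it are logged.
* **No per-wavelength calibration.** No measured per-axis absorption
  coefficients for cleared adult brain are available to ship; the phantom
  default of $k = 5\times10^{-4}\,\mu m^{-1}$ is an arbitrary but plausible
  placeholder and is labelled as such wherever it appears.

## Mosaic stitching

Tiles are registered pairwise by maximising Pearson correlation over a
central crop of the nominal overlap, searching integer offsets within a
configurable radius (default 10 voxels; per-axis radii are accepted because
thin z-stacks cannot support a deep z-search). A central, intensity-
normalised crop resists the smooth ramp that depth attenuation adds to both
tiles. Ties break toward the nominal offset, then lexicographically in
(z, y, x). Offsets are integer-voxel only — downstream analysis operates at
voxel scale, and integer offsets keep the tests exact. Pairwise offsets are
made globally consistent by least squares over the translation graph
(anchor tile at the origin); edges scoring below 0.3 are flagged unreliable
and fall back to their nominal offset. Fusion blends overlaps by linear
feathering (each tile weighted by its distance to its own nearest face), so
identical overlap content is reproduced exactly and single-tile voxels are
copied verbatim. How the original stitching plugin blended seams is not
documented; feathering is this package's choice.

## Synthetic data: what it emulates, what it does not

The generator produces every input the pipeline needs, with ground truth:

* an ellipsoidal brain of uniform autofluorescent background with a
  brighter peripheral rim (the strong autofluorescence of the brain
  surface), planted cells of two morphological classes — neurons as one
  bright sphere with up to two thin neurites, glia as a faint soma with a
  bushy cluster of 5–9 small lobes — in a toy atlas of ellipsoid octants;
* forward Beer–Lambert attenuation with known coefficients, then CCD-style
  noise: Poisson on gain-scaled intensity plus Gaussian read noise, clipped
  to 12 bits;
* jittered tile mosaics whose boundary tiles are pinned to the volume edges
  (the stage starts and ends at the sample boundary), so the tile union
  always covers the volume while interior tiles carry the positioning
  error;
* shadow-stripe images: Beer–Lambert line integrals through absorbing
  spheres, swept plane by plane along the tilted illumination direction
  with linear resampling of the *transmission* (resampling optical depth
  instead would smear opaque shadows by orders of magnitude); averaging
  over symmetric angles reproduces the suppression of stripes by a rotating
  light sheet;
* plate-assay tables with quintuplicate positives and triplicate
  no-fluorophore controls per condition and step, readings =
  background + retention × signal + reader noise.

Not emulated: realistic point-spread functions, refractive-index-mismatch
aberrations, scattering beyond single-exponential absorption, axon tracts,
and cell-class appearance beyond glance-level separability. Tests passing
on phantoms therefore certify the *arithmetic* of each stage — masks,
depths, corrections, offsets, counts — not the optical fidelity of any
forward model. Cell class is always an input annotation; the package never
infers it from images.

Every generator takes its seed as an explicit argument, restores the
caller's RNG state afterwards, and is bit-reproducible for identical
spec + seed.

## Connectivity counting conventions

* Region assignment is voxel containment: 0-based floor indexing on
  half-open voxel intervals. Manual annotation has no convention to follow;
  this one is unambiguous and exactly testable.
* The injection site is an atlas *flag* on the entorhinal-cortex cluster
  (ectorhinal, perirhinal, lateral and medial entorhinal cortex,
  ipsilateral only), not a radius around a coordinate; flagged regions are
  excluded from the "ipsilateral without injection site" input rollups.
* The count tables follow the published grouping verbatim, including
  placements one might debate anatomically (corpus callosum under
  subcortical; external capsule and alveus under hippocampal).
* Red-only (AAV-marker) cells stay in the data model but never enter the
  EGFP count tables.
* Reported percentages round half-even to one decimal; whether the original
  figures rounded half-up is unknowable from the printed values, so the R
  default is used and documented.
* Conservation (every rollup equals the sum of its leaves) is asserted on
  every table build, not just in tests.

The in-package annotation fixture (`table2_fixture()`) realises the
published per-region counts as one node per counted cell at synthetic
positions inside the matching toy-atlas block; aggregating it reproduces
the printed table cell for cell, which is what the acceptance suite
asserts.

## Longitudinal comparison and the preservation assay

Registration operates on corresponding landmark sets, not voxel
intensities: the original alignment was interactive, and landmark least
squares is its reproducible core (node sets are already first-class here).
The single scale-change number is $(|\det A|^{1/3} - 1)\cdot 100\%$ — an
isotropic summary, chosen because one printed number implies one. Since
point-set registration never resamples images, the interpolation kernel
used for display alignment is irrelevant here. Display-range normalisation
maps intensities linearly between (low, high) ranges whose lows are the
image background; when excitation doses are attached, the width ratio is
checked against the dose ratio (10% relative tolerance → "consistent").
The bundled example ranges 70–1269 and 63–462 give a width ratio of
1199/399 ≈ 3.005 against a dose ratio of 4.65/1.55 = 3.0.

Assay quantification subtracts the control mean from the positive mean per
step and normalises to the initial (PBS) corrected value. SDs propagate by
the first-order delta method with step and initial treated as independent
(the plotted SDs in such assays state no method; first-order is the
standard choice). Negative corrected values are reported as-is; a
non-positive initial value flags the condition unquantifiable rather than
producing a misleading percentage. The quantification is invariant under
affine reader rescaling, which the tests assert.

## Problem sizes and numerical tolerances

The test suite exercises phantoms up to 128³ voxels (the attenuation
round-trip, which holds to ≤10⁻⁶ relative error in-mask), coefficient
recovery on 48×72×72 (noise-free, within 2%) and 20 noisy seeds at
40×64×64 (median error within 10%, typically ~2%), 50 stitching fixtures
of 3×3 jittered mosaics on 10×72×72 volumes (exact recovery), and
Monte-Carlo checks with 50–200 seeds for the noise-floor and assay
properties. These sizes keep the full suite around half a minute on one
core while leaving each statistical check comfortably powered; all
simulations scale linearly should larger phantoms be wanted.

Degenerate inputs are first-class: constant background windows warn and
return the constant; empty masks, unstitchable jitter, disconnected tile
graphs, coplanar landmark sets, negative retentions and zero denominators
all raise typed errors or NA-with-note rather than silently producing
numbers.

## Known limitations

* The attenuation model is single-exponential per axis with spatially
  constant coefficients; scattering, wavelength dependence and regional
  variation are out of scope.
* Stitching is translation-only at integer voxels; rotation/affine tile
  registration and illumination flat-fielding between tiles are not
  implemented.
* The toy atlas is a block layout for testing region assignment and
  aggregation; registering real brains to a reference atlas is out of
  scope.
* The shadow sweep resamples once per y-plane; tilted stripe edges blur by
  roughly a voxel relative to an exact ray march (the tests bound this
  against a brute-force oracle).
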