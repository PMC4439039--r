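# clearbrain

Quantitative analysis of cleared whole mouse brains imaged by light-sheet
fluorescence microscopy (LSFM).

Clearing a brain by refractive-index matching makes it transparent enough to
image end to end with a light sheet, but the raw recordings still need a
computational pipeline before any biology can be counted: tiled z-stacks must
be stitched into one volume, the depth-dependent loss of excitation and
emission light in tissue must be corrected, manually annotated cell-body
positions must be assigned to brain regions and aggregated into connectivity
tables, and longitudinal re-imaging sessions and fluorophore-preservation
assays must be quantified on a common scale. `clearbrain` implements that
pipeline as a tested, reusable R package. Because raw LSFM volumes of cleared
brains run to hundreds of gigabytes and none are bundled here, the package
ships a synthetic-data module that generates every input with known ground
truth — phantom brains, tile mosaics, shadowed illumination, plate-assay
decay series — so each stage is verifiable at desk scale.

## The models at the core

**Depth attenuation correction.** Inside the binary tissue mask, observed
intensity is modelled as Beer–Lambert attenuation of both the excitation
light (along the illumination axis y) and the emission light (along the
detection axis z):

    I_obs = I_true · exp(−k_y·Δy) · exp(−k_z·Δz)

where Δy and Δz are the cumulative tissue path lengths (µm) from the
illumination-side and detection-side tissue boundaries to the voxel, and
k_y, k_z are effective absorption coefficients (µm⁻¹). The correction field
is the reciprocal, `IntensityCorrection(Δy,Δz) = 1/(e^{−k_y Δy} e^{−k_z Δz})`,
clamped, Gaussian-filtered (σ = 2 voxels per axis), and multiplied onto the
data. The tissue mask comes from a histogram threshold that keeps the upper
1% of intensities in a background-only image window; the coefficients are
estimated by regressing log mean in-mask intensity on depth, replacing the
manual profile tuning such corrections usually rely on.

**Connectivity counting.** Cell-body annotations (KNOSSOS-style `.nml`
skeletons or CSV) carry a channel flag (EGFP green / mRFP1 red), a
morphological class (neuron or glia) and a 3D position. Nodes are assigned
to atlas regions by voxel containment and aggregated into a
region × class count table with group rollups (cortical, subcortical,
hippocampal, olfactory), hemisphere splits, and the injection-site cluster
(entorhinal-cortex regions) excluded from input counts. Derived statistics
are the glia fraction inside and outside the hippocampus and the
contralateral share of monosynaptic input.

**Stability machinery.** Landmark-based least-squares affine registration
summarises longitudinal geometry change as `(|det A|^{1/3} − 1)·100%`;
display ranges recorded at different excitation powers are mapped linearly
onto a common scale with a dose-consistency check; plate-reader assays are
quantified as background-corrected percent-of-initial fluorescence with
delta-method error propagation.

## Worked example

Aggregate the bundled annotation fixture into the connectivity table and its
derived fractions:

```r
library(clearbrain)
atlas <- toy_atlas()
nodes <- assign_regions(table2_fixture(atlas), atlas)
tab   <- aggregate_counts(nodes, atlas)
tab
#> <region_count_table>
#>        group inj_neurons inj_glia ipsi_neurons ipsi_glia contra_neurons contra_glia
#>     cortical        2319       32         2385        17             58           0
#>  subcortical           0        0          325         5             22           0
#>  hippocampal           0        0          863       880              5           0
#>    olfactory           0        0          110         1              0           0
#> totals:
#>  inj_neurons inj_glia ipsi_neurons ipsi_glia contra_neurons contra_glia
#>         2319       32         3683       903             85           0
derived_fractions(tab)[1:3]
#> $hippocampal_glia_pct        50.5
#> $extra_hippocampal_glia_pct   0.8
#> $contralateral_input_pct      2.3
```

Reading the numbers: of the 1743 EGFP-labelled cells in the ipsilateral
hippocampus, 50.5% show glia-like morphology, against 0.8% outside the
hippocampus; contralateral neurons contribute 2.3% of the monosynaptic input
to the injected entorhinal cortex (85 of 3768 input neurons).

Estimate attenuation coefficients on a noisy phantom whose true values are
k_y = 5×10⁻⁴, k_z = 3×10⁻⁴ µm⁻¹:

```r
ph    <- generate_phantom(phantom_spec(shape = c(48, 72, 72), cells = list(),
                                       rim_um = 0, rim_gain = 0,
                                       ky = 5e-4, kz = 3e-4,
                                       poisson_gain = 1, read_sd = 4))
thr   <- background_threshold(ph$channels$green,
                              list(y = c(1, 8), x = c(1, 8)), min_area = 64)
mask  <- compute_tissue_mask(ph$channels$green, thr)
estimate_coefficients(ph$channels$green, mask)
#> <attenuation_model> ky = 0.0005039 /um, kz = 0.0002671 /um
#>   fit R^2: y = 0.9027601, z = 0.8986249
```

A command-line wrapper with subcommands
`simulate | stitch | correct | assign | stats | register | assay | run |
validate` is installed at `inst/scripts/clearbrain`; the `run` subcommand
drives the whole pipeline from a JSON config into a deterministic artifact
directory.

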