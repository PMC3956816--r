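---
title: "Projected hip densitometry from quantitative CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projected hip densitometry from quantitative CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxa)
```

## The measurement problem

Clinical hip densitometry reports areal bone mineral density (aBMD,
g/cm^2): the mineral mass of the proximal femur divided by its projected
area, measured in standard regions of interest (femoral neck, trochanter,
intertrochanter, and their union, Total Hip). DXA measures this quantity
directly by dual-energy projection. A calibrated 3D CT scan contains
strictly more information: every voxel carries a mineral-equivalent
volumetric density once an in-scan calibration phantom maps scanner HU to
mg/cm^3 of aqueous K2HPO4. `ctxa` turns such a volume into a DXA-like
projection and measures the same ROIs, with one capability DXA lacks: a
voxel-level split of each ROI into cortical and trabecular compartments.

The pipeline is: **calibrate** (rod fit + QA) → **segment** (adaptive
threshold + cortical-envelope fill) → **orient** (standard pose) →
**project** (anteroposterior ray sums) → **ROIs** → **compartments**,
plus a statistics module for the precision, interobserver and
cross-device analyses used to validate such systems, and a digital femur
phantom that makes every stage testable against analytic ground truth.

## Calibration

Each calibration rod is sampled over a disk eroded to 70% of its nominal
radius, and over a slice range eroded by half a slice at each end, so
partial-volume rims never enter the mean. Mean rod HU against nominal
density is fitted by unweighted ordinary least squares (the rod
configuration does not justify weighting, and a two-rod layout reduces to
the exact two-point line). Per-rod residuals are reported for QA.

The QA check measures the calibrated density of the 200.0 mg/cm^3
aqueous-K2HPO4 reference and reports the percent deviation, a pass flag
(default tolerance plus-or-minus 2%, configurable; the tolerance is a
policy default, not a physical constant), and a suggested beam-hardening
slope factor `200 / measured`. Beam hardening biases the effective
calibration slope; a single multiplicative slope correction from the
reference rod is the simplest correction consistent with that mechanism.
It is reported, never silently applied — `apply_beam_hardening = TRUE`
opts in.

## Segmentation

Three parameters control bone segmentation, all in mg/cm^3 equivalent
density except the neighborhood width:

| parameter | default | meaning |
|---|---|---|
| `floor_threshold` | -250 | below this a voxel can never be bone |
| `neighborhood_width` | 5 pixels | local-mean window |
| `seed_threshold` | 120 | initial "tentatively bone" threshold |

Voxels above the seed threshold form the initial set; refinement then
erodes it: a voxel stays bone only while its density is at least the
local mean density over the window centred on it (and always strictly
above the floor). Two implementation choices deserve explanation.

First, the refinement is *erosive* (it never adds voxels the seed stage
did not propose). A rule that re-admitted any voxel at or above its local
mean would classify a uniform water background as bone, since a constant
field equals its own local mean everywhere. Seeding at 120 mg/cm^3 and
eroding preserves the intended semantics: the seed proposes, the local
mean disposes. Because the local mean field does not depend on the
labels, the erosion reaches a fixed point in one sweep; the loop runs to
label stability anyway (cap 50) so the rule stays correct if the
neighborhood definition is ever changed to a label-dependent one.

Second, the window is quasi-isotropic in millimetres: the stated width is
in in-plane pixels, and the per-axis voxel count is rescaled by the axis
spacing (never below one slice along z). At the default acquisition
geometry (0.781 mm pixels, 3 mm slices) a literal 5-voxel cube would
reach plus-or-minus 6 mm axially; for surfaces curved on that scale
(femoral head radius about 20 mm) the cube mean underestimates the
surface threshold and dilates the mask by about a millimetre exactly
where the head and neck curve fastest. A first-order analysis shows the
local-mean rule recovers the 0.5-occupancy surface exactly for a *flat*
interface of any orientation — including the slice-thickness caps — so
shrinking the axial reach removes the curvature bias without disturbing
cap behaviour. On the digital phantom this choice brings the segmented
volume within about 1% of the 0.5-occupancy rasterization of the true
geometry.

A 1e-6 mg/cm^3 slack on the comparison keeps exact ties (uniform
regions) stable against floating-point averaging noise.

`fill_cortical_envelope()` then absorbs everything inside the outer
cortex — marrow is deliberately not separated from bone within the
envelope. Filling is per-axial-slice first, then 3D, which guarantees the
envelope on anisotropic grids; only the largest 26-connected component
intersecting the user box is kept, with ties broken by centroid proximity
to the box centre. Voxels between the floor and seed thresholds therefore
enter the mask only via the envelope, which matches the physical intent:
low-density marrow belongs to the bone envelope, not to the adaptive
boundary decision.

## Standard pose

The standard pose has the femoral shaft vertical in the coronal and
sagittal views and the femoral neck horizontal in the axial view. The
estimated rotation maps the shaft axis to +z and the component of the
neck axis orthogonal to z to +x; a rigid rotation cannot additionally
zero the neck's elevation unless the neck is perpendicular to the shaft,
so elevation (the neck-shaft angle) is preserved, which is what the
projected neck-axis angle measures later.

The shaft axis is fitted through per-slice centroids of the distal 40%
of the mask. Slices whose cross-sectional area exceeds the median by more
than 2% are rejected (they carry the lesser trochanter), and the line is
fitted by long-baseline Theil-Sen (median of pairwise slopes over slice
pairs at least 10 mm apart). The median fit is immune both to remaining
outlier slices and to the staircase that slice-quantized masks exhibit
after rotation; a plain least-squares or voxel-PCA fit is measurably
tilted by either. The head centre comes from a short mean-shift around
the voxel farthest from the shaft line; the in-plane (azimuth) component
of the neck axis is taken from the shaft-to-head chord, which for a neck
lying in a vertical plane equals the true in-plane component and is far
less noisy than the corridor PCA that estimates the full 3D neck axis.
A mask whose distal principal variances are within a factor 1.3 of each
other (a sphere; no shaft) raises an orientation failure prompting manual
angles.

Resampling onto the isotropic grid (default 0.781 mm, the in-plane
pitch, so projected pixel area is well defined) interpolates density and
mask occupancy trilinearly; occupancy is thresholded at 0.5 and density
in retained voxels is occupancy-normalized, so boundary voxels keep
physical densities and total mass is conserved to about 1%. Non-bone
voxels carry `NA` — zero is a valid equivalent density. The output
lattice is snapped so that an identity rotation of an isotropic volume
reproduces it exactly.

## Projection and ROIs

Projection sums bone voxels along anteroposterior lines: per pixel, a
mineral mass (g), a bone path volume (cm^3), and derived aBMD and path
length. The sums are plain summation — mass is conserved exactly, and
pixels with no bone are exactly zero. Volumetric BMD uses the bone path
volume, not any enclosing box.

ROI placement works on the background-free silhouette (no 15%-of-peak
profile rule is needed, because unlike DXA there is no residual
soft-tissue background): the head is the largest inscribed circle of the
superior silhouette (distance transform); the neck cross-section
minimizes the silhouette chord over candidate axis angles and stations
marching from the head centre toward the shaft, with stations inside the
shaft column excluded so junction corners cannot masquerade as the
isthmus. Because the width-vs-angle profile is flat near its minimum
relative to pixel quantization, the angle is then sharpened from the
local tangents of the two silhouette edges flanking the isthmus, which
run parallel to the neck axis. The neck box is 15 mm wide along the axis
(a conventional DXA-like default) and spans the neck with a half-height
of 0.75 times the minimal width. The intertrochanter lower boundary sits
where the medial silhouette profile returns to the shaft edge (mode of
the profile below the neck) after the lesser-trochanter prominence — the
discrete analogue of the maximal-curvature corner at the lower junction
of the lesser trochanter and the shaft. Silhouette pixels medial of the
neck box are the femoral head and belong to no ROI; lateral pixels above
the extended inferior box edge are trochanter; the remainder above the
boundary is intertrochanter. Total Hip is the exact pixel union. All
landmarks are geometric conventions of this package (the clinical ROI
definitions are not published as formulas); each is deterministic and
overridable, and right hips are mirrored internally so placement is
symmetric.

Compartments: voxels at or above 350 mg/cm^3 (configurable) are
cortical, the rest trabecular. Both compartment masks are re-projected
and measured over the same ROI pixels, so cortical plus trabecular mass
and path volume equal the integral values exactly by construction.

## The digital femur phantom

The phantom is a constructive-solid-geometry union of four primitives
(head sphere r 21 mm; neck cylinder r 12.5 mm, length 38 mm at a 130
degree neck-shaft angle; shaft cylinder r 14 mm, length 70 mm; lesser
trochanter sphere r 9 mm), a 3 mm cortical shell at 800 mg/cm^3 over a
150 mg/cm^3 trabecular interior, water background, and a three-rod
calibration insert (0, 100, 200 mg/cm^3) kept several millimetres clear
of the bone so phantom and femur never merge into one connected
component. Dimensions and densities are typical adult proximal-femur
values; the trabecular density exceeds the 120 mg/cm^3 seed so interiors
seed correctly, and the cortical density is well above the 350 mg/cm^3
compartment threshold. Density is rasterized with 3x supersampled
partial-volume averaging, HU is the exact inverse of the configured
calibration (slope 1.25 mg/cm^3 per HU, intercept -8), and Gaussian HU
noise (default 0) is added deterministically per seed.

The verification oracle never touches the voxel pipeline: because every
primitive axis lies in the coronal mid-plane, the anteroposterior chord
through the bone is a single interval with a closed-form length, and the
eroded union that defines the trabecular core is exactly the union of
analytically eroded primitives; only the in-plane integration is numeric
(10x the acquisition pixel by default, with 10x-vs-20x agreement checked
at 0.5%).

What the phantom does *not* emulate: trabecular texture, beam-hardening
streaks, scatter, metal, soft-tissue inhomogeneity, and anatomic shape
variation. Passing tests therefore demonstrate correctness of the
geometry, calibration and bookkeeping chain under ideal imaging, not
robustness to clinical image quality.

Typical accuracy at the default 0.781 x 0.781 x 3 mm geometry, from the
test suite: total mass within about 3% of the analytic value (the
irreducible cost of summing partial-volume densities over a
0.5-occupancy mask), regional aBMD within 2-5% of the oracle, cortical
fraction within 1 percentage point, rotation recovery within about 0.2
degrees, neck angle within about 1 degree. Halving the voxel spacing
tightens the mass and area errors roughly in proportion.

## Densitometry statistics

Long-term precision is the root-mean-square of per-patient sample SDs
(n-1 denominator, computed without regard for any bone-change trend),
unweighted across patients: the plain reading of an "RMS average of the
SD estimates". Patients contribute 3 or 4 visits; the unweighted and
df-weighted versions coincide when visit counts are equal, and a
`weighted = TRUE` flag provides the df-weighted variant. CV uses the
grand mean of patient means. The interobserver comparison defaults to a
paired t-test (the same scans are analyzed twice) with percent difference
quoted against observer 1; an unpaired Welch option exists because the
pairing is a modelling choice, and the denominator choice is immaterial
at the 0.1% level for realistic means. Cross-device agreement is OLS of
DXA on CTXA (so slope and intercept read as "DXA expected from CTXA"),
with Pearson R and SEE = sqrt(RSS/(n-2)). Welch's t with Satterthwaite
df justifies pooling sites by comparing per-site bias distributions, and
the Anderson-Darling case-3 statistic (estimated mean and variance, the
standard small-sample adjustment, 5% critical value 0.752) screens for
non-normality; its A-squared value is affine-invariant, so it applies to
BMD in any unit.

Simulation sizes in the tests (500 cohorts of 22 patients x 3 visits for
estimator recovery; 10,000 replicates for Welch type-I calibration; 1,000
seeds for Anderson-Darling calibration) were chosen so that Monte-Carlo
standard errors are several times smaller than the tolerances being
asserted.

## Degenerate inputs and numerical conventions

Coordinates are mm in patient axes (x left-right, y anterior-posterior,
z inferior-superior), voxel centres at integer multiples of the spacing,
0-based externally and half-open in all interval conventions; masses in
g, areas cm^2, volumes cm^3, volumetric densities mg/cm^3
(1 g = 1000 mg fixed). Empty segmentation results are legal (empty
mask); an empty mask warns on envelope fill and projects to an all-zero
image; an empty ROI is an error (no measure exists). Constant input to
the normality test, zero x-variance in regression, and both-degenerate
Welch inputs are errors rather than NaNs. All ties documented above
(equal component sizes, equal chord widths) break deterministically.

## Known limitations

Volume I/O is NIfTI-only in this build: no maintained DICOM or NRRD
reader is available to the package, so DICOM series must be converted
(for example with dcm2niix) before analysis, and `read_ct_volume()`
says so explicitly. T-scores are computed only against user-supplied
young-normal parameters; no reference population ships with the package.
The patient-level tables behind the bundled clinical summary statistics
are not redistributable, so the headline precision and cross-device
regressions can be recomputed only by users who obtain those data and
convert them to the package CSV schemas (see
`supplementary_data_path()`). The auto-placement landmarks are tuned for
proximal-femur geometry; grossly pathological anatomy should use the
manual overrides, which are first-class inputs, not fallbacks.
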