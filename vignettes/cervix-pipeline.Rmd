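---
title: "Automated multi-layer cervix analysis: models, conventions and numerical choices"
author: "cervimetry authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated multi-layer cervix analysis: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervimetry)
```

# The problem

During pregnancy the uterine cervix remodels continuously; its length is the
established imaging biomarker for preterm-birth risk, and volumetric changes
of its tissue layers are of growing research interest. Motion-corrected 3D
T2-weighted MRI reconstructions (at roughly 0.8 mm isotropic resolution)
make a full 3D analysis possible, but manual segmentation takes tens of
minutes per case and manual 2D measurements carry substantial inter-observer
variability. `cervimetry` implements an automated pipeline for this setting:
multi-label parcellation conventions, landmark-based biometry, per-label
volumetry, a trainable 3D segmentation network, groupwise atlas
construction, and gestational-age normative charts.

The package is deliberately testable without patient data: a parametric
cervix phantom with analytically known geometry stands in for reconstructed
images, so every stage can be validated by parameter recovery against exact
ground truth.

# Parcellation convention

Five tissue labels on a 3D integer grid (`label_volume`):

| code | label | T2w appearance |
|------|-------------------------|-----------------------------------------|
| 0 | background | — |
| 1 | endocervical canal (ECC) | regional mixture of high and low signal (mucus) |
| 2 | inner stroma / subglandular zone (SGZ) | darkest cervical layer |
| 3 | outer stroma (OS) | intermediate, slightly darker than surrounding tissue |
| 4 | cyst | brightest focal regions, mostly within the canal |
| 5 | bladder | fluid-bright, adjacent organ |

All geometry lives in world millimetres (RAS+) through the NIfTI affine;
landmarks and measurements are never expressed in voxel indices, which makes
every measurement invariant to grid orientation. Labels are resampled with
nearest-neighbour interpolation only — a label is a category, not a
quantity.

# The cervix phantom

`phantom_spec()` defines a two-segment canal centreline (inlet → mid →
outlet). The canal is the set of points within `canal_radius` of the
centreline, cut flat at the inlet and outlet planes (perpendicular to the
respective segment) so the canal has clean open ends that touch background —
mirroring how the reconstructed canal terminates at the internal and
external os. Inner and outer stroma are concentric shells of the same
construction; cyst spheres must lie inside the canal and overwrite canal
voxels; an optional bladder sphere sits beyond the inlet.

Because the centreline is exactly two straight segments, the clinical
two-line cervical length is the *true* arc length — curvature enters only
through the inlet–mid–outlet angle, and the true diameters are exactly
`2 * canal_radius`. Rasterization uses majority voting over supersampled
points (default 3³ per voxel) with ties broken by a fixed label priority
(cyst > canal > inner > outer), which makes the rasterizer reproducible and
order-stable.

Ground-truth label volumes use closed forms when the centreline is straight
(`pi r^2 L` and shell analogues). For a bent centreline the rounded elbow
region has no elementary closed form, so the truth volumes are computed by
fine geometric quadrature (0.15 mm point sampling) of the same *continuous*
implicit solid — independent of the label grid, so it remains a valid
oracle for voxel-counting convergence tests. The quadrature agrees with the
closed forms to better than 0.5 % on straight phantoms, which is itself a
test in the suite.

The intensity renderer (`render_intensity()`) assigns per-label means that
respect the observed T2w contrast ordering, adds a smooth zero-mean
regional modulation inside the canal (the mixed high/low mucus signal), a
smooth multiplicative bias field (exponentiated random quadratic), and
Gaussian noise — all deterministic given a seed. With the modulation, bias
and noise disabled the render is exactly piecewise constant, which pins the
contract in tests. What the phantom does *not* emulate: partial-volume
intensity mixing at boundaries, anisotropic reconstruction artefacts,
funneling or post-surgical shapes, and surrounding anatomy beyond a
spherical bladder. Passing phantom tests therefore demonstrates correctness
of the *algorithms*, not clinical performance on real images.

# Biometry

The measurement protocol follows clinical convention:

1. **End interfaces.** The inlet and outlet regions are localised as
   interfaces between the canal (including cysts) and background. A strict
   voxel interface has two sides; `cervimetry` uses both: canal/cyst voxels
   with a face-adjacent background voxel *and* background voxels
   face-adjacent to canal/cyst. The one-sided variant would place all ROI
   voxel centres about half a voxel inside the end surface, biasing each
   end landmark inward by ~`spacing/2` and shortening the length
   systematically by roughly one voxel; the symmetric interface centres the
   ROI on the continuous surface. Face (6-)adjacency defines the
   interface; 26-connectivity groups it into components; the two largest
   components are the canal ends. If they nearly touch (closer than two
   voxels) the geometry is reported as ambiguous.
2. **Inlet/outlet disambiguation.** Which end is the internal os cannot be
   decided from a label map alone. The default rule calls the more
   superior end the inlet (the internal os lies toward the uterine cavity,
   superior in supine imaging); `inlet = "inferior"` or
   `inlet = "nearest-to"` with a point override it.
3. **Landmarks.** Inlet and outlet centres are arithmetic means of their
   ROI voxel centres; the midpoint is the mean world coordinate of the
   canal label (canal only, not cysts — the definitions are applied
   literally, and for a curved canal the midpoint deliberately lies off
   the canal axis).
4. **Length.** The two-line measurement:
   `|inlet - midpoint| + |midpoint - outlet|`.
5. **Diameters.** Measured at the inlet and outlet centre-point levels, in
   the plane through the three landmarks (for collinear landmarks the
   world sagittal plane is the fallback, matching the clinical convention).
   Rays march from the centre in 0.1 mm steps along
   `normalize(plane_normal x axis_direction)` in both directions, sampling
   labels nearest-neighbour, and stop at the first sample labelled inner
   stroma or background — the boundary is defined by the inner layer. The
   diameter is the distance between the two stop points.

Two numerical-robustness details matter at 0.8 mm resolution. First, the
voxelized end surface is a staircase with half-voxel amplitude; a ray
marching just inside a flat end would cross that staircase and stop far too
early (halving the measured diameter). A stop sample is therefore ignored
when shifting it half a voxel along the canal axis lands back inside
canal/cyst: the staircase is axial, whereas the boundary being measured is
radial. Second, the end-surface centroid itself lies *on* the surface, so
`run_biometry()` nudges the marching start point sub-voxel inward along the
canal axis (onto a canal voxel, plus half a voxel) before measuring.
`measure_diameter()` keeps its strict contract and errors when the given
centre is not inside canal or cyst.

On a seeded suite of 50 random phantoms (lengths 20–45 mm, radii 2–5 mm,
bend angles 120–180°, 0.8 mm spacing — the randomized-suite defaults), the
pipeline recovers length with a mean absolute error around 1 mm and
diameters around 0.5 mm; the acceptance script reproduces these numbers.
The residual length error is dominated by the midpoint definition itself:
the canal centroid of a strongly bent canal is pulled inside the bend, so
the two-line polyline through it is slightly shorter than the true
centreline — an inherent property of the published measurement definition,
not of this implementation.

# Volumetry

`compute_volumes()` counts voxels per label and multiplies by the physical
voxel volume `|det A|` of the affine — exact with respect to the labels and
matching the way volume differences are evaluated. Cyst volume is included
into the total canal volume (`canal_total_mm3`), and cysts are counted as
26-connected components. No smoothed surface integration is attempted.

# Evaluation metrics

Dice overlap (`2|A∩B| / (|A|+|B|)`, defined as 1 for two empty masks),
absolute and relative volume difference (referenced to the first argument,
the ground-truth/refined labels), and the intraclass correlation
coefficient. The ICC variant is not dictated by the evaluation setting, so
the package uses ICC(2,1) — two-way random effects, absolute agreement,
single measure — the standard choice for comparing automated against manual
raters. It is computed from the mean-squares decomposition and verified in
tests against the variance-components closed form
`sigma^2_case / (sigma^2_case + sigma^2_noise)` by simulation.

# Segmentation network

`train_segmentation()` implements the published recipe: a 3D UNet encoder–
decoder with 3×3×3 convolution and upsampling kernels, ReLU activations,
channelwise normalisation after every convolution, dropout 0.5 at the
bottleneck, batch size 1, combined soft-Dice + cross-entropy loss (equal
weights — the balance between the two terms is not specified, so the
simplest symmetric choice is used and is configurable), AdamW with default
betas, weight decay 1e-5 and a learning rate decaying linearly to zero at
the final iteration. Preprocessing resamples and zero-pads each image onto
an isotropic cube (aspect preserved) and rescales intensities to [0, 1];
the mapping is retained so predictions are projected back onto the input
grid. Augmentation applies random affine rotations (up to ±45°), a random
multiplicative bias field and random gamma contrast, each independently per
iteration; optional piecewise-linear quantile histogram matching to a
reference image is available.

The full-scale configuration — five levels with output channels
32/64/128/256/512 on a 128³ grid for 100 000 iterations at `lr_init` 1e-3 —
is constructible through `unet_config()` but is a GPU-scale workload. The
package's working configuration is a reduced-scale analog chosen for
single-CPU tractability: the same five-level architecture with the channel
widths scaled down eightfold (4/8/16/32/64) on a 64³ grid for 1000
iterations. Keeping the depth matters more than keeping the width here:
the endocervical canal shares its intensity range with background and is
recognisable only by its context inside the dark inner-stroma ring, and
that context is aggregated by the deep encoder levels — a shallower
reduction (three levels) fails to learn the canal at all within this
iteration budget, while narrower channels mostly cost accuracy, not
feasibility. A second scaling consequence deserves emphasis: Adam-family
optimisers move each parameter by at most about one learning rate per
step, so `lr_init * iterations` is the total distance the optimiser can
travel — about 100 in the full recipe, but only ~0.5 with `lr_init` 1e-3
at 1000 iterations, where training visibly stalls (cross-entropy pinned
near the class-prior entropy, no canal voxels ever predicted). The
reduced-scale runs therefore use `lr_init` 2e-2 (movement budget ~20,
still fivefold below the full recipe), at which the loss trajectory is
stable and converges within the budget; the configuration default remains
the full-scale 1e-3. Trained at this reduced scale on 20 rendered
phantoms, held-out canal and inner-stroma volumes agree with ground truth
within the published error budget (relative volume difference below 10 %),
which the acceptance script re-verifies end to end.

The network layers themselves (convolutions via shifted strided BLAS
accumulation in single precision, normalisation, pooling, nearest-neighbour
upsampling, loss and full backpropagation) are implemented in compiled code
inside the package; gradient correctness is established by finite-difference
checks and the parameter count is pinned against an independent hand count
in the test suite.

# Atlas construction

`build_atlas()` follows the groupwise template procedure: the initial
reference is the first image resampled to the target spacing (0.8 mm by
default); each of the (default 5) iterations registers every subject to the
current template — rigid, then affine initialised from the rigid result —
averages the warped images voxelwise, and applies Laplacian sharpening
(`out = img - alpha * L(img)` with the 6-neighbour Laplacian, clamped to
the input range). The sharpening amount is not specified anywhere
authoritative; the default is `alpha = 0.5` and it is exposed in
`atlas_config()`. Registration maximises normalised cross-correlation by
Nelder–Mead over a trilinear resampler at two resolutions; registration
engines are interchangeable in this procedure, and a non-rigid refinement
can be plugged in as a function (`nonrigid = function(template, warped)`),
disabled by default since free-form deformation is out of proportion for
the averaging/sharpening logic being exercised. With `alpha = 0`, the atlas
of N identical inputs reproduces the input (fixed point); known rigid
offsets are recovered within 0.5 mm and 1°.

# Normative charts

`fit_trend()` fits a least-squares polynomial of gestational age (degree 1
by default, degree 2 optional — the functional form behind published charts
is not stated, so the simplest is the default) and builds 5th/50th/95th
centile bands by offsetting the fitted curve by the empirical residual
quantiles. Constant offsets make the bands distribution-free and guarantee
centile monotonicity over the whole range. `export_charts()` writes one
scatter+trend+band figure per metric (points coloured by field strength)
and a CSV of centile curves sampled every 0.5 weeks. Cohort-level covariate
analysis (maternal age, BMI, ethnicity) is out of scope; the table schema
simply carries extra columns through.

# Worked example

```{r example, eval = FALSE}
spec <- phantom_spec(inlet_point = c(0, 0, 15), mid_point = c(0, 0, 0),
                     outlet_point = c(0, 0, -15), canal_radius = 3)
ph <- generate_phantom(spec)
ph$truth          # exact geometry: length 30 mm, diameters 6 mm
run_biometry(ph$labels)
compute_volumes(ph$labels)
```

# Numerical choices and degenerate inputs

* Ray marching step 0.1 mm with nearest-neighbour label sampling; errors
  are bounded by the voxel size, matching the measurement tolerance scale.
* Collinear landmarks: the best-fit plane is undefined; the world sagittal
  plane (left–right normal) is used, matching the clinical convention.
* A canal with no background contact (fully enclosed) has no end
  interfaces and is reported as such rather than guessed at.
* Degenerate all-equal ICC input returns 1 with a warning; a zero reference
  volume with non-zero prediction yields an undefined (NA) relative
  difference with a warning.
* Phantom rasterization tie-breaks and the suite generator are seeded and
  fully reproducible; rendering and training restore the caller's RNG
  state.

# Problem sizes used in the test suite

The suite exercises the same code paths as a full-scale analysis at sizes
chosen for quick, deterministic runs: 50-phantom biometry recovery at
0.8 mm spacing; volumetry oracles at 0.4 mm; segmentation at grid 64 with
20 training and 5 held-out rendered phantoms for 1000 iterations (the
longest single step, about ten minutes on one CPU); atlas experiments on
~50³ grids with one or two groupwise iterations; chart recovery on n = 200
synthetic tables. The full-scale configurations remain available through
the same interfaces.

# Known limitations

* The phantom's flat-capped two-segment geometry cannot represent
  funneling, mucus plugs of irregular shape, or post-surgical anatomy.
* The midpoint-centroid length definition slightly underestimates the true
  centreline length of strongly bent canals (see Biometry above); the
  effect is inherent to the published definition.
* The reduced-scale network is an analog, not a reproduction: no claim is
  made about performance on real 0.55T/3T images or about matching the
  originally trained weights.
* Rigid/affine registration assumes overlapping fields of view and a
  shared contrast; the non-rigid stage is intentionally pluggable rather
  than built in.
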