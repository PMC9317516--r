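---
title: "Measuring pedicle screw placement accuracy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pedicle screw placement accuracy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`spineacc` measures, in silico, how accurately pedicle screws were placed
relative to a surgical plan, and provides the statistics of a split-spine
non-inferiority trial comparing two navigation techniques (3D-printed
drill guides, "3DPG", versus computer-assisted surgery, "CAS"). This
vignette documents the models, the parameter defaults and their
rationale, the numerical choices, and what the synthetic data can and
cannot tell you about real patients.

## The measurement model

Every screw is summarized by two numbers against its plan:

* **Entry-point deviation** (mm): the Euclidean distance between the
  planned entry point and the realized entry point, both taken on the
  bone surface. The realized entry is the first intersection of the
  realized screw axis with the planning surface mesh. (An "in-plane"
  variant that projects the difference onto the local surface tangent
  plane is available via `measure_config(entry_method = "inplane")`;
  the 3D distance is the default because the realized axis is cast onto
  the same surface, which already removes the surface-normal component.)
* **3D angular deviation** (degrees): `acos` of the dot product between
  the planned and realized unit axes, with the realized axis flipped, if
  necessary, to point into the bone — fitted cylinder axes carry no
  intrinsic orientation, and without the flip a 5° error would
  occasionally be reported as 175°.

The realized axis is obtained in three steps, none of which involves a
human rater:

1. **Segmentation.** Voxels at or above a metal threshold (default
   2500 HU, far above cortical bone at ~1200 HU and far below titanium at
   ~3000 HU) inside a tubular region of interest around the expected screw
   position; the largest 6-connected component is kept, and a second
   component of comparable size raises an ambiguity warning.
2. **Registration.** The post-operative bone surface is registered to the
   planning surface per vertebra with rigid ICP (below), so deviations are
   computed in the planning frame. Patient repositioning between scans is
   thereby irrelevant by construction, and the package asserts this
   literally: composing an arbitrary extra rigid transform into the
   post-operative scene changes no estimate by more than 0.05 mm / 0.05°.
3. **Cylinder fit.** The screw axis is the axis of the cylinder
   minimizing the sum of squared radial residuals $\sum_i (d_i - r)^2$
   over the segmented voxel centres, where $d_i$ is the distance of point
   $i$ from the axis. The axis is initialized at the first principal axis
   through the centroid and refined with Levenberg–Marquardt
   (`minpack.lm`), the radius profiled out as the mean radial distance.
   Non-elongated clouds (longest principal extent < 3× the next) are
   rejected rather than fitted.

### Registration details

ICP alternates nearest-neighbour correspondence (a compiled kd-tree) with
the closed-form SVD (Kabsch) rigid update. Initialization aligns
centroids and principal axes, scoring the four proper-rotation sign
disambiguations by correspondence rms. Iterations stop when the rms
improves by less than 1e-4 mm (at most 100 iterations); the trimmed rms
sequence is non-increasing by construction and is asserted in the tests.

Two choices deviate from a textbook trimmed point-to-point ICP, and both
are deliberate:

* **Metal is masked by dilation, not trimmed.** Thresholding alone cannot
  remove an implant from an iso-surface: the partial-volume halo around
  the screw always crosses the bone iso-level somewhere, leaving a
  spurious tube of surface points. The pipeline therefore dilates the
  metal mask by 1.5 mm (≈ 5× the blur sigma) and replaces it with
  trabecular HU before extracting surfaces.
* **The pipeline registers untrimmed, with a point-to-plane polish.**
  With metal removed there are no gross outliers left, and on phantoms
  with large flat faces fixed-fraction trimming lets the solution slide
  tangentially (we observed errors up to 1.3 mm at trim 0.2 that vanish
  at trim 0). The final point-to-point solution is then polished by a few
  point-to-plane Gauss–Newton iterations using target normals from the
  volume gradient, which removes the small tangential bias of
  point-to-point matching between two independent samplings of the same
  surface. Residual registration error at 0.4 mm spacing is ≈ 0.12° /
  0.11 mm. `icp_register()` itself retains fixed-fraction trimming
  (default 0.2) for generic use on contaminated clouds.

## The synthetic-data generator

There is no public imaging for this problem — patient CTs stay in the
hospital — so the package ships a first-class generator whose defaults
*are* the study conditions of the simulated trial.

**Geometry.** A vertebra-like solid: a 36 × 22 × 22 mm box body, a 7 mm
radius posterior arch cylinder, and two 3.5 mm radius pedicle tubes along
the planned screw axes (3.5 mm diameter screws, 28 mm long, 10° medial
convergence, 5° cranial tilt). The cranial tilt and an off-centre arch
also break the 180° rotational symmetry a mirror-symmetric phantom would
have, keeping surface registration unambiguous. The phantom is a union of
signed-distance primitives; voxelization, surface meshing (marching
tetrahedra on the clean SDF) and ray-cast entry points all derive from
the same implicit solid, so generator ground truth and pipeline
measurements share one geometric definition.

**Imaging.** Isotropic 0.4 mm voxels; HU map soft 40 / trabecular 300 /
cortical 1200 / screw 3000 (air −1000); cortical shell 1.2 mm; Gaussian
blur sigma 0.3 mm as a partial-volume surrogate; additive Gaussian noise
20 HU. Bone surfaces are extracted at the soft/cortical midpoint
(620 HU), where the blurred step crosses exactly at the true surface for
a locally flat interface. The values are chosen to be threshold-separable
in the way clinical protocols assume; the geometry pipeline is
insensitive to their exact values.

**Surgical error model.** Per arm: the realized axis is the planned axis
shifted by an isotropic Gaussian entry offset (sd 1.5 mm per component)
and tilted about the planned entry by a half-normal angle
(|N(0, 8°)|) at a uniform azimuth. The entry is then snapped back to the
bone surface along the new axis, which makes the generator's entry
deviation definition identical to the pipeline's surface-based one (the
surface-normal component of the offset is absorbed; what remains is a 2D
tangential Rayleigh deviation). The defaults reproduce the deviation
magnitudes reported for guided cervical screw placement — median entry
deviation ≈ 1.8 mm and median angular deviation ≈ 5.4° — identically in
both arms (the trial this emulates found no difference between arms).
Draws that would push a screw outside the imaged volume are redrawn
(probability < 1%; the scan covers the instrumented anatomy in reality
too). The Gaussian/half-normal form is an assumption for testing: no
distributional model of real surgical error is implied.

**Pairing and repositioning.** Each patient receives one 3DPG and one CAS
screw per level; the 3DPG side is assigned by block-balanced
randomization (block size 2). The post-operative scene of every level is
voxelized under a hidden random rigid repositioning (≤ 15°, ≤ 10 mm) —
genuinely re-voxelized on a new grid, not just re-labelled — so
registration is tested against real resampling effects.

**What passing tests do not show.** The phantom is geometrically simple:
no anatomical shape variation, no metal streak artifacts, no deformation
between scans, no segmentation ambiguity from osteophytes or adjacent
instrumentation. Passing recovery tests demonstrates that the
*measurement chain* is unbiased and precise at clinical imaging scales;
it does not validate segmentation or registration robustness on real
pathological anatomy.

## Breach simulation

`max_rotation_to_breach()` finds, by bisection to 0.01° on [0°, 45°], the
largest tilt of a screw about its entry point (in a chosen azimuth plane)
for which the screw's lateral surface stays inside the pedicle tube; the
translation analogue uses bisection to 1e-6 mm. Containment samples the
screw surface on a 50 × 64 grid, giving < 0.05° discretization error at
clinical scales, and treats the tube ends as *open*: a screw legitimately
enters the pedicle at one end and exits into the vertebral body at the
other, so only the lateral wall can be breached. (The strict
closed-cylinder predicate is available as `cylinder_contains()`.)

`breach_margin()` summarizes a population of screw/pedicle pairs by each
pair's worst-case breach angle over an azimuth grid (24 azimuths by
default; a mean-over-azimuth policy is available) and returns the
(1 − coverage) empirical quantile — the rotation tolerated by the given
fraction of screws. Because the construction behind published pilot
values is not fully specified, a normal-theory mean + z·sd variant is
also exposed; the quantile is the default. Population geometry is
parametric (pedicle radii Gaussian 3.5 ± 0.5 mm truncated above the screw
radius), standing in for patient-derived pedicle models.

For the coaxial reference case (1.75 mm screw in a 3.5 mm pedicle, 30 mm
long, pivot at the tube entrance) the breach angle is 3.35°, close to the
thin-screw slab estimate asin((R − r)/L) — and to the ~3° angular margins
such pilots have been used to justify.

## Trial statistics

The primary analysis treats level-paired differences (3DPG − CAS) with a
one-sample t confidence interval; non-inferiority is declared when the
upper bound of the two-sided 95% CI stays below the margin (1 mm entry,
3° angle). This CI rule is equivalent to a one-sided t-test at α = 0.025,
and both the decision and the one-sided p-value are reported. The paired
analysis matches the split-spine design; screws could also be treated as
independent by passing pooled per-arm values directly to
`noninferiority_test()`. Within-patient clustering across levels is
deliberately not modelled.

`sample_size_noninferiority()` starts from the normal approximation
$n_0 = ((z_{1-\alpha} + z_{\beta})\,\sigma / (\Delta - \mu))^2$ and
iterates on the noncentral t distribution; at σ = 1, Δ − μ = 0.5,
one-sided α = 0.05 and 90% power it returns the classic n = 36.
`power_by_simulation()` is the Monte-Carlo cross-check, and the type-I
error at μ = Δ is asserted to equal α within binomial error in the tests.

## Numerical choices and problem sizes

* Bisection tolerances: 0.01° (rotation), 1e-6 mm (translation); ICP rms
  tolerance 1e-4 mm; cylinder-fit convergence by Levenberg–Marquardt
  defaults (200 iterations max).
* Degenerate inputs error early with typed conditions
  (`spineaccDegenerateInput`, `spineaccMissingScrew`, ...): collinear
  point sets, spheres passed to the cylinder fitter, empty segmentations,
  screws outside the volume, odd randomization blocks.
* Ties and orientation: fitted axes are disambiguated against the planned
  direction; PCA eigenbases are forced to proper rotations; the
  deterministic frame used for azimuths is fixed by the smallest
  direction component.
* The test suite exercises the full study conditions (10 patients ×
  3 levels, 60 screws, 0.4 mm spacing) once, in the end-to-end recovery
  test; routine tests run a coarser 0.6–0.8 mm phantom to stay fast.
  `scripts/acceptance.R` runs the same 10 × 3 trial at 0.4 mm for its
  trial section, 1000 pairs for the breach margin, and 10⁴ replicates for
  the calibration checks.

## Known limitations

* Point-to-point/point-to-plane ICP on clean phantom surfaces does not
  establish robustness to real segmentation noise, metal artifacts, or
  partial overlap beyond the simulated repositioning range.
* The cylinder fit assumes the screw is well modelled by one cylinder;
  polyaxial heads or severely bent screws would need a two-segment model.
* Entry deviation depends on the surface mesh near the entry; on very
  coarse meshes the ray-cast entry inherits the chord error.
* The breach model is a straight elliptic tube without cortical
  thickness; real pedicle walls curve and vary in strength.
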