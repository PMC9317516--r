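# spineacc

3D accuracy measurement and non-inferiority analysis for pedicle screw
placement.

## The problem

Randomized trials comparing spinal navigation techniques — for example
patient-specific 3D-printed drill guides (3DPG) against computer-assisted
surgery (CAS) — need an observer-independent way to measure how far each
implanted screw ended up from its plan, and a statistical framework to
decide whether one technique is *non-inferior* to the other. `spineacc`
implements that whole chain for in-silico studies:

1. **Synthetic split-spine data.** A parametric vertebra-like phantom
   (box body, posterior arch, two pedicle tubes) is voxelized into CT-like
   volumes with distinct Hounsfield signatures for soft tissue, trabecular
   and cortical bone, and titanium, including partial-volume blur and
   noise. Screws are planted at known deviations from the plan — an
   isotropic Gaussian entry offset plus a half-normal tilt about the entry
   point — with one 3DPG and one CAS screw per vertebral level, the sides
   assigned by block-balanced randomization.
2. **Measurement.** Per vertebra, the post-operative scan is registered to
   the planning scan with trimmed iterative-closest-point (ICP) rigid
   registration of bone surfaces (metal masked out), each screw is
   segmented by Hounsfield threshold, an analytic cylinder is fitted to
   the screw voxels by least squares, and two metrics are reported per
   screw: the **entry-point deviation** (mm, distance between the planned
   and realized entry on the bone surface) and the **3D angular
   deviation** (degrees, angle between the planned and realized axes).
3. **Breach simulation.** For a screw inside a (circular or elliptic)
   pedicle tube, the largest rotation about the entry point — and the
   largest lateral translation — before the screw surface breaches the
   pedicle wall, and population coverage margins (e.g. the rotation
   tolerated by 99% of screws), used to justify non-inferiority margins.
4. **Trial statistics.** Level-paired differences (3DPG − CAS), a
   one-sample t confidence interval, and the CI-crossing rule: the test
   technique is non-inferior when the upper bound of the 95% CI for the
   mean difference stays below the margin Δ (1 mm for entry, 3° for
   angle). Sample-size iteration on the noncentral t distribution and
   Monte-Carlo power checks are included.

## Worked example

```r
library(spineacc)

# a 2-patient, 1-level trial at 0.4 mm voxel spacing
ds  <- generate_dataset(phantom_spec(), deviation_model(),
                        n_patients = 2, n_levels = 1, seed = 11)
rec <- run_pipeline(ds)
rec[, c("screw_id", "arm", "entry_mm", "angle_deg")]
#>       screw_id  arm entry_mm angle_deg
#> 1  P01_L1_left  CAS 2.281190  4.297896
#> 2 P01_L1_right 3DPG 2.323126  3.147649
#> 3  P02_L1_left 3DPG 2.459332  2.393239
#> 4 P02_L1_right  CAS 1.138893  4.113965
```

Each row is one screw: the pipeline segmented it from the post-operative
volume, registered that volume back to the plan, fitted a cylinder to the
metal voxels, and measured its entry-point (mm) and angular (degrees)
deviation from the planned trajectory. Against the hidden ground truth of
this dataset the absolute measurement errors are about 0.06 mm and 0.2°
on average — far below the deviations being measured.

A full in-silico trial with the non-inferiority analysis:

```r
cfg <- run_config(n_patients = 10, n_levels = 3, seed = 1)
rep <- run_end_to_end(cfg, out_dir = "run1")   # writes CSV/JSON outputs
rep$analysis
```

The breach pilot that motivates a 3° angular margin:

```r
scr <- trajectory(c(0, 0, 0), c(0, 0, 1), length = 30, radius = 1.75)
ped <- pedicle_model(trajectory(c(0, 0, 0), c(0, 0, 1), 30, 3.5), radius = 3.5)
max_rotation_to_breach(scr, ped)     # 3.35 degrees for the coaxial reference
pop <- simulate_breach_population(1000, seed = 1)
breach_margin(pop, coverage = 0.99)  # rotation tolerated by 99% of screws
```

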