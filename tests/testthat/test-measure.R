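# Measurement stages: segmentation, ICP registration, cylinder fitting,
# and deviation computation against planted ground truth.

test_that("screw segmentation recovers the planted cylinder geometry", {
  aff <- diag(4); aff[1:3, 1:3] <- 0.4 * diag(3); aff[1:3, 4] <- c(-12, -12, -4)
  vol <- ct_volume(array(300, c(60, 60, 100)), aff)
  tr <- trajectory(c(0, 0, 0), c(0, 0, 1), length = 30, radius = 1.75)
  vol <- plant_screw(vol, tr, 3000)
  pts <- segment_screw_voxels(vol, 2500, roi = tr, margin = 5)
  # all returned voxels lie inside the 1-voxel-dilated analytic cylinder
  w <- sweep(pts, 2, tr$entry)
  s <- as.vector(w %*% tr$direction)
  rad <- sqrt(pmax(rowSums(w^2) - s^2, 0))
  pad <- 0.4 * sqrt(3)
  expect_true(all(rad <= 1.75 + pad & s >= -pad & s <= 30 + pad))
  # centroid near the analytic cylinder midpoint
  expect_lt(spineacc:::vnorm(colMeans(pts) - (tr$entry + 15 * tr$direction)), 0.4)
  # threshold above the implant HU: missing screw
  expect_error(segment_screw_voxels(vol, 3500, roi = tr),
               class = "spineaccMissingScrew")
  # two similar components trigger the ambiguity warning
  vol2 <- plant_screw(vol, trajectory(c(8, 8, 0), c(0, 0, 1), 30, 1.75), 3000)
  expect_warning(segment_screw_voxels(vol2, 2500, roi = tr, margin = 12),
                 "ambiguous")
})

test_that("ICP recovers a planted transform and reports a monotone objective", {
  ph <- build_phantom(coarse_spec(), imaging = FALSE)
  pts <- extract_surface_points(ph$volume, 620)
  set.seed(21)
  tr <- rt_from_axis_angle(rnorm(3), 15, center = colMeans(pts), translation = c(5, -4, 3))
  reg <- icp_register(apply_transform(tr, pts), pts)
  e <- rt_compose(reg$transform, tr)
  expect_lt(rt_angle(e), 0.1)
  expect_lt(spineacc:::vnorm(e$translation), 0.1)
  expect_true(all(diff(reg$rms_history) <= 1e-12))
  expect_lt(reg$rms, 0.05)
  # already-aligned source converges immediately to the identity
  reg0 <- icp_register(pts, pts, init = rt_identity())
  expect_lt(rt_angle(reg0$transform), 1e-4)
  expect_lt(spineacc:::vnorm(reg0$transform$translation), 1e-4)
  expect_lte(reg0$iterations, 2)
})

test_that("trimmed ICP tolerates gross outliers", {
  ph <- build_phantom(coarse_spec(), imaging = FALSE)
  pts <- extract_surface_points(ph$volume, 620)
  pts <- pts[seq(1, nrow(pts), 4), ]
  set.seed(22)
  tr <- rt_from_axis_angle(rnorm(3), 12, center = colMeans(pts), translation = c(6, 2, -4))
  src <- apply_transform(tr, pts)
  n_out <- round(0.2 * nrow(src))
  idx <- sample(nrow(src), n_out)
  src[idx, ] <- matrix(runif(3 * n_out, -60, 60), n_out, 3)
  reg <- icp_register(src, pts, trim_fraction = 0.3)
  e <- rt_compose(reg$transform, tr)
  expect_lt(rt_angle(e), 0.5)
  expect_lt(spineacc:::vnorm(e$translation), 0.5)
})

test_that("ICP rejects degenerate input", {
  line <- cbind(seq(0, 1, length.out = 50), 0, 0)
  expect_error(icp_register(line, line), class = "spineaccDegenerateInput")
  expect_error(icp_register(matrix(rnorm(6), 2, 3), matrix(rnorm(30), 10, 3)),
               class = "spineaccDegenerateInput")
})

test_that("cylinder fits are exact on noiseless lattices and stable under noise", {
  d <- c(0.25, 0.3, 0.92)
  P <- cylinder_lattice(c(5, -3, 2), d, 30, 1.75)
  f <- fit_cylinder(P)
  expect_lt(axis_angle(f$axis_direction, d), 0.01)
  expect_lt(abs(f$radius - 1.75), 1e-3)
  expect_lt(f$rms_radial_residual, 1e-6)
  # Monte-Carlo: sd 0.2 mm point noise
  set.seed(31)
  worst_ang <- 0; worst_rad <- 0
  for (i in 1:100) {
    dd <- rnorm(3); dd <- dd / spineacc:::vnorm(dd)
    Pn <- cylinder_lattice(rnorm(3, 0, 5), dd, 30, 1.75, jitter_sd = 0.2)
    fn <- fit_cylinder(Pn)
    worst_ang <- max(worst_ang, axis_angle(fn$axis_direction, dd))
    worst_rad <- max(worst_rad, abs(fn$radius - 1.75))
  }
  expect_lt(worst_ang, 0.3)
  expect_lt(worst_rad, 0.05)
})

test_that("cylinder fitting refuses spheres and tiny clouds", {
  set.seed(32)
  sph <- matrix(rnorm(3000), ncol = 3)
  sph <- sph / spineacc:::row_norms(sph) * 5
  expect_error(fit_cylinder(sph), class = "spineaccDegenerateInput")
  expect_error(fit_cylinder(matrix(rnorm(30), 10, 3)), class = "spineaccDegenerateInput")
})

test_that("pipeline recovers planted entry offsets and tilts at full resolution", {
  spec <- phantom_spec()  # 0.4 mm study conditions
  # arm-specific deterministic deviations: 3DPG gets a 2 mm lateral entry
  # offset, CAS gets a pure 5.7 degree tilt
  dm <- deviation_model(entry_sd = 0, angle_sd = 0,
                        entry_bias = rbind(c(2, 0, 0), c(0, 0, 0)),
                        angle_bias = c(0, 5.7))
  ds <- generate_dataset(spec, dm, n_patients = 1, n_levels = 1, seed = 61)
  rec <- run_pipeline(ds)
  expect_true(all(rec$flag == ""))
  off <- rec[rec$arm == "3DPG", ]
  tlt <- rec[rec$arm == "CAS", ]
  expect_equal(off$entry_mm, 2, tolerance = 0.3 / 2)   # absolute 0.3 mm on a 2 mm truth
  expect_lt(off$angle_deg, 0.3)
  expect_equal(tlt$angle_deg, 5.7, tolerance = 0.3 / 5.7)
  expect_lt(tlt$entry_mm, 0.3)
  # and the unperturbed case collapses to the discretization floor
  ds0 <- generate_dataset(spec, deviation_model(0, 0), n_patients = 1,
                          n_levels = 1, seed = 62)
  rec0 <- run_pipeline(ds0)
  expect_true(all(rec0$entry_mm <= 0.3))
  expect_true(all(rec0$angle_deg <= 0.3))
})

test_that("a deleted screw is flagged missing and the rest of the level survives", {
  ds <- small_dataset()
  ds$levels <- ds$levels[1]
  lev <- ds$levels[[1]]
  # erase the left screw's metal from the post-op volume
  planted <- transform_trajectory(lev$hidden, lev$screws$left$actual)
  v <- lev$postop$voxels
  idx <- which(v >= 2000)
  ctr <- voxel_to_world(lev$postop, arrayInd(idx, dim(v)))
  w <- sweep(ctr, 2, planted$entry)
  s <- as.vector(w %*% planted$direction)
  rad2 <- rowSums(w^2) - s^2
  kill <- idx[s > -3 & s < planted$length + 3 & rad2 < (planted$radius + 2)^2]
  v[kill] <- 300
  ds$levels[[1]]$postop <- ct_volume(v, lev$postop$affine)
  rec <- run_pipeline(ds)
  expect_equal(rec$flag[rec$side == "left"], "missing_screw")
  expect_true(is.na(rec$entry_mm[rec$side == "left"]))
  expect_equal(rec$flag[rec$side == "right"], "")
  expect_false(is.na(rec$entry_mm[rec$side == "right"]))
})
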