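# Synthetic-data generator: voxelization, HU signatures, screw planting,
# split-spine dataset structure and its deviation distributions.

test_that("clean voxelization puts the right HU in the right places", {
  spec <- coarse_spec()
  lab <- spineacc:::voxelize_phantom(spec)
  # phantom center of the body box is trabecular, far corner is soft
  ijk_body <- round(world_to_voxel(lab, spec$body_center))
  expect_identical(lab$voxels[ijk_body[1], ijk_body[2], ijk_body[3]],
                   spec$hu[["trabecular"]])
  expect_identical(lab$voxels[2, 2, 2], spec$hu[["soft"]])
  # a point just inside the body wall is cortical
  wall <- spec$body_center + c(spec$body_size[1] / 2 - spec$cortical_thickness / 2, 0, 0)
  ijk_wall <- round(world_to_voxel(lab, wall))
  expect_identical(lab$voxels[ijk_wall[1], ijk_wall[2], ijk_wall[3]],
                   spec$hu[["cortical"]])
  expect_error(phantom_spec(spacing = 1, cortical_thickness = 1.2), "too coarse")
  expect_error(phantom_spec(pedicle_radius = 1.5, screw_radius = 1.75), "exceed")
})

test_that("compiled SDF grid agrees with the reference signed distance", {
  spec <- coarse_spec()
  lab <- spineacc:::voxelize_phantom(spec)
  set.seed(12)
  pts <- cbind(runif(500, -25, 25), runif(500, -30, 28), runif(500, -18, 18))
  s_ref <- phantom_sdf(spec, pts)
  ijk <- world_to_voxel(lab, pts)
  inside_lab <- lab$voxels[round(ijk)] != spec$hu[["soft"]]
  # where the reference SDF is decisive (> half voxel from the surface),
  # the voxelized labels must agree
  sure <- abs(s_ref) > spec$spacing
  expect_true(all((s_ref[sure] < 0) == inside_lab[sure]))
})

test_that("segmented bone volume matches a fine-grid integral of the solid", {
  spec <- coarse_spec(spacing = 0.5, blur_sigma = 0, noise_sd = 0)
  lab <- spineacc:::voxelize_phantom(spec)
  vox_volume <- sum(lab$voxels >= spec$hu[["trabecular"]]) * spec$spacing^3
  # independent reference: R signed-distance field on a shifted fine grid
  h <- 0.25
  b <- spineacc:::phantom_bounds(spec)
  xs <- seq(b[1, 1] - 1, b[2, 1] + 1, by = h)
  ys <- seq(b[1, 2] - 1, b[2, 2] + 1, by = h)
  zs <- seq(b[1, 3] - 1, b[2, 3] + 1, by = h)
  count <- 0
  for (z in zs) {
    g <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)), z)
    count <- count + sum(phantom_sdf(spec, g) <= 0)
  }
  ref_volume <- count * h^3
  expect_lt(abs(vox_volume - ref_volume) / ref_volume, 0.02)
})

test_that("plant_screw fills the analytic cylinder and nothing else", {
  aff <- diag(4); aff[1:3, 1:3] <- 0.4 * diag(3); aff[1:3, 4] <- c(-12, -12, -4)
  vol <- ct_volume(array(40, c(60, 60, 100)), aff)
  tr <- trajectory(c(0, 0, 0), c(0.1, 0.1, 0.99), length = 30, radius = 1.75)
  out <- plant_screw(vol, tr, 3000)
  n_set <- sum(out$voxels == 3000)
  expect_lt(abs(n_set - pi * 1.75^2 * 30 / 0.4^3) / (pi * 1.75^2 * 30 / 0.4^3), 0.05)
  # idempotent
  out2 <- plant_screw(out, tr, 3000)
  expect_identical(out2$voxels, out$voxels)
  # every modified voxel lies inside the 1-voxel-dilated analytic cylinder
  idx <- which(out$voxels != 40)
  ctr <- voxel_to_world(out, arrayInd(idx, dim(out$voxels)))
  w <- sweep(ctr, 2, tr$entry)
  s <- as.vector(w %*% tr$direction)
  rad <- sqrt(pmax(rowSums(w^2) - s^2, 0))
  pad <- 0.4 * sqrt(3)
  expect_true(all(rad <= 1.75 + pad & s >= -pad & s <= 30 + pad))
  # out-of-bounds screw errors
  expect_error(plant_screw(vol, trajectory(c(11, 0, 0), c(0, 0, 1), 50, 1.75), 3000),
               "outside")
})

test_that("dataset generation is deterministic and structurally balanced", {
  spec <- coarse_spec()
  d1 <- generate_dataset(spec, deviation_model(), n_patients = 4, n_levels = 2,
                         seed = 33, voxelize = FALSE)
  d2 <- generate_dataset(spec, deviation_model(), n_patients = 4, n_levels = 2,
                         seed = 33, voxelize = FALSE)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(spec, deviation_model(), n_patients = 4, n_levels = 2,
                         seed = 34, voxelize = FALSE)
  expect_false(identical(d1$truth, d3$truth))
  # one 3DPG and one CAS per level, and a patient's sides are consistent
  tab <- table(d1$truth$patient, d1$truth$level, d1$truth$arm)
  expect_true(all(tab == 1))
  # self-consistency: stored angular truth equals the angle of the stored axes
  for (lev in d1$levels) {
    for (side in c("left", "right")) {
      row <- d1$truth[d1$truth$patient == lev$patient & d1$truth$level == lev$level &
                        d1$truth$side == side, ]
      expect_equal(row$angle_deg,
                   angle_between(d1$planned[[side]]$direction,
                                 lev$screws[[side]]$actual$direction),
                   tolerance = 1e-9)
    }
  }
})

test_that("an all-zero deviation model reproduces the plan exactly", {
  ds <- generate_dataset(coarse_spec(), deviation_model(0, 0), n_patients = 2,
                         n_levels = 1, seed = 5, voxelize = FALSE)
  expect_true(all(ds$truth$angle_deg < 1e-9))
  expect_true(all(ds$truth$entry_mm < 1e-6))
})

test_that("generated angular deviations follow the half-normal model", {
  sd_ang <- 5
  ds <- generate_dataset(coarse_spec(), deviation_model(entry_sd = 1, angle_sd = sd_ang),
                         n_patients = 500, n_levels = 1, seed = 77, voxelize = FALSE)
  ang <- ds$truth$angle_deg
  expect_equal(length(ang), 1000)
  hn_mean <- sd_ang * sqrt(2 / pi)
  hn_sd <- sd_ang * sqrt(1 - 2 / pi)
  expect_lt(abs(mean(ang) - hn_mean), 3 * hn_sd / sqrt(length(ang)))
})

test_that("iso-surface position error shrinks roughly linearly with spacing", {
  err_at <- function(spacing) {
    # trabecular raised above the iso level so the only crossing of the
    # soft/cortical midpoint is the outer bone surface
    spec <- coarse_spec(spacing = spacing, noise_sd = 0,
                        hu = c(air = -1000, soft = 40, trabecular = 800,
                               cortical = 1200, screw = 3000))
    lab <- spineacc:::voxelize_phantom(spec)
    vol <- apply_imaging(lab, spec$blur_sigma, 0)
    pts <- extract_surface_points(vol, (spec$hu[["soft"]] + spec$hu[["cortical"]]) / 2)
    pts <- pts[seq(1, nrow(pts), by = 7), , drop = FALSE]
    mean(abs(phantom_sdf(spec, pts)))
  }
  e_coarse <- err_at(1.0)
  e_fine <- err_at(0.5)
  expect_lt(e_fine, e_coarse / 1.3)
  expect_lt(e_fine, 0.2)  # sub-voxel at 0.5 mm
})

test_that("marching tetrahedra meshes are watertight and metrically accurate", {
  # sphere signed-distance field, radius 8, grid 0.5 mm
  dims <- c(40, 40, 40)
  aff <- diag(4); aff[1:3, 1:3] <- 0.5 * diag(3); aff[1:3, 4] <- c(-9.75, -9.75, -9.75)
  g <- spineacc:::voxel_center_grid(dims, aff)
  s <- sqrt(rowSums(g^2)) - 8
  mesh <- extract_surface_mesh(ct_volume(array(s, dims), aff), 0,
                               positive_inside = FALSE, weld = TRUE)
  expect_equal(mesh_area(mesh), 4 * pi * 64, tolerance = 0.01)
  # watertight: every undirected edge is shared by exactly two faces
  ed <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)], mesh$faces[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  expect_true(all(table(key) == 2))
  # normals point outward
  ctr <- (mesh$vertices[mesh$faces[, 1], ] + mesh$vertices[mesh$faces[, 2], ] +
            mesh$vertices[mesh$faces[, 3], ]) / 3
  e1 <- mesh$vertices[mesh$faces[, 2], ] - mesh$vertices[mesh$faces[, 1], ]
  e2 <- mesh$vertices[mesh$faces[, 3], ] - mesh$vertices[mesh$faces[, 1], ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  expect_true(all(rowSums(nrm * ctr) > 0))
})
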