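# Synthetic split-spine data: parametric vertebra-like phantoms, CT
# voxelization with Hounsfield signatures, screw planting at controlled
# deviations, and paired left/right datasets with known ground truth.
#
# The phantom is a solid union of three primitives: a box vertebral body,
# a horizontal cylinder standing in for the posterior arch, and two
# oblique pedicle tubes bridging them, one per side. Screws run from the
# posterior arch surface through the pedicle into the body, converging
# medially with a slight cranial tilt (the tilt also removes the 180-degree
# rotational symmetry a purely mirror-symmetric phantom would have, which
# keeps surface registration unambiguous).

#' Parametric vertebra-like phantom specification
#'
#' Defines the solid geometry, the Hounsfield signature of each tissue
#' class, and the imaging model (voxel spacing, partial-volume blur,
#' additive noise). All lengths in mm, all intensities in HU.
#'
#' @param body_size,body_center Box vertebral body edge lengths and centre.
#' @param arch_radius,arch_halflength,arch_center Posterior-arch cylinder
#'   (axis along x).
#' @param pedicle_radius,pedicle_halflength Pedicle tube radius and axial
#'   half-length; the tube is centred on the planned screw axis.
#' @param screw_radius,screw_length Screw cylinder dimensions.
#' @param lateral_offset Distance of each pedicle axis from the midline.
#' @param convergence_deg Medial convergence of the screw axes.
#' @param cranial_tilt_deg Cranial tilt of the screw axes.
#' @param hu Named HU map: `air`, `soft`, `trabecular`, `cortical`, `screw`.
#' @param cortical_thickness Cortical shell thickness; must be resolved by
#'   at least 2 voxels.
#' @param spacing Isotropic voxel size.
#' @param blur_sigma Gaussian blur sigma (mm), a partial-volume surrogate.
#' @param noise_sd Additive Gaussian noise (HU).
#' @param margin Padding between the bone and the volume border.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_size = c(36, 22, 22),
                         body_center = c(0, 10, 0),
                         arch_radius = 7,
                         arch_halflength = 16,
                         arch_center = c(0, -16, 1.5),
                         pedicle_radius = 3.5,
                         pedicle_halflength = 14,
                         screw_radius = 1.75,
                         screw_length = 28,
                         lateral_offset = 9,
                         convergence_deg = 10,
                         cranial_tilt_deg = 5,
                         hu = c(air = -1000, soft = 40, trabecular = 300,
                                cortical = 1200, screw = 3000),
                         cortical_thickness = 1.2,
                         spacing = 0.4,
                         blur_sigma = 0.3,
                         noise_sd = 20,
                         margin = 8) {
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (blur_sigma < 0) stop("blur_sigma must be non-negative", call. = FALSE)
  if (cortical_thickness < 2 * spacing)
    stop("spacing too coarse to resolve the cortical shell (need >= 2 voxels)",
         call. = FALSE)
  if (pedicle_radius <= screw_radius)
    stop("pedicle radius must exceed the screw radius", call. = FALSE)
  need <- c("air", "soft", "trabecular", "cortical", "screw")
  if (!all(need %in% names(hu)))
    stop("hu map must name: ", paste(need, collapse = ", "), call. = FALSE)
  structure(list(body_size = body_size, body_center = body_center,
                 arch_radius = arch_radius, arch_halflength = arch_halflength,
                 arch_center = arch_center, pedicle_radius = pedicle_radius,
                 pedicle_halflength = pedicle_halflength,
                 screw_radius = screw_radius, screw_length = screw_length,
                 lateral_offset = lateral_offset,
                 convergence_deg = convergence_deg,
                 cranial_tilt_deg = cranial_tilt_deg,
                 hu = hu, cortical_thickness = cortical_thickness,
                 spacing = spacing, blur_sigma = blur_sigma,
                 noise_sd = noise_sd, margin = margin),
            class = "phantom_spec")
}

# signed distance to an axis-aligned box (negative inside)
sdf_box <- function(pts, center, size) {
  q <- abs(sweep(pts, 2L, center)) - matrix(size / 2, nrow(pts), 3L, byrow = TRUE)
  qp <- pmax(q, 0)
  outside <- sqrt(rowSums(qp * qp))
  inside <- pmin(pmax(q[, 1], pmax(q[, 2], q[, 3])), 0)
  outside + inside
}

# signed distance to a finite (capped) cylinder
sdf_capped_cylinder <- function(pts, center, direction, halflength, radius) {
  d <- unit(direction)
  w <- sweep(pts, 2L, center)
  s <- as.vector(w %*% d)
  rad <- sqrt(pmax(rowSums(w * w) - s * s, 0))
  dr <- rad - radius
  dz <- abs(s) - halflength
  inside <- pmin(pmax(dr, dz), 0)
  outside <- sqrt(pmax(dr, 0)^2 + pmax(dz, 0)^2)
  inside + outside
}

# planned screw axes in the phantom frame; side "left" is +x.
# Returned trajectories have a provisional entry on the axis, well
# posterior of the bone; generate_dataset() snaps entries to the surface.
phantom_axes <- function(spec) {
  out <- list()
  for (side in c("left", "right")) {
    s <- if (side == "left") 1 else -1
    cv <- spec$convergence_deg * pi / 180
    tl <- spec$cranial_tilt_deg * pi / 180
    d <- unit(c(-s * sin(cv), cos(cv), sin(tl)))
    anchor <- c(s * spec$lateral_offset, -10, spec$arch_center[3])
    out[[side]] <- trajectory(anchor - 20 * d, d,
                              length = spec$screw_length,
                              radius = spec$screw_radius,
                              id = side)
  }
  out
}

# primitive parameter matrices for the compiled grid evaluator
phantom_primitives <- function(spec) {
  boxes <- matrix(c(spec$body_center, spec$body_size), 1L)
  cyls <- rbind(c(spec$arch_center, 1, 0, 0, spec$arch_halflength, spec$arch_radius))
  for (ax in phantom_axes(spec)) {
    center <- ax$entry + 20 * ax$direction
    cyls <- rbind(cyls, c(center, ax$direction, spec$pedicle_halflength,
                          spec$pedicle_radius))
  }
  list(boxes = boxes, cyls = cyls)
}

# compiled SDF over a voxel grid; transform maps phantom frame -> world
sdf_on_grid <- function(spec, dims, affine, transform = rt_identity()) {
  Tinv <- rt_invert(transform)
  M <- rbind(cbind(Tinv$rotation, Tinv$translation), c(0, 0, 0, 1)) %*% affine
  prim <- phantom_primitives(spec)
  sdf_grid(as.integer(dims), M[1:3, , drop = FALSE], prim$boxes, prim$cyls)
}

#' Signed distance from points to the phantom solid
#'
#' Negative inside the bone, positive outside; the union of the body box,
#' arch cylinder, and the two pedicle tubes.
#'
#' @param spec A `phantom_spec`.
#' @param pts n x 3 matrix of points (phantom frame, mm).
#' @return Numeric vector of signed distances (mm).
#' @export
phantom_sdf <- function(spec, pts) {
  pts <- as_point_matrix(pts)
  s <- sdf_box(pts, spec$body_center, spec$body_size)
  s <- pmin(s, sdf_capped_cylinder(pts, spec$arch_center, c(1, 0, 0),
                                   spec$arch_halflength, spec$arch_radius))
  for (ax in phantom_axes(spec)) {
    center <- ax$entry + 20 * ax$direction   # the anchor on the axis
    s <- pmin(s, sdf_capped_cylinder(pts, center, ax$direction,
                                     spec$pedicle_halflength, spec$pedicle_radius))
  }
  s
}

# axis-aligned bounds of the solid in the phantom frame (2 x 3 matrix)
phantom_bounds <- function(spec) {
  lo <- pmin(spec$body_center - spec$body_size / 2,
             spec$arch_center - c(spec$arch_halflength, spec$arch_radius, spec$arch_radius))
  hi <- pmax(spec$body_center + spec$body_size / 2,
             spec$arch_center + c(spec$arch_halflength, spec$arch_radius, spec$arch_radius))
  for (ax in phantom_axes(spec)) {
    center <- ax$entry + 20 * ax$direction
    ext <- abs(ax$direction) * spec$pedicle_halflength + spec$pedicle_radius
    lo <- pmin(lo, center - ext)
    hi <- pmax(hi, center + ext)
  }
  rbind(lo, hi)
}

# Voxelize the phantom (optionally under a rigid repositioning of the
# anatomy) into a clean tissue-label HU volume on an axis-aligned world
# grid covering the moved bone plus the spec margin.
voxelize_phantom <- function(spec, transform = rt_identity()) {
  b <- phantom_bounds(spec)
  corners <- as.matrix(expand.grid(b[, 1], b[, 2], b[, 3]))
  wc <- apply_transform(transform, corners)
  lo <- apply(wc, 2L, min) - spec$margin
  hi <- apply(wc, 2L, max) + spec$margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spec$spacing)) + 1L)
  affine <- diag(4)
  affine[1:3, 1:3] <- diag(rep(spec$spacing, 3))
  affine[1:3, 4] <- lo
  s <- sdf_on_grid(spec, dims, affine, transform)
  v <- rep(spec$hu[["soft"]], length(s))
  v[s <= 0] <- spec$hu[["cortical"]]
  v[s <= -spec$cortical_thickness] <- spec$hu[["trabecular"]]
  ct_volume(array(v, dims), affine)
}

#' Build a phantom: surface mesh plus CT volume
#'
#' Voxelizes the phantom solid into a tissue-label volume (cortical shell,
#' trabecular interior, soft-tissue background), applies the imaging model
#' (Gaussian blur as a partial-volume surrogate, additive HU noise), and
#' extracts the watertight outer bone surface from the clean signed
#' distance field.
#'
#' @param spec A `phantom_spec`.
#' @param imaging Apply blur and noise (default `TRUE`); if `FALSE` the
#'   returned volume holds the clean tissue labels.
#' @param seed Optional seed for the noise draw.
#' @return A list with elements `mesh` (`surface_mesh`), `volume`
#'   (`ct_volume`), and `planned` (left/right planned `trajectory`s with
#'   entries snapped to the surface).
#' @export
build_phantom <- function(spec, imaging = TRUE, seed = NULL) {
  labels <- voxelize_phantom(spec)
  mesh <- phantom_mesh(spec)
  planned <- snap_axes_to_surface(phantom_axes(spec), mesh)
  vol <- if (imaging) apply_imaging(labels, spec$blur_sigma, spec$noise_sd, seed = seed)
         else labels
  list(mesh = mesh, volume = vol, planned = planned)
}

# watertight outer-surface mesh from the clean signed distance field
phantom_mesh <- function(spec) {
  b <- phantom_bounds(spec)
  lo <- b[1, ] - 2 * spec$spacing
  hi <- b[2, ] + 2 * spec$spacing
  dims <- as.integer(ceiling((hi - lo) / spec$spacing)) + 1L
  affine <- diag(4)
  affine[1:3, 1:3] <- diag(rep(spec$spacing, 3))
  affine[1:3, 4] <- lo
  s <- sdf_on_grid(spec, dims, affine)
  extract_surface_mesh(ct_volume(array(s, dims), affine), iso = 0,
                       positive_inside = FALSE)
}

snap_axes_to_surface <- function(axes, mesh) {
  lapply(axes, function(ax) {
    hit <- ray_surface_entry(ax, mesh)
    if (is.null(hit)) stop("planned axis misses the phantom surface", call. = FALSE)
    trajectory(as.numeric(hit), ax$direction, ax$length, ax$radius, id = ax$id)
  })
}

#' Apply the imaging model to a clean label volume
#'
#' Gaussian blur (sigma in mm, converted to voxels per axis) followed by
#' additive Gaussian noise, emulating partial-volume averaging and CT
#' quantum noise. Planting screws must happen before this step.
#'
#' @param vol A `ct_volume` of tissue labels.
#' @param blur_sigma Blur sigma in mm (0 disables).
#' @param noise_sd Noise standard deviation in HU (0 disables).
#' @param seed Optional seed for the noise draw.
#' @return The imaged `ct_volume`.
#' @export
apply_imaging <- function(vol, blur_sigma, noise_sd, seed = NULL) {
  v <- vol$voxels
  if (blur_sigma > 0) v <- gaussian_blur3(v, blur_sigma / vol$spacing)
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(length(v), 0, noise_sd)
             else with_seed(seed, stats::rnorm(length(v), 0, noise_sd))
    v <- v + array(noise, dim(v))
  }
  ct_volume(v, vol$affine)
}

#' Plant a metal screw into a CT volume
#'
#' Sets every voxel whose centre lies inside the screw cylinder to
#' `hu_screw`. Intended for clean label volumes, before [apply_imaging()].
#'
#' @param vol A `ct_volume`.
#' @param actual A `trajectory`: the realized screw axis in world mm.
#' @param hu_screw HU value of the implant (default titanium-range 3000).
#' @return The modified `ct_volume`.
#' @export
plant_screw <- function(vol, actual, hu_screw = 3000) {
  d <- dim(vol$voxels)
  tip <- actual$entry + actual$length * actual$direction
  lo <- pmin(actual$entry, tip) - actual$radius
  hi <- pmax(actual$entry, tip) + actual$radius
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]), c(lo[3], hi[3])))
  idx <- world_to_voxel(vol, corners)
  ilo <- floor(apply(idx, 2L, min))
  ihi <- ceiling(apply(idx, 2L, max))
  if (any(ilo < 1) || any(ihi > d))
    stop("screw extends outside the volume", call. = FALSE)
  rng <- lapply(1:3, function(a) seq.int(ilo[a], ihi[a]))
  sub <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  ctr <- voxel_to_world(vol, sub)
  w <- sweep(ctr, 2L, actual$entry)
  s <- as.vector(w %*% actual$direction)
  r2 <- rowSums(w * w) - s * s
  inside <- s >= 0 & s <= actual$length & r2 <= actual$radius^2
  if (any(inside)) {
    lin <- sub[inside, 1L] + d[1L] * (sub[inside, 2L] - 1L) +
      d[1L] * d[2L] * (sub[inside, 3L] - 1L)
    vol$voxels[lin] <- hu_screw
  }
  vol
}

#' Per-arm surgical deviation model
#'
#' Gaussian error model for realized screw trajectories: an isotropic
#' entry offset (sd `entry_sd` per component, mm, plus `entry_bias`) and a
#' tilt whose magnitude is half-normal (|N(0, `angle_sd`)| degrees, plus
#' `angle_bias`) about a uniformly random azimuth, pivoting at the planned
#' entry point. Element 1 parameterizes the 3DPG arm, element 2 the CAS
#' arm; scalars are recycled to both arms.
#'
#' The defaults emulate deviation magnitudes reported for guided cervical
#' screw placement (median entry deviation near 1.8 mm, median angular
#' deviation near 5.5 degrees), identical in both arms.
#'
#' @param entry_sd Per-component entry offset sd, mm (length 1 or 2).
#' @param angle_sd Tilt magnitude sd, degrees (length 1 or 2).
#' @param entry_bias Systematic entry offset, a 3-vector or 2 x 3 matrix.
#' @param angle_bias Systematic tilt, degrees (length 1 or 2).
#' @return An object of class `deviation_model`.
#' @export
deviation_model <- function(entry_sd = 1.5, angle_sd = 8, entry_bias = c(0, 0, 0),
                            angle_bias = 0) {
  two <- function(x) if (length(x) == 1L) rep(x, 2L) else x
  entry_sd <- two(entry_sd); angle_sd <- two(angle_sd); angle_bias <- two(angle_bias)
  if (!is.matrix(entry_bias)) entry_bias <- rbind(entry_bias, entry_bias)
  if (any(entry_sd < 0) || any(angle_sd < 0))
    stop("deviation sds must be non-negative", call. = FALSE)
  arms <- c("3DPG", "CAS")
  structure(list(entry_sd = stats::setNames(entry_sd, arms),
                 angle_sd = stats::setNames(angle_sd, arms),
                 entry_bias = entry_bias,
                 angle_bias = stats::setNames(angle_bias, arms)),
            class = "deviation_model")
}

arm_params <- function(model, arm) {
  i <- match(arm, c("3DPG", "CAS"))
  list(entry_sd = model$entry_sd[[i]], angle_sd = model$angle_sd[[i]],
       entry_bias = model$entry_bias[i, ], angle_bias = model$angle_bias[[i]])
}

# Perturb a planned trajectory: offset the axis, tilt about the planned
# entry, then snap the entry to the bone surface along the new axis.
perturb_trajectory <- function(planned, mesh, offset, tilt_deg, azimuth_rad) {
  fr <- make_frame(planned$direction)
  w <- cos(azimuth_rad) * fr$u + sin(azimuth_rad) * fr$v
  R <- rotation_matrix(cross3(planned$direction, w), tilt_deg)
  dir2 <- as.vector(R %*% planned$direction)
  shifted <- trajectory(planned$entry + offset, dir2, planned$length,
                        planned$radius, id = planned$id)
  hit <- ray_surface_entry(shifted, mesh)
  if (is.null(hit)) return(NULL)
  trajectory(as.numeric(hit), dir2, planned$length, planned$radius, id = planned$id)
}

#' Generate a paired split-spine dataset with known ground truth
#'
#' Builds a planning phantom, assigns the 3DPG technique to the left or
#' right side of each patient by block-balanced randomization (the other
#' side receives CAS), perturbs each planned trajectory according to its
#' arm's [deviation_model()], and synthesizes for every vertebral level a
#' pre-operative volume plus a post-operative volume in which the anatomy
#' has been rigidly repositioned (recorded as hidden ground truth) and
#' both screws planted.
#'
#' Perturbation draws that would push a screw outside the imaged field of
#' view are redrawn (at most 20 times), mirroring the clinical constraint
#' that the scan covers the instrumented anatomy.
#'
#' @param spec A `phantom_spec`.
#' @param dev_model A `deviation_model`.
#' @param n_patients Number of patients.
#' @param n_levels Instrumented vertebral levels per patient.
#' @param seed Integer seed; the entire dataset is reproducible from it.
#' @param voxelize If `FALSE`, skip volume synthesis and return only
#'   trajectories and ground truth (fast; for statistical checks).
#' @param block_size Randomization block size (even).
#' @param reposition_max_angle,reposition_max_translation Magnitude of the
#'   hidden rigid repositioning between scans (degrees, mm).
#' @return An object of class `splitspine_dataset`: fields `mesh`,
#'   `planned` (left/right), `levels` (per-level volumes, screws, hidden
#'   transform), and `truth` (a data.frame of per-screw ground-truth
#'   deviations).
#' @export
generate_dataset <- function(spec, dev_model = deviation_model(),
                             n_patients = 10, n_levels = 3, seed = 1,
                             voxelize = TRUE, block_size = 2,
                             reposition_max_angle = 15,
                             reposition_max_translation = 10) {
  if (n_patients < 1 || n_levels < 1) stop("need at least one patient and level", call. = FALSE)
  seeds <- derive_seeds(seed, 3L)
  mesh <- phantom_mesh(spec)
  planned <- snap_axes_to_surface(phantom_axes(spec), mesh)
  scheme <- randomize_sides(n_patients, block_size = block_size, seed = seeds[1L])

  b <- phantom_bounds(spec)
  fov_lo <- b[1, ] - spec$margin + 2 * spec$spacing
  fov_hi <- b[2, ] + spec$margin - 2 * spec$spacing
  in_fov <- function(tr) {
    tip <- tr$entry + tr$length * tr$direction
    lo <- pmin(tr$entry, tip) - tr$radius
    hi <- pmax(tr$entry, tip) + tr$radius
    all(lo >= fov_lo) && all(hi <= fov_hi)
  }

  labels0 <- NULL
  preop_clean <- NULL
  if (voxelize) {
    labels0 <- voxelize_phantom(spec)
    preop_clean <- if (spec$blur_sigma > 0)
      ct_volume(gaussian_blur3(labels0$voxels, spec$blur_sigma / labels0$spacing),
                labels0$affine) else labels0
  }

  levels <- list()
  truth <- list()
  with_seed(seeds[2L], {
    for (p in seq_len(n_patients)) {
      side_3dpg <- scheme$side_3dpg[p]
      for (lv in seq_len(n_levels)) {
        hidden <- random_rigid_transform(reposition_max_angle,
                                         reposition_max_translation,
                                         center = colMeans(b))
        screws <- list()
        for (side in c("left", "right")) {
          arm <- if (side == side_3dpg) "3DPG" else "CAS"
          par <- arm_params(dev_model, arm)
          actual <- NULL
          for (try in 1:20) {
            offset <- stats::rnorm(3, 0, par$entry_sd) + par$entry_bias
            tilt <- abs(stats::rnorm(1, 0, par$angle_sd)) + par$angle_bias
            az <- stats::runif(1, 0, 2 * pi)
            cand <- perturb_trajectory(planned[[side]], mesh, offset, tilt, az)
            if (!is.null(cand) && in_fov(cand)) { actual <- cand; break }
          }
          if (is.null(actual))
            stop("could not draw an in-field screw perturbation; ",
                 "deviation sds too large for the phantom field of view",
                 call. = FALSE)
          sid <- sprintf("P%02d_L%d_%s", p, lv, side)
          screws[[side]] <- list(arm = arm, actual = actual, tilt_deg = tilt)
          truth[[length(truth) + 1L]] <- data.frame(
            screw_id = sid, patient = p, level = lv, side = side, arm = arm,
            entry_mm = vnorm(actual$entry - planned[[side]]$entry),
            angle_deg = angle_between(planned[[side]]$direction, actual$direction),
            stringsAsFactors = FALSE)
        }
        lev <- list(patient = p, level = lv, hidden = hidden, screws = screws)
        if (voxelize) {
          pre <- if (spec$noise_sd > 0)
            ct_volume(preop_clean$voxels +
                        array(stats::rnorm(length(preop_clean$voxels), 0, spec$noise_sd),
                              dim(preop_clean$voxels)),
                      preop_clean$affine) else preop_clean
          post_lab <- voxelize_phantom(spec, transform = hidden)
          for (side in c("left", "right")) {
            planted <- transform_trajectory(hidden, screws[[side]]$actual)
            post_lab <- plant_screw(post_lab, planted, spec$hu[["screw"]])
          }
          post <- apply_imaging(post_lab, spec$blur_sigma, spec$noise_sd)
          lev$preop <- pre
          lev$postop <- post
        }
        levels[[length(levels) + 1L]] <- lev
      }
    }
  })

  structure(list(spec = spec, dev_model = dev_model, mesh = mesh,
                 planned = planned, scheme = scheme, levels = levels,
                 truth = do.call(rbind, truth), seed = seed,
                 voxelized = voxelize),
            class = "splitspine_dataset")
}

#' @export
print.splitspine_dataset <- function(x, ...) {
  cat(sprintf("split-spine dataset: %d levels, %d screws%s, seed %d\n",
              length(x$levels), nrow(x$truth),
              if (x$voxelized) "" else " (trajectories only)", x$seed))
  invisible(x)
}

#' Rigidly reposition every post-operative scene of a dataset
#'
#' Composes an extra rigid transform into the world mapping of each
#' post-operative volume (and into the recorded hidden repositioning), as
#' if the patient had been aligned differently at the post-operative scan.
#' Ground-truth deviations are unaffected; a correct measurement pipeline
#' must return the same estimates.
#'
#' @param dataset A `splitspine_dataset` with volumes.
#' @param t A `rigid_transform`, or a list of one per level.
#' @return The repositioned dataset.
#' @export
transform_scene <- function(dataset, t) {
  if (!dataset$voxelized) stop("dataset has no volumes", call. = FALSE)
  for (i in seq_along(dataset$levels)) {
    ti <- if (inherits(t, "rigid_transform")) t else t[[i]]
    dataset$levels[[i]]$postop <- transform_volume(ti, dataset$levels[[i]]$postop)
    dataset$levels[[i]]$hidden <- rt_compose(ti, dataset$levels[[i]]$hidden)
  }
  dataset
}
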