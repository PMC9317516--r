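# The accuracy pipeline: Hounsfield-threshold screw segmentation, trimmed
# iterative-closest-point rigid registration per vertebra, analytic
# least-squares cylinder fitting, and entry-point / angular deviation
# metrics against the plan.

err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "spineaccError")))
}

#' Segment screw voxels by Hounsfield threshold
#'
#' Selects voxels at or above `hu_threshold` within a tubular region of
#' interest around the expected screw axis, keeps the largest 6-connected
#' component, and returns the world coordinates of the voxel centres.
#'
#' @param vol A `ct_volume` (post-operative).
#' @param hu_threshold Metal threshold in HU; must sit above the bone
#'   range (default 2500).
#' @param roi A `trajectory`: the expected screw axis in the volume's
#'   world frame.
#' @param margin Radial/axial margin (mm) widening the region of interest.
#' @return n x 3 matrix of world-mm points, with attribute `n_components`.
#'   Errors with class `spineaccMissingScrew` when nothing exceeds the
#'   threshold; warns when a second component of comparable size exists.
#' @export
segment_screw_voxels <- function(vol, hu_threshold = 2500, roi, margin = 6) {
  d <- dim(vol$voxels)
  tip <- roi$entry + roi$length * roi$direction
  lo <- pmin(roi$entry, tip) - roi$radius - margin
  hi <- pmax(roi$entry, tip) + roi$radius + margin
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]), c(lo[3], hi[3])))
  idx <- world_to_voxel(vol, corners)
  ilo <- pmax(1, floor(apply(idx, 2L, min)))
  ihi <- pmin(d, ceiling(apply(idx, 2L, max)))
  if (any(ilo > ihi)) err("screw region of interest lies outside the volume", "spineaccMissingScrew")
  rng <- lapply(1:3, function(a) seq.int(ilo[a], ihi[a]))
  sub <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  vals <- vol$voxels[sub]
  ctr <- voxel_to_world(vol, sub)
  w <- sweep(ctr, 2L, roi$entry)
  s <- as.vector(w %*% roi$direction)
  r2 <- rowSums(w * w) - s * s
  keep <- vals >= hu_threshold & s >= -margin & s <= roi$length + margin &
    r2 <= (roi$radius + margin)^2
  if (!any(keep))
    err("no voxels above the metal threshold in the screw region", "spineaccMissingScrew")
  sub <- sub[keep, , drop = FALSE]
  comp <- connected_components_6(sub)
  sizes <- tabulate(comp)
  main <- which.max(sizes)
  if (length(sizes) > 1L && sort(sizes, decreasing = TRUE)[2L] >= 0.5 * sizes[main])
    warning("ambiguous screw segmentation: two components of similar size",
            call. = FALSE)
  pts <- voxel_to_world(vol, sub[comp == main, , drop = FALSE])
  attr(pts, "n_components") <- length(sizes)
  pts
}

# 6-connectivity components of a set of voxel index triples (n x 3).
# Union-find with path halving; edges found by matching linear indices.
connected_components_6 <- function(sub) {
  n <- nrow(sub)
  span <- apply(sub, 2L, max) + 1L
  lin <- sub[, 1L] + span[1L] * (sub[, 2L] + span[2L] * sub[, 3L])
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  steps <- c(1L, span[1L], span[1L] * span[2L])
  for (stp in steps) {
    j <- match(lin + stp, lin)
    ok <- which(!is.na(j))
    for (a in ok) {
      ra <- find(a); rb <- find(j[a])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Closed-form least-squares rigid transform mapping point set A onto B.
kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2L, ca), sweep(B, 2L, cb))
  sv <- svd(H)
  s <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  rigid_transform(R, cb - as.vector(R %*% ca))
}

# proper-rotation eigenbasis of a point cloud's covariance
pca_basis <- function(P) {
  e <- eigen(stats::cov(P), symmetric = TRUE)
  U <- e$vectors
  if (det(U) < 0) U[, 3L] <- -U[, 3L]
  list(U = U, values = e$values, center = colMeans(P))
}

#' Trimmed iterative-closest-point rigid registration
#'
#' Alternates nearest-neighbour correspondence (kd-tree) with the
#' closed-form SVD rigid update, excluding the worst `trim_fraction` of
#' correspondences each iteration. Initialization (when `init` is `NULL`)
#' aligns centroids and principal axes, scoring the four proper-rotation
#' sign disambiguations by their trimmed correspondence rms. The trimmed
#' rms is monotone non-increasing across iterations.
#'
#' @param source n x 3 matrix of points to move (e.g. a post-operative
#'   bone surface).
#' @param target m x 3 matrix (or `surface_mesh`) of reference points.
#' @param init Optional initial `rigid_transform`.
#' @param max_iter Maximum iterations.
#' @param tol Stop when the trimmed rms improves by less than this (mm).
#' @param trim_fraction Fraction of worst correspondences discarded
#'   (0 disables trimming).
#' @param max_source_points Deterministic subsample cap on the source.
#' @param target_normals Optional unit normals of the target points (one
#'   per row). When given, the point-to-point solution is polished by a
#'   few point-to-plane Gauss-Newton iterations, which removes the small
#'   tangential bias of point-to-point matching between two independent
#'   surface samplings.
#' @param plane_iter Number of point-to-plane polish iterations.
#' @return An object of class `icp_registration`: `transform` (mapping
#'   source frame onto target frame), `rms` (final trimmed rms, mm),
#'   `rms_history`, `iterations`, `converged`.
#' @export
icp_register <- function(source, target, init = NULL, max_iter = 100,
                         tol = 1e-4, trim_fraction = 0.2,
                         max_source_points = 6000,
                         target_normals = NULL, plane_iter = 15) {
  if (inherits(source, "surface_mesh")) source <- source$vertices
  if (inherits(target, "surface_mesh")) target <- target$vertices
  source <- as_point_matrix(source); target <- as_point_matrix(target)
  check_nondegenerate <- function(P, what) {
    if (nrow(P) < 3L) err(paste(what, "needs at least 3 points"), "spineaccDegenerateInput")
    sv <- svd(sweep(P[seq_len(min(nrow(P), 2000L)), , drop = FALSE], 2L,
                    colMeans(P)))$d
    if (sv[2L] < 1e-9 * max(sv[1L], 1))
      err(paste(what, "points are collinear"), "spineaccDegenerateInput")
  }
  check_nondegenerate(source, "source")
  check_nondegenerate(target, "target")
  if (trim_fraction < 0 || trim_fraction >= 1)
    stop("trim_fraction must be in [0, 1)", call. = FALSE)

  if (nrow(source) > max_source_points) {
    pick <- unique(round(seq(1, nrow(source), length.out = max_source_points)))
    S <- source[pick, , drop = FALSE]
  } else S <- source
  tree <- kd_build(target)
  nkeep <- max(3L, ceiling((1 - trim_fraction) * nrow(S)))

  trimmed_rms <- function(tr) {
    q <- kd_query(tree, apply_transform(tr, S))
    d <- sort(q$dist)[seq_len(nkeep)]
    sqrt(mean(d * d))
  }

  if (is.null(init)) {
    ps <- pca_basis(S)
    pt <- pca_basis(if (nrow(target) > 8000L)
      target[unique(round(seq(1, nrow(target), length.out = 8000L))), , drop = FALSE]
      else target)
    cand <- lapply(list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
                   function(sg) {
                     R <- pt$U %*% diag(sg) %*% t(ps$U)
                     rigid_transform(R, pt$center - as.vector(R %*% ps$center))
                   })
    scores <- vapply(cand, trimmed_rms, numeric(1))
    tr <- cand[[which.min(scores)]]
  } else tr <- init

  hist <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    q <- kd_query(tree, apply_transform(tr, S))
    ord <- order(q$dist)[seq_len(nkeep)]
    rms <- sqrt(mean(q$dist[ord]^2))
    hist <- c(hist, rms)
    if (prev - rms < tol) { converged <- TRUE; break }
    prev <- rms
    tr <- kabsch(S[ord, , drop = FALSE], target[q$index[ord], , drop = FALSE])
  }
  if (!is.null(target_normals)) {
    for (it2 in seq_len(plane_iter)) {
      SP <- apply_transform(tr, S)
      q <- kd_query(tree, SP)
      keep <- order(q$dist)[seq_len(nkeep)]
      p <- SP[keep, , drop = FALSE]
      m <- target[q$index[keep], , drop = FALSE]
      nn <- target_normals[q$index[keep], , drop = FALSE]
      r <- rowSums((p - m) * nn)
      J <- cbind(p[, 2] * nn[, 3] - p[, 3] * nn[, 2],
                 p[, 3] * nn[, 1] - p[, 1] * nn[, 3],
                 p[, 1] * nn[, 2] - p[, 2] * nn[, 1],
                 nn)
      x <- tryCatch(solve(crossprod(J), -crossprod(J, r)), error = function(e) NULL)
      if (is.null(x)) break
      x <- as.vector(x)
      ang <- vnorm(x[1:3])
      Rupd <- if (ang < 1e-14) diag(3) else rotation_matrix(x[1:3], ang * 180 / pi)
      tr <- rt_compose(rigid_transform(Rupd, x[4:6]), tr)
      if (ang < 1e-10 && vnorm(x[4:6]) < 1e-10) break
    }
    q <- kd_query(tree, apply_transform(tr, S))
    final_rms <- sqrt(mean(sort(q$dist)[seq_len(nkeep)]^2))
  }
  if (is.null(target_normals)) final_rms <- hist[length(hist)]
  structure(list(transform = tr, rms = final_rms,
                 rms_history = hist, iterations = length(hist),
                 converged = converged),
            class = "icp_registration")
}

#' @export
print.icp_registration <- function(x, ...) {
  cat(sprintf("ICP registration: trimmed rms %.4f mm after %d iterations (%s)\n",
              x$rms, x$iterations, if (x$converged) "converged" else "max_iter reached"))
  print(x$transform)
  invisible(x)
}

#' Least-squares cylinder fit to a point cloud
#'
#' Fits an infinite cylinder by minimizing the sum of squared radial
#' residuals `(d_i - r)^2`, where `d_i` is the distance of point `i` from
#' the axis. The axis is initialized as the first principal axis through
#' the centroid and refined by Levenberg-Marquardt over axis point and
#' direction, with the radius profiled out as the mean radial distance.
#'
#' @param points n x 3 matrix of world-mm points (n >= 50); the cloud must
#'   be elongated (longest principal extent at least 3x the next).
#' @return An object of class `cylinder_fit`: `axis_point`,
#'   `axis_direction` (unit), `radius`, `rms_radial_residual`, `n_points`.
#' @export
fit_cylinder <- function(points) {
  P <- as_point_matrix(points)
  if (nrow(P) < 50L) err("cylinder fit needs at least 50 points", "spineaccDegenerateInput")
  pb <- pca_basis(P)
  if (sqrt(pb$values[1L] / max(pb$values[2L], 1e-12)) < 3)
    err("point cloud is not elongated; refusing cylinder fit", "spineaccDegenerateInput")
  d0 <- pb$U[, 1L]
  c0 <- pb$center
  fr <- make_frame(d0)
  radial <- function(par) {
    p <- c0 + par[1L] * fr$u + par[2L] * fr$v
    d <- unit(d0 + par[3L] * fr$u + par[4L] * fr$v)
    w <- sweep(P, 2L, p)
    s <- as.vector(w %*% d)
    sqrt(pmax(rowSums(w * w) - s * s, 0))
  }
  fit <- minpack.lm::nls.lm(par = c(0, 0, 0, 0),
                            fn = function(par) { r <- radial(par); r - mean(r) },
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$info %in% 1:4)
    err(paste0("cylinder fit did not converge (", fit$message, ")"), "spineaccFitFailure")
  par <- fit$par
  r <- radial(par)
  structure(list(axis_point = c0 + par[1L] * fr$u + par[2L] * fr$v,
                 axis_direction = unit(d0 + par[3L] * fr$u + par[4L] * fr$v),
                 radius = mean(r),
                 rms_radial_residual = sqrt(mean((r - mean(r))^2)),
                 n_points = nrow(P)),
            class = "cylinder_fit")
}

#' @export
print.cylinder_fit <- function(x, ...) {
  cat(sprintf("cylinder fit: r = %.3f mm, rms residual %.4f mm, %d points, axis (%.3f, %.3f, %.3f)\n",
              x$radius, x$rms_radial_residual, x$n_points,
              x$axis_direction[1], x$axis_direction[2], x$axis_direction[3]))
  invisible(x)
}

#' Entry-point and angular deviation of a fitted screw from its plan
#'
#' Maps the fitted screw axis into the planning frame, orients it along
#' the planned direction (fitted axes carry no intrinsic orientation),
#' locates the realized entry as the first intersection of the axis with
#' the planning bone surface, and reports the Euclidean entry-point
#' deviation and the 3D angular deviation. When the mapped axis misses
#' the surface the closest point on the axis to the planned entry is used
#' and the record is flagged `entry_fallback`.
#'
#' @param planned Planned `trajectory` (planning frame).
#' @param fit A `cylinder_fit` in the post-operative frame.
#' @param mesh Planning-frame bone `surface_mesh`.
#' @param transform `rigid_transform` mapping the post-operative frame
#'   onto the planning frame (from [icp_register()]).
#' @param entry_method `"surface3d"` (default) for the 3D distance between
#'   entry points; `"inplane"` projects the difference onto the surface
#'   tangent plane at the realized entry.
#' @return A list: `entry_mm`, `angle_deg`, `entry_point`, `direction`,
#'   `flag` (`""` or `"entry_fallback"`).
#' @export
compute_deviation <- function(planned, fit, mesh, transform = rt_identity(),
                              entry_method = c("surface3d", "inplane")) {
  entry_method <- match.arg(entry_method)
  dm <- as.vector(transform$rotation %*% fit$axis_direction)
  if (sum(dm * planned$direction) < 0) dm <- -dm
  pm <- apply_transform(transform, fit$axis_point)
  hit <- ray_surface_entry(trajectory(pm, dm, planned$length, planned$radius), mesh)
  flag <- ""
  if (is.null(hit)) {
    flag <- "entry_fallback"
    s <- sum((planned$entry - pm) * dm)
    realized <- pm + s * dm
    nrm <- NULL
  } else {
    realized <- as.numeric(hit)
    nrm <- attr(hit, "normal")
  }
  delta <- realized - planned$entry
  if (entry_method == "inplane" && !is.null(nrm))
    delta <- delta - sum(delta * nrm) * nrm
  list(entry_mm = vnorm(delta),
       angle_deg = angle_between(planned$direction, dm),
       entry_point = realized,
       direction = dm,
       flag = flag)
}

#' Measurement pipeline configuration
#'
#' @param hu_threshold Metal segmentation threshold (HU).
#' @param iso Bone surface iso level (HU); `NULL` picks the soft/cortical
#'   midpoint of the dataset's HU map.
#' @param trim_fraction,max_iter,tol,max_source_points ICP settings, see
#'   [icp_register()]. The pipeline default is no trimming: metal is
#'   removed by dilated masking before surface extraction, and on
#'   phantoms with large flat faces fixed-fraction trimming lets the
#'   registration slide tangentially.
#' @param point_to_plane Polish the registration with point-to-plane
#'   iterations using target surface normals (default `TRUE`).
#' @param mask_dilate_mm Metal mask dilation, see
#'   [extract_surface_points()].
#' @param roi_margin Segmentation region-of-interest margin (mm).
#' @param entry_method Entry-point deviation definition, see
#'   [compute_deviation()].
#' @return A list of class `measure_config`.
#' @export
measure_config <- function(hu_threshold = 2500, iso = NULL, trim_fraction = 0,
                           max_iter = 100, tol = 1e-4, max_source_points = 6000,
                           point_to_plane = TRUE, mask_dilate_mm = 1.5,
                           roi_margin = 6, entry_method = "surface3d") {
  structure(list(hu_threshold = hu_threshold, iso = iso,
                 trim_fraction = trim_fraction, max_iter = max_iter, tol = tol,
                 max_source_points = max_source_points,
                 point_to_plane = point_to_plane, mask_dilate_mm = mask_dilate_mm,
                 roi_margin = roi_margin, entry_method = entry_method),
            class = "measure_config")
}

#' Run the full accuracy pipeline on a split-spine dataset
#'
#' Per vertebral level: extract bone surfaces from the pre- and
#' post-operative volumes (metal masked out), register them with trimmed
#' ICP, segment each screw by Hounsfield threshold around its expected
#' position, fit an analytic cylinder, and compute entry-point and
#' angular deviations against the plan. Per-screw failures are flagged
#' and the pipeline continues (per-protocol semantics).
#'
#' @param dataset A `splitspine_dataset` with volumes.
#' @param config A [measure_config()].
#' @return A data.frame with one row per screw: `screw_id`, `patient`,
#'   `level`, `side`, `arm`, `entry_mm`, `angle_deg`, `registration_rms`,
#'   `flag`; failed screws carry `NA` metrics. The per-level registration
#'   transforms are attached as attribute `registrations`.
#' @export
run_pipeline <- function(dataset, config = measure_config()) {
  if (!inherits(dataset, "splitspine_dataset") || !dataset$voxelized)
    stop("need a voxelized splitspine_dataset", call. = FALSE)
  hu <- dataset$spec$hu
  iso <- config$iso %||% ((hu[["soft"]] + hu[["cortical"]]) / 2)
  rows <- list()
  regs <- list()
  for (lev in dataset$levels) {
    rec <- tryCatch({
      pre_pts <- extract_surface_points(lev$preop, iso,
                                        normals = config$point_to_plane)
      post_pts <- extract_surface_points(lev$postop, iso,
                                         mask_above = config$hu_threshold,
                                         mask_value = hu[["trabecular"]],
                                         mask_dilate_mm = config$mask_dilate_mm)
      icp_register(post_pts, pre_pts,
                   max_iter = config$max_iter, tol = config$tol,
                   trim_fraction = config$trim_fraction,
                   max_source_points = config$max_source_points,
                   target_normals = attr(pre_pts, "normals"))
    }, error = function(e) e)
    reg_failed <- inherits(rec, "error")
    regs[[length(regs) + 1L]] <- if (reg_failed) NULL else rec
    Tmap <- if (reg_failed) NULL else rec$transform
    Tinv <- if (reg_failed) NULL else rt_invert(Tmap)
    for (side in c("left", "right")) {
      planned <- dataset$planned[[side]]
      sid <- sprintf("P%02d_L%d_%s", lev$patient, lev$level, side)
      row <- data.frame(screw_id = sid, patient = lev$patient, level = lev$level,
                        side = side, arm = lev$screws[[side]]$arm,
                        entry_mm = NA_real_, angle_deg = NA_real_,
                        registration_rms = if (reg_failed) NA_real_ else rec$rms,
                        flag = if (reg_failed) "registration_failed" else "",
                        stringsAsFactors = FALSE)
      if (!reg_failed) {
        res <- tryCatch({
          expected <- transform_trajectory(Tinv, planned)
          pts <- segment_screw_voxels(lev$postop, config$hu_threshold,
                                      roi = expected, margin = config$roi_margin)
          fit <- fit_cylinder(pts)
          compute_deviation(planned, fit, dataset$mesh, Tmap,
                            entry_method = config$entry_method)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          row$flag <- if (inherits(res, "spineaccMissingScrew")) "missing_screw"
                      else paste0("failed: ", conditionMessage(res))
        } else {
          row$entry_mm <- res$entry_mm
          row$angle_deg <- res$angle_deg
          if (nzchar(res$flag)) row$flag <- res$flag
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "registrations") <- regs
  out
}
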