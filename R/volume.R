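# CT volumes: a 3D Hounsfield array plus an affine mapping 0-based voxel
# indices to world mm (NIfTI convention, RAS).

#' CT volume in Hounsfield units
#'
#' @param voxels 3D numeric array of HU values.
#' @param affine 4x4 matrix mapping 0-based voxel indices `(i, j, k, 1)` to
#'   world mm. Must be invertible.
#' @return An object of class `ct_volume` with a `spacing` field (mm per
#'   axis, from the affine column norms).
#' @export
ct_volume <- function(voxels, affine) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array", call. = FALSE)
  affine <- matrix(as.numeric(affine), 4L, 4L)
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible", call. = FALSE)
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0)) stop("voxel spacing must be positive", call. = FALSE)
  structure(list(voxels = voxels, affine = affine, spacing = spacing),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct volume: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Convert voxel indices to world coordinates
#' @param vol A `ct_volume`.
#' @param ijk n x 3 matrix of 1-based voxel indices (may be fractional).
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- as_point_matrix(ijk)
  h <- cbind(ijk - 1, 1) %*% t(vol$affine)
  h[, 1:3, drop = FALSE]
}

#' Convert world coordinates to (fractional, 1-based) voxel indices
#' @param vol A `ct_volume`.
#' @param xyz n x 3 matrix of world mm coordinates.
#' @return n x 3 matrix of fractional 1-based voxel indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- as_point_matrix(xyz)
  h <- cbind(xyz, 1) %*% t(solve(vol$affine))
  h[, 1:3, drop = FALSE] + 1
}

#' Compose a rigid transform into a volume's world mapping
#'
#' Leaves voxel data untouched and premultiplies the affine, so every
#' world-coordinate quantity derived from the volume moves rigidly by `t`.
#' This models repositioning the scanned object without resampling.
#'
#' @param t A `rigid_transform`.
#' @param vol A `ct_volume`.
#' @return The repositioned `ct_volume`.
#' @export
transform_volume <- function(t, vol) {
  M <- rbind(cbind(t$rotation, t$translation), c(0, 0, 0, 1))
  ct_volume(vol$voxels, M %*% vol$affine)
}

# World coordinates of all voxel centers, as an n x 3 matrix in array order.
voxel_center_grid <- function(dims, affine) {
  i <- seq_len(dims[1L]) - 1
  j <- seq_len(dims[2L]) - 1
  k <- seq_len(dims[3L]) - 1
  n <- prod(dims)
  ii <- rep.int(i, dims[2L] * dims[3L])
  jj <- rep.int(rep(j, each = dims[1L]), dims[3L])
  kk <- rep(k, each = dims[1L] * dims[2L])
  cbind(ii, jj, kk, 1) %*% t(affine)[, 1:3, drop = FALSE]
}

# Separable Gaussian blur of a 3D array; sigma_vox per axis (voxels).
# Edge handling: renormalized kernel (replicate-equivalent mass).
gaussian_blur3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-(seq(-r, r))^2 / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, d)
    wt <- array(0, d)
    n <- d[ax]
    for (off in seq(-r, r)) {
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      if (!any(ok)) next
      dst <- which(ok)
      srcv <- src[ok]
      if (ax == 1L) {
        acc[dst, , ] <- acc[dst, , ] + w[off + r + 1L] * arr[srcv, , ]
        wt[dst, , ] <- wt[dst, , ] + w[off + r + 1L]
      } else if (ax == 2L) {
        acc[, dst, ] <- acc[, dst, ] + w[off + r + 1L] * arr[, srcv, ]
        wt[, dst, ] <- wt[, dst, ] + w[off + r + 1L]
      } else {
        acc[, , dst] <- acc[, , dst] + w[off + r + 1L] * arr[, , srcv]
        wt[, , dst] <- wt[, , dst] + w[off + r + 1L]
      }
    }
    arr <- acc / wt
  }
  arr
}

#' Sub-voxel surface points of an iso-level crossing
#'
#' Finds every grid edge along which the volume crosses `iso` and places a
#' point at the linearly interpolated crossing. The result is a dense,
#' sub-voxel-accurate sampling of the iso-surface, suitable as input to
#' [icp_register()]. Voxels at or above `mask_above` (e.g. metal) can be
#' replaced by `mask_value` first so implants do not contribute surface.
#'
#' @param vol A `ct_volume`.
#' @param iso Iso level in HU (e.g. midway between soft tissue and cortical
#'   bone for the outer bone surface).
#' @param mask_above,mask_value Optional metal masking (HU): voxels at or
#'   above `mask_above` are replaced by `mask_value` so implants
#'   contribute no surface.
#' @param mask_dilate_mm Dilation radius (mm) applied to the metal mask
#'   before replacement, removing the partial-volume halo around
#'   implants.
#' @param normals If `TRUE`, attach unit surface normals (from the volume
#'   gradient, pointing towards increasing values) as attribute
#'   `normals`.
#' @return n x 3 matrix of world-mm surface points.
#' @export
extract_surface_points <- function(vol, iso, mask_above = NULL, mask_value = NULL,
                                   mask_dilate_mm = 1.5, normals = FALSE) {
  v <- vol$voxels
  if (!is.null(mask_above)) {
    m <- v >= mask_above
    if (any(m) && mask_dilate_mm > 0)
      m <- dilate_mask(m, ceiling(mask_dilate_mm / vol$spacing))
    v[m] <- mask_value
  }
  d <- dim(v)
  out <- vector("list", 3L)
  for (ax in 1:3) {
    n <- d[ax]
    if (ax == 1L) { a <- v[-n, , , drop = FALSE] - iso; b <- v[-1L, , , drop = FALSE] - iso }
    else if (ax == 2L) { a <- v[, -n, , drop = FALSE] - iso; b <- v[, -1L, , drop = FALSE] - iso }
    else { a <- v[, , -n, drop = FALSE] - iso; b <- v[, , -1L, drop = FALSE] - iso }
    cross <- which(a * b < 0)
    if (!length(cross)) next
    tt <- a[cross] / (a[cross] - b[cross])
    dd <- dim(a)
    idx <- arrayInd(cross, dd)
    ijk <- idx
    ijk <- matrix(as.numeric(ijk), ncol = 3L)
    ijk[, ax] <- ijk[, ax] + tt
    out[[ax]] <- ijk
  }
  ijk <- do.call(rbind, out)
  if (is.null(ijk) || nrow(ijk) == 0L)
    stop("no iso-surface crossings found", call. = FALSE)
  pts <- voxel_to_world(vol, ijk)
  if (normals) {
    rc <- pmin(pmax(round(ijk), 2L), matrix(d - 1L, nrow(ijk), 3L, byrow = TRUE))
    lin <- function(i, j, k) i + d[1L] * (j - 1L) + d[1L] * d[2L] * (k - 1L)
    g <- cbind(v[lin(rc[, 1] + 1L, rc[, 2], rc[, 3])] - v[lin(rc[, 1] - 1L, rc[, 2], rc[, 3])],
               v[lin(rc[, 1], rc[, 2] + 1L, rc[, 3])] - v[lin(rc[, 1], rc[, 2] - 1L, rc[, 3])],
               v[lin(rc[, 1], rc[, 2], rc[, 3] + 1L)] - v[lin(rc[, 1], rc[, 2], rc[, 3] - 1L)])
    g <- g %*% solve(vol$affine[1:3, 1:3])        # index-space gradient -> world
    nl <- row_norms(g)
    nl[nl == 0] <- 1
    attr(pts, "normals") <- g / nl
  }
  pts
}

# binary dilation of a 3D mask by r voxels per axis (box kernel via shifts)
dilate_mask <- function(m, r) {
  d <- dim(m)
  out <- m
  for (ax in 1:3) {
    acc <- out
    n <- d[ax]
    for (off in seq_len(r[min(ax, length(r))])) {
      if (ax == 1L) {
        acc[seq_len(n - off), , ] <- acc[seq_len(n - off), , ] | out[seq_len(n - off) + off, , ]
        acc[seq_len(n - off) + off, , ] <- acc[seq_len(n - off) + off, , ] | out[seq_len(n - off), , ]
      } else if (ax == 2L) {
        acc[, seq_len(n - off), ] <- acc[, seq_len(n - off), ] | out[, seq_len(n - off) + off, ]
        acc[, seq_len(n - off) + off, ] <- acc[, seq_len(n - off) + off, ] | out[, seq_len(n - off), ]
      } else {
        acc[, , seq_len(n - off)] <- acc[, , seq_len(n - off)] | out[, , seq_len(n - off) + off]
        acc[, , seq_len(n - off) + off] <- acc[, , seq_len(n - off) + off] | out[, , seq_len(n - off)]
      }
    }
    out <- acc
  }
  out
}

# --- marching tetrahedra -----------------------------------------------
# Kuhn 6-tetrahedra decomposition of each grid cube; consistent across
# shared faces, so the extracted surface is watertight. Returns a
# triangle-soup surface_mesh (weld with weld_mesh() if unique vertices
# are needed).

# local corner offsets, corner c = (x, y, z) bit pattern, 0-based ids 0..7
.mt_corners <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(1,1,0),
                     c(0,0,1), c(1,0,1), c(0,1,1), c(1,1,1))
# six tets of the Kuhn split: {0, a, b, 7} over monotone paths 0->a->b->7
.mt_tets <- rbind(c(0,1,3,7), c(0,1,5,7), c(0,2,3,7),
                  c(0,2,6,7), c(0,4,5,7), c(0,4,6,7)) + 1L
# tet edges as pairs of local tet-vertex ids 1..4
.mt_edges <- rbind(c(1,2), c(1,3), c(1,4), c(2,3), c(2,4), c(3,4))

# case table: for each 4-bit inside pattern, triangles as triples of edge ids
.mt_cases <- local({
  cases <- vector("list", 16L)
  edge_id <- function(a, b) which(.mt_edges[, 1] == min(a, b) & .mt_edges[, 2] == max(a, b))
  for (code in 0:15) {
    inside <- which(bitwAnd(code, c(1L, 2L, 4L, 8L)) != 0L)
    outside <- setdiff(1:4, inside)
    tri <- NULL
    if (length(inside) == 1L || length(inside) == 3L) {
      v <- if (length(inside) == 1L) inside else outside
      o <- setdiff(1:4, v)
      tri <- matrix(c(edge_id(v, o[1]), edge_id(v, o[2]), edge_id(v, o[3])), 1L)
    } else if (length(inside) == 2L) {
      v <- inside; o <- outside
      e1 <- edge_id(v[1], o[1]); e2 <- edge_id(v[1], o[2])
      e3 <- edge_id(v[2], o[2]); e4 <- edge_id(v[2], o[1])
      tri <- rbind(c(e1, e2, e3), c(e1, e3, e4))
    }
    cases[[code + 1L]] <- tri
  }
  cases
})

#' Extract an iso-surface mesh from a volume
#'
#' Marching-tetrahedra iso-surface over the cube grid of voxel centers.
#' Triangles are oriented with normals pointing from the "inside"
#' (values >= `iso` when `positive_inside`) to the outside.
#'
#' @param vol A `ct_volume`.
#' @param iso Iso level.
#' @param positive_inside Logical; if `TRUE` (default) values above `iso`
#'   are interior (HU convention: bone bright). Use `FALSE` for signed
#'   distance fields where the interior is negative.
#' @param weld Weld coincident vertices (slower; default `FALSE`).
#' @return A `surface_mesh` in world coordinates.
#' @export
extract_surface_mesh <- function(vol, iso, positive_inside = TRUE, weld = FALSE) {
  v <- vol$voxels - iso
  if (!positive_inside) v <- -v
  d <- dim(v)
  inside <- v >= 0
  # cubes whose 8 corners are not all on one side
  cs <- inside[-d[1], -d[2], -d[3]]
  storage.mode(cs) <- "integer"
  acc <- cs
  for (ci in 2:8) {
    o <- .mt_corners[ci, ]
    acc <- acc + inside[(1 + o[1]):(d[1] - 1 + o[1]),
                        (1 + o[2]):(d[2] - 1 + o[2]),
                        (1 + o[3]):(d[3] - 1 + o[3])]
  }
  bidx <- which(acc > 0L & acc < 8L)
  if (!length(bidx)) stop("iso level crosses no cube of the volume", call. = FALSE)
  base <- arrayInd(bidx, d - 1L)                      # 1-based cube base corner
  nc <- nrow(base)
  lin <- function(off) {
    (base[, 1] + off[1]) +
      d[1] * (base[, 2] + off[2] - 1L) +
      d[1] * d[2] * (base[, 3] + off[3] - 1L)
  }
  corner_lin <- sapply(seq_len(8L), function(ci) lin(.mt_corners[ci, ]))  # nc x 8
  tris <- vector("list", 6L * 14L * 2L)
  ti <- 0L
  for (tt in 1:6) {
    cl <- corner_lin[, .mt_tets[tt, ], drop = FALSE]  # nc x 4 linear indices
    vv <- matrix(v[cl], ncol = 4L)
    ins <- vv >= 0
    code <- ins[, 1] + 2L * ins[, 2] + 4L * ins[, 3] + 8L * ins[, 4]
    for (cd in 1:14) {                                # skip empty/full
      rows <- which(code == cd)
      if (!length(rows)) next
      tris_cd <- .mt_cases[[cd + 1L]]
      # positions of the 4 tet corners (voxel index space, 1-based)
      pos <- lapply(1:4, function(m) {
        ci <- .mt_tets[tt, m]
        sweep(base[rows, , drop = FALSE], 2L, .mt_corners[ci, ], "+")
      })
      val <- vv[rows, , drop = FALSE]
      epts <- lapply(seq_len(6L), function(e) {
        a <- .mt_edges[e, 1]; b <- .mt_edges[e, 2]
        va <- val[, a]; vb <- val[, b]
        tfrac <- va / (va - vb)
        tfrac[!is.finite(tfrac)] <- 0.5
        pos[[a]] + tfrac * (pos[[b]] - pos[[a]])
      })
      # orientation reference: from inside corners toward outside corners
      insm <- ins[rows, , drop = FALSE]
      cin <- Reduce(`+`, lapply(1:4, function(m) pos[[m]] * insm[, m])) / rowSums(insm)
      cout <- Reduce(`+`, lapply(1:4, function(m) pos[[m]] * (!insm[, m]))) / rowSums(!insm)
      ref <- cout - cin
      for (r in seq_len(nrow(tris_cd))) {
        A <- epts[[tris_cd[r, 1]]]; B <- epts[[tris_cd[r, 2]]]; C <- epts[[tris_cd[r, 3]]]
        e1 <- B - A; e2 <- C - A
        nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                     e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                     e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
        flip <- rowSums(nrm * ref) > 0  # normal should point inside->outside? see below
        # normal must point away from interior: ref points inside->outside,
        # so keep normals aligned with ref
        Bf <- B; Cf <- C
        swap <- which(!flip)
        if (length(swap)) { Bf[swap, ] <- C[swap, ]; Cf[swap, ] <- B[swap, ] }
        ti <- ti + 1L
        tris[[ti]] <- rbind(A, Bf, Cf)[rep(seq_len(nrow(A)), each = 3L) +
                                         c(0L, nrow(A), 2L * nrow(A)), , drop = FALSE]
      }
    }
  }
  soup <- do.call(rbind, tris[seq_len(ti)])
  # drop zero-area triangles (two edge points coincide)
  a <- soup[seq(1, nrow(soup), 3L), , drop = FALSE]
  b <- soup[seq(2, nrow(soup), 3L), , drop = FALSE]
  cc <- soup[seq(3, nrow(soup), 3L), , drop = FALSE]
  ok <- row_norms(b - a) > 1e-12 & row_norms(cc - a) > 1e-12 & row_norms(cc - b) > 1e-12
  keep <- rep(ok, each = 3L)
  soup <- soup[keep, , drop = FALSE]
  verts <- voxel_to_world(vol, soup)
  m <- surface_mesh(verts, matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE))
  if (weld) weld_mesh(m) else m
}
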