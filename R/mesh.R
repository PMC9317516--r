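# Triangle surface meshes: construction, simple generators used as test
# phantoms, welding, areas, and ray casting for entry-point location.

#' Triangle surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex positions (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (ncol(vertices) != 3L) stop("vertices must be n x 3", call. = FALSE)
  if (nrow(faces) < 1L) stop("mesh has no faces", call. = FALSE)
  if (any(faces < 1L) || any(faces > nrow(vertices)) || anyNA(faces))
    stop("face indices out of range", call. = FALSE)
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface mesh: %d vertices, %d faces, area %.2f mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh A `surface_mesh`.
#' @return Numeric scalar.
#' @export
mesh_area <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1L], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2L], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  cx <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(row_norms(cx)) / 2
}

#' Merge coincident mesh vertices
#'
#' Collapses vertices closer than `tol` (on a rounding grid) to a single
#' vertex and drops degenerate faces. Useful after reading triangle-soup
#' formats such as STL.
#'
#' @param mesh A `surface_mesh`.
#' @param tol Welding tolerance in mm.
#' @return A `surface_mesh` with unique vertices.
#' @export
weld_mesh <- function(mesh, tol = 1e-6) {
  key <- paste(round(mesh$vertices[, 1] / tol),
               round(mesh$vertices[, 2] / tol),
               round(mesh$vertices[, 3] / tol))
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  verts <- mesh$vertices[uk, , drop = FALSE]
  faces <- matrix(map[mesh$faces], ncol = 3L)
  keep <- faces[, 1] != faces[, 2] & faces[, 1] != faces[, 3] & faces[, 2] != faces[, 3]
  surface_mesh(verts, faces[keep, , drop = FALSE])
}

#' Axis-aligned box mesh
#'
#' @param center Box centre (mm).
#' @param size Edge lengths, length-3 (mm).
#' @return A `surface_mesh` with 12 triangles, outward-facing normals.
#' @export
mesh_box <- function(center = c(0, 0, 0), size = c(1, 1, 1)) {
  h <- as.numeric(size) / 2
  s <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  v <- sweep(sweep(s, 2L, h, "*"), 2L, as.numeric(center), "+")
  # vertex order: (x,y,z) signs in expand.grid order; faces wound outward
  f <- rbind(c(1, 3, 7), c(1, 7, 5),   # x-
             c(2, 8, 4), c(2, 6, 8),   # x+
             c(1, 5, 6), c(1, 6, 2),   # y-
             c(3, 4, 8), c(3, 8, 7),   # y+
             c(1, 2, 4), c(1, 4, 3),   # z-
             c(5, 8, 6), c(5, 7, 8))   # z+
  surface_mesh(v, f)
}

#' Latitude-longitude sphere mesh
#'
#' @param center Sphere centre (mm).
#' @param radius Radius (mm).
#' @param n Number of latitude bands (longitudes use `2n`).
#' @return A `surface_mesh`.
#' @export
mesh_uv_sphere <- function(center = c(0, 0, 0), radius = 1, n = 32L) {
  n <- as.integer(n)
  th <- seq(0, pi, length.out = n + 1L)
  ph <- seq(0, 2 * pi, length.out = 2L * n + 1L)[-(2L * n + 1L)]
  grid <- expand.grid(th = th, ph = ph)
  v <- cbind(sin(grid$th) * cos(grid$ph),
             sin(grid$th) * sin(grid$ph),
             cos(grid$th)) * radius
  v <- sweep(v, 2L, as.numeric(center), "+")
  idx <- function(i, j) (j - 1L) * (n + 1L) + i   # i latitude row, j longitude col
  faces <- list()
  for (j in seq_len(2L * n)) {
    j2 <- if (j == 2L * n) 1L else j + 1L
    i <- seq_len(n)
    faces[[length(faces) + 1L]] <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j2))
    faces[[length(faces) + 1L]] <- cbind(idx(i, j), idx(i + 1L, j2), idx(i, j2))
  }
  weld_mesh(surface_mesh(v, do.call(rbind, faces)))
}

# Vectorized Moeller-Trumbore: intersect one ray with every triangle.
# Returns list(t, face) of the nearest hit with t > tmin, or NULL.
ray_mesh_hit <- function(origin, direction, mesh, tmin = 1e-9) {
  v0 <- mesh$vertices[mesh$faces[, 1L], , drop = FALSE]
  v1 <- mesh$vertices[mesh$faces[, 2L], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 3L], , drop = FALSE]
  e1 <- v1 - v0
  e2 <- v2 - v0
  d <- unit(as.numeric(direction))
  # h = d x e2
  h <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
             d[3] * e2[, 1] - d[1] * e2[, 3],
             d[1] * e2[, 2] - d[2] * e2[, 1])
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-12
  f <- ifelse(ok, 1 / a, NA_real_)
  s <- sweep(v0, 2L, as.numeric(origin), FUN = function(x, y) y - x) # origin - v0
  u <- f * rowSums(s * h)
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  v <- f * (q[, 1] * d[1] + q[, 2] * d[2] + q[, 3] * d[3])
  tt <- f * rowSums(e2 * q)
  hit <- ok & !is.na(u) & u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9 & tt > tmin
  if (!any(hit)) return(NULL)
  i <- which(hit)[which.min(tt[hit])]
  list(t = tt[i], face = i)
}

#' Entry point of a trajectory on a bone surface
#'
#' Casts a ray along the trajectory axis from a point backed off outside
#' the mesh and returns the first intersection with the surface -- the
#' realized entry point. Returns `NULL` when the axis misses the mesh.
#'
#' @param traj A `trajectory`.
#' @param mesh A `surface_mesh` (watertight in the region of interest).
#' @param back_off Distance (mm) to retreat along the axis before casting;
#'   default is twice the mesh bounding-box diagonal, guaranteeing a start
#'   outside the surface.
#' @return Length-3 entry point with attributes `normal` (unit outward-ish
#'   triangle normal) and `face` (triangle index), or `NULL` if no hit.
#' @export
ray_surface_entry <- function(traj, mesh, back_off = NULL) {
  if (is.null(back_off)) {
    rng <- apply(mesh$vertices, 2L, range)
    back_off <- 2 * vnorm(rng[2L, ] - rng[1L, ]) + 1
  }
  origin <- traj$entry - back_off * traj$direction
  hit <- ray_mesh_hit(origin, traj$direction, mesh)
  if (is.null(hit)) return(NULL)
  p <- origin + hit$t * traj$direction
  f <- mesh$faces[hit$face, ]
  n <- cross3(mesh$vertices[f[2L], ] - mesh$vertices[f[1L], ],
              mesh$vertices[f[3L], ] - mesh$vertices[f[1L], ])
  n <- unit(n)
  if (sum(n * traj$direction) > 0) n <- -n  # orient against the ray (outward)
  attr(p, "normal") <- n
  attr(p, "face") <- hit$face
  p
}

#' Apply a rigid transform to a mesh
#' @param t A `rigid_transform`.
#' @param mesh A `surface_mesh`.
#' @return The transformed `surface_mesh`.
#' @export
transform_mesh <- function(t, mesh) {
  surface_mesh(apply_transform(t, mesh$vertices), mesh$faces)
}
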