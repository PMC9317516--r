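# File formats: NIfTI volumes, STL/PLY meshes, trajectory tables.

#' Read a CT volume from NIfTI
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `ct_volume` with the file's index-to-world (RAS mm) affine.
#' @export
read_ct_volume <- function(path) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    err(paste0("not a readable NIfTI file: ", path, " (",
                               conditionMessage(e), ")"), "spineaccFormatError"))
  affine <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  ct_volume(array(as.numeric(img), dim(img)), matrix(affine, 4L, 4L))
}

#' Write a CT volume to NIfTI
#'
#' @param vol A `ct_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$voxels)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a triangle mesh (STL or PLY)
#'
#' Dialect (binary or ASCII) is detected automatically; format is chosen
#' by file extension.
#'
#' @param path Path to an `.stl` or `.ply` file.
#' @return A `surface_mesh`. STL triangle soup is returned as read; use
#'   [weld_mesh()] to merge coincident vertices.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         err(paste0("unsupported mesh format: .", ext), "spineaccFormatError"))
}

#' Write a triangle mesh (STL or PLY)
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path; format chosen by extension (`.stl` / `.ply`).
#' @param format `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  if (!inherits(mesh, "surface_mesh") || nrow(mesh$faces) == 0L)
    err("refusing to write an empty mesh", "spineaccFormatError")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(mesh, path, format),
         ply = write_ply(mesh, path, format),
         err(paste0("unsupported mesh format: .", ext), "spineaccFormatError"))
  invisible(path)
}

mesh_triangle_soup <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1L], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2L], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3L], , drop = FALSE])
}

write_stl <- function(mesh, path, format) {
  tri <- mesh_triangle_soup(mesh)
  n <- nrow(tri$a)
  e1 <- tri$b - tri$a; e2 <- tri$c - tri$a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nl <- row_norms(nrm)
  nrm <- nrm / ifelse(nl > 0, nl, 1)
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(n)) {
      writeLines(c(sprintf("  facet normal %g %g %g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %g %g %g", tri$a[i, 1], tri$a[i, 2], tri$a[i, 3]),
                   sprintf("      vertex %g %g %g", tri$b[i, 1], tri$b[i, 2], tri$b[i, 3]),
                   sprintf("      vertex %g %g %g", tri$c[i, 1], tri$c[i, 2], tri$c[i, 3]),
                   "    endloop",
                   "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(formatC("spineacc binary STL", width = -80)), con)
    writeBin(as.integer(n), con, size = 4L, endian = "little")
    block <- t(cbind(nrm, tri$a, tri$b, tri$c))  # 12 floats per facet
    for (i in seq_len(n)) {
      writeBin(as.numeric(block[, i]), con, size = 4L, endian = "little")
      writeBin(as.integer(0L), con, size = 2L, endian = "little")
    }
  }
}

read_stl <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) err("not an STL file (too short)", "spineaccFormatError")
  con <- file(path, "rb")
  head84 <- readBin(con, "raw", n = min(84L, sz))
  close(con)
  is_binary <- FALSE
  if (sz >= 84) {
    n <- readBin(head84[81:84], "integer", size = 4L, endian = "little")
    if (!is.na(n) && n >= 0 && sz == 84 + 50 * as.numeric(n)) is_binary <- TRUE
  }
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80L)
    n <- readBin(con, "integer", size = 4L, endian = "little")
    if (n < 1L) err("STL file contains no triangles", "spineaccFormatError")
    raw <- readBin(con, "raw", n = 50L * n)
    m <- matrix(raw, nrow = 50L)
    fl <- readBin(as.vector(m[1:48, ]), "numeric", n = 12L * n, size = 4L,
                  endian = "little")
    facets <- matrix(fl, nrow = 12L)  # normal + 3 vertices per column
    verts <- matrix(as.vector(facets[4:12, , drop = FALSE]), ncol = 3L, byrow = TRUE)
    surface_mesh(verts, matrix(seq_len(3L * n), ncol = 3L, byrow = TRUE))
  } else {
    lines <- readLines(path, warn = FALSE)
    if (!length(lines) || !grepl("^\\s*solid", lines[1L]))
      err("not an STL file", "spineaccFormatError")
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (!length(vl) || length(vl) %% 3L != 0L)
      err("malformed ASCII STL: vertex count not a multiple of 3", "spineaccFormatError")
    nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
    verts <- do.call(rbind, nums)
    if (anyNA(verts)) err("malformed ASCII STL: non-numeric vertex", "spineaccFormatError")
    surface_mesh(verts, matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE))
  }
}

write_ply <- function(mesh, path, format) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  hdr <- c("ply",
           if (format == "ascii") "format ascii 1.0" else "format binary_little_endian 1.0",
           paste("element vertex", nv),
           "property float x", "property float y", "property float z",
           paste("element face", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                       mesh$vertices[, 3]), con)
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                       mesh$faces[, 3] - 1L), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    writeBin(as.numeric(t(mesh$vertices)), con, size = 4L, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4L, endian = "little")
    }
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readBin(con, "raw", n = 1L)
    line <- raw(0)
    while (length(ln) && ln != as.raw(10L)) { line <- c(line, ln); ln <- readBin(con, "raw", n = 1L) }
    if (!length(ln) && !length(line)) err("truncated PLY header", "spineaccFormatError")
    txt <- sub("\r$", "", rawToChar(line))
    hdr <- c(hdr, txt)
    if (identical(txt, "end_header")) break
    if (length(hdr) == 1L && !identical(txt, "ply"))
      err("not a PLY file", "spineaccFormatError")
    if (length(hdr) > 200L) err("malformed PLY header", "spineaccFormatError")
  }
  fmt <- sub("^format\\s+(\\S+).*", "\\1", grep("^format", hdr, value = TRUE)[1L])
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)[1L]))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face", hdr, value = TRUE)[1L]))
  if (is.na(nv) || is.na(nf) || nv < 3L || nf < 1L)
    err("malformed PLY: missing vertex/face counts", "spineaccFormatError")
  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    rest <- rest[nzchar(trimws(rest))]
    vp <- do.call(rbind, lapply(strsplit(trimws(rest[seq_len(nv)]), "\\s+"),
                                function(x) as.numeric(x[1:3])))
    fp <- do.call(rbind, lapply(strsplit(trimws(rest[nv + seq_len(nf)]), "\\s+"),
                                function(x) as.integer(x[2:4])))
  } else if (fmt == "binary_little_endian") {
    vp <- matrix(readBin(con, "numeric", n = 3L * nv, size = 4L, endian = "little"),
                 ncol = 3L, byrow = TRUE)
    fp <- matrix(0L, nf, 3L)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", n = 1L))
      if (cnt != 3L) err("PLY faces must be triangles", "spineaccFormatError")
      fp[i, ] <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
    }
  } else err(paste("unsupported PLY format:", fmt), "spineaccFormatError")
  if (anyNA(vp) || anyNA(fp)) err("malformed PLY body", "spineaccFormatError")
  if (any(fp < 0L) || any(fp >= nv)) err("corrupt PLY face index", "spineaccFormatError")
  surface_mesh(vp, fp + 1L)
}

#' Convert trajectories to a data.frame
#'
#' @param trajs A list of `trajectory` objects, optionally with `arm`,
#'   `level`, `side` metadata attached as list columns of equal length.
#' @param meta Optional data.frame of per-trajectory metadata (`arm`,
#'   `level`, `side`, ...).
#' @return A data.frame with columns `id`, `entry_x_mm` ... `radius_mm`.
#' @export
trajectories_to_df <- function(trajs, meta = NULL) {
  df <- do.call(rbind, lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    data.frame(id = tr$id %||% names(trajs)[i] %||% as.character(i),
               entry_x_mm = tr$entry[1], entry_y_mm = tr$entry[2],
               entry_z_mm = tr$entry[3],
               direction_x = tr$direction[1], direction_y = tr$direction[2],
               direction_z = tr$direction[3],
               length_mm = tr$length, radius_mm = tr$radius,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(meta)) df <- cbind(df, meta)
  df
}

#' Convert a trajectory table back to trajectory objects
#' @param df A data.frame as produced by [trajectories_to_df()].
#' @return Named list of `trajectory` objects.
#' @export
df_to_trajectories <- function(df) {
  out <- lapply(seq_len(nrow(df)), function(i)
    trajectory(c(df$entry_x_mm[i], df$entry_y_mm[i], df$entry_z_mm[i]),
               c(df$direction_x[i], df$direction_y[i], df$direction_z[i]),
               df$length_mm[i], df$radius_mm[i], id = df$id[i]))
  stats::setNames(out, df$id)
}

#' Write / read a trajectory table as CSV
#' @param trajs List of `trajectory` objects (write) .
#' @param path CSV path.
#' @param meta Optional metadata columns, see [trajectories_to_df()].
#' @return The path (write) or a named list of trajectories (read).
#' @export
write_trajectories <- function(trajs, path, meta = NULL) {
  utils::write.csv(trajectories_to_df(trajs, meta), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df_to_trajectories(utils::read.csv(path, stringsAsFactors = FALSE))
}
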