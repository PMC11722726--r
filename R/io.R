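#' Export a triangle mesh to STL, OBJ, PLY or legacy VTK
#'
#' Writers are bit-stable: identical meshes produce byte-identical files
#' (fixed field ordering and number formatting, no timestamps).  STL is
#' binary little-endian (float32 vertices); OBJ, PLY and VTK legacy
#' polydata are ASCII with full double precision.
#'
#' @param mesh a [trimesh()] with at least one face.
#' @param path output file path.
#' @param format `"stl"`, `"obj"`, `"ply"` or `"vtk"`; default inferred
#'   from the file extension.
#' @return the path, invisibly.
#' @export
export_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "trimesh"))
  if (nrow(mesh$faces) == 0L || nrow(mesh$vertices) == 0L)
    stop("refusing to export an empty mesh")
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("stl", "obj", "ply", "vtk"))
  v <- mesh$vertices
  f <- mesh$faces
  switch(format,
    stl = {
      con <- file(path, "wb")
      on.exit(close(con))
      header <- charToRaw(formatC("cardiogen binary STL", width = -80))
      writeBin(header[1:80], con)
      writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
      a <- v[f[, 1], , drop = FALSE]
      b <- v[f[, 2], , drop = FALSE]
      c_ <- v[f[, 3], , drop = FALSE]
      n <- .cross_rows(b - a, c_ - a)
      nn <- sqrt(rowSums(n^2)); nn[nn < 1e-30] <- 1
      n <- n / nn
      # 12 float32 per facet (normal, v1, v2, v3) + 2 attribute bytes
      block <- t(cbind(n, a, b, c_))
      fr <- writeBin(as.numeric(block), raw(), size = 4, endian = "little")
      body <- rbind(matrix(fr, nrow = 48L), matrix(as.raw(0), 2L, nrow(f)))
      writeBin(as.vector(body), con)
    },
    obj = {
      lines <- c(
        "# cardiogen OBJ",
        sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
        sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
      )
      writeLines(lines, path)
    },
    ply = {
      lines <- c(
        "ply", "format ascii 1.0", "comment cardiogen",
        sprintf("element vertex %d", nrow(v)),
        "property double x", "property double y", "property double z",
        sprintf("element face %d", nrow(f)),
        "property list uchar int vertex_indices", "end_header",
        sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
        sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
      )
      writeLines(lines, path)
    },
    vtk = {
      lines <- c(
        "# vtk DataFile Version 3.0", "cardiogen surface", "ASCII",
        "DATASET POLYDATA",
        sprintf("POINTS %d double", nrow(v)),
        sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
        sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)),
        sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
      )
      writeLines(lines, path)
    }
  )
  invisible(path)
}

#' Read a mesh written by [export_mesh()]
#'
#' @param path mesh file (`.stl`, `.obj`, `.ply` or `.vtk`).
#' @param format override the extension-derived format.
#' @return a [trimesh()].  STL triangle soups are re-indexed by exact
#'   vertex match.
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("stl", "obj", "ply", "vtk"))
  switch(format,
    stl = {
      con <- file(path, "rb")
      on.exit(close(con))
      invisible(readBin(con, "raw", 80))
      nf <- readBin(con, "integer", 1, size = 4, endian = "little")
      raw_all <- readBin(con, "raw", nf * 50L)
      m <- matrix(raw_all, nrow = 50L)
      vals <- matrix(readBin(as.vector(m[1:48, , drop = FALSE]), "numeric",
                             n = 12L * nf, size = 4, endian = "little"),
                     nrow = 12L)
      tri <- t(vals[4:12, , drop = FALSE])
      pts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
                   tri[, 7:9, drop = FALSE])
      key <- apply(pts, 1, paste, collapse = ",")
      uk <- !duplicated(key)
      idx <- match(key, key[uk])
      v <- pts[uk, , drop = FALSE]
      f <- matrix(idx, ncol = 3)
      trimesh(v, f)
    },
    obj = {
      lines <- readLines(path)
      vl <- grep("^v ", lines, value = TRUE)
      fl <- grep("^f ", lines, value = TRUE)
      v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p)
        as.numeric(p[2:4])))
      f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
        as.integer(sub("/.*", "", p[2:4]))))
      trimesh(v, f)
    },
    ply = {
      lines <- readLines(path)
      nv <- as.integer(sub("element vertex ", "",
                           grep("^element vertex", lines, value = TRUE)))
      nf <- as.integer(sub("element face ", "",
                           grep("^element face", lines, value = TRUE)))
      start <- which(lines == "end_header") + 1L
      v <- do.call(rbind, lapply(strsplit(lines[start:(start + nv - 1L)],
                                          "\\s+"), as.numeric))
      fl <- strsplit(lines[(start + nv):(start + nv + nf - 1L)], "\\s+")
      f <- do.call(rbind, lapply(fl, function(p) as.integer(p[2:4]) + 1L))
      trimesh(v, f)
    },
    vtk = {
      lines <- readLines(path)
      ip <- grep("^POINTS", lines)
      nv <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
      v <- do.call(rbind, lapply(strsplit(lines[(ip + 1L):(ip + nv)],
                                          "\\s+"), as.numeric))
      if_ <- grep("^POLYGONS", lines)
      nf <- as.integer(strsplit(lines[if_], "\\s+")[[1]][2])
      fl <- strsplit(lines[(if_ + 1L):(if_ + nf)], "\\s+")
      f <- do.call(rbind, lapply(fl, function(p) as.integer(p[2:4]) + 1L))
      trimesh(v, f)
    }
  )
}

#' Write a cohort measurement manifest CSV
#'
#' One row per model with the measurement columns used throughout the
#' package (id, group, height, thickness min/max/avg, radius min/max/avg,
#' cavity volume) plus any validation-flag columns present.  Output is
#' deterministic: reruns produce byte-identical files.
#'
#' @param records a manifest data frame (e.g. from
#'   [build_default_cohort()]`$manifest`) or an `"lv_cohort"` object.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(records, path) {
  if (inherits(records, "lv_cohort")) records <- records$manifest
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("no records to write")
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
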