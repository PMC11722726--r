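#' Indexed triangle surface mesh
#'
#' `trimesh()` builds the triangle-mesh container used by every geometry
#' builder in the package: a numeric `n x 3` vertex matrix (coordinates in
#' millimetres) and an integer `m x 3` face matrix of 1-based vertex indices,
#' counter-clockwise when seen from outside the surface.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in mm).
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param lateral optional logical vector, one flag per vertex, marking
#'   vertices that belong to the lateral (non-cap) surface.  Used by
#'   [mesh_metrics()] to exclude cap fans from radius statistics.  Defaults
#'   to all `TRUE`.
#' @return an object of class `"trimesh"`.
#' @seealso [mesh_volume()], [mesh_metrics()], [is_watertight()]
#' @export
trimesh <- function(vertices, faces, lateral = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L)
    stop("'vertices' must have 3 columns (x, y, z)")
  if (ncol(faces) != 3L)
    stop("'faces' must have 3 columns of vertex indices")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices must lie in 1..nrow(vertices)")
  }
  if (is.null(lateral)) lateral <- rep(TRUE, nrow(vertices))
  if (length(lateral) != nrow(vertices))
    stop("'lateral' must have one flag per vertex")
  structure(
    list(vertices = vertices, faces = faces, lateral = as.logical(lateral)),
    class = "trimesh"
  )
}

#' @export
print.trimesh <- function(x, ...) {
  wt <- tryCatch(is_watertight(x), error = function(e) NA)
  cat(sprintf("<trimesh: %d vertices, %d faces, watertight: %s>\n",
              nrow(x$vertices), nrow(x$faces),
              ifelse(is.na(wt), "?", ifelse(wt, "yes", "no"))))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# directed edge list of a face matrix, one row per half-edge
.half_edges <- function(faces) {
  rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
}

#' Test topological watertightness
#'
#' A mesh is watertight (2-manifold without boundary, consistently oriented)
#' when every undirected edge is shared by exactly two faces and every
#' directed half-edge occurs exactly once.
#'
#' @param mesh a [trimesh()].
#' @return `TRUE` or `FALSE`.
#' @export
is_watertight <- function(mesh) {
  stopifnot(inherits(mesh, "trimesh"))
  if (nrow(mesh$faces) == 0L) return(FALSE)
  he <- .half_edges(mesh$faces)
  nv <- nrow(mesh$vertices)
  dkey <- he[, 1] * (nv + 1) + he[, 2]          # directed
  if (anyDuplicated(dkey) > 0L) return(FALSE)
  ukey <- pmin(he[, 1], he[, 2]) * (nv + 1) + pmax(he[, 1], he[, 2])
  all(tabulate(match(ukey, unique(ukey))) == 2L)
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem volume: the sum over faces of signed tetrahedron
#' volumes against the origin.  The result is orientation-corrected to be
#' positive, so meshes with consistently inward normals report the same
#' volume as their outward-oriented twin.
#'
#' @param mesh a watertight [trimesh()].
#' @return enclosed volume in cubic millimetres.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "trimesh"))
  if (!is_watertight(mesh))
    stop("mesh_volume() requires a watertight mesh")
  v <- mesh$vertices
  a <- v[mesh$faces[, 1], , drop = FALSE]
  b <- v[mesh$faces[, 2], , drop = FALSE]
  c_ <- v[mesh$faces[, 3], , drop = FALSE]
  # scalar triple product a . (b x c) per face
  cx <- b[, 2] * c_[, 3] - b[, 3] * c_[, 2]
  cy <- b[, 3] * c_[, 1] - b[, 1] * c_[, 3]
  cz <- b[, 1] * c_[, 2] - b[, 2] * c_[, 1]
  abs(sum(a[, 1] * cx + a[, 2] * cy + a[, 3] * cz)) / 6
}

# per-face areas
.face_areas <- function(mesh) {
  v <- mesh$vertices
  ab <- v[mesh$faces[, 2], , drop = FALSE] - v[mesh$faces[, 1], , drop = FALSE]
  ac <- v[mesh$faces[, 3], , drop = FALSE] - v[mesh$faces[, 1], , drop = FALSE]
  nx <- ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2]
  ny <- ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3]
  nz <- ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1]
  sqrt(nx^2 + ny^2 + nz^2) / 2
}

#' Height and radius statistics of a mesh
#'
#' Measures the long-axis extent and the radial statistics used in cohort
#' manifests.  Height is the extent of vertex projections on `axis`.  Radii
#' are distances of lateral-surface vertices from the axis line through the
#' vertex centroid.  Cap vertices and an apex exclusion band (vertices within
#' `apex_exclude` mm of the apex-side extreme, the end of maximal projection)
#' are excluded from radius statistics so a rounded or tapered apex does not
#' drive the minimum radius to zero; `radius_avg` is the area-weighted mean
#' over the retained vertices.
#'
#' @param mesh a [trimesh()].
#' @param axis long-axis direction (default +Z, the package convention for
#'   both the left ventricle and the valve).
#' @param apex_exclude width of the apex exclusion band in mm (default 2).
#' @return list with `height`, `radius_min`, `radius_max`, `radius_avg` (mm).
#' @export
mesh_metrics <- function(mesh, axis = c(0, 0, 1), apex_exclude = 2) {
  stopifnot(inherits(mesh, "trimesh"))
  if (nrow(mesh$vertices) == 0L) stop("empty mesh")
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (nrm < .Machine$double.eps) stop("zero-length axis")
  axis <- axis / nrm

  v <- mesh$vertices
  proj <- drop(v %*% axis)
  height <- max(proj) - min(proj)

  ctr <- colMeans(v)
  d <- sweep(v, 2, ctr)
  along <- drop(d %*% axis)
  perp <- d - outer(along, axis)
  radius <- sqrt(rowSums(perp^2))

  keep <- mesh$lateral & (proj <= max(proj) - apex_exclude)
  if (!any(keep)) keep <- mesh$lateral
  if (!any(keep)) keep <- rep(TRUE, nrow(v))

  # vertex weights: one third of incident face area
  fa <- .face_areas(mesh)
  w <- numeric(nrow(v))
  for (k in 1:3) {
    tw <- tapply(fa, mesh$faces[, k], sum)
    idx <- as.integer(names(tw))
    w[idx] <- w[idx] + tw / 3
  }
  wk <- w[keep]
  if (sum(wk) <= 0) wk <- rep(1, sum(keep))

  list(
    height = height,
    radius_min = min(radius[keep]),
    radius_max = max(radius[keep]),
    radius_avg = sum(radius[keep] * wk) / sum(wk)
  )
}

#' Rigid-motion and merge helpers
#'
#' `mesh_transform()` applies `x -> x R^T + t` to the vertices;
#' `rotation_z()` builds the rotation matrix about +Z by `angle` radians;
#' `mesh_merge()` concatenates meshes into one (indices re-offset).
#'
#' @param mesh a [trimesh()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 offset in mm.
#' @return a transformed or merged [trimesh()].
#' @export
mesh_transform <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(mesh, "trimesh"))
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, as.numeric(translation), `+`)
  trimesh(v, mesh$faces, mesh$lateral)
}

#' @rdname mesh_transform
#' @param angle rotation angle in radians.
#' @export
rotation_z <- function(angle) {
  ca <- cos(angle); sa <- sin(angle)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

#' @rdname mesh_transform
#' @param meshes list of [trimesh()] objects.
#' @export
mesh_merge <- function(meshes) {
  stopifnot(length(meshes) >= 1L, all(vapply(meshes, inherits, TRUE, "trimesh")))
  off <- 0L
  vs <- list(); fs <- list(); ls <- list()
  for (m in meshes) {
    vs[[length(vs) + 1L]] <- m$vertices
    fs[[length(fs) + 1L]] <- m$faces + off
    ls[[length(ls) + 1L]] <- m$lateral
    off <- off + nrow(m$vertices)
  }
  trimesh(do.call(rbind, vs), do.call(rbind, fs), unlist(ls))
}

#' Icosphere test solid
#'
#' Subdivided icosahedron projected onto a sphere; a convenient watertight
#' benchmark mesh for the volume and thickness metrology.
#'
#' @param radius sphere radius in mm.
#' @param subdivisions number of 4-to-1 triangle subdivisions (0 = raw
#'   icosahedron).
#' @param center sphere center.
#' @return a watertight [trimesh()].
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- pmin(he[, 1], he[, 2]) * (nv + 1) + pmax(he[, 1], he[, 2])
    ukey <- unique(key)
    mid_id <- nv + match(key, ukey)
    ue <- he[!duplicated(key), , drop = FALSE]
    mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    v <- rbind(v, mids)
    m12 <- mid_id[seq_len(nrow(f))]
    m23 <- mid_id[nrow(f) + seq_len(nrow(f))]
    m31 <- mid_id[2 * nrow(f) + seq_len(nrow(f))]
    f <- rbind(
      cbind(f[, 1], m12, m31),
      cbind(f[, 2], m23, m12),
      cbind(f[, 3], m31, m23),
      cbind(m12, m23, m31)
    )
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, as.numeric(center), `+`)
  trimesh(v, f)
}
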