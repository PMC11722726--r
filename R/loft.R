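#' Planar control ellipse of a lofted surface
#'
#' One cross-section of a loft: an ellipse in the plane z = const with
#' center offset (`cx`, `cy`) and semi-axes (`ax`, `ay`).  Circular sections
#' are the `ax == ay` special case.
#'
#' @param z axial position (mm).
#' @param ax,ay semi-axes (mm), strictly positive.
#' @param cx,cy in-plane center offset (mm).
#' @return an object of class `"ellipse_section"`.
#' @export
ellipse_section <- function(z, ax, ay = ax, cx = 0, cy = 0) {
  stopifnot(is.finite(z), is.finite(ax), is.finite(ay))
  if (ax <= 0 || ay <= 0) stop("ellipse semi-axes must be > 0")
  structure(list(z = z, cx = cx, cy = cy, ax = ax, ay = ay),
            class = "ellipse_section")
}

# sample an ellipse_section on a shared theta grid -> n x 3 ring
.sample_section <- function(sec, theta) {
  cbind(sec$cx + sec$ax * cos(theta),
        sec$cy + sec$ay * sin(theta),
        rep(sec$z, length(theta)))
}

# stitch an ordered list of n_theta x 3 rings into a triangle tube;
# optional fan caps at first/last ring.  Orientation: outward normals for
# rings ordered by increasing z and sampled counter-clockwise in (x, y).
.stitch_rings <- function(rings, cap_ends = TRUE) {
  n <- nrow(rings[[1]])
  m <- length(rings)
  v <- do.call(rbind, rings)
  j <- seq_len(n)
  jn <- c(seq_len(n)[-1], 1L)               # next theta index, wrapped
  fs <- vector("list", m - 1L)
  for (i in seq_len(m - 1L)) {
    a <- (i - 1L) * n + j                   # ring i
    b <- (i - 1L) * n + jn
    c_ <- i * n + j                         # ring i + 1
    d <- i * n + jn
    fs[[i]] <- rbind(cbind(a, b, c_), cbind(c_, b, d))
  }
  faces <- do.call(rbind, fs)
  lateral <- rep(TRUE, nrow(v))
  if (cap_ends) {
    c0 <- colMeans(rings[[1]])
    c1 <- colMeans(rings[[m]])
    i0 <- nrow(v) + 1L
    i1 <- nrow(v) + 2L
    v <- rbind(v, c0, c1)
    lateral <- c(lateral, FALSE, FALSE)
    bottom <- cbind(rep(i0, n), jn, j)                      # normal -z
    top <- cbind(rep(i1, n), (m - 1L) * n + j, (m - 1L) * n + jn)  # +z
    faces <- rbind(faces, bottom, top)
  }
  trimesh(v, faces, lateral)
}

#' Loft a stack of control ellipses into a triangle surface
#'
#' The lofting primitive behind the left-ventricle builder: consecutive
#' cross-sections, sampled on a shared azimuthal grid, are stitched with
#' triangle strips (vertex j of ring i connects to vertex j of ring i + 1,
#' no twist minimisation); optional fan caps to the section centroids close
#' the first and last section, yielding a watertight solid.
#'
#' For piecewise-linear radius profiles the enclosed volume of the capped
#' loft equals the polygon-corrected solid-of-revolution integral
#' `(n/2) sin(2 pi / n) * integral r(z)^2 dz` exactly, converging to
#' `pi * integral r(z)^2 dz` as `n_theta` grows.
#'
#' @param sections list of [ellipse_section()] objects, strictly ordered by
#'   increasing `z`; at least two.
#' @param n_theta azimuthal resolution (>= 8 vertices per ring).
#' @param cap_ends close both ends with centroid fans (default `TRUE`).
#' @return a [trimesh()]; watertight when capped.
#' @export
loft_ellipses <- function(sections, n_theta = 96, cap_ends = TRUE) {
  if (length(sections) < 2L)
    stop("loft_ellipses() needs at least 2 sections")
  if (!all(vapply(sections, inherits, TRUE, "ellipse_section")))
    stop("'sections' must be a list of ellipse_section objects")
  if (n_theta < 8L) stop("n_theta must be >= 8")
  z <- vapply(sections, `[[`, 0, "z")
  if (any(diff(z) <= 0))
    stop("section z-coordinates must be strictly increasing")
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  rings <- lapply(sections, .sample_section, theta = theta)
  .stitch_rings(rings, cap_ends = cap_ends)
}

#' Surface of revolution with an azimuthal bulge
#'
#' Revolves a planar (radius, z) polyline about +Z, adding a non-negative
#' radial increment `bulge(z, theta)` per vertex.  With `bulge = NULL` (or a
#' function returning 0) this is a plain surface of revolution.  The aortic
#' root uses a three-fold bulge to carve the sinuses of Valsalva.
#'
#' @param profile 2-column matrix (radius mm, z mm); radii > 0, z strictly
#'   increasing.
#' @param n_theta azimuthal resolution (>= 8).
#' @param bulge `function(z, theta)` returning a non-negative radial
#'   increment in mm, vectorised over `theta`; `NULL` for none.
#' @param n_z resample the polyline to about this many rings (linear
#'   interpolation; original profile z's are always kept).
#' @param extra_z additional axial stations forced into the ring grid.
#' @param cap_ends close ends with centroid fans (default `FALSE`: tubes).
#' @return a [trimesh()].
#' @export
revolve_with_bulge <- function(profile, n_theta = 96, bulge = NULL,
                               n_z = NULL, extra_z = NULL, cap_ends = FALSE) {
  profile <- as.matrix(profile)
  if (ncol(profile) != 2L || nrow(profile) < 2L)
    stop("'profile' must be a 2-column (radius, z) matrix with >= 2 rows")
  if (n_theta < 8L) stop("n_theta must be >= 8")
  r <- profile[, 1]; z <- profile[, 2]
  if (any(r <= 0)) stop("profile radii must be > 0")
  if (any(diff(z) <= 0)) stop("profile z must be strictly increasing")

  zs <- z
  if (!is.null(n_z) && n_z > length(z))
    zs <- union(zs, seq(min(z), max(z), length.out = n_z))
  if (!is.null(extra_z))
    zs <- union(zs, extra_z[extra_z >= min(z) & extra_z <= max(z)])
  zs <- sort(zs)
  rs <- stats::approx(z, r, xout = zs)$y

  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  rings <- vector("list", length(zs))
  for (i in seq_along(zs)) {
    inc <- if (is.null(bulge)) 0 else bulge(zs[i], theta)
    if (any(inc < -1e-12)) stop("bulge must be non-negative")
    rho <- rs[i] + inc
    if (any(rho <= 0)) stop("bulge produces non-positive radius")
    rings[[i]] <- cbind(rho * cos(theta), rho * sin(theta), zs[i])
  }
  .stitch_rings(rings, cap_ends = cap_ends)
}
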