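#' Aortic valve leaflet control parameters
#'
#' The four scalars that control a leaflet: `R` the aortic (annulus) radius,
#' `H` the leaflet height, `a` the curvature modifier of the generating
#' curve (`a = 0` is the straight-line limit), and `k` the free-edge shape
#' exponent (larger `k` flattens the free edge toward the commissures).
#' Units mm; `a` and `k` dimensionless.
#'
#' @param R aortic radius (mm, > 0).
#' @param H leaflet height (mm, > 0).
#' @param a curvature modifier (>= 0).
#' @param k free-edge shape exponent (> 0).
#' @return an object of class `"leaflet_params"`.
#' @export
leaflet_params <- function(R, H, a = 1, k = 2) {
  if (R <= 0) stop("R must be > 0")
  if (H <= 0) stop("H must be > 0")
  if (a < 0) stop("a must be >= 0")
  if (k <= 0) stop("k must be > 0")
  structure(list(R = R, H = H, a = a, k = k), class = "leaflet_params")
}

# physiological ranges per population (mm), used by root_params() and the
# cohort sampler/validator
.root_ranges <- function(population = c("adult", "child")) {
  population <- match.arg(population)
  if (population == "adult")
    list(annulus_radius = c(7.5, 15),      # aortic diameter 15-30 mm
         bulb_height = c(17, 25),
         sinus_height = c(17, 20),
         sinus_depth = c(1.5, 3))
  else
    list(annulus_radius = c(3, 10),        # aortic diameter 6-20 mm
         bulb_height = c(6, 14),
         sinus_height = c(6, 14),
         sinus_depth = c(1.5, 3))
}

#' Aortic root control parameters
#'
#' Cylinder radius and bulb height of the aortic root plus the axial height
#' and radial depth of the three sinuses of Valsalva.  Parameters are
#' checked against the physiological range of the chosen population
#' (adult: bulb height 17-25 mm, sinus height 17-20 mm, sinus depth
#' 1.5-3 mm, aortic diameter 15-30 mm; child: diameter 6-20 mm, bulb and
#' sinus height 6-14 mm).  Defaults are the adult range midpoints.
#'
#' @param annulus_radius root cylinder radius (mm).
#' @param bulb_height axial height of the bulb (mm).
#' @param sinus_height axial extent of the sinus pockets (mm).
#' @param sinus_depth maximal radial depth of a sinus pocket (mm).
#' @param population `"adult"` or `"child"`.
#' @param override skip the range check (out-of-range values error
#'   otherwise).
#' @return an object of class `"root_params"`.
#' @export
root_params <- function(annulus_radius = 11, bulb_height = 21,
                        sinus_height = 18.5, sinus_depth = 2.25,
                        population = c("adult", "child"),
                        override = FALSE) {
  population <- match.arg(population)
  p <- list(annulus_radius = annulus_radius, bulb_height = bulb_height,
            sinus_height = sinus_height, sinus_depth = sinus_depth)
  if (any(unlist(p) <= 0)) stop("root parameters must be > 0")
  if (!override) {
    rng <- .root_ranges(population)
    for (nm in names(rng)) {
      if (p[[nm]] < rng[[nm]][1] || p[[nm]] > rng[[nm]][2])
        stop(sprintf(
          "%s = %g mm outside %s range [%g, %g] (use override = TRUE)",
          nm, p[[nm]], population, rng[[nm]][1], rng[[nm]][2]))
    }
  }
  structure(c(p, list(population = population)), class = "root_params")
}

#' Leaflet generating curve
#'
#' The planar curve swept to form a leaflet:
#' `z(x) = H * log(1 + a (1 - x/R)) / log(1 + a)` on `x` in `[0, R]`, so the
#' free-edge midpoint sits at height `H` over the axis (`x = 0`) and the
#' wall attachment lies in the annulus plane (`z(R) = 0`).  `a` bends the
#' belly of the curve; as `a -> 0` the curve degenerates continuously to
#' the straight line `H (1 - x/R)`.
#'
#' @param params a [leaflet_params()].
#' @param n_samples number of points (>= 2), equally spaced in `x`.
#' @return 2-column matrix of (x, z) pairs from `x = 0` to `x = R`.
#' @export
generating_curve <- function(params, n_samples = 50) {
  stopifnot(inherits(params, "leaflet_params"))
  if (n_samples < 2L) stop("n_samples must be >= 2")
  x <- seq(0, params$R, length.out = n_samples)
  cbind(x = x, z = .gen_curve_z(x, params$R, params$H, params$a))
}

.gen_curve_z <- function(x, R, H, a) {
  u <- 1 - x / R
  if (a < 1e-8) H * u else H * log1p(a * u) / log1p(a)
}

#' Free-edge height profile across a leaflet sector
#'
#' Scale factor `f(theta) = 1 - (|theta|/Theta)^k` applied to the leaflet
#' height across the 120-degree sector: 1 at the sector midline, 0 at the
#' commissures (`theta = +/- Theta`).  Larger `k` keeps the edge high
#' (flatter) toward the commissures.
#'
#' @param k shape exponent (> 0).
#' @param theta sweep angle(s), radians, `|theta| <= Theta`.
#' @param Theta half-sector angle, radians (default 60 degrees: three equal
#'   sectors).
#' @return height scale(s) in `[0, 1]`.
#' @export
free_edge_profile <- function(k, theta, Theta = pi / 3) {
  if (k <= 0) stop("k must be > 0")
  if (any(abs(theta) > Theta + 1e-12))
    stop("|theta| must not exceed the half-sector angle")
  1 - (pmin(abs(theta) / Theta, 1))^k
}

#' Build one aortic valve leaflet surface
#'
#' Sweeps the generating curve over the sector `theta` in `[-60, 60]`
#' degrees about the valve axis (+Z): at azimuth `theta` the curve is
#' evaluated with effective height `H * f(theta)` (see
#' [free_edge_profile()]) and stretched radially from the axis (`x = 0`,
#' the free edge) to the annulus circle of radius `R` (the attachment
#' edge, at `z = 0`).  The result is an open zero-thickness midsurface.
#'
#' @param params a [leaflet_params()].
#' @param n_theta azimuthal resolution across the sector (>= 8).
#' @param n_radial radial resolution along the generating curve (>= 8).
#' @param sector_rotation rigid rotation of the finished leaflet about +Z
#'   (radians); the three leaflets of a valve use 0, 120 and 240 degrees.
#' @return an open [trimesh()].
#' @export
build_leaflet <- function(params, n_theta = 48, n_radial = 24,
                          sector_rotation = 0) {
  stopifnot(inherits(params, "leaflet_params"))
  if (n_theta < 8L || n_radial < 8L) stop("resolutions must be >= 8")
  Theta <- pi / 3
  th <- seq(-Theta, Theta, length.out = n_theta + 1L)
  x <- seq(0, params$R, length.out = n_radial + 1L)
  f <- free_edge_profile(params$k, th, Theta)
  base_z <- .gen_curve_z(x, params$R, params$H, params$a) / params$H

  nt <- length(th); nr <- length(x)
  # vertex grid: row-major over (theta, radial)
  X <- outer(cos(th), x)        # nt x nr radial coordinate in plane
  Y <- outer(sin(th), x)
  Z <- outer(params$H * f, base_z)
  v <- cbind(as.vector(X), as.vector(Y), as.vector(Z))
  idx <- function(i, j) (j - 1L) * nt + i   # column-major: j radial, i theta
  fs <- vector("list", nr - 1L)
  i <- seq_len(nt - 1L)
  for (j in seq_len(nr - 1L)) {
    a <- idx(i, j); b <- idx(i + 1L, j)
    c_ <- idx(i, j + 1L); d <- idx(i + 1L, j + 1L)
    fs[[j]] <- rbind(cbind(a, c_, b), cbind(b, c_, d))
  }
  m <- trimesh(v, do.call(rbind, fs))
  if (sector_rotation != 0)
    m <- mesh_transform(m, rotation_z(sector_rotation))
  m
}

#' Build the aortic root with three sinuses of Valsalva
#'
#' A cylinder of radius `annulus_radius` and height `bulb_height`, revolved
#' with the outward radial bulge
#' `sinus_depth * g(z) * max(0, cos(3 theta))^p`, where the axial window
#' `g(z) = sin^2(pi z / sinus_height)` is supported on `[0, sinus_height]`
#' with unit peak.  The three-fold azimuthal factor carves exactly three
#' sinus pockets; `p` (default 2) sharpens their azimuthal boundaries.
#'
#' @param params a [root_params()].
#' @param n_theta azimuthal resolution (>= 8).
#' @param n_z axial resolution (number of rings; the bulge peak station is
#'   always included).
#' @param p azimuthal sharpness exponent of the sinus bulge.
#' @return an open-tube [trimesh()].
#' @export
build_aortic_root <- function(params, n_theta = 96, n_z = 48, p = 2) {
  stopifnot(inherits(params, "root_params"))
  hs <- params$sinus_height
  bulge <- function(z, theta) {
    g <- if (z >= 0 && z <= hs) sin(pi * z / hs)^2 else 0
    params$sinus_depth * g * pmax(0, cos(3 * theta))^p
  }
  profile <- cbind(radius = c(params$annulus_radius, params$annulus_radius),
                   z = c(0, params$bulb_height))
  revolve_with_bulge(profile, n_theta = n_theta, bulge = bulge,
                     n_z = n_z, extra_z = hs / 2, cap_ends = FALSE)
}

#' Assemble a three-leaflet aortic valve
#'
#' The aortic root plus three identical leaflets at 120-degree spacing
#' about the valve axis.  The leaflet radius must match the root annulus
#' radius; set `rescale = TRUE` to rescale the leaflet parameters to the
#' root instead of erroring.
#'
#' @param leaflet a [leaflet_params()].
#' @param root a [root_params()].
#' @param rescale rescale leaflet `R` (and proportionally `H`) to the root
#'   annulus radius on mismatch.
#' @param n_theta,n_radial,n_z resolutions passed to the builders.
#' @return list of class `"valve_assembly"` with elements `root`
#'   (a [trimesh()]), `leaflets` (list of 3 [trimesh()]), `leaflet_params`,
#'   `root_params`.
#' @export
assemble_valve <- function(leaflet, root, rescale = FALSE,
                           n_theta = 48, n_radial = 24, n_z = 48) {
  stopifnot(inherits(leaflet, "leaflet_params"), inherits(root, "root_params"))
  if (abs(leaflet$R - root$annulus_radius) > 1e-9) {
    if (!rescale)
      stop(sprintf(
        "leaflet R = %g mm does not match root annulus radius %g mm (set rescale = TRUE)",
        leaflet$R, root$annulus_radius))
    s <- root$annulus_radius / leaflet$R
    leaflet <- leaflet_params(R = root$annulus_radius, H = leaflet$H * s,
                              a = leaflet$a, k = leaflet$k)
  }
  base <- build_leaflet(leaflet, n_theta = n_theta, n_radial = n_radial)
  leaflets <- lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(ang)
    mesh_transform(base, rotation_z(ang)))
  structure(
    list(root = build_aortic_root(root, n_theta = max(n_theta * 2, 96),
                                  n_z = n_z),
         leaflets = leaflets,
         leaflet_params = leaflet, root_params = root),
    class = "valve_assembly")
}

#' @export
print.valve_assembly <- function(x, ...) {
  cat(sprintf(
    "<valve_assembly: R = %g mm, H = %g mm, a = %g, k = %g, %s root>\n",
    x$leaflet_params$R, x$leaflet_params$H, x$leaflet_params$a,
    x$leaflet_params$k, x$root_params$population))
  invisible(x)
}
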