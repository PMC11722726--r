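#' Height family of left-ventricle models
#'
#' Affinely rescales the z-coordinates of the base profile to each target
#' height, leaving all radii and the wall offset untouched.  The default
#' heights are the seven levels of the shipped cohort, 73-89 mm.
#'
#' @param base an [lv_profile()] (default [default_profile()]).
#' @param heights target heights in mm.
#' @param n_theta,n_z mesh resolutions passed to [build_lv()].
#' @return list of [build_lv()] models, one per height.
#' @export
height_family <- function(base = default_profile(),
                          heights = c(73, 75, 77, 79, 82, 85, 89),
                          n_theta = 96, n_z = 64) {
  stopifnot(inherits(base, "lv_profile"))
  if (any(heights <= 0)) stop("heights must be > 0")
  lapply(heights, function(h) {
    s <- h / base$height
    secs <- lapply(base$sections, function(sec)
      ellipse_section(z = sec$z * s, ax = sec$ax, ay = sec$ay,
                      cx = sec$cx, cy = sec$cy))
    build_lv(lv_profile(secs, height = h, wall_offset = base$wall_offset),
             n_theta = n_theta, n_z = n_z)
  })
}

#' Wall-thickness family of left-ventricle models
#'
#' Replaces the wall offset of the base profile per level; the inner shell
#' is identical across the family.  The seven default offsets are
#' calibrated stand-ins bracketing the average outer radius of the shipped
#' cohort (about 30.5-32 mm).
#'
#' @param base an [lv_profile()].
#' @param offsets wall offsets in mm (> 0).
#' @inheritParams height_family
#' @return list of [build_lv()] models, one per offset.
#' @export
thickness_family <- function(base = default_profile(),
                             offsets = c(8.5, 9, 9.5, 9.75, 10.5, 11, 11.5),
                             n_theta = 96, n_z = 64) {
  stopifnot(inherits(base, "lv_profile"))
  if (any(offsets <= 0)) stop("offsets must be > 0")
  lapply(offsets, function(o)
    build_lv(lv_profile(base$sections, height = base$height, wall_offset = o),
             n_theta = n_theta, n_z = n_z))
}

# default shape-family edits: x-shifts of mid-ventricular section centers
# plus mild radius rescaling of the equatorial section.  Calibrated
# stand-ins (the published per-model edits are not recoverable); heights
# and wall offset are untouched.
.default_shape_edits <- function() {
  list(
    list(sections = 4:6, cx = 2.0,  scale_section = 5L, scale = 1.000),
    list(sections = 4:6, cx = -2.0, scale_section = 5L, scale = 1.012),
    list(sections = 3:6, cx = 3.0,  scale_section = 5L, scale = 0.992),
    list(sections = 4:7, cx = -3.0, scale_section = 5L, scale = 1.012),
    list(sections = 4:6, cx = 4.0,  scale_section = 5L, scale = 1.005),
    list(sections = 3:7, cx = 2.5,  scale_section = 5L, scale = 0.997),
    list(sections = 4:6, cx = -2.5, scale_section = 5L, scale = 0.985)
  )
}

#' Shape family of left-ventricle models
#'
#' Produces asymmetric variants of the base profile by shifting the centers
#' of selected control sections along the x-axis and rescaling selected
#' section radii, holding height and wall offset fixed.  Each edit is a
#' list with `sections` (indices to shift), `cx` (shift in mm), and
#' optionally `scale_section` + `scale` (radius rescale of one section).
#'
#' @param base an [lv_profile()].
#' @param edits list of edit sets; `NULL` for the seven shipped defaults.
#' @inheritParams height_family
#' @return list of [build_lv()] models, one per edit set.
#' @export
shape_family <- function(base = default_profile(), edits = NULL,
                         n_theta = 96, n_z = 64) {
  stopifnot(inherits(base, "lv_profile"))
  if (is.null(edits)) edits <- .default_shape_edits()
  lapply(edits, function(e) {
    secs <- base$sections
    for (i in e$sections) {
      if (i < 1L || i > length(secs)) stop("edit section index out of range")
      secs[[i]]$cx <- secs[[i]]$cx + e$cx
    }
    if (!is.null(e$scale_section)) {
      i <- e$scale_section
      if (secs[[i]]$ax * e$scale <= 0) stop("radius scale collapses a section")
      secs[[i]]$ax <- secs[[i]]$ax * e$scale
      secs[[i]]$ay <- secs[[i]]$ay * e$scale
    }
    build_lv(lv_profile(secs, height = base$height,
                        wall_offset = base$wall_offset),
             n_theta = n_theta, n_z = n_z)
  })
}

#' Build the default 22-model left-ventricle cohort
#'
#' One baseline model plus seven height variants (73-89 mm), seven
#' wall-thickness variants and seven shape variants, each measured with
#' [measure_lv()].  Fully deterministic: reruns are identical.
#'
#' @param n_theta,n_z mesh resolutions (defaults chosen so the whole cohort
#'   builds and measures in well under a minute).
#' @return list of class `"lv_cohort"` with `models` (22 [build_lv()]
#'   models) and `manifest` (data frame, one row per model with the Table-style
#'   columns: id, group, height, thickness min/max/avg, radius min/max/avg,
#'   cavity volume).
#' @export
build_default_cohort <- function(n_theta = 64, n_z = 48) {
  base <- default_profile()
  models <- c(
    list(build_lv(base, n_theta = n_theta, n_z = n_z)),
    height_family(base, n_theta = n_theta, n_z = n_z),
    thickness_family(base, n_theta = n_theta, n_z = n_z),
    shape_family(base, n_theta = n_theta, n_z = n_z)
  )
  groups <- c("original", rep("height", 7), rep("thickness", 7),
              rep("shape", 7))
  meas <- lapply(models, measure_lv)
  manifest <- data.frame(
    id = seq_along(models) - 1L,
    group = groups,
    height = vapply(meas, `[[`, 0, "height"),
    thickness_min = vapply(meas, `[[`, 0, "thickness_min"),
    thickness_max = vapply(meas, `[[`, 0, "thickness_max"),
    thickness_avg = vapply(meas, `[[`, 0, "thickness_avg"),
    radius_min = vapply(meas, `[[`, 0, "radius_min"),
    radius_max = vapply(meas, `[[`, 0, "radius_max"),
    radius_avg = vapply(meas, `[[`, 0, "radius_avg"),
    cavity_volume = vapply(meas, `[[`, 0, "cavity_volume"),
    stringsAsFactors = FALSE
  )
  structure(list(models = models, manifest = manifest), class = "lv_cohort")
}

#' @export
print.lv_cohort <- function(x, ...) {
  cat(sprintf("<lv_cohort: %d models (%s)>\n", length(x$models),
              paste(names(table(x$manifest$group)), collapse = ", ")))
  print(utils::head(x$manifest, 3))
  invisible(x)
}

#' Sample a seeded pseudo-random valve cohort
#'
#' Draws `n` valve parameter tuples uniformly within the physiological
#' ranges of the chosen population (aortic radius from the diameter range,
#' bulb height, sinus height, sinus depth; leaflet height and shape
#' controls).  The same seed always reproduces the same draw; the
#' generator name and seed are recorded in the result.
#'
#' @param n number of models (> 0).
#' @param seed integer RNG seed.
#' @param population `"adult"` or `"child"`.
#' @param leaflet_height_range leaflet height range in mm (default 8-14 mm
#'   adult, 5-12 mm child; patient leaflets do not exceed 14 mm).
#' @param a_range,k_range ranges for the curvature modifier and free-edge
#'   exponent.
#' @param common_weight optional probability of drawing the aortic diameter
#'   from its "commonly observed" sub-range (adult 20-23 mm, child
#'   7-13 mm) instead of the full range; `NULL` (default) samples the full
#'   range uniformly.
#' @return data frame of class `"valve_cohort"`, one row per model, with
#'   attributes `seed` and `generator`.
#' @export
sample_valve_cohort <- function(n, seed, population = c("adult", "child"),
                                leaflet_height_range = NULL,
                                a_range = c(0.2, 3), k_range = c(1, 4),
                                common_weight = NULL) {
  if (n <= 0) stop("n must be > 0")
  population <- match.arg(population)
  rng <- .root_ranges(population)
  if (is.null(leaflet_height_range))
    leaflet_height_range <- if (population == "adult") c(8, 14) else c(5, 12)
  common_diam <- if (population == "adult") c(20, 23) else c(7, 13)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")

  runif_rng <- function(r, m = n) stats::runif(m, r[1], r[2])
  radius <- runif_rng(rng$annulus_radius)
  if (!is.null(common_weight)) {
    use_common <- stats::runif(n) < common_weight
    radius[use_common] <- stats::runif(sum(use_common),
                                       common_diam[1] / 2, common_diam[2] / 2)
  }
  out <- data.frame(
    id = seq_len(n) - 1L,
    annulus_radius = radius,
    aortic_diameter = 2 * radius,
    bulb_height = runif_rng(rng$bulb_height),
    sinus_height = runif_rng(rng$sinus_height),
    sinus_depth = runif_rng(rng$sinus_depth),
    leaflet_height = runif_rng(leaflet_height_range),
    a = runif_rng(a_range),
    k = runif_rng(k_range),
    stringsAsFactors = FALSE
  )
  attr(out, "seed") <- seed
  attr(out, "generator") <- "Mersenne-Twister"
  attr(out, "population") <- population
  class(out) <- c("valve_cohort", class(out))
  out
}

# patient-envelope and design ranges used by validate_physiology()
.physio_ranges <- function(population) {
  root <- .root_ranges(population)
  list(
    lv_height = c(75, 85),          # patient LV heights, mm
    lv_thickness = c(8, 11),        # patient wall thickness, mm
    lv_radius = c(26, 31),          # patient LV radius, mm
    lv_volume = c(108, 140),        # patient cavity volume, mL
    aortic_diameter = root$annulus_radius * 2,
    bulb_height = root$bulb_height,
    sinus_height = root$sinus_height,
    sinus_depth = root$sinus_depth,
    leaflet_radius = c(0, 14),      # patient leaflets never exceeded 14 mm
    leaflet_height = c(0, 14)
  )
}

#' Validate measurements against physiological ranges
#'
#' Flags each supplied dimension as in or out of the physiological design
#' ranges and the patient envelope (left ventricle: height 75-85 mm, wall
#' 8-11 mm, radius 26-31 mm, cavity volume 108-140 mL; valve: leaflet
#' radius and height at most 14 mm; root dimensions per population).
#' Returns flags, never errors: out-of-range models are reported, not
#' rejected.  LV cavity volume is additionally given a 15 percent soft
#' margin (`volume_soft_ok`), the tolerance used for the shipped families.
#'
#' @param measurements named list or one-row data frame; recognised names:
#'   `height`, `thickness_avg` (or `thickness`), `radius_avg` (or
#'   `radius`), `cavity_volume`, `aortic_diameter`, `bulb_height`,
#'   `sinus_height`, `sinus_depth`, `leaflet_radius`, `leaflet_height`.
#'   Missing entries are skipped.
#' @param population `"adult"` or `"child"`.
#' @return named logical vector of in-range flags (`TRUE` = in range).
#' @export
validate_physiology <- function(measurements, population = c("adult", "child")) {
  population <- match.arg(population)
  m <- as.list(measurements)
  rng <- .physio_ranges(population)
  flag <- function(val, r) !is.null(val) && val >= r[1] && val <= r[2]
  out <- logical(0)
  pick <- function(...) {
    for (nm in c(...)) if (!is.null(m[[nm]])) return(m[[nm]])
    NULL
  }
  checks <- list(
    height_ok = list(pick("height", "lv_height"), rng$lv_height),
    thickness_ok = list(pick("thickness_avg", "thickness"), rng$lv_thickness),
    radius_ok = list(pick("radius_avg", "radius"), rng$lv_radius),
    volume_ok = list(pick("cavity_volume", "volume"), rng$lv_volume),
    aortic_diameter_ok = list(pick("aortic_diameter"), rng$aortic_diameter),
    bulb_height_ok = list(pick("bulb_height"), rng$bulb_height),
    sinus_height_ok = list(pick("sinus_height"), rng$sinus_height),
    sinus_depth_ok = list(pick("sinus_depth"), rng$sinus_depth),
    leaflet_radius_ok = list(pick("leaflet_radius", "annulus_radius"),
                             rng$leaflet_radius),
    leaflet_height_ok = list(pick("leaflet_height"), rng$leaflet_height)
  )
  for (nm in names(checks)) {
    val <- checks[[nm]][[1]]
    if (!is.null(val)) out[nm] <- flag(val, checks[[nm]][[2]])
  }
  vol <- pick("cavity_volume", "volume")
  if (!is.null(vol)) {
    soft <- rng$lv_volume * c(0.85, 1.15)
    out["volume_soft_ok"] <- vol >= soft[1] && vol <= soft[2]
  }
  out
}
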