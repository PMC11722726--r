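test_that("generating curve satisfies its boundary conditions and examples", {
  p <- leaflet_params(R = 12, H = 12, a = 1, k = 2)
  gc <- generating_curve(p, n_samples = 3)      # x = 0, 6, 12
  expect_equal(unname(gc[1, "z"]), 12)                  # free-edge midpoint at H
  expect_equal(unname(gc[3, "z"]), 0)                   # wall attachment at annulus
  expect_equal(unname(gc[2, "z"]), 12 * log(1.5) / log(2), tolerance = 1e-12)
})

test_that("generating curve degenerates continuously to the linear limit", {
  p <- leaflet_params(R = 10, H = 8, a = 1e-9, k = 2)
  gc <- generating_curve(p, n_samples = 41)
  lin <- 8 * (1 - gc[, "x"] / 10)
  expect_lt(max(abs(gc[, "z"] - lin)), 1e-6 * 8)
})

test_that("generating curve is monotone decreasing and bounded for a grid of a", {
  for (a in c(0, 0.3, 1, 5, 20)) {
    p <- leaflet_params(R = 11, H = 13, a = a, k = 2)
    z <- generating_curve(p, n_samples = 100)[, "z"]
    expect_true(all(diff(z) < 0))
    expect_true(all(z >= 0 & z <= 13))
  }
})

test_that("free-edge profile hits its anchors and scales with k", {
  Th <- pi / 3
  expect_equal(free_edge_profile(2, 0), 1)
  expect_equal(free_edge_profile(2, Th), 0)
  expect_equal(free_edge_profile(2, -Th), 0)
  expect_equal(free_edge_profile(1, Th / 2), 0.5)
  expect_equal(free_edge_profile(2, Th / 2), 0.75)
  expect_error(free_edge_profile(2, Th * 1.1), "half-sector")
  # larger k raises the edge at interior angles (finite differences)
  for (th in c(0.2, 0.6, 0.9)) {
    df <- free_edge_profile(2 + 1e-6, th) - free_edge_profile(2, th)
    expect_gt(df, 0)
  }
})

test_that("leaflet surface anchors: free-edge midpoint at H, commissures at 0", {
  p <- leaflet_params(R = 12, H = 10, a = 1, k = 2)
  leaf <- build_leaflet(p, n_theta = 48, n_radial = 24)
  expect_equal(max(leaf$vertices[, 3]), 10, tolerance = 1e-12)
  # commissure edges (theta = +/-60 deg) lie in the annulus plane
  ang <- atan2(leaf$vertices[, 2], leaf$vertices[, 1])
  comm <- abs(abs(ang) - pi / 3) < 1e-9 &
    sqrt(rowSums(leaf$vertices[, 1:2]^2)) > 1e-9
  expect_true(any(comm))
  expect_lt(max(abs(leaf$vertices[comm, 3])), 1e-12)
  # attachment edge on the cylinder of radius R
  rad <- sqrt(rowSums(leaf$vertices[, 1:2]^2))
  expect_equal(max(rad), 12, tolerance = 1e-12)
})

test_that("leaflet area grows monotonically with height", {
  areas <- vapply(c(8, 10, 12, 14), function(H) {
    leaf <- build_leaflet(leaflet_params(R = 12, H = H, a = 1, k = 2),
                          n_theta = 24, n_radial = 16)
    sum(cardiogen:::.face_areas(leaf))
  }, 0)
  expect_true(all(diff(areas) > 0))
})

test_that("aortic root reduces to a cylinder at zero sinus depth", {
  rp <- root_params(sinus_depth = 1e-9, override = TRUE)
  m <- build_aortic_root(rp, n_theta = 48, n_z = 12)
  rad <- sqrt(rowSums(m$vertices[, 1:2]^2))
  expect_equal(max(rad) - min(rad), 0, tolerance = 1e-8)
})

test_that("root with adult defaults has bulb height 21 and peak radius R + depth", {
  rp <- root_params()     # adult range midpoints
  m <- build_aortic_root(rp, n_theta = 96, n_z = 48)
  expect_equal(mesh_metrics(m, apex_exclude = 0)$height, 21)
  rad <- sqrt(rowSums(m$vertices[, 1:2]^2))
  expect_equal(max(rad), rp$annulus_radius + rp$sinus_depth,
               tolerance = 1e-12)
})

test_that("root parameters are validated per population", {
  expect_error(root_params(bulb_height = 30), "range")
  expect_silent(root_params(bulb_height = 30, override = TRUE))
  expect_error(root_params(annulus_radius = 12, population = "child"),
               "range")
  expect_silent(root_params(annulus_radius = 8, bulb_height = 10,
                            sinus_height = 10, sinus_depth = 2,
                            population = "child"))
})

test_that("valve assembly has three leaflets with exact 120-degree symmetry", {
  asm <- assemble_valve(leaflet_params(11, 11, a = 1.5, k = 2.5),
                        root_params())
  expect_length(asm$leaflets, 3L)
  for (i in 1:3) {
    rot <- mesh_transform(asm$leaflets[[i]], rotation_z(2 * pi / 3))
    nxt <- asm$leaflets[[if (i == 3) 1 else i + 1]]
    expect_lt(max(abs(rot$vertices - nxt$vertices)), 1e-9)
  }
})

test_that("assembly rejects a leaflet/root radius mismatch unless rescaled", {
  expect_error(assemble_valve(leaflet_params(10, 11), root_params(12)),
               "rescale")
  asm <- assemble_valve(leaflet_params(10, 11), root_params(12),
                        rescale = TRUE)
  expect_equal(asm$leaflet_params$R, 12)
  expect_equal(asm$leaflet_params$H, 11 * 1.2)   # proportional rescale
})
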