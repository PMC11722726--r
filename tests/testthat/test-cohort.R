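low <- list(n_theta = 32, n_z = 24)   # fast resolutions for family tests

test_that("height family hits the requested heights exactly, radii untouched", {
  fam <- height_family(n_theta = low$n_theta, n_z = low$n_z)
  h <- vapply(fam, function(m) measure_lv(m)$height, 0)
  expect_equal(h, c(73, 75, 77, 79, 82, 85, 89))
  rmax <- vapply(fam, function(m) measure_lv(m)$radius_max, 0)
  expect_equal(rmax, rep(37.5, 7))
  # cavity volume strictly increases with height at fixed radii
  vol <- vapply(fam, function(m) mesh_volume(m$inner), 0)
  expect_true(all(diff(vol[order(h)]) > 0))
  expect_equal(vol / vol[which(h == 73)], h / 73, tolerance = 1e-10)
})

test_that("height family at the base height reproduces the base model", {
  base <- build_lv(default_profile(), n_theta = low$n_theta, n_z = low$n_z)
  fam <- height_family(heights = 80, n_theta = low$n_theta, n_z = low$n_z)
  expect_equal(fam[[1]]$inner$vertices, base$inner$vertices)
  expect_equal(fam[[1]]$outer$vertices, base$outer$vertices)
})

test_that("thickness family: 7 default levels, radius_max monotone in offset", {
  fam <- thickness_family(n_theta = low$n_theta, n_z = low$n_z)
  expect_length(fam, 7L)
  offs <- c(8.5, 9, 9.5, 9.75, 10.5, 11, 11.5)
  rmax <- vapply(fam, function(m) measure_lv(m)$radius_max, 0)
  expect_equal(rmax, 27.5 + offs)
  expect_true(all(diff(rmax) > 0))
  # inner shell identical across the family
  expect_equal(fam[[1]]$inner$vertices, fam[[7]]$inner$vertices)
  # identity offset reproduces the base outer shell
  same <- thickness_family(offsets = 10, n_theta = low$n_theta, n_z = low$n_z)
  base <- build_lv(default_profile(), n_theta = low$n_theta, n_z = low$n_z)
  expect_equal(same[[1]]$outer$vertices, base$outer$vertices)
})

test_that("shape family shifts the cavity centroid and preserves height", {
  fam <- shape_family(n_theta = low$n_theta, n_z = low$n_z)
  expect_length(fam, 7L)
  h <- vapply(fam, function(m) measure_lv(m)$height, 0)
  expect_equal(h, rep(80, 7))
  # explicit +3 mm mid-section shift moves the cavity center of mass in +x
  shifted <- shape_family(edits = list(list(sections = 4:6, cx = 3)),
                          n_theta = low$n_theta, n_z = low$n_z)[[1]]
  expect_gt(mean(shifted$inner$vertices[, 1]), 0.5)
  # empty edit is the identity
  ident <- shape_family(edits = list(list(sections = integer(0), cx = 0)),
                        n_theta = low$n_theta, n_z = low$n_z)[[1]]
  base <- build_lv(default_profile(), n_theta = low$n_theta, n_z = low$n_z)
  expect_equal(ident$inner$vertices, base$inner$vertices)
})

test_that("default cohort is 22 models with a complete, deterministic manifest", {
  coh <- build_default_cohort(n_theta = 32, n_z = 24)
  expect_length(coh$models, 22L)
  expect_equal(nrow(coh$manifest), 22L)
  expect_equal(as.vector(table(coh$manifest$group)[c("original", "height",
                                                     "thickness", "shape")]),
               c(1L, 7L, 7L, 7L))
  expect_true(all(c("height", "thickness_min", "thickness_max",
                    "thickness_avg", "radius_min", "radius_max",
                    "radius_avg", "cavity_volume") %in%
                    names(coh$manifest)))
  coh2 <- build_default_cohort(n_theta = 32, n_z = 24)
  expect_identical(coh$manifest, coh2$manifest)
})

test_that("seeded valve cohort is reproducible and respects adult ranges", {
  a <- sample_valve_cohort(50, seed = 42)
  b <- sample_valve_cohort(50, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, sample_valve_cohort(50, seed = 43)))
  expect_true(all(a$aortic_diameter >= 15 & a$aortic_diameter <= 30))
  expect_true(all(a$sinus_depth >= 1.5 & a$sinus_depth <= 3))
  expect_true(all(a$bulb_height >= 17 & a$bulb_height <= 25))
  expect_true(all(a$leaflet_height <= 14))
  expect_equal(attr(a, "generator"), "Mersenne-Twister")
  expect_equal(attr(a, "seed"), 42)
})

test_that("child cohort ranges and the common-diameter mixture are honoured", {
  ch <- sample_valve_cohort(40, seed = 7, population = "child")
  expect_true(all(ch$aortic_diameter >= 6 & ch$aortic_diameter <= 20))
  expect_true(all(ch$bulb_height >= 6 & ch$bulb_height <= 14))
  mix <- sample_valve_cohort(200, seed = 7, common_weight = 1)
  expect_true(all(mix$aortic_diameter >= 20 & mix$aortic_diameter <= 23))
})

test_that("physiological validator flags out-of-range dimensions", {
  f <- validate_physiology(list(aortic_diameter = 31))
  expect_false(f[["aortic_diameter_ok"]])
  f <- validate_physiology(list(leaflet_radius = 13, leaflet_height = 12))
  expect_true(f[["leaflet_radius_ok"]])
  expect_true(f[["leaflet_height_ok"]])
  f <- validate_physiology(list(height = 80, cavity_volume = 124))
  expect_true(all(f))
})

test_that("every default-cohort model passes the soft cavity-volume check", {
  coh <- build_default_cohort(n_theta = 32, n_z = 24)
  ok <- vapply(seq_len(nrow(coh$manifest)), function(i)
    validate_physiology(as.list(coh$manifest[i, ]))[["volume_soft_ok"]],
    TRUE)
  expect_true(all(ok))
})
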