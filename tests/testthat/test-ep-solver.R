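test_that("assembled operator is symmetric, annihilates constants, reports dt", {
  cab <- cable_mesh(50, 0.5)
  op <- assemble_diffusion(cab, ep_params())
  n <- length(op$mass)
  expect_equal(max(abs(op$K - Matrix::t(op$K))), 0)
  expect_lt(max(abs(op$K %*% rep(1, n))), 1e-12)
  expect_gt(op$dt_stable, 0)
  # negative semidefinite: x' K x <= 0 for random x
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(n)
    expect_lte(as.numeric(t(x) %*% op$K %*% x), 1e-10)
  }
  # same properties on a surface mesh with anisotropic fibers
  lv <- build_lv(default_profile(), n_theta = 32, n_z = 20)
  opm <- assemble_diffusion(lv$outer, ep_params(d_ani = 2))
  expect_lt(max(abs(opm$K - Matrix::t(opm$K))), 1e-12)
  expect_lt(max(abs(opm$K %*% rep(1, length(opm$mass)))), 1e-10)
})

test_that("disconnected domains are rejected", {
  two <- mesh_merge(list(icosphere(5, 1), icosphere(5, 1, center = c(30, 0, 0))))
  expect_error(assemble_diffusion(two, ep_params()), "disconnected")
})

test_that("pure diffusion conserves the mass-weighted potential to 1e-10", {
  cab <- cable_mesh(100, 0.5)
  pd <- ep_params(c = 0)          # no excitation, r stays 0: diffusion only
  set.seed(11)
  phi0 <- runif(length(cab$x))
  op <- assemble_diffusion(cab, pd)
  s <- simulate_monodomain(cab, pd, T_end = 50, phi0 = phi0,
                           sample_dt = 50, op = op)
  m0 <- sum(op$mass * s$phi[, 1])
  m1 <- sum(op$mass * s$phi[, 2])
  expect_lt(abs(m1 - m0) / abs(m0), 1e-10)
})

test_that("an unstimulated tissue stays at the -80 mV resting potential", {
  cab <- cable_mesh(30, 1)
  s <- simulate_monodomain(cab, ep_params(), T_end = 50, sample_dt = 25)
  expect_true(all(s$phi == 0))
  expect_true(all(s$Phi == -80))
  expect_true(all(s$S_a == 0))
})

test_that("a stimulated cable activates end to end and fully repolarizes", {
  cab <- cable_mesh(100, 0.5)
  ph <- ep_params(t_alpha = 0)    # homogeneous time scale on the cable
  s <- simulate_monodomain(cab, ph, stimulus = default_stimulus(),
                           T_end = 900, sample_dt = 5)
  at <- activation_front(s)
  expect_true(all(!is.na(at)))                       # wave reached far end
  expect_true(all(diff(at[20:201]) > 0))             # travels monotonically
  final <- s$Phi[, ncol(s$Phi)]
  expect_lt(max(abs(final - (-80))), 2)              # within 2 mV of rest
  # peak potential near the printed physiological maximum
  expect_gt(max(s$Phi), 0)
  expect_lt(max(s$Phi), 25)
})

test_that("front speed scales as sqrt(d_iso): ratio 2 between d and 4d", {
  cab <- cable_mesh(100, 0.5)
  stim <- default_stimulus()
  run <- function(d) {
    pr <- ep_params(t_alpha = 0, d_iso = d)
    s <- simulate_monodomain(cab, pr, stimulus = stim,
                             T_end = if (d > 1) 200 else 350,
                             sample_dt = 0.5)
    at <- activation_front(s)
    w <- which(cab$x >= 20 & cab$x <= 80)
    1 / unname(coef(stats::lm(at[w] ~ cab$x[w]))[2])
  }
  ratio <- run(4) / run(1)
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("identical inputs give bit-identical trajectories", {
  cab <- cable_mesh(40, 1)
  s1 <- simulate_monodomain(cab, ep_params(), stimulus = default_stimulus(),
                            T_end = 60, sample_dt = 10)
  s2 <- simulate_monodomain(cab, ep_params(), stimulus = default_stimulus(),
                            T_end = 60, sample_dt = 10)
  expect_identical(s1$phi, s2$phi)
  expect_identical(s1$r, s2$r)
  expect_identical(s1$S_a, s2$S_a)
})

test_that("instability is detected and aborts with a diagnostic", {
  cab <- cable_mesh(40, 1)
  op <- assemble_diffusion(cab, ep_params())
  expect_warning(
    expect_error(
      simulate_monodomain(cab, ep_params(), stimulus = default_stimulus(),
                          T_end = 60, dt = 10 * op$dt_stable, op = op),
      "unstable"),
    "stability")
})

test_that("stretch above unity depolarizes resting tissue toward phi_s", {
  cab <- cable_mesh(30, 1)
  s <- simulate_monodomain(cab, ep_params(t_alpha = 0), T_end = 100,
                           sample_dt = 50, lambda_f = 1.1)
  # I_m = G_s (lambda-1)(phi - phi_s) < 0 at rest pushes phi upward
  expect_true(all(s$phi[, 2] > 0))
  s0 <- simulate_monodomain(cab, ep_params(t_alpha = 0), T_end = 100,
                            sample_dt = 50, lambda_f = 0.9)
  expect_true(all(s0$phi[, 2] == 0))                 # compression: gated off
})

test_that("apex-to-base time-scale heterogeneity shortens basal recovery", {
  # on a vertical cable the apex (top) has t_a = 0 and the base t_a = t_alpha,
  # so beta_t and with it the action-potential duration grows toward the apex
  cab <- cable_mesh(80, 1)
  pr <- ep_params()
  op <- assemble_diffusion(cab, pr)
  bt <- local_time_scale(activation_time(cab$x, 80, pr), pr)
  expect_equal(bt[1], pr$t_beta * (1 - pr$tau0))     # base, t_a = t_alpha
  expect_equal(bt[length(bt)], pr$t_beta)            # apex, t_a = 0
  expect_true(all(diff(bt) > 0))
})
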