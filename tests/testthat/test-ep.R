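p <- ep_params()

test_that("dimensionalization maps rest and peak to -80 and +20 mV", {
  expect_equal(dimensionalize_potential(0, p), -80)
  expect_equal(dimensionalize_potential(1, p), 20)
  expect_equal(dimensionalize_potential(0.5, p), -30)
  # affine and monotone
  phis <- seq(-0.2, 1.2, by = 0.1)
  expect_true(all(diff(dimensionalize_potential(phis, p)) > 0))
})

test_that("activation time and local time scale follow the apex-to-base law", {
  expect_equal(activation_time(80, 80, p), 0)     # apex activates first
  expect_equal(activation_time(0, 80, p), p$t_alpha)
  expect_error(activation_time(10, 0, p), "nonzero")
  # t_a = t0 leaves beta_t at its base value
  expect_equal(local_time_scale(p$t0, p), p$t_beta)
  expect_error(local_time_scale(1e6, p), "beta_t")
})

test_that("excitation current nullclines and the worked value hold", {
  expect_equal(electric_current(0, 0.7, p), 0)
  expect_equal(electric_current(p$alpha, 0, p), 0)
  expect_equal(electric_current(1, 0, p), 0)
  expect_equal(electric_current(0.5, 0, p), 8 * 0.5 * 0.35 * (-0.5))
})

test_that("recovery kinetics have the resting fixed point and worked values", {
  expect_equal(recovery_rate(0, 0, p), 0)
  expect_equal(recovery_rate(1, 0, p), 0.002 * (8 * 0.15))
  expect_equal(recovery_rate(0, 0.5, p),
               (0.002 + 0.2 * 0.5 / 0.3) * (-0.5), tolerance = 1e-12)
})

test_that("stretch current is gated by tension only", {
  expect_equal(stretch_current(1, 0.5, p), 0)
  expect_equal(stretch_current(0.9, 0.5, p), 0)      # compression: closed
  expect_equal(stretch_current(1.1, 0, ep_params(G_s = 1)),
               0.1 * (0 - 0.6), tolerance = 1e-12)
  expect_error(stretch_current(-1, 0, p), "lambda_f")
})

test_that("dimensional ionic current composes the nondimensional parts", {
  expect_equal(ionic_current(0, 0, 1, params = p), 0)
  i1 <- ionic_current(0.5, 0, 1, beta_t = 10, params = p)
  i2 <- ionic_current(0.5, 0, 1, beta_t = 20, params = p)
  expect_equal(i1 / i2, 2)
  expect_equal(i1, p$C_m * (p$beta_phi / 10) * (-0.7), tolerance = 1e-12)
})

test_that("delay function is a bounded monotone sigmoid with exact midpoint", {
  expect_equal(delay_function(-1e6, p), p$eps0)
  expect_equal(delay_function(1e6, p), p$eps1)
  expect_equal(delay_function(p$Phi_t, p),
               p$eps0 + (p$eps1 - p$eps0) * exp(-1), tolerance = 1e-12)
  Phis <- seq(-60, 40, by = 5)   # tail below -60 mV is flat at eps0 in doubles
  eps <- delay_function(Phis, p)
  expect_true(all(diff(eps) > 0))
  expect_true(all(eps >= p$eps0 & eps <= p$eps1))
})

test_that("active stress relaxes monotonically to k_T (Phi - Phi_r)", {
  expect_equal(active_stress_rate(p$Phi_r, 0, p), 0)
  target <- p$k_T * (20 - p$Phi_r)                  # 50 kPa at 20 mV
  Sa <- 0; dt <- 0.05
  gaps <- numeric(400)
  for (i in 1:400) {
    Sa <- Sa + dt * active_stress_rate(20, Sa, p)
    gaps[i] <- target - Sa
  }
  for (i in 1:7600) Sa <- Sa + dt * active_stress_rate(20, Sa, p)
  expect_true(all(diff(gaps) < 0) && all(gaps > 0))  # monotone approach
  expect_equal(Sa, target, tolerance = 1e-3)
  expect_equal(active_stress_rate(20, target, p), 0)
})

test_that("active stress tensor distributes S_a along the fiber frame", {
  fr <- fiber_frame(c(1, 0, 0), c(0, 1, 0))
  expect_equal(active_stress_tensor(diag(0, 3), 0, fr, p), diag(0, 3))
  pe <- ep_params(eta1 = 1, eta2 = 0, eta3 = 0)
  expect_equal(active_stress_tensor(diag(0, 3), 50, fr, pe),
               diag(c(50, 0, 0)))
  # eigenvalues of the added term are S_a * {eta1, eta2, eta3}
  add <- active_stress_tensor(diag(0, 3), 50, fr, p)
  expect_equal(sort(eigen(add, symmetric = TRUE)$values),
               sort(50 * c(p$eta1, p$eta2, p$eta3)))
  expect_equal(add, t(add))
  expect_error(fiber_frame(c(1, 0, 0), c(1, 0, 0)), "orthonormal")
})

test_that("conductivity tensor combines isotropic and fiber parts", {
  pe <- ep_params(d_iso = 1, d_ani = 2, C_m = 1, chi_m = 1)
  expect_equal(conductivity_tensor(c(1, 0, 0), pe), diag(c(3, 1, 1)))
  expect_error(conductivity_tensor(c(2, 0, 0), pe), "unit")
})
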