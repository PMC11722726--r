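#' Aliev-Panfilov monodomain model parameters
#'
#' Parameter set of the two-variable Aliev-Panfilov excitation model with
#' anisotropic monodomain conduction, apex-to-base activation-time
#' rescaling, stretch-induced current and active-stress dynamics.  The
#' potential scale and offset are fixed by the physiological resting and
#' peak potentials (-80 mV and +20 mV); the excitation/recovery constants
#' default to the canonical Aliev-Panfilov set; the remaining constants
#' are literature-standard calibration knobs.
#'
#' @param chi_m surface-to-volume ratio (1/mm; default 140).
#' @param C_m membrane capacitance (uF/mm^2; default 0.01).
#' @param d_iso,d_ani isotropic / fiber-aligned conductivity scalars
#'   (model units; effective diffusivities in mm^2/ms).
#' @param beta_phi potential scale (mV).
#' @param delta_phi potential offset (mV; the resting potential).
#' @param c excitation strength of the cubic current.
#' @param alpha excitation threshold.
#' @param b recovery threshold.
#' @param gamma recovery base rate.
#' @param mu1,mu2 recovery rate-modulation constants.
#' @param G_s stretch-activated channel conductance.
#' @param phi_s nondimensional stretch reversal potential.
#' @param t_alpha apex-to-base activation-time span (ms).
#' @param t_beta base time scale (ms).
#' @param tau0 activation-time correction weight.
#' @param t0,t1 activation-time window (ms), `t1 != t0`.
#' @param k_T contractility (kPa/mV).
#' @param Phi_r resting potential (mV).
#' @param eps0,eps1 bounds of the active-stress delay rate (1/ms),
#'   `eps1 >= eps0 > 0`.
#' @param zeta delay-function steepness (1/mV).
#' @param Phi_t delay-function threshold potential (mV).
#' @param eta1,eta2,eta3 active-stress weights along fiber, sheet and
#'   sheet-normal directions.
#' @return an object of class `"ep_params"`.
#' @export
ep_params <- function(chi_m = 140, C_m = 0.01,
                      d_iso = 1, d_ani = 0,
                      beta_phi = 100, delta_phi = -80,
                      c = 8, alpha = 0.15, b = 0.15,
                      gamma = 0.002, mu1 = 0.2, mu2 = 0.3,
                      G_s = 10, phi_s = 0.6,
                      t_alpha = 40, t_beta = 12.9, tau0 = 0.5,
                      t0 = 0, t1 = 40,
                      k_T = 0.5, Phi_r = -80,
                      eps0 = 0.02, eps1 = 0.1,
                      zeta = 0.1, Phi_t = -30,
                      eta1 = 1, eta2 = 0.4, eta3 = 0.2) {
  if (beta_phi <= 0) stop("beta_phi must be > 0")
  if (mu2 <= 0) stop("mu2 must be > 0")
  if (!(eps1 >= eps0 && eps0 > 0)) stop("need eps1 >= eps0 > 0")
  if (zeta <= 0) stop("zeta must be > 0")
  if (t1 == t0) stop("t1 must differ from t0")
  structure(as.list(environment()), class = "ep_params")
}

#' @export
print.ep_params <- function(x, ...) {
  cat(sprintf(
    paste0("<ep_params: potential %g..%g mV; c = %g, alpha = %g, b = %g;",
           " d_iso = %g, d_ani = %g; k_T = %g kPa/mV>\n"),
    x$delta_phi, x$delta_phi + x$beta_phi, x$c, x$alpha, x$b,
    x$d_iso, x$d_ani, x$k_T))
  invisible(x)
}

#' Dimensionalize the transmembrane potential
#'
#' Affine map `Phi = beta_phi * phi + delta_phi` from the nondimensional
#' potential (0 at rest, 1 fully excited) to millivolts; the defaults map
#' `[0, 1]` onto exactly `[-80, 20]` mV.
#'
#' @param phi nondimensional potential(s).
#' @param params an [ep_params()].
#' @return potential(s) in mV.
#' @export
dimensionalize_potential <- function(phi, params = ep_params()) {
  params$beta_phi * phi + params$delta_phi
}

#' Apex-to-base activation time and local time scale
#'
#' `activation_time()` gives the local activation time
#' `t_a = t_alpha * (1 - Z / Z_apex)` (zero at the apex, `t_alpha` at the
#' base, so regions that depolarize last repolarize first);
#' `local_time_scale()` converts it to the nondimensional-to-ms time scale
#' `beta_t = t_beta * (1 - tau0 * (t_a - t0) / (t1 - t0))`, which must stay
#' positive over the mesh.
#'
#' @param Z axial coordinate(s) measured from the base (mm).
#' @param Z_apex apex coordinate (mm, nonzero).
#' @param params an [ep_params()].
#' @return `activation_time()`: `t_a` in ms; `local_time_scale()`:
#'   `beta_t` in ms.
#' @export
activation_time <- function(Z, Z_apex, params = ep_params()) {
  if (Z_apex == 0) stop("Z_apex must be nonzero")
  params$t_alpha * (1 - Z / Z_apex)
}

#' @rdname activation_time
#' @param t_a activation time(s) in ms.
#' @export
local_time_scale <- function(t_a, params = ep_params()) {
  bt <- params$t_beta * (1 - params$tau0 * (t_a - params$t0) /
                           (params$t1 - params$t0))
  if (any(bt <= 0))
    stop("parameters yield a non-positive local time scale beta_t")
  bt
}

#' Aliev-Panfilov excitation current
#'
#' Cubic excitation plus recovery coupling:
#' `I_e = c * phi * (phi - alpha) * (phi - 1) + r * phi` (nondimensional).
#' Vanishes at rest (`phi = 0`, any `r`), at threshold (`phi = alpha`,
#' `r = 0`) and at full excitation (`phi = 1`, `r = 0`).
#'
#' @param phi nondimensional potential.
#' @param r recovery variable.
#' @param params an [ep_params()].
#' @return nondimensional current.
#' @export
electric_current <- function(phi, r, params = ep_params()) {
  params$c * phi * (phi - params$alpha) * (phi - 1) + r * phi
}

#' Recovery-variable rate
#'
#' `dr/dtau = (gamma + mu1 * r / (mu2 + phi)) *
#' (-r - c * phi * (phi - b - 1))`, the Aliev-Panfilov recovery kinetics
#' with potential-dependent rate modulation.
#'
#' @inheritParams electric_current
#' @return `dr/dtau` (nondimensional).
#' @export
recovery_rate <- function(phi, r, params = ep_params()) {
  (params$gamma + params$mu1 * r / (params$mu2 + phi)) *
    (-r - params$c * phi * (phi - params$b - 1))
}

#' Stretch-induced (mechano-electric) current
#'
#' Stretch-activated-channel current
#' `I_m = H(lambda_f - 1) * G_s * (lambda_f - 1) * (phi - phi_s)` where `H`
#' is the Heaviside tension gate: the channel conducts only under fiber
#' tension (`lambda_f > 1`), never in compression.
#'
#' @param lambda_f fiber stretch ratio (> 0; 1 = unstretched).
#' @param phi nondimensional potential.
#' @param params an [ep_params()].
#' @return nondimensional current.
#' @export
stretch_current <- function(lambda_f, phi, params = ep_params()) {
  if (any(lambda_f <= 0)) stop("lambda_f must be > 0")
  ifelse(lambda_f > 1,
         params$G_s * (lambda_f - 1) * (phi - params$phi_s),
         0)
}

#' Dimensional ionic current
#'
#' `I_ion = C_m * (beta_phi / beta_t) * (I_e + I_m)`: the nondimensional
#' excitation and stretch currents rescaled to match experimental potential
#' and activation-time values.
#'
#' @inheritParams electric_current
#' @param lambda_f fiber stretch ratio.
#' @param beta_t local time scale in ms (see [local_time_scale()]).
#' @return dimensional current density.
#' @export
ionic_current <- function(phi, r, lambda_f = 1, beta_t = NULL,
                          params = ep_params()) {
  if (is.null(beta_t)) beta_t <- params$t_beta
  if (any(beta_t <= 0)) stop("beta_t must be > 0")
  params$C_m * (params$beta_phi / beta_t) *
    (electric_current(phi, r, params) +
       stretch_current(lambda_f, phi, params))
}

#' Active-stress delay function
#'
#' Double-exponential (Gompertz) sigmoid
#' `epsilon(Phi) = eps0 + (eps1 - eps0) * exp(-exp(-zeta * (Phi - Phi_t)))`:
#' smooth, monotone increasing and bounded in `[eps0, eps1]`, governing how
#' fast the active stress tracks its potential-driven target.
#'
#' @param Phi dimensional potential (mV).
#' @param params an [ep_params()].
#' @return rate(s) in 1/ms, in `[eps0, eps1]`.
#' @export
delay_function <- function(Phi, params = ep_params()) {
  params$eps0 + (params$eps1 - params$eps0) *
    exp(-exp(-params$zeta * (Phi - params$Phi_t)))
}

#' Active-stress rate
#'
#' `dS_a/dt = epsilon(Phi) * (k_T * (Phi - Phi_r) - S_a)`: the active
#' stress relaxes at rate `epsilon(Phi)` toward the contractility-scaled
#' drive `k_T * (Phi - Phi_r)`, its steady state at constant potential.
#'
#' @param Phi dimensional potential (mV).
#' @param S_a active stress (kPa).
#' @param params an [ep_params()].
#' @return `dS_a/dt` in kPa/ms.
#' @export
active_stress_rate <- function(Phi, S_a, params = ep_params()) {
  delay_function(Phi, params) * (params$k_T * (Phi - params$Phi_r) - S_a)
}

#' Orthonormal fiber-sheet-normal triple
#'
#' @param a0 fiber direction.
#' @param s0 sheet direction.
#' @param n0 sheet-normal direction (default `a0 x s0`).
#' @return list of class `"fiber_frame"` with unit, mutually orthogonal
#'   `a0`, `s0`, `n0` (checked to 1e-6).
#' @export
fiber_frame <- function(a0, s0, n0 = NULL) {
  a0 <- as.numeric(a0); s0 <- as.numeric(s0)
  if (is.null(n0)) n0 <- c(a0[2] * s0[3] - a0[3] * s0[2],
                           a0[3] * s0[1] - a0[1] * s0[3],
                           a0[1] * s0[2] - a0[2] * s0[1])
  n0 <- as.numeric(n0)
  M <- rbind(a0, s0, n0)
  if (max(abs(M %*% t(M) - diag(3))) > 1e-6)
    stop("fiber triple must be orthonormal (to 1e-6)")
  structure(list(a0 = a0, s0 = s0, n0 = n0), class = "fiber_frame")
}

#' Add active stress to a second Piola-Kirchhoff tensor
#'
#' `S = S_passive + S_a * (eta1 a0 (x) a0 + eta2 s0 (x) s0 +
#' eta3 n0 (x) n0)`: the scalar active stress is distributed along the
#' fiber, sheet and sheet-normal directions in the proportions
#' `eta1 : eta2 : eta3`.  The added term is symmetric with eigenvalues
#' `S_a * {eta1, eta2, eta3}`.
#'
#' @param S_passive symmetric 3x3 passive stress tensor (kPa).
#' @param S_a scalar active stress (kPa).
#' @param fibers a [fiber_frame()].
#' @param params an [ep_params()].
#' @return symmetric 3x3 stress tensor (kPa).
#' @export
active_stress_tensor <- function(S_passive, S_a, fibers,
                                 params = ep_params()) {
  stopifnot(inherits(fibers, "fiber_frame"))
  S_passive <- as.matrix(S_passive)
  if (!isTRUE(all.equal(S_passive, t(S_passive), tolerance = 1e-8)))
    stop("S_passive must be symmetric")
  S_passive + S_a * (params$eta1 * tcrossprod(fibers$a0) +
                       params$eta2 * tcrossprod(fibers$s0) +
                       params$eta3 * tcrossprod(fibers$n0))
}

#' Monodomain conductivity tensor
#'
#' `D = (d_iso * C_m / chi_m) I + (d_ani * C_m / chi_m) a0 (x) a0`:
#' isotropic background conduction plus a fiber-aligned anisotropic part.
#'
#' @param a0 unit fiber direction.
#' @param params an [ep_params()].
#' @return symmetric 3x3 conductivity tensor.
#' @export
conductivity_tensor <- function(a0, params = ep_params()) {
  a0 <- as.numeric(a0)
  if (abs(sum(a0^2) - 1) > 1e-6) stop("a0 must be a unit vector")
  s <- params$C_m / params$chi_m
  s * (params$d_iso * diag(3) + params$d_ani * tcrossprod(a0))
}
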