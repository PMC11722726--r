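#' 1D cable domain for the monodomain solver
#'
#' A uniform 1D cable along +Z: the simplest conduction domain, used for
#' front-speed and repolarization studies where the analytic
#' reaction-diffusion scaling laws are available.
#'
#' @param length cable length (mm).
#' @param h node spacing (mm).
#' @return object of class `"cable_mesh"` with node coordinates `x`.
#' @export
cable_mesh <- function(length = 100, h = 0.5) {
  if (length <= 0 || h <= 0 || h > length) stop("invalid cable dimensions")
  structure(list(x = seq(0, length, by = h), h = h, length = length),
            class = "cable_mesh")
}

# default circumferential fiber field on a surface mesh: unit horizontal
# tangent z_hat x radial, per face (falls back to isotropic where undefined)
.default_fibers <- function(mesh) {
  ctr <- (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
            mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
            mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
  a <- cbind(-ctr[, 2], ctr[, 1], 0)
  nrm <- sqrt(rowSums(a^2))
  ok <- nrm > 1e-9
  a[ok, ] <- a[ok, ] / nrm[ok]
  a[!ok, ] <- 0
  a
}

#' Assemble the discrete monodomain diffusion operator
#'
#' Mass-lumped linear finite elements with zero-flux (natural) boundaries.
#' The effective diffusivity tensor is `d_iso I + d_ani a0 (x) a0`
#' (mm^2/ms) per element, with the fiber direction projected into each
#' triangle's plane on surface meshes; on a cable the fiber lies along the
#' cable so the scalar diffusivity is `d_iso + d_ani`.  The assembled
#' stiffness `K` is symmetric, negative semidefinite and annihilates
#' constant fields; the explicit-Euler stability bound
#' `dt < 2 / lambda_max(M^-1 (-K))` is estimated by power iteration and
#' reported as `dt_stable` (with a 0.9 safety factor).
#'
#' @param mesh a [trimesh()] or [cable_mesh()]; must be connected.
#' @param params an [ep_params()] (supplies `d_iso`, `d_ani`).
#' @param fibers per-element unit fiber directions: `NULL` for the default
#'   (circumferential on surface meshes, axial on cables), a single
#'   3-vector, or an `n_faces x 3` matrix.
#' @return object of class `"diffusion_operator"`: sparse `K`, lumped mass
#'   vector `mass`, node coordinates `coords`, `dt_stable`.
#' @export
assemble_diffusion <- function(mesh, params = ep_params(), fibers = NULL) {
  if (inherits(mesh, "cable_mesh")) {
    n <- length(mesh$x)
    h <- mesh$h
    d <- params$d_iso + params$d_ani
    i <- c(seq_len(n - 1L), 2:n, seq_len(n))
    j <- c(2:n, seq_len(n - 1L), seq_len(n))
    x <- c(rep(d / h, 2L * (n - 1L)), -c(1, rep(2, n - 2L), 1) * d / h)
    K <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
    mass <- c(h / 2, rep(h, n - 2L), h / 2)
    coords <- cbind(0, 0, mesh$x)
  } else if (inherits(mesh, "trimesh")) {
    V <- mesh$vertices
    F <- mesh$faces
    nf <- nrow(F)
    if (is.null(fibers)) fibers <- .default_fibers(mesh)
    if (is.null(dim(fibers))) fibers <- matrix(fibers, nf, 3, byrow = TRUE)
    p1 <- V[F[, 1], , drop = FALSE]
    p2 <- V[F[, 2], , drop = FALSE]
    p3 <- V[F[, 3], , drop = FALSE]
    N <- .cross_rows(p2 - p1, p3 - p1)
    nrmN <- sqrt(rowSums(N^2))
    if (any(nrmN < 1e-14)) stop("degenerate triangle in mesh")
    area <- nrmN / 2
    nhat <- N / nrmN
    # hat-function gradients: grad_i = nhat x e_i / (2 area), e_i opposite edge
    G1 <- .cross_rows(nhat, p3 - p2) / (2 * area)
    G2 <- .cross_rows(nhat, p1 - p3) / (2 * area)
    G3 <- .cross_rows(nhat, p2 - p1) / (2 * area)
    # in-plane fiber projection, renormalised where defined
    at <- fibers - nhat * rowSums(fibers * nhat)
    an <- sqrt(rowSums(at^2))
    ok <- an > 1e-8
    at[ok, ] <- at[ok, ] / an[ok]
    at[!ok, ] <- 0
    DG <- function(G) params$d_iso * G + params$d_ani * at * rowSums(G * at)
    Gs <- list(G1, G2, G3)
    DGs <- lapply(Gs, DG)
    ii <- jj <- xx <- vector("list", 9L)
    k <- 0L
    for (a in 1:3) for (b in 1:3) {
      k <- k + 1L
      ii[[k]] <- F[, a]; jj[[k]] <- F[, b]
      xx[[k]] <- -area * rowSums(Gs[[a]] * DGs[[b]])
    }
    K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                              x = unlist(xx), dims = rep(nrow(V), 2L))
    K <- (K + Matrix::t(K)) / 2
    mass <- numeric(nrow(V))
    for (a in 1:3) {
      tw <- tapply(area / 3, F[, a], sum)
      idx <- as.integer(names(tw))
      mass[idx] <- mass[idx] + tw
    }
    coords <- V
  } else stop("mesh must be a trimesh or cable_mesh")

  if (!.is_connected(K)) stop("mesh is disconnected")

  # power iteration for the largest eigenvalue of M^-1 (-K)
  n <- length(mass)
  v <- rep(1, n) + sin(seq_len(n))
  lam <- 0
  for (it in 1:60) {
    w <- as.numeric(-(K %*% v)) / mass
    lam_new <- sqrt(sum(w^2)) / sqrt(sum(v^2))
    v <- w / max(abs(w))
    if (abs(lam_new - lam) < 1e-8 * max(lam_new, 1)) { lam <- lam_new; break }
    lam <- lam_new
  }
  structure(list(K = K, mass = mass, coords = coords,
                 dt_stable = 0.9 * 2 / lam, lambda_max = lam),
            class = "diffusion_operator")
}

.cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.is_connected <- function(K) {
  n <- nrow(K)
  A <- K != 0
  reach <- logical(n)
  reach[1] <- TRUE
  repeat {
    new <- as.logical(A %*% reach) & !reach
    if (!any(new)) break
    reach <- reach | new
  }
  all(reach)
}

#' Explicit monodomain Aliev-Panfilov simulation
#'
#' Forward-Euler integration of the nondimensional potential `phi` and
#' recovery variable `r` on a mesh or cable, with the active stress `S_a`
#' co-integrated per node.  The update is
#' `dphi/dt = M^-1 K phi - (I_e + I_m) / beta_t + I_stim`,
#' `dr/dt = recovery_rate(phi, r) / beta_t`,
#' `dS_a/dt = epsilon(Phi) (k_T (Phi - Phi_r) - S_a)`,
#' where the local time scale `beta_t` follows the apex-to-base activation
#' time of each node's axial coordinate and the boundaries are no-flux.
#' The dimensional potential is `Phi = beta_phi * phi + delta_phi`.
#'
#' @param mesh a [trimesh()] or [cable_mesh()].
#' @param params an [ep_params()].
#' @param fibers per-element fiber directions (see [assemble_diffusion()]).
#' @param stimulus `NULL`, or a list with `nodes` (indices), `amplitude`
#'   (1/ms, added to `dphi/dt`), `duration` (ms) and optional `start` (ms).
#' @param T_end end time (ms).
#' @param dt time step (ms); `NULL` uses the operator's stability bound
#'   capped at 0.05 ms.
#' @param sample_dt sampling interval of the stored series (ms).
#' @param phi0,r0,Sa0 initial fields (scalars recycled; defaults 0).
#' @param lambda_f fiber stretch field (scalar or per node; default 1,
#'   mechanics decoupled, so the stretch current vanishes).
#' @param op optional precomputed [assemble_diffusion()] operator.
#' @return object of class `"ep_series"`: `times` (ms), matrices `phi`,
#'   `r`, `S_a`, `Phi` (nodes x samples), node `coords`, `dt` used.
#' @export
simulate_monodomain <- function(mesh, params = ep_params(), fibers = NULL,
                                stimulus = NULL, T_end = 100, dt = NULL,
                                sample_dt = 1, phi0 = 0, r0 = 0, Sa0 = 0,
                                lambda_f = 1, op = NULL) {
  if (is.null(op)) op <- assemble_diffusion(mesh, params, fibers)
  n <- length(op$mass)
  if (is.null(dt)) dt <- min(op$dt_stable, 0.05)
  if (dt > op$dt_stable)
    warning(sprintf("dt = %g ms exceeds the stability bound %g ms",
                    dt, op$dt_stable))
  Z <- op$coords[, 3]
  Z_apex <- max(Z)
  t_a <- if (Z_apex == 0) rep(0, n) else activation_time(Z, Z_apex, params)
  beta_t <- local_time_scale(t_a, params)

  phi <- rep_len(as.numeric(phi0), n)
  r <- rep_len(as.numeric(r0), n)
  Sa <- rep_len(as.numeric(Sa0), n)
  lambda_f <- rep_len(as.numeric(lambda_f), n)

  stim_vec <- numeric(n)
  stim_start <- 0; stim_end <- -1
  if (!is.null(stimulus)) {
    stim_vec[stimulus$nodes] <- stimulus$amplitude
    stim_start <- if (is.null(stimulus$start)) 0 else stimulus$start
    stim_end <- stim_start + stimulus$duration
  }

  sample_times <- seq(0, T_end, by = sample_dt)
  ns <- length(sample_times)
  PHI <- R <- SA <- matrix(NA_real_, n, ns)
  rec <- function(s) { PHI[, s] <<- phi; R[, s] <<- r; SA[, s] <<- Sa }
  rec(1L)
  next_s <- 2L

  K <- op$K; mass <- op$mass
  nsteps <- ceiling(T_end / dt)
  t <- 0
  tension <- lambda_f > 1
  for (step in seq_len(nsteps)) {
    Ie <- params$c * phi * (phi - params$alpha) * (phi - 1) + r * phi
    Im <- numeric(n)
    if (any(tension))
      Im[tension] <- params$G_s * (lambda_f[tension] - 1) *
        (phi[tension] - params$phi_s)
    diff_term <- as.numeric(K %*% phi) / mass
    dphi <- diff_term - (Ie + Im) / beta_t
    if (t >= stim_start && t < stim_end) dphi <- dphi + stim_vec
    dr <- (params$gamma + params$mu1 * r / (params$mu2 + phi)) *
      (-r - params$c * phi * (phi - params$b - 1)) / beta_t
    Phi <- params$beta_phi * phi + params$delta_phi
    dSa <- delay_function(Phi, params) *
      (params$k_T * (Phi - params$Phi_r) - Sa)
    phi <- phi + dt * dphi
    r <- r + dt * dr
    Sa <- Sa + dt * dSa
    t <- t + dt
    if (max(abs(phi)) > 2)
      stop(sprintf(
        "monodomain integration unstable at t = %.3f ms (|phi| > 2); reduce dt",
        t))
    while (next_s <= ns && sample_times[next_s] <= t + 1e-9) {
      rec(next_s); next_s <- next_s + 1L
    }
  }
  while (next_s <= ns) { rec(next_s); next_s <- next_s + 1L }
  structure(list(times = sample_times, phi = PHI, r = R, S_a = SA,
                 Phi = params$beta_phi * PHI + params$delta_phi,
                 coords = op$coords, dt = dt, params = params),
            class = "ep_series")
}

#' @export
print.ep_series <- function(x, ...) {
  cat(sprintf(
    "<ep_series: %d nodes, %d samples over %g ms (dt = %g ms)>\n",
    nrow(x$phi), ncol(x$phi), max(x$times), x$dt))
  cat(sprintf("  potential range %.1f .. %.1f mV\n",
              min(x$Phi, na.rm = TRUE), max(x$Phi, na.rm = TRUE)))
  invisible(x)
}

#' First activation time per node
#'
#' Linearly interpolated first upward crossing of `phi` through
#' `threshold`; `NA` for nodes never activated.  Used to measure conduction
#' front speed.
#'
#' @param series an `"ep_series"` from [simulate_monodomain()].
#' @param threshold nondimensional activation threshold (default 0.5).
#' @return numeric vector of activation times (ms) per node.
#' @export
activation_front <- function(series, threshold = 0.5) {
  stopifnot(inherits(series, "ep_series"))
  apply(series$phi, 1L, function(p) {
    above <- which(p >= threshold)
    if (length(above) == 0L) return(NA_real_)
    i <- above[1]
    if (i == 1L) return(series$times[1])
    t0 <- series$times[i - 1L]; t1 <- series$times[i]
    p0 <- p[i - 1L]; p1 <- p[i]
    t0 + (threshold - p0) / (p1 - p0) * (t1 - t0)
  })
}
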