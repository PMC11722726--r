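# shared fixture builders (everything generated in code)

unit_cube <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0, normal -z
    c(5, 6, 7), c(6, 8, 7),   # z = 1, normal +z
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6)    # x = 1
  )
  trimesh(v, f)
}

circle_sections <- function(r, z) {
  mapply(function(rr, zz) ellipse_section(z = zz, ax = rr), r, z,
         SIMPLIFY = FALSE)
}

# polygon-corrected solid-of-revolution volume of a piecewise-linear
# radius profile: (n/2) sin(2 pi / n) * integral r(z)^2 dz, the segment
# integral evaluated exactly
polygon_revolution_volume <- function(r, z, n_theta) {
  h <- diff(z)
  I <- sum(h * (r[-length(r)]^2 + r[-length(r)] * r[-1] + r[-1]^2) / 3)
  (n_theta / 2) * sin(2 * pi / n_theta) * I
}

default_stimulus <- function(nodes = 1:5) {
  list(nodes = nodes, amplitude = 1, duration = 1)
}
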