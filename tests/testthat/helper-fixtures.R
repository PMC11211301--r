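# Small fixtures shared across test files.

# odd-sized grid whose centre voxel sits exactly on the rotation axis
centered_grid <- function(n = 33L, nz = 9L, vox = 8) {
  voxel_grid(c(n, n, nz), vox)
}

# orbit data.frame with explicit angles/radii (bypasses auto-contouring)
fixed_orbit <- function(angles_deg, radius) {
  structure(data.frame(angle_deg = angles_deg,
                       head = 1L,
                       radius = rep_len(radius, length(angles_deg))),
            class = c("orbit_spec", "data.frame"))
}

# volume with random activity confined to the central third (stays inside
# the field of view under any rotation)
interior_random_volume <- function(grid, seed = 1) {
  withr::with_seed(seed, {
    v <- array(0, grid$n)
    idx <- lapply(grid$n, function(n) seq(floor(n / 3), ceiling(2 * n / 3)))
    v[idx[[1]], idx[[2]], idx[[3]]] <-
      runif(length(idx[[1]]) * length(idx[[2]]) * length(idx[[3]]))
    v
  })
}

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# Gaussian-blurred uniform ball: analytic profile and the RC it implies,
# via the erf-based closed form integrated radially (independent oracle).
blurred_ball_profile <- function(r, R, sigma) {
  ifelse(r < 1e-12,
         erf(R / (sigma * sqrt(2))) -
           sqrt(2 / pi) * (R / sigma) * exp(-R^2 / (2 * sigma^2)),
         0.5 * (erf((R + r) / (sigma * sqrt(2))) +
                  erf((R - r) / (sigma * sqrt(2)))) -
           sigma / (r * sqrt(2 * pi)) *
             (exp(-(r - R)^2 / (2 * sigma^2)) -
                exp(-(r + R)^2 / (2 * sigma^2))))
}

blurred_ball_rc_oracle <- function(R, sigma) {
  3 / R^3 * integrate(function(r) blurred_ball_profile(r, R, sigma) * r^2,
                      0, R, rel.tol = 1e-10)$value
}
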