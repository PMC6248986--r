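# Analytic phantoms and oracles shared across the test files. Everything is
# built in code; no binary fixtures.

# regular n-gon outline of a circle, optionally rotated by phase
circle_points <- function(r, n = 10, center = c(0, 0), phase = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n + phase
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# constant-radius cylinder annotation (polygonal cross-section)
cylinder_annotation <- function(r = 20, n_slices = 10, n_points = 10,
                                dz = 2.6, center = c(0, 0),
                                pore_id = "cyl", eye_id = "eye-1") {
  slices <- lapply(seq_len(n_slices), function(i) {
    slice_annotation(i, circle_points(r, n_points, center))
  })
  pore_annotation(pore_id, eye_id, slices, dz)
}

# linear-taper cone: radius r0 at the first slice shrinking linearly
cone_annotation <- function(r0 = 30, n_slices = 93, n_points = 60, dz = 2.6) {
  h <- n_slices * dz
  slices <- lapply(seq_len(n_slices), function(i) {
    z_mid <- (i - 0.5) * dz
    r <- r0 * (1 - z_mid / h)
    slice_annotation(i, circle_points(r, n_points))
  })
  pore_annotation("cone", "eye-1", slices, dz)
}

# analytic masks built by direct voxel-center tests
mask_from_indicator <- function(f, spacing, half_extent, pad = 4) {
  dims <- as.integer(ceiling(2 * half_extent / spacing) + 2 * pad)
  origin <- -dims * spacing / 2
  x <- origin[1] + (seq_len(dims[1]) - 0.5) * spacing[1]
  y <- origin[2] + (seq_len(dims[2]) - 0.5) * spacing[2]
  z <- origin[3] + (seq_len(dims[3]) - 0.5) * spacing[3]
  occ <- array(FALSE, dims)
  for (k in seq_len(dims[3])) {
    occ[, , k] <- outer(x, y, function(xx, yy) f(xx, yy, z[k]))
  }
  pore_mask(voxel_grid(spacing, origin, dims), occ)
}

ball_mask <- function(r = 20, spacing = c(1, 1, 2.6), center = c(0, 0, 0)) {
  mask_from_indicator(function(x, y, z) {
    (x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2 <= r^2
  }, spacing, rep(r + max(abs(center)), 3))
}

ellipsoid_mask <- function(a, b, c, spacing = c(0.5, 0.5, 0.5)) {
  mask_from_indicator(function(x, y, z) {
    (x / a)^2 + (y / b)^2 + (z / c)^2 <= 1
  }, spacing, c(a, b, c))
}

# midpoint-rule quadrature of the ellipsoid surface integral; converges to
# ~1e-6 relative at this resolution (independent of the mesh estimator)
ellipsoid_area_quadrature <- function(a, b, c, n_theta = 1000, n_phi = 2000) {
  th <- pi * (seq_len(n_theta) - 0.5) / n_theta
  ph <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
  g <- outer(th, ph, function(t, p) {
    sin(t) * sqrt((b * c * cos(p))^2 * sin(t)^2 +
                  (a * c * sin(p))^2 * sin(t)^2 + (a * b * cos(t))^2)
  })
  sum(g) * (pi / n_theta) * (2 * pi / n_phi)
}

# profile whose noiseless solid is an exact circular cylinder of radius r:
# axial equivalent semi-axis h*sqrt(5/3) gives a flat (q = 0) taper, and
# lateral equivalent semi-axes r*sqrt(5)/2 give base semi-axes exactly r
uniform_cylinder_profile <- function(r = 22, n_slices = 93, n_points = 10,
                                     dz = 2.6, seed = 1L) {
  h <- n_slices * dz / 2
  generator_profile(
    group_label = "normal", slices_per_pore = n_slices,
    points_per_slice = n_points, slice_interval_um = dz,
    semi_axis_means_um = c(h * sqrt(5 / 3), r * sqrt(5) / 2, r * sqrt(5) / 2),
    semi_axis_cv = c(0, 0, 0), tortuosity_amplitude_um = 0,
    roughness_amplitude_rel = 0, angular_jitter_deg = 0,
    radial_jitter_rel = 0, seed = seed)
}

# serialize an annotation for byte-level determinism comparisons
annotation_bytes <- function(a) serialize(a, NULL)
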