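test_that("cylinder annotations match their closed forms", {
  A <- polygon_area(circle_points(20, 10))
  ann <- cylinder_annotation(20, n_slices = 10, n_points = 10)
  expect_equal(average_cross_sectional_area(ann), A, tolerance = 1e-12)
  expect_equal(pore_volume(ann), A * 10 * 2.6, tolerance = 1e-12)
  # a pore spanning the full LC thickness has V_adj equal to its mean area
  expect_equal(adjusted_volume(pore_volume(ann), 10 * 2.6), A,
               tolerance = 1e-12)
  # single slice
  one <- cylinder_annotation(20, n_slices = 1, n_points = 10)
  expect_equal(pore_volume(one), A * 2.6, tolerance = 1e-12)
})

test_that("mean area of two slices with areas 100 and 200 is 150", {
  mk <- function(target, z) {
    # square with area `target`
    s <- sqrt(target) / 2
    slice_annotation(z, rbind(c(-s, -s), c(s, -s), c(s, s), c(-s, s)))
  }
  ann <- pore_annotation("p", "e", list(mk(100, 1), mk(200, 2)), 2.6)
  expect_equal(average_cross_sectional_area(ann), 150)
})

test_that("adjusted_volume rejects nonpositive thickness", {
  expect_error(adjusted_volume(100, 0), "positive")
  expect_error(adjusted_volume(100, -3), "positive")
})

test_that("cone volume matches the closed-form frustum sum and the analytic cone", {
  ann <- cone_annotation(r0 = 30, n_slices = 93, n_points = 60)
  v <- pore_volume(ann)
  # oracle: slab sum with exact circle areas at the same slice centers,
  # corrected for the inscribed 60-gon
  h <- 93 * 2.6
  z_mid <- (seq_len(93) - 0.5) * 2.6
  poly_factor <- 60 / (2 * pi) * sin(2 * pi / 60)
  oracle <- sum(pi * (30 * (1 - z_mid / h))^2) * 2.6 * poly_factor
  expect_equal(v, oracle, tolerance = 1e-9)
  expect_lt(abs(v - pi * 30^2 * h / 3) / (pi * 30^2 * h / 3), 0.02)
})

test_that("surface area of a digitized ball is within 3% of the sphere", {
  m <- ball_mask(20, c(1, 1, 2.6))
  expect_lt(abs(surface_area(m) / (4 * pi * 20^2) - 1), 0.03)
})

test_that("surface area of an anisotropically digitized box is within 3%", {
  m <- mask_from_indicator(function(x, y, z) {
    abs(x) <= 40 & abs(y) <= 40 & abs(z) <= 31.2
  }, c(1, 1, 2.6), c(40, 40, 31.2))
  true <- 2 * (80 * 80 + 80 * 62.4 + 80 * 62.4)
  expect_lt(abs(surface_area(m) / true - 1), 0.03)
})

test_that("surface area of an ellipsoid matches numerical quadrature within 2%", {
  a <- 35.2; b <- 9.8; c <- 6.2
  m <- ellipsoid_mask(a, b, c)
  oracle <- ellipsoid_area_quadrature(a, b, c)
  expect_lt(abs(surface_area(m) / oracle - 1), 0.02)
})

test_that("surface area is additive over disjoint components", {
  r1 <- 18; r2 <- 11
  sp <- c(1, 1, 2.6)
  two <- mask_from_indicator(function(x, y, z) {
    ((x + 25)^2 + y^2 + z^2 <= r1^2) | ((x - 30)^2 + y^2 + z^2 <= r2^2)
  }, sp, c(60, r1, r1))
  singles <- surface_area(ball_mask(r1, sp)) + surface_area(ball_mask(r2, sp))
  expect_equal(surface_area(two), singles, tolerance = 0.01)
})

test_that("true sphericity is 1 for an exact sphere and errors on bad input", {
  r <- 13.7
  expect_equal(true_sphericity(4 / 3 * pi * r^3, 4 * pi * r^2), 1,
               tolerance = 1e-12)
  expect_error(true_sphericity(0, 10), "positive")
  expect_error(true_sphericity(10, 0), "positive")
})

test_that("sphericity of the digitized ball is 1 within discretization tolerance", {
  m <- ball_mask(20, c(1, 1, 2.6))
  v <- sum(m$occupancy) * prod(m$grid$spacing)
  psi <- true_sphericity(v, surface_area(m))
  expect_lt(abs(psi - 1), 0.03)
})

test_that("principal values of a ball match r/sqrt(5) and the Monte-Carlo oracle", {
  r <- 20
  pv <- principal_values(ball_mask(r, c(1, 1, 2.6))) * 1000  # um
  expect_true(all(abs(pv / (r / sqrt(5)) - 1) < 0.02))
  # independent oracle: covariance of 1e6 uniform points in the ball
  set.seed(11)
  n <- 1e6
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2)) * r * runif(n)^(1 / 3)
  mc <- sqrt(eigen(cov(u), symmetric = TRUE, only.values = TRUE)$values)
  expect_true(all(abs(pv / mc - 1) < 0.02))
})

test_that("principal values are sorted and degenerate masks behave", {
  g <- voxel_grid(c(1, 1, 1), c(0, 0, 0), c(30, 5, 5))
  occ <- array(FALSE, c(30, 5, 5)); occ[, 3, 3] <- TRUE  # a line of voxels
  pv <- principal_values(pore_mask(g, occ))
  expect_true(pv[1] > 0)
  expect_equal(pv[2], 0, tolerance = 1e-12)
  expect_equal(pv[3], 0, tolerance = 1e-12)

  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_warning(
    pv1 <- principal_values(pore_mask(voxel_grid(c(1, 1, 1), c(0, 0, 0),
                                                 c(5, 5, 5)), one)),
    "single")
  expect_equal(pv1, c(0, 0, 0))

  empty <- pore_mask(voxel_grid(c(1, 1, 1), c(0, 0, 0), c(4, 4, 4)),
                     array(FALSE, c(4, 4, 4)))
  expect_error(principal_values(empty), "empty")
  expect_error(surface_area(empty), "empty")
})

test_that("metrics are scale-equivariant: s^2 area, s^3 volume, s P, invariant sphericity", {
  s <- 2
  base <- cylinder_annotation(12, n_slices = 21, n_points = 16, dz = 2.6)
  scaled_slices <- lapply(base$slices, function(sl) {
    slice_annotation(sl$z_index, sl$points * s)
  })
  scaled <- pore_annotation("cyl-s", "e", scaled_slices, 2.6 * s)
  eye1 <- eye_record("eye-1", "normal", 21 * 2.6, list(base))
  eye2 <- eye_record("e", "normal", 21 * 2.6 * s, list(scaled))
  m1 <- compute_pore_metrics(base, eye1, lateral_pitch_um = 0.8)
  m2 <- compute_pore_metrics(scaled, eye2, lateral_pitch_um = 0.8 * s)
  expect_equal(m2$mean_area_um2, s^2 * m1$mean_area_um2, tolerance = 1e-9)
  expect_equal(m2$volume_um3, s^3 * m1$volume_um3, tolerance = 1e-9)
  expect_equal(m2$p1_mm, s * m1$p1_mm, tolerance = 1e-6)
  expect_equal(m2$p2_mm, s * m1$p2_mm, tolerance = 1e-6)
  expect_equal(m2$sphericity, m1$sphericity, tolerance = 1e-6)
})

test_that("sphericity and principal values are rotation-invariant", {
  # exact under a 90-degree grid-aligned rotation of the mask
  m <- ellipsoid_mask(20, 12, 8, spacing = c(1, 1, 1))
  occ_rot <- aperm(m$occupancy, c(2, 1, 3))[rev(seq_len(dim(m$occupancy)[2])), , ]
  m_rot <- pore_mask(voxel_grid(c(1, 1, 1), m$grid$origin[c(2, 1, 3)],
                                dim(occ_rot)), occ_rot)
  # principal values are exact under the rotation; the meshed surface moves
  # only through the tetrahedral decomposition's diagonal orientation (< 1%)
  expect_equal(principal_values(m_rot), principal_values(m), tolerance = 1e-12)
  expect_equal(surface_area(m_rot), surface_area(m), tolerance = 0.01)

  # within 3% under an arbitrary in-plane rotation of the annotation
  set.seed(3)
  ann <- cylinder_annotation(15, n_slices = 15, n_points = 24)
  ann$slices <- lapply(ann$slices, function(sl) {
    slice_annotation(sl$z_index,
                     sl$points * rep(c(1.4, 0.8), each = nrow(sl$points)))
  })
  th <- 0.61
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- pore_annotation("r", "e", lapply(ann$slices, function(sl) {
    slice_annotation(sl$z_index, sl$points %*% t(R))
  }), 2.6)
  eye <- eye_record("eye-1", "normal", 15 * 2.6, list(ann))
  eye_r <- eye_record("e", "normal", 15 * 2.6, list(rot))
  m0 <- compute_pore_metrics(ann, eye, lateral_pitch_um = 0.7)
  m1 <- compute_pore_metrics(rot, eye_r, lateral_pitch_um = 0.7)
  expect_lt(abs(m1$sphericity / m0$sphericity - 1), 0.03)
  expect_lt(abs(m1$p1_mm / m0$p1_mm - 1), 0.03)
  expect_lt(abs(m1$p2_mm / m0$p2_mm - 1), 0.03)
  expect_lt(abs(m1$p3_mm / m0$p3_mm - 1), 0.03)
})

test_that("compute_pore_metrics is deterministic and bundles consistent fields", {
  ann <- cylinder_annotation(18, n_slices = 9, n_points = 12)
  eye <- eye_record("eye-1", "normal", 9 * 2.6, list(ann))
  m1 <- compute_pore_metrics(ann, eye)
  m2 <- compute_pore_metrics(ann, eye)
  expect_identical(m1, m2)
  expect_true(m1$p1_mm >= m1$p2_mm && m1$p2_mm >= m1$p3_mm)
  expect_equal(m1$adjusted_volume_um2,
               m1$volume_um3 / eye$lc_thickness_um, tolerance = 1e-12)
  expect_lt(m1$sphericity, 1)  # squat cylinder, not a ball
  expect_error(compute_pore_metrics(ann, eye_record("other", "normal", 100,
                                                    list(ann))),
               "belongs to eye")
})
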