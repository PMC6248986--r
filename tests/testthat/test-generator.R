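test_that("noiseless circular profile places every margin point exactly on the circle", {
  r <- 21.5
  prof <- uniform_cylinder_profile(r, n_slices = 93, n_points = 10)
  gp <- generate_pore(prof, seed = 4, truth = FALSE)
  for (s in gp$annotation$slices) {
    radii <- sqrt(rowSums(s$points^2))
    expect_equal(radii, rep(r, 10), tolerance = 1e-9)
  }
})

test_that("identical (profile, seed) gives byte-identical annotations", {
  prof <- generator_profile(seed = 9)
  g1 <- generate_pore(prof, seed = 9, truth = FALSE)
  g2 <- generate_pore(prof, seed = 9, truth = FALSE)
  expect_identical(annotation_bytes(g1$annotation),
                   annotation_bytes(g2$annotation))
  g3 <- generate_pore(prof, seed = 10, truth = FALSE)
  expect_false(identical(annotation_bytes(g1$annotation),
                         annotation_bytes(g3$annotation)))
})

test_that("the default pore carries over 900 margin points across ~90 slices", {
  prof <- generator_profile()
  gp <- generate_pore(prof, truth = FALSE)
  n_pts <- sum(vapply(gp$annotation$slices, function(s) nrow(s$points),
                      integer(1)))
  expect_equal(length(gp$annotation$slices), 93L)
  expect_equal(n_pts, 930L)
  expect_gt(n_pts, 900L)
})

test_that("margin points are strictly ordered by angle about the slice centroid", {
  prof <- generator_profile(seed = 2)
  gp <- generate_pore(prof, seed = 2, truth = FALSE)
  for (s in gp$annotation$slices[c(1, 20, 47, 93)]) {
    ctr <- colMeans(s$points)
    ang <- atan2(s$points[, 2] - ctr[2], s$points[, 1] - ctr[1])
    rot <- (ang - ang[1]) %% (2 * pi)
    expect_true(all(diff(rot) > 0))
  }
})

test_that("degenerate profiles are rejected with explicit messages", {
  expect_error(generator_profile(semi_axis_means_um = c(0, 30, 20)),
               "positive|degenerate")
  expect_error(generator_profile(roughness_amplitude_rel = 1.2), "\\[0, 1\\)")
  expect_error(generator_profile(points_per_slice = 2), ">= 3")
  expect_error(generator_profile(slices_per_pore = 0), ">= 1")
  # axial extent infeasible for the slice count: needs more spread than a rod
  expect_error(generator_profile(semi_axis_means_um = c(200, 30, 20)),
               "infeasible")
})

test_that("default two-group cohort has 4 + 4 eyes and 160 pores", {
  eyes <- generate_cohort(generator_profile("normal"),
                          generator_profile("glaucoma", seed = 2), seed = 5)
  expect_length(eyes, 8L)
  expect_equal(sum(vapply(eyes, function(e) length(e$pores), integer(1))),
               160L)
  expect_setequal(unique(vapply(eyes, function(e) e$group, character(1))),
                  c("normal", "glaucoma"))
  expect_true(all(vapply(eyes, function(e) e$lc_thickness_um > 0, logical(1))))
})

test_that("a 1-eye, 1-pore cohort yields a single annotation", {
  p <- generator_profile(n_eyes = 1, pores_per_eye = 1, seed = 3)
  eyes <- generate_cohort(p, generator_profile("glaucoma", n_eyes = 1,
                                               pores_per_eye = 1, seed = 3),
                          seed = 3)
  expect_length(eyes, 2L)
  expect_length(eyes[[1]]$pores, 1L)
})

test_that("the same master seed reproduces the whole cohort", {
  np <- generator_profile(n_eyes = 2, pores_per_eye = 3, seed = 1)
  gp <- generator_profile("glaucoma", n_eyes = 2, pores_per_eye = 3, seed = 1)
  c1 <- generate_cohort(np, gp, seed = 42)
  c2 <- generate_cohort(np, gp, seed = 42)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
})

test_that("pipeline volume approaches the ground-truth volume as slices increase", {
  # same physical solid (length 241.8 um) sampled with 23 vs 93 slices; many
  # margin points so the polygon chord bias does not mask the slab error, and
  # a mild taper (q = 0.5) whose area profile has non-zero end slopes so the
  # midpoint slab sum carries a genuine O(dz^2) error
  mk <- function(n_slices) {
    h <- 241.8 / 2
    generator_profile(
      slices_per_pore = n_slices, slice_interval_um = 241.8 / n_slices,
      points_per_slice = 360,
      semi_axis_means_um = c(h, 33, 21), semi_axis_cv = c(0, 0, 0),
      tortuosity_amplitude_um = 0, roughness_amplitude_rel = 0,
      angular_jitter_deg = 0, radial_jitter_rel = 0, seed = 1)
  }
  rel_err <- vapply(c(23L, 93L), function(n) {
    gp <- generate_pore(mk(n), seed = 1, truth = TRUE)
    abs(pore_volume(gp$annotation) / gp$truth$volume_um3 - 1)
  }, numeric(1))
  expect_lt(rel_err[2], rel_err[1])
  expect_lt(rel_err[2], 0.01)
})

test_that("ground-truth covariance matches the pipeline on a noiseless solid", {
  prof <- generator_profile(semi_axis_cv = c(0, 0, 0),
                            tortuosity_amplitude_um = 0,
                            roughness_amplitude_rel = 0,
                            angular_jitter_deg = 0, radial_jitter_rel = 0,
                            points_per_slice = 48, seed = 6)
  gp <- generate_pore(prof, seed = 6, truth = TRUE)
  expect_true(all(diff(gp$truth$cov_eigenvalues_um2) <= 0))  # sorted desc
  expect_gt(gp$truth$volume_um3, 0)
  mask <- rasterize_pore(gp$annotation, lateral_pitch_um = 1)
  pv <- principal_values(largest_component(mask, warn = FALSE)) * 1000
  expect_equal(pv, gp$truth$principal_values_mm * 1000, tolerance = 0.03)
})

test_that("increasing roughness strictly decreases measured mean sphericity", {
  psis <- vapply(c(0.05, 0.2, 0.35), function(rho) {
    prof <- generator_profile(roughness_amplitude_rel = rho,
                              semi_axis_cv = c(0, 0, 0), seed = 21)
    mean(vapply(1:3, function(i) {
      gp <- generate_pore(prof, seed = 100 + i, truth = FALSE)
      mask <- largest_component(rasterize_pore(gp$annotation,
                                               lateral_pitch_um = 1.25),
                                warn = FALSE)
      true_sphericity(pore_volume(gp$annotation), surface_area(mask))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(psis) < 0))
})
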