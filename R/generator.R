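# Synthetic annotated pore cohorts. A pore is modelled as a tortuous
# generalized cylinder: an elliptical base cross-section, tapered axially,
# modulated by low-order angular harmonics and a smooth axial radial wobble
# (both scaled by one roughness dial), swept along a wobbling centerline.
# Margin points emulate a human grader: ~10 per C-scan at roughly equal
# angles with angular and radial jitter.
#
# The three `semi_axis_means_um` are the *equivalent-ellipsoid* semi-axes of
# the noiseless solid: the generator shapes the axial taper and base ellipse
# so that the noiseless coordinate-covariance standard deviations equal
# semi_axis/sqrt(5) along each principal direction (the exact relation for a
# uniform ellipsoid). This makes the axes directly commensurate with the
# pipeline's principal values P1-P3.

#' Generator profile for one cohort group
#'
#' @param group_label `"normal"` or `"glaucoma"`.
#' @param n_eyes number of eyes in the group (default 4).
#' @param pores_per_eye pores annotated per eye (default 20).
#' @param slices_per_pore C-scan slices spanned by each pore (default 93).
#' @param slice_interval_um axial C-scan spacing in micrometres (default 2.6).
#' @param points_per_slice margin points marked per C-scan (default 10).
#' @param semi_axis_means_um length-3: equivalent-ellipsoid semi-axes
#'   (axial, lateral major, lateral minor) of the mean pore, in micrometres.
#' @param semi_axis_cv length-3 coefficient of variation of each semi-axis
#'   across pores (lognormal, unit mean).
#' @param tortuosity_amplitude_um lateral centerline wobble amplitude.
#' @param roughness_amplitude_rel relative radial boundary perturbation, the
#'   single dial coupling the angular harmonics and the axial radial wobble;
#'   drives sphericity downward. In `[0, 1)`.
#' @param angular_jitter_deg sd of the angular placement noise of margin
#'   points, degrees.
#' @param radial_jitter_rel sd of the relative radial placement noise.
#' @param lc_thickness_mean_um,lc_thickness_sd_um per-eye LC thickness
#'   distribution (normal, truncated at 100 um).
#' @param axial_wobble_wavelength_um center of the axial radial-scale wobble
#'   wavelength band, micrometres.
#' @param harmonic_orders integer angular harmonic orders; must stay below
#'   the Nyquist order `points_per_slice / 2`.
#' @param harmonic_coupling amplitude of the harmonics per unit roughness.
#' @param harmonic_twist_wavelength_um center of the axial wavelength band of
#'   the harmonic phase twist. The fast twist corrugates the surface
#'   helically while leaving per-slice area and the coordinate covariance
#'   nearly unchanged — it is the main surface-roughening mechanism, which
#'   is what lets sphericity calibrate independently of area and P1-P3.
#' @param seed integer default seed used when none is passed to the
#'   generating functions.
#' @return an object of class `lp_profile`.
#' @export
generator_profile <- function(group_label = c("normal", "glaucoma"),
                              n_eyes = 4L,
                              pores_per_eye = 20L,
                              slices_per_pore = 93L,
                              slice_interval_um = 2.6,
                              points_per_slice = 10L,
                              semi_axis_means_um = c(78.7, 33, 21),
                              semi_axis_cv = c(0.20, 0.18, 0.18),
                              tortuosity_amplitude_um = 5,
                              roughness_amplitude_rel = 0.30,
                              angular_jitter_deg = 4,
                              radial_jitter_rel = 0.03,
                              lc_thickness_mean_um = 242,
                              lc_thickness_sd_um = 25,
                              axial_wobble_wavelength_um = 10.4,
                              harmonic_orders = 2:4,
                              harmonic_coupling = 1.2,
                              harmonic_twist_wavelength_um = 24,
                              seed = 1L) {
  p <- structure(list(
    group_label = match.arg(group_label),
    n_eyes = as.integer(n_eyes),
    pores_per_eye = as.integer(pores_per_eye),
    slices_per_pore = as.integer(slices_per_pore),
    slice_interval_um = as.numeric(slice_interval_um),
    points_per_slice = as.integer(points_per_slice),
    semi_axis_means_um = as.numeric(semi_axis_means_um),
    semi_axis_cv = as.numeric(semi_axis_cv),
    tortuosity_amplitude_um = as.numeric(tortuosity_amplitude_um),
    roughness_amplitude_rel = as.numeric(roughness_amplitude_rel),
    angular_jitter_deg = as.numeric(angular_jitter_deg),
    radial_jitter_rel = as.numeric(radial_jitter_rel),
    lc_thickness_mean_um = as.numeric(lc_thickness_mean_um),
    lc_thickness_sd_um = as.numeric(lc_thickness_sd_um),
    axial_wobble_wavelength_um = as.numeric(axial_wobble_wavelength_um),
    harmonic_orders = as.integer(harmonic_orders),
    harmonic_coupling = as.numeric(harmonic_coupling),
    harmonic_twist_wavelength_um = as.numeric(harmonic_twist_wavelength_um),
    seed = as.integer(seed)), class = "lp_profile")
  validate_profile(p)
  p
}

validate_profile <- function(p) {
  stopifnot(inherits(p, "lp_profile"))
  with(p, {
    if (n_eyes < 1L || pores_per_eye < 1L) stop("counts must be >= 1")
    if (slices_per_pore < 1L) stop("slices_per_pore must be >= 1")
    if (points_per_slice < 3L) stop("points_per_slice must be >= 3")
    if (length(semi_axis_means_um) != 3L || any(semi_axis_means_um <= 0)) {
      stop("semi_axis_means_um must be 3 positive lengths; a zero axis gives ",
           "a degenerate (flat) pore")
    }
    if (length(semi_axis_cv) != 3L || any(semi_axis_cv < 0)) {
      stop("semi_axis_cv must be 3 non-negative values")
    }
    if (roughness_amplitude_rel < 0 || roughness_amplitude_rel >= 1) {
      stop("roughness_amplitude_rel must lie in [0, 1)")
    }
    if (slice_interval_um <= 0) stop("slice_interval_um must be positive")
    if (lc_thickness_mean_um <= 0 || lc_thickness_sd_um < 0) {
      stop("LC thickness parameters must be positive")
    }
    if (tortuosity_amplitude_um < 0 || angular_jitter_deg < 0 ||
        radial_jitter_rel < 0) {
      stop("noise amplitudes must be non-negative")
    }
    if (any(harmonic_orders >= points_per_slice / 2)) {
      stop("harmonic_orders must stay below the Nyquist order ",
           "points_per_slice / 2")
    }
  })
  # axial feasibility: the equivalent axial semi-axis cannot demand a larger
  # axial spread than a uniform rod of the pore's length provides
  geom <- profile_geometry(p)
  invisible(p)
}

#' @export
print.lp_profile <- function(x, ...) {
  cat(sprintf("<lp_profile> %s: %d eyes x %d pores, %d slices x %d points\n",
              x$group_label, x$n_eyes, x$pores_per_eye, x$slices_per_pore,
              x$points_per_slice))
  cat(sprintf("  semi-axes (%.1f, %.1f, %.1f) um, roughness %.3f, LC %.0f +/- %.0f um\n",
              x$semi_axis_means_um[1], x$semi_axis_means_um[2],
              x$semi_axis_means_um[3], x$roughness_amplitude_rel,
              x$lc_thickness_mean_um, x$lc_thickness_sd_um))
  invisible(x)
}

# mean of (1 - u^2)^p over u uniform on [-1, 1]
mom_g <- function(p) {
  exp(0.5 * log(pi) + lgamma(p + 1) - log(2) - lgamma(p + 1.5))
}

# Internal solid parameters from the equivalent-ellipsoid semi-axes:
# taper exponent q from the axial axis, base ellipse semi-axes from the
# lateral ones. Axial profile: cross-section scale g(u) = (1-u^2)^q, so the
# area weight is g^2 and the axial variance is h^2 / (4q + 3).
profile_geometry <- function(p, semi_axes = p$semi_axis_means_um) {
  h <- p$slices_per_pore * p$slice_interval_um / 2
  sigma_z <- semi_axes[1] / sqrt(5)
  ratio2 <- (h / sigma_z)^2
  if (ratio2 < 3 - 1e-9) {
    stop(sprintf(paste0("axial semi-axis %.1f um is infeasible for %d slices ",
                        "at %.2f um: the axial spread of the solid cannot ",
                        "exceed that of a uniform rod (max %.1f um)"),
                 semi_axes[1], p$slices_per_pore, p$slice_interval_um,
                 h / sqrt(3) * sqrt(5)))
  }
  q <- max(0, (ratio2 - 3) / 4)
  m2 <- mom_g(2 * q)
  m4 <- mom_g(4 * q)
  a0 <- 2 * (semi_axes[2] / sqrt(5)) / sqrt(m4 / m2)
  b0 <- 2 * (semi_axes[3] / sqrt(5)) / sqrt(m4 / m2)
  list(h = h, q = q, a0 = a0, b0 = b0, m2 = m2, m4 = m4)
}

ellipse_radius <- function(a, b, theta) {
  a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
}

# Deterministic sub-seed from (master seed, eye index, pore index); Lehmer-
# style mixing mod 2^31 - 1 keeps everything in exact double arithmetic and
# makes each pore's stream independent of generation order.
derive_seed <- function(master, eye_index, pore_index = 0L) {
  m <- 2147483647
  h <- (abs(as.numeric(master)) %% m)
  h <- (h * 48271 + as.numeric(eye_index) * 1299721 + 11) %% m
  h <- (h * 48271 + as.numeric(pore_index) * 7368787 + 17) %% m
  h <- (h * 48271 + 29) %% m
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate one synthetic pore annotation with its ground truth
#'
#' Draws one pore from the profile's shape distribution and samples its margin
#' points the way a human grader would (near-equal angles, angular and radial
#' jitter). Identical `(profile, seed)` yields identical output.
#'
#' @param profile an [generator_profile()].
#' @param seed integer seed for this pore's random stream (defaults to the
#'   profile seed).
#' @param center_um en-face position of the pore center, micrometres.
#' @param pore_id,eye_id identifiers stored in the annotation.
#' @param truth compute the [generator ground truth][generate_pore] (noiseless
#'   solid volume and covariance by high-resolution quadrature)? Adds ~50 ms.
#' @return a list with elements `annotation` (an [pore_annotation()]) and
#'   `truth` (a list with the true centerline, per-slice shape parameters,
#'   true volume and true covariance eigenvalues; `NULL` if `truth = FALSE`).
#' @export
generate_pore <- function(profile, seed = profile$seed, center_um = c(0, 0),
                          pore_id = "pore-1", eye_id = "eye-1", truth = TRUE) {
  validate_profile(profile)
  with_seed(seed, {
    n <- profile$slices_per_pore
    npts <- profile$points_per_slice
    dz <- profile$slice_interval_um
    L <- n * dz
    rho <- profile$roughness_amplitude_rel

    # per-pore semi-axis factors (lognormal, unit mean)
    f <- vapply(profile$semi_axis_cv, function(cv) lognormal_factor(1, cv),
                numeric(1))
    axes <- profile$semi_axis_means_um * f
    # keep the axial spread feasible for the fixed slice count (the bound
    # itself is the untapered cylinder, q = 0)
    h <- L / 2
    axes[1] <- min(axes[1], h / sqrt(3) * sqrt(5))
    geom <- profile_geometry(profile, semi_axes = axes)

    u <- ((seq_len(n) - 0.5) / n) * 2 - 1
    z <- u * h                                   # axial position, pore frame
    g <- pmax(1 - u^2, 0)^geom$q

    # smooth axial radial-scale wobble, unit RMS, band around the profile
    # wavelength; deliberately a minor component (0.5 rho) because scale
    # wobble inflates the area-weighted lateral covariance
    nk <- 6L
    lam <- profile$axial_wobble_wavelength_um * c(0.7, 0.85, 1, 1.2, 1.5, 1.9)
    wph <- runif(nk, 0, 2 * pi)
    W <- rowSums(vapply(seq_len(nk),
                        function(i) cos(2 * pi * z / lam[i] + wph[i]),
                        numeric(n))) / sqrt(nk / 2)
    s <- pmax(1 + 0.5 * rho * W, 0.15)

    # low-order angular harmonics twisting helically along z: the fast twist
    # corrugates the surface at near-constant per-slice area and covariance
    ords <- profile$harmonic_orders
    eps <- rho * profile$harmonic_coupling / sqrt(length(ords))
    hph <- runif(length(ords), 0, 2 * pi)
    twist <- sample(c(-1, 1), length(ords), replace = TRUE) * 2 * pi /
      runif(length(ords), 0.75 * profile$harmonic_twist_wavelength_um,
            1.25 * profile$harmonic_twist_wavelength_um)

    # wobbling centerline
    tph <- runif(2, 0, 2 * pi)
    tort <- profile$tortuosity_amplitude_um
    cx <- center_um[1] + tort * cos(2 * pi * z / L + tph[1])
    cy <- center_um[2] + tort * sin(1.3 * 2 * pi * z / L + tph[2])

    th0 <- 2 * pi * (seq_len(npts) - 1) / npts
    spacing <- 2 * pi / npts
    jitter_sd <- profile$angular_jitter_deg * pi / 180
    rmin_base <- 0.05 * min(geom$a0, geom$b0)

    slices <- vector("list", n)
    for (i in seq_len(n)) {
      jit <- pmin(pmax(rnorm(npts, 0, jitter_sd), -0.45 * spacing),
                  0.45 * spacing)
      th <- th0 + jit
      r <- ellipse_radius(geom$a0 * g[i], geom$b0 * g[i], th)
      modl <- rep(1, npts)
      for (m in seq_along(ords)) {
        modl <- modl + eps * cos(ords[m] * th + hph[m] + twist[m] * z[i])
      }
      rj <- 1 + profile$radial_jitter_rel * rnorm(npts)
      r <- pmax(r * s[i] * modl * pmax(rj, 0.1),
                rmin_base * g[i] + 1e-6)
      pts <- cbind(cx[i] + r * cos(th), cy[i] + r * sin(th))
      # points are at strictly increasing angle about the slice center with
      # positive radii, so the polygon is star-shaped (simple) and CCW by
      # construction; build the slice directly instead of re-validating
      slices[[i]] <- structure(list(z_index = i, points = unname(pts)),
                               class = "lp_slice")
    }
    ann <- pore_annotation(pore_id, eye_id, slices, dz)

    tr <- NULL
    if (truth) {
      tr <- pore_ground_truth(geom, s_fun = function(zz) {
        pmax(1 + rho * rowSums(vapply(seq_len(nk),
          function(i) cos(2 * pi * zz / lam[i] + wph[i]),
          numeric(length(zz)))) / sqrt(nk / 2), 0.15)
      }, harmonics = list(orders = ords, eps = eps, phase = hph,
                          twist = twist),
      center_fun = function(zz) {
        cbind(center_um[1] + tort * cos(2 * pi * zz / L + tph[1]),
              center_um[2] + tort * sin(1.3 * 2 * pi * zz / L + tph[2]))
      }, h = h, rmin_base = rmin_base)
      tr$centerline <- cbind(x = cx, y = cy, z = z)
      tr$axial_scale <- s
      tr$slice_semi_axes <- cbind(a = geom$a0 * g, b = geom$b0 * g)
    }
    list(annotation = ann, truth = tr)
  })
}

# High-resolution numeric ground truth of the continuous (noiseless-sampling)
# solid: volume and coordinate covariance via angular + axial quadrature.
pore_ground_truth <- function(geom, s_fun, harmonics, center_fun, h,
                              rmin_base, nz = 1201L, ntheta = 360L) {
  zz <- seq(-h, h, length.out = nz)
  uu <- zz / h
  gg <- pmax(1 - uu^2, 0)^geom$q
  ss <- s_fun(zz)
  ctr <- center_fun(zz)
  th <- 2 * pi * (seq_len(ntheta) - 0.5) / ntheta
  ct <- cos(th); st <- sin(th)
  ords <- harmonics$orders
  A <- Mx <- My <- Ixx <- Iyy <- Ixy <- numeric(nz)
  for (i in seq_len(nz)) {
    if (gg[i] <= 0) next
    r <- ellipse_radius(geom$a0 * gg[i], geom$b0 * gg[i], th)
    modl <- rep(1, ntheta)
    for (m in seq_along(ords)) {
      modl <- modl + harmonics$eps *
        cos(ords[m] * th + harmonics$phase[m] + harmonics$twist[m] * zz[i])
    }
    r <- pmax(r * ss[i] * modl, rmin_base * gg[i] + 1e-6)
    dth <- 2 * pi / ntheta
    A[i] <- sum(r^2) / 2 * dth
    Mx[i] <- sum(r^3 * ct) / 3 * dth
    My[i] <- sum(r^3 * st) / 3 * dth
    Ixx[i] <- sum(r^4 * ct^2) / 4 * dth
    Iyy[i] <- sum(r^4 * st^2) / 4 * dth
    Ixy[i] <- sum(r^4 * ct * st) / 4 * dth
  }
  wint <- function(v) {  # trapezoid along z
    sum((v[-1] + v[-nz]) / 2) * (zz[2] - zz[1])
  }
  V <- wint(A)
  N <- V
  mx <- wint(ctr[, 1] * A + Mx) / N
  my <- wint(ctr[, 2] * A + My) / N
  mz <- wint(zz * A) / N
  Sxx <- wint(Ixx + 2 * ctr[, 1] * Mx + ctr[, 1]^2 * A) / N - mx^2
  Syy <- wint(Iyy + 2 * ctr[, 2] * My + ctr[, 2]^2 * A) / N - my^2
  Szz <- wint(zz^2 * A) / N - mz^2
  Sxy <- wint(Ixy + ctr[, 1] * My + ctr[, 2] * Mx +
                ctr[, 1] * ctr[, 2] * A) / N - mx * my
  Sxz <- wint(zz * (ctr[, 1] * A + Mx)) / N - mx * mz
  Syz <- wint(zz * (ctr[, 2] * A + My)) / N - my * mz
  cov <- matrix(c(Sxx, Sxy, Sxz, Sxy, Syy, Syz, Sxz, Syz, Szz), 3, 3)
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  list(volume_um3 = V,
       cov_eigenvalues_um2 = ev,
       principal_values_mm = sqrt(pmax(ev, 0)) / 1000,
       mean_um = c(mx, my, mz))
}

#' Generate a two-group cohort of annotated eyes
#'
#' Produces `n_eyes` eyes per group, each with `pores_per_eye` pores laid out
#' on a jittered en-face grid, and an eye-level LC thickness drawn from the
#' profile distribution. Per-eye and per-pore sub-seeds are derived
#' deterministically from the master seed, so the cohort is reproducible and
#' independent of generation order.
#'
#' @param normal_profile,glaucoma_profile [generator_profile()] objects.
#' @param seed master integer seed (defaults to the normal profile's seed).
#' @param truth attach ground-truth sidecars to each pore (slower).
#' @return list of [eye_record()] objects (normals first); pore ground truths,
#'   when requested, are attached as the `"truth"` attribute of each eye's
#'   pore list entry.
#' @export
generate_cohort <- function(normal_profile, glaucoma_profile,
                            seed = normal_profile$seed, truth = FALSE) {
  validate_profile(normal_profile)
  validate_profile(glaucoma_profile)
  eyes <- list()
  for (gi in 1:2) {
    prof <- if (gi == 1) normal_profile else glaucoma_profile
    tag <- if (gi == 1) "N" else "G"
    for (e in seq_len(prof$n_eyes)) {
      eye_seed <- derive_seed(seed, (gi - 1) * 1000 + e, 0L)
      lc <- with_seed(eye_seed, {
        max(100, rnorm(1, prof$lc_thickness_mean_um, prof$lc_thickness_sd_um))
      })
      centers <- with_seed(eye_seed + 1L, pore_layout(prof$pores_per_eye))
      pores <- vector("list", prof$pores_per_eye)
      for (p in seq_len(prof$pores_per_eye)) {
        ps <- derive_seed(seed, (gi - 1) * 1000 + e, p)
        gp <- generate_pore(prof, seed = ps, center_um = centers[p, ],
                            pore_id = sprintf("%s%d-p%02d", tag, e, p),
                            eye_id = sprintf("%s%d", tag, e), truth = truth)
        ann <- gp$annotation
        if (truth) attr(ann, "truth") <- gp$truth
        pores[[p]] <- ann
      }
      eyes[[length(eyes) + 1L]] <-
        eye_record(sprintf("%s%d", tag, e), prof$group_label, lc, pores)
    }
  }
  eyes
}

# Jittered-grid en-face layout within a ~2.2 x 1.8 mm field: keeps the 20
# pores of an eye laterally separated, as in an en-face LC view.
pore_layout <- function(n) {
  ncol <- ceiling(sqrt(n * 2.2 / 1.8))
  nrow <- ceiling(n / ncol)
  cw <- 2200 / ncol; ch <- 1800 / nrow
  idx <- seq_len(n) - 1L
  gx <- (idx %% ncol) * cw - 1100 + cw / 2
  gy <- (idx %/% ncol) * ch - 900 + ch / 2
  cbind(gx + runif(n, -0.18, 0.18) * cw, gy + runif(n, -0.18, 0.18) * ch)
}
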