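test_that("exact Mann-Whitney matches full enumeration on 3 vs 3", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 0.1)
  # oracle: enumerate all C(6,3) = 20 group labelings of the pooled data and
  # double the smaller tail of the U_x permutation distribution
  pool <- 1:6
  labelings <- combn(6, 3)
  ux_stat <- function(xi) sum(rank(pool)[xi]) - 3 * 4 / 2
  us <- apply(labelings, 2, ux_stat)
  u_obs <- ux_stat(1:3)
  p_oracle <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
})

test_that("the exact null distribution matches dwilcox across sample sizes", {
  for (ns in list(c(3, 5), c(6, 6), c(4, 9))) {
    n1 <- ns[1]; n2 <- ns[2]
    for (u in c(0, 3, floor(n1 * n2 / 3))) {
      expect_equal(lcpore3d:::exact_u_cdf(u, n1, n2),
                   stats::pwilcox(u, n1, n2), tolerance = 1e-12)
    }
  }
})

test_that("identical samples give U = n^2/2 and p near 1", {
  x <- c(3.2, 5.5, 7.1, 9.4, 2.2)
  res <- mann_whitney_u(x, x)
  expect_equal(res$U, length(x)^2 / 2)
  expect_equal(res$method, "normal-approximation")  # ties force approximation
  expect_gt(res$p_value, 0.9)
  # fully constant data
  expect_equal(mann_whitney_u(rep(1, 4), rep(1, 6))$p_value, 1)
})

test_that("exact and approximate p agree within 0.01 for tie-free mid-size samples", {
  set.seed(19)
  for (i in 1:6) {
    n1 <- sample(8:20, 1); n2 <- sample(8:20, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, -1, 1))
    res <- mann_whitney_u(x, y)
    n <- n1 + n2
    sig <- sqrt(n1 * n2 * (n + 1) / 12)
    z <- (res$U - n1 * n2 / 2 + 0.5) / sig
    p_approx <- min(1, 2 * pnorm(z))
    if (res$method == "exact") {
      expect_lt(abs(res$p_value - p_approx), 0.01)
    }
    # and the package's exact p agrees with wilcox.test's
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    if (res$method == "exact") {
      expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
    }
  }
})

test_that("U is invariant under strictly monotone transforms", {
  set.seed(23)
  x <- rnorm(12); y <- rnorm(15, 0.7)
  u0 <- mann_whitney_u(x, y)$U
  for (f in list(function(v) exp(v), function(v) v^3,
                 function(v) atan(v) * 10 + 100)) {
    expect_equal(mann_whitney_u(f(x), f(y))$U, u0)
  }
})

test_that("empty samples are rejected", {
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
  expect_error(mann_whitney_u(1:3, numeric(0)), "non-empty")
})

test_that("compare_groups produces one comparison per parameter with means and flags", {
  set.seed(5)
  n <- 30
  met <- data.frame(
    eye_id = rep(c("N1", "G1"), each = n),
    group = rep(c("normal", "glaucoma"), each = n),
    pore_id = sprintf("p%02d", 1:(2 * n)),
    mean_area_um2 = c(rnorm(n, 1570, 100), rnorm(n, 1100, 100)),
    adjusted_volume_um2 = c(rnorm(n, 1590, 120), rnorm(n, 1175, 120)),
    sphericity = c(rnorm(n, 0.26, 0.01), rnorm(n, 0.282, 0.01)),
    p1_mm = c(rnorm(n, 0.035, 0.002), rnorm(n, 0.026, 0.002)),
    p2_mm = c(rnorm(n, 0.0098, 0.0008), rnorm(n, 0.0083, 0.0008)),
    p3_mm = c(rnorm(n, 0.0062, 0.0005), rnorm(n, 0.0052, 0.0005)))
  cmp <- compare_groups(met)
  expect_s3_class(cmp, "lp_comparison")
  expect_equal(nrow(cmp), 6L)
  expect_true(all(cmp$significant))
  expect_true(all(cmp$U >= 0 & cmp$U <= cmp$n_1 * cmp$n_2))
  expect_true(all(cmp$p_value > 0 & cmp$p_value <= 1))
  # eye-level aggregation collapses to one observation per eye
  cmp_eye <- compare_groups(met, by_eye = TRUE)
  expect_true(all(cmp_eye$n_1 == 1 & cmp_eye$n_2 == 1))
  expect_true(all(cmp_eye$method == "exact"))
  expect_true(all(cmp_eye$p_value == 1))  # 1 vs 1: U = 0, p = 2 * 1/2
  # single group is an error
  expect_error(compare_groups(met[met$group == "normal", ]), "single group")
})

test_that("type-I error of the pore-level comparison is near 0.05 under the null", {
  # both groups from one profile; annotation-only area path keeps 220
  # replicates affordable, and the tested comparison machinery is identical
  prof <- generator_profile(slices_per_pore = 31,
                            semi_axis_means_um = c(40, 33, 21), seed = 77)
  n_rep <- 220L
  n_per <- 15L
  rejections <- 0L
  for (rep in seq_len(n_rep)) {
    areas <- vapply(seq_len(2 * n_per), function(i) {
      gp <- generate_pore(prof, seed = lcpore3d:::derive_seed(77, rep, i),
                          truth = FALSE)
      average_cross_sectional_area(gp$annotation)
    }, numeric(1))
    p <- mann_whitney_u(areas[seq_len(n_per)],
                        areas[n_per + seq_len(n_per)])$p_value
    if (p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  # 95% binomial envelope around 0.05 for 220 replicates
  half <- 1.96 * sqrt(0.05 * 0.95 / n_rep)
  expect_gt(rate, 0.05 - half - 1e-9)
  expect_lt(rate, 0.05 + half + 1e-9)
})

test_that("comparison tables are written as CSV and Markdown", {
  met <- data.frame(
    eye_id = rep(c("N1", "G1"), each = 8),
    group = rep(c("normal", "glaucoma"), each = 8),
    pore_id = sprintf("p%02d", 1:16),
    mean_area_um2 = c(rnorm(8, 1500, 50), rnorm(8, 1100, 50)))
  cmp <- compare_groups(met, parameters = "mean_area_um2")
  csv <- tempfile(fileext = ".csv"); md <- tempfile(fileext = ".md")
  write_comparison(cmp, csv_path = csv, md_path = md)
  re <- read.csv(csv)
  expect_equal(nrow(re), 1L)
  expect_true(any(grepl("mean_area_um2", readLines(md))))
})
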