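test_that("quartile thresholds follow the linear-interpolation rule", {
  thr <- quartile_thresholds(1:8)
  expect_equal(unname(unclass(thr)), c(2.75, 4.5, 6.25))
  same <- quartile_thresholds(rep(7.5, 10))
  expect_equal(unname(unclass(same)), c(7.5, 7.5, 7.5))
  expect_error(quartile_thresholds(1:3), "at least 4")
})

test_that("160 distinct values split into 40/40/40/40 classes", {
  set.seed(13)
  vals <- sample(runif(160, 500, 2500))
  thr <- quartile_thresholds(vals)
  counts <- table(classify_severity(vals, thr))
  expect_equal(unname(c(counts)), rep(40L, 4L))
})

test_that("boundary values take the left-closed convention", {
  thr <- quartile_thresholds(1:8)  # Q1 2.75, Q2 4.5, Q3 6.25
  expect_equal(as.character(classify_severity(2.0, thr)), "severe")
  expect_equal(as.character(classify_severity(2.75, thr)), "moderate")
  expect_equal(as.character(classify_severity(4.5, thr)), "mild")  # exactly Q2
  expect_equal(as.character(classify_severity(6.25, thr)), "normal")
  expect_equal(as.character(classify_severity(7.0, thr)), "normal")
})

test_that("classification is monotone: smaller area is at least as severe", {
  set.seed(29)
  vals <- runif(50, 100, 3000)
  thr <- quartile_thresholds(vals)
  sev <- as.integer(classify_severity(sort(vals), thr))  # severe = 1 ... normal = 4
  expect_true(all(diff(sev) >= 0))
})

test_that("severity map labels every pore once and renders one color per class", {
  pores <- lapply(1:4, function(i) {
    cylinder_annotation(5 + 3 * i, n_slices = 3, n_points = 12,
                        center = c(i * 40, 0), pore_id = paste0("p", i),
                        eye_id = "E1")
  })
  eye <- eye_record("E1", "normal", 3 * 2.6, pores)
  met <- data.frame(eye_id = "E1", pore_id = paste0("p", 1:4),
                    mean_area_um2 = pi * (5 + 3 * (1:4))^2)
  map <- severity_map(eye, met, canvas_um = 200, pixel_um = 2)
  expect_equal(nrow(map$labels), 4L)
  expect_setequal(map$labels$label, c("severe", "moderate", "mild", "normal"))
  # four distinct fill colors present in the raster besides the background
  cols <- apply(matrix(map$raster, ncol = 3), 1, paste, collapse = ",")
  expect_equal(length(setdiff(unique(cols), "0.25,0.25,0.25")), 4L)
})

test_that("rendered maps are byte-identical for identical input", {
  pores <- lapply(1:4, function(i) {
    cylinder_annotation(8 + i, n_slices = 3, center = c(i * 30, -20),
                        pore_id = paste0("p", i), eye_id = "E1")
  })
  eye <- eye_record("E1", "normal", 3 * 2.6, pores)
  met <- data.frame(eye_id = "E1", pore_id = paste0("p", 1:4),
                    mean_area_um2 = pi * (8 + 1:4)^2)
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  write_severity_map(severity_map(eye, met, canvas_um = 150), f1,
                     tempfile(fileext = ".csv"))
  write_severity_map(severity_map(eye, met, canvas_um = 150), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("pores without metrics are reported by id", {
  pores <- list(cylinder_annotation(10, n_slices = 3, pore_id = "pX",
                                    eye_id = "E1"))
  eye <- eye_record("E1", "normal", 3 * 2.6, pores)
  met <- data.frame(eye_id = "E1", pore_id = "other",
                    mean_area_um2 = c(100, 200, 300, 400))
  expect_error(severity_map(eye, met), "pX")
})

test_that("an eye with smaller pores collects at least as many severe labels", {
  # two eyes against pooled thresholds; the small-pore eye must dominate the
  # severe class (oracle: direct count from the metrics table)
  set.seed(41)
  met <- data.frame(
    eye_id = rep(c("N1", "G1"), each = 20),
    pore_id = sprintf("p%02d", 1:40),
    mean_area_um2 = c(rnorm(20, 1570, 300), rnorm(20, 1100, 250)))
  thr <- quartile_thresholds(met$mean_area_um2)
  lab <- classify_severity(met$mean_area_um2, thr)
  n_sev <- tapply(lab == "severe", met$eye_id, sum)
  expect_gte(n_sev[["G1"]], n_sev[["N1"]])
})
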