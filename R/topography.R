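# Quartile severity classification and the en-face severity map. Pores are
# classed by their mean cross-sectional area: *smaller* pores are more severe
# (glaucomatous pores are smaller), so the first quartile is "severe" and the
# top quartile "normal". Display colors follow the severe=red, moderate=
# yellow, mild=green, normal=white convention.

severity_levels <- function() c("severe", "moderate", "mild", "normal")

severity_colors <- function() {
  c(severe = "#FF0000", moderate = "#FFFF00", mild = "#00CC00",
    normal = "#FFFFFF")
}

#' Quartile thresholds of pooled mean areas
#'
#' 25th/50th/75th percentiles of the pooled per-pore mean cross-sectional
#' areas, under the linear-interpolation quantile rule (R's default type 7),
#' so thresholds are reproducible.
#'
#' @param values numeric vector of mean areas (um^2), at least 4 values.
#' @return an object of class `lp_thresholds`: named numeric (Q1, Q2, Q3).
#' @export
quartile_thresholds <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L) {
    stop("at least 4 values are needed to form quartile thresholds")
  }
  if (anyNA(values)) stop("values must not contain NA")
  q <- quantile(values, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(setNames(q, c("Q1", "Q2", "Q3")), class = "lp_thresholds")
}

#' @export
print.lp_thresholds <- function(x, ...) {
  cat(sprintf("<lp_thresholds> Q1 = %.4g, Q2 = %.4g, Q3 = %.4g um^2\n",
              x[["Q1"]], x[["Q2"]], x[["Q3"]]))
  invisible(x)
}

#' Severity class of a pore
#'
#' Half-open intervals, left-closed on the less-severe side, so every value
#' gets exactly one class: severe if `A < Q1`, moderate if `Q1 <= A < Q2`,
#' mild if `Q2 <= A < Q3`, normal if `A >= Q3`.
#'
#' @param mean_area_um2 numeric vector of mean areas.
#' @param thresholds an [quartile_thresholds()] object.
#' @return factor with levels severe, moderate, mild, normal.
#' @export
classify_severity <- function(mean_area_um2, thresholds) {
  stopifnot(inherits(thresholds, "lp_thresholds"))
  a <- as.numeric(mean_area_um2)
  lab <- ifelse(a < thresholds[["Q1"]], "severe",
         ifelse(a < thresholds[["Q2"]], "moderate",
         ifelse(a < thresholds[["Q3"]], "mild", "normal")))
  factor(lab, levels = severity_levels())
}

#' Build a severity map for one eye
#'
#' Labels each of the eye's pores against (by default pooled-cohort)
#' thresholds and renders a deterministic en-face raster: each pore's
#' footprint (its mid-depth outline) filled in its class color over a neutral
#' dark background.
#'
#' @param eye an [eye_record()].
#' @param metrics the cohort metrics table ([compute_cohort_metrics()]);
#'   thresholds are computed from its pooled `mean_area_um2` unless given.
#' @param thresholds optional [quartile_thresholds()]; pass per-eye thresholds
#'   here to switch off cohort pooling.
#' @param canvas_um canvas half-extent in micrometres (the raster spans
#'   `[-canvas_um, canvas_um]` in x and y; default 1500, a 3 x 3 mm field).
#' @param pixel_um raster pixel size (default 5).
#' @return an object of class `lp_severity_map`: list with `thresholds`,
#'   `labels` (data.frame: pore_id, x_um, y_um, label, color) and `raster`
#'   (H x W x 3 rgb array on the unit interval).
#' @export
severity_map <- function(eye, metrics, thresholds = NULL, canvas_um = 1500,
                         pixel_um = 5) {
  stopifnot(inherits(eye, "lp_eye"), is.data.frame(metrics))
  if (is.null(thresholds)) {
    thresholds <- quartile_thresholds(metrics$mean_area_um2)
  }
  stopifnot(inherits(thresholds, "lp_thresholds"))
  met <- metrics[metrics$eye_id == eye$eye_id, , drop = FALSE]
  ids <- vapply(eye$pores, function(p) p$pore_id, character(1))
  missing <- setdiff(ids, met$pore_id)
  if (length(missing) > 0) {
    stop("no metrics (hence no centroid) for pores: ",
         paste(missing, collapse = ", "))
  }
  n <- floor(2 * canvas_um / pixel_um)
  canvas <- array(0.25, c(n, n, 3))  # neutral dark background
  rows <- list()
  for (p in eye$pores) {
    mid <- p$slices[[ceiling(n_slices(p) / 2)]]
    ctr <- polygon_centroid(mid$points)
    a <- met$mean_area_um2[met$pore_id == p$pore_id][1]
    lab <- as.character(classify_severity(a, thresholds))
    col <- severity_colors()[[lab]]
    rgb <- grDevices::col2rgb(col)[, 1] / 255
    fill <- .fill_polygon_cpp(mid$points, -canvas_um, -canvas_um,
                              pixel_um, pixel_um, n, n)
    for (ch in 1:3) {
      plane <- canvas[, , ch]
      plane[fill] <- rgb[ch]
      canvas[, , ch] <- plane
    }
    rows[[length(rows) + 1L]] <- data.frame(
      pore_id = p$pore_id, x_um = ctr[1], y_um = ctr[2], label = lab,
      color = col, stringsAsFactors = FALSE)
  }
  structure(list(eye_id = eye$eye_id, thresholds = thresholds,
                 labels = do.call(rbind, rows), raster = canvas,
                 pixel_um = pixel_um, canvas_um = canvas_um),
            class = "lp_severity_map")
}

#' @export
print.lp_severity_map <- function(x, ...) {
  cat(sprintf("<lp_severity_map> eye %s: %d pores\n", x$eye_id,
              nrow(x$labels)))
  print(table(factor(x$labels$label, levels = severity_levels())))
  invisible(x)
}

#' Write a severity map to PNG and CSV
#'
#' The PNG is written deterministically (identical input gives identical
#' bytes); the CSV holds one row per pore: pore_id, x_um, y_um, label, color.
#'
#' @param map an [severity_map()].
#' @param png_path,csv_path output paths; `NULL` skips that file.
#' @return invisibly, the map.
#' @export
write_severity_map <- function(map, png_path = NULL, csv_path = NULL) {
  stopifnot(inherits(map, "lp_severity_map"))
  if (!is.null(png_path)) {
    # image convention: row 1 is the top of the picture (largest y)
    img <- aperm(map$raster, c(2, 1, 3))[dim(map$raster)[2]:1, , ]
    png::writePNG(img, png_path)
  }
  if (!is.null(csv_path)) {
    write.csv(map$labels, csv_path, row.names = FALSE)
  }
  invisible(map)
}
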