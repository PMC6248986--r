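# Annotation containers: the pipeline's primary input. One pore is a stack of
# per-C-scan margin-point outlines at a fixed axial interval (default 2.6 um,
# the C-scan spacing of the source volumes).

#' Single C-scan outline of a pore
#'
#' @param z_index integer slice index within the C-scan stack.
#' @param points numeric matrix (x, y) of margin points in micrometres;
#'   at least 3 non-collinear points. Points are ordered counter-clockwise
#'   (via [order_margin_points()]) on construction.
#' @return an object of class `lp_slice`.
#' @export
slice_annotation <- function(z_index, points) {
  stopifnot(length(z_index) == 1L, is.finite(z_index), z_index == round(z_index))
  pts <- order_margin_points(points)
  structure(list(z_index = as.integer(z_index), points = pts),
            class = "lp_slice")
}

#' Pore annotation: a stack of C-scan outlines
#'
#' @param pore_id,eye_id character identifiers.
#' @param slices list of [slice_annotation()] objects with strictly increasing,
#'   contiguous `z_index`.
#' @param slice_interval_um axial distance between consecutive C-scans, in
#'   micrometres (default 2.6).
#' @return an object of class `lp_annotation`.
#' @export
pore_annotation <- function(pore_id, eye_id, slices, slice_interval_um = 2.6) {
  stopifnot(is.list(slices), length(slices) >= 1L,
            is.numeric(slice_interval_um), slice_interval_um > 0)
  ok <- vapply(slices, inherits, logical(1), "lp_slice")
  if (!all(ok)) stop("slices must all be slice_annotation() objects")
  z <- vapply(slices, function(s) s$z_index, integer(1))
  if (length(z) > 1L && !all(diff(z) == 1L)) {
    stop("slice z_indices must be strictly increasing and contiguous; got gaps at ",
         paste(z[which(diff(z) != 1L)], collapse = ", "))
  }
  structure(list(pore_id = as.character(pore_id),
                 eye_id = as.character(eye_id),
                 slice_interval_um = as.numeric(slice_interval_um),
                 slices = slices[order(z)]),
            class = "lp_annotation")
}

#' @export
print.lp_annotation <- function(x, ...) {
  npts <- sum(vapply(x$slices, function(s) nrow(s$points), integer(1)))
  cat(sprintf("<lp_annotation> pore %s (eye %s): %d slices at %.3g um, %d margin points\n",
              x$pore_id, x$eye_id, length(x$slices), x$slice_interval_um, npts))
  invisible(x)
}

n_slices <- function(annotation) length(annotation$slices)

annotation_z_range_um <- function(a) {
  z <- vapply(a$slices, function(s) s$z_index, integer(1))
  range(z) * a$slice_interval_um
}

annotation_bbox <- function(a) {
  pts <- do.call(rbind, lapply(a$slices, function(s) s$points))
  rbind(lo = apply(pts, 2, min), hi = apply(pts, 2, max))
}

#' Per-eye record: group label, LC thickness and the eye's pores
#'
#' @param eye_id character identifier.
#' @param group `"normal"` or `"glaucoma"`.
#' @param lc_thickness_um average lamina cribrosa thickness of the eye, in
#'   micrometres; used to adjust pore volumes.
#' @param pores list of [pore_annotation()] objects.
#' @return an object of class `lp_eye`.
#' @export
eye_record <- function(eye_id, group = c("normal", "glaucoma"),
                       lc_thickness_um, pores) {
  group <- match.arg(group)
  stopifnot(is.numeric(lc_thickness_um), lc_thickness_um > 0,
            is.list(pores), length(pores) >= 1L)
  ok <- vapply(pores, inherits, logical(1), "lp_annotation")
  if (!all(ok)) stop("pores must all be pore_annotation() objects")
  structure(list(eye_id = as.character(eye_id), group = group,
                 lc_thickness_um = as.numeric(lc_thickness_um), pores = pores),
            class = "lp_eye")
}

#' @export
print.lp_eye <- function(x, ...) {
  cat(sprintf("<lp_eye> %s (%s): %d pores, LC thickness %.1f um\n",
              x$eye_id, x$group, length(x$pores), x$lc_thickness_um))
  invisible(x)
}
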