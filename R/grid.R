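# Voxel-grid reconstruction of an annotated pore. The grid lives in continuous
# physical coordinates: voxel (i,j,k) (0-based) covers the half-open box
# [x0 + i*dx, x0 + (i+1)*dx) x ... and its *center* carries the inside test.
# Each annotated C-scan fills exactly one z-layer of full thickness dz (slab
# rule): one closed contour per image, no interpolation between images.

#' Anisotropic voxel grid
#'
#' @param spacing numeric length-3, voxel spacing (dx, dy, dz) in micrometres.
#' @param origin numeric length-3, physical position of the grid corner
#'   (x0, y0, z0) in micrometres.
#' @param dims integer length-3, number of voxels along each axis.
#' @return an object of class `lp_grid`.
#' @export
voxel_grid <- function(spacing, origin, dims) {
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  dims <- as.integer(dims)
  stopifnot(length(spacing) == 3L, all(spacing > 0),
            length(origin) == 3L, all(is.finite(origin)),
            length(dims) == 3L, all(dims >= 1L))
  structure(list(spacing = spacing, origin = origin, dims = dims),
            class = "lp_grid")
}

#' @export
print.lp_grid <- function(x, ...) {
  cat(sprintf("<lp_grid> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) um\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Default grid enclosing an annotation
#'
#' Builds a voxel grid covering the annotation's bounding box with a margin of
#' `pad` lateral voxels and one empty z-layer on each side. The axial spacing
#' equals the annotation's slice interval and z-layers are aligned so each
#' annotated C-scan maps to exactly one layer.
#'
#' @param annotation a [pore_annotation()].
#' @param lateral_pitch_um lateral voxel size in micrometres (default 1.0,
#'   well below the ~45 um pore diameter so surface-area error stays small).
#' @param pad number of padding voxels around the lateral bounding box.
#' @return an `lp_grid`.
#' @export
grid_for_annotation <- function(annotation, lateral_pitch_um = 1.0, pad = 3L) {
  stopifnot(inherits(annotation, "lp_annotation"), lateral_pitch_um > 0)
  bb <- annotation_bbox(annotation)
  dz <- annotation$slice_interval_um
  z0i <- annotation$slices[[1L]]$z_index
  x0 <- bb["lo", 1] - pad * lateral_pitch_um
  y0 <- bb["lo", 2] - pad * lateral_pitch_um
  nx <- ceiling((bb["hi", 1] - x0) / lateral_pitch_um) + pad
  ny <- ceiling((bb["hi", 2] - y0) / lateral_pitch_um) + pad
  # layer k center sits at z0 + (k + 0.5) dz; align so layer 1 (0-based) is
  # the first annotated slice, leaving one empty boundary layer below/above
  z0 <- (z0i - 1) * dz - dz / 2
  nz <- n_slices(annotation) + 2L
  voxel_grid(c(lateral_pitch_um, lateral_pitch_um, dz), c(x0, y0, z0),
             c(nx, ny, nz))
}

#' Binary pore mask on a voxel grid
#'
#' @param grid an [voxel_grid()].
#' @param occupancy logical 3D array matching `grid$dims`.
#' @param coverage optional numeric array of fractional in-plane coverage,
#'   carried along by the rasterizer for diagnostics.
#' @return an object of class `lp_mask`.
#' @export
pore_mask <- function(grid, occupancy, coverage = NULL) {
  stopifnot(inherits(grid, "lp_grid"), is.logical(occupancy))
  if (!identical(dim(occupancy), as.integer(grid$dims))) {
    stop("occupancy dimensions do not match the grid")
  }
  structure(list(grid = grid, occupancy = occupancy, coverage = coverage),
            class = "lp_mask")
}

#' @export
print.lp_mask <- function(x, ...) {
  print(x$grid)
  cat(sprintf("  %d occupied voxels (%.3g um^3 each)\n",
              sum(x$occupancy), prod(x$grid$spacing)))
  invisible(x)
}

#' Rasterize a pore annotation into a voxel mask
#'
#' A voxel is occupied iff its center lies inside (or on the boundary of) the
#' polygon of the C-scan slab containing it. Slabs have full thickness dz and
#' are centered on the annotated planes.
#'
#' @param annotation a [pore_annotation()].
#' @param grid an `lp_grid` covering the annotation, or `NULL` to build one
#'   with [grid_for_annotation()].
#' @param lateral_pitch_um lateral pitch used when `grid` is `NULL`.
#' @return an [pore_mask()].
#' @export
rasterize_pore <- function(annotation, grid = NULL, lateral_pitch_um = 1.0) {
  stopifnot(inherits(annotation, "lp_annotation"))
  if (is.null(grid)) {
    grid <- grid_for_annotation(annotation, lateral_pitch_um)
  }
  stopifnot(inherits(grid, "lp_grid"))
  bb <- annotation_bbox(annotation)
  gx <- grid$origin + grid$spacing * grid$dims
  if (bb["lo", 1] < grid$origin[1] || bb["lo", 2] < grid$origin[2] ||
      bb["hi", 1] > gx[1] || bb["hi", 2] > gx[2]) {
    stop(sprintf(paste0("grid does not cover the annotation laterally: ",
                        "annotation spans x [%.2f, %.2f], y [%.2f, %.2f] um ",
                        "but grid covers x [%.2f, %.2f], y [%.2f, %.2f] um"),
                 bb["lo", 1], bb["hi", 1], bb["lo", 2], bb["hi", 2],
                 grid$origin[1], gx[1], grid$origin[2], gx[2]))
  }
  dz <- grid$spacing[3]
  occ <- array(FALSE, grid$dims)
  for (s in annotation$slices) {
    zc <- s$z_index * annotation$slice_interval_um
    k <- floor((zc - grid$origin[3]) / dz)  # 0-based layer of the slab center
    if (k < 0 || k >= grid$dims[3]) {
      stop(sprintf("grid does not cover slice z_index %d (z = %.2f um)",
                   s$z_index, zc))
    }
    layer <- .fill_polygon_cpp(s$points, grid$origin[1], grid$origin[2],
                               grid$spacing[1], grid$spacing[2],
                               grid$dims[1], grid$dims[2])
    occ[, , k + 1L] <- occ[, , k + 1L] | layer
  }
  if (!any(occ)) {
    stop("rasterization produced an empty mask; the annotation outlines are ",
         "smaller than a single voxel at this pitch")
  }
  pore_mask(grid, occ)
}

#' Gaussian smoothing of a binary mask (optional preprocessing)
#'
#' Blurs the occupancy field with an isotropic (in voxel units) Gaussian of
#' standard deviation `radius_voxels` and re-thresholds at 0.5. This mirrors a
#' radius-1 Gaussian preprocessing step sometimes applied to segmented LC
#' volumes; it is off by default in the pipeline. `radius_voxels = 0` is the
#' identity. Interior voxels of large solids are unchanged; isolated voxels
#' are removed.
#'
#' @param mask an [pore_mask()].
#' @param radius_voxels Gaussian sigma in voxels (default 1).
#' @return a smoothed `lp_mask`.
#' @export
smooth_mask <- function(mask, radius_voxels = 1) {
  stopifnot(inherits(mask, "lp_mask"), radius_voxels >= 0)
  if (radius_voxels == 0) return(mask)
  f <- .gaussian_blur_cpp(as.numeric(mask$occupancy), mask$grid$dims,
                          rep(radius_voxels, 3L))
  occ <- array(f >= 0.5, mask$grid$dims)
  pore_mask(mask$grid, occ)
}
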