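# File formats. Annotations travel as canonical JSON (fixed key order, 9
# significant digits, so identical objects give identical bytes) or as the
# flat CSV dialect; masks as NIfTI (spacing in pixdim) or multi-page TIFF
# (spacing supplied by the caller); profiles and configs as JSON/YAML.

fmt_num <- function(x) {
  v <- vapply(x, function(xx) sprintf("%.9g", xx), character(1))
  v[v == "-0"] <- "0"
  v
}

annotation_to_json <- function(a) {
  sl <- vapply(a$slices, function(s) {
    pts <- apply(s$points, 1, function(p) {
      paste0("[", fmt_num(p[1]), ",", fmt_num(p[2]), "]")
    })
    sprintf("{\"z_index\":%d,\"points\":[%s]}", s$z_index,
            paste(pts, collapse = ","))
  }, character(1))
  sprintf(paste0("{\"pore_id\":\"%s\",\"eye_id\":\"%s\",",
                 "\"slice_interval_um\":%s,\"slices\":[%s]}"),
          a$pore_id, a$eye_id, fmt_num(a$slice_interval_um),
          paste(sl, collapse = ","))
}

#' Write pore annotations
#'
#' JSON (canonical, byte-stable) or CSV, chosen by file extension. The JSON
#' schema is an array of
#' `{pore_id, eye_id, slice_interval_um, slices: [{z_index, points: [[x,y],...]}]}`
#' objects; the CSV dialect has columns
#' `pore_id, eye_id, z_index, point_index, x_um, y_um`.
#'
#' @param annotations a [pore_annotation()] or list of them.
#' @param path output file (`.json` or `.csv`).
#' @return invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  if (inherits(annotations, "lp_annotation")) annotations <- list(annotations)
  ok <- vapply(annotations, inherits, logical(1), "lp_annotation")
  if (!all(ok)) stop("annotations must be pore_annotation() objects")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    body <- vapply(annotations, annotation_to_json, character(1))
    writeLines(paste0("[", paste(body, collapse = ","), "]"), path,
               useBytes = TRUE)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    rows <- lapply(annotations, function(a) {
      do.call(rbind, lapply(a$slices, function(s) {
        data.frame(pore_id = a$pore_id, eye_id = a$eye_id,
                   z_index = s$z_index,
                   point_index = seq_len(nrow(s$points)),
                   x_um = s$points[, 1], y_um = s$points[, 2],
                   stringsAsFactors = FALSE)
      }))
    })
    write.csv(do.call(rbind, rows), path, row.names = FALSE)
  } else {
    stop("unsupported annotation format: ", path, " (use .json or .csv)")
  }
  invisible(path)
}

#' Read pore annotations
#'
#' Counterpart of [write_annotations()]. Schema violations are reported with
#' the offending pore and slice.
#'
#' @param path `.json` or `.csv` annotation file.
#' @param slice_interval_um slice interval for the CSV dialect (which does not
#'   carry it); ignored for JSON.
#' @return list of [pore_annotation()] objects.
#' @export
read_annotations <- function(path, slice_interval_um = 2.6) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!is.list(raw)) stop("annotation JSON must be an array of pores")
    lapply(seq_along(raw), function(i) {
      a <- raw[[i]]
      for (f in c("pore_id", "eye_id", "slice_interval_um", "slices")) {
        if (is.null(a[[f]])) {
          stop(sprintf("annotation %d: missing field '%s'", i, f))
        }
      }
      slices <- lapply(seq_along(a$slices), function(j) {
        s <- a$slices[[j]]
        if (is.null(s$z_index) || is.null(s$points)) {
          stop(sprintf("pore %s, slice %d: missing z_index or points",
                       a$pore_id, j))
        }
        pts <- do.call(rbind, lapply(s$points, unlist))
        if (is.null(pts) || nrow(pts) < 3L) {
          stop(sprintf("pore %s, slice z_index %s: fewer than 3 margin points",
                       a$pore_id, s$z_index))
        }
        tryCatch(slice_annotation(s$z_index, pts), error = function(e) {
          stop(sprintf("pore %s, slice z_index %s: %s", a$pore_id, s$z_index,
                       conditionMessage(e)))
        })
      })
      pore_annotation(a$pore_id, a$eye_id, slices, a$slice_interval_um)
    })
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("pore_id", "eye_id", "z_index", "point_index", "x_um", "y_um")
    if (!all(need %in% colnames(d))) {
      stop("annotation CSV must have columns: ", paste(need, collapse = ", "))
    }
    lapply(split(d, d$pore_id), function(dp) {
      slices <- lapply(split(dp, dp$z_index), function(ds) {
        ds <- ds[order(ds$point_index), ]
        if (nrow(ds) < 3L) {
          stop(sprintf("pore %s, slice z_index %d: fewer than 3 margin points",
                       dp$pore_id[1], ds$z_index[1]))
        }
        slice_annotation(ds$z_index[1], cbind(ds$x_um, ds$y_um))
      })
      z <- vapply(slices, function(s) s$z_index, integer(1))
      pore_annotation(dp$pore_id[1], dp$eye_id[1], slices[order(z)],
                      slice_interval_um)
    })
  } else {
    stop("unsupported annotation format: ", path)
  }
}

#' Write eye metadata (group, LC thickness) as CSV
#' @param eyes list of [eye_record()] objects.
#' @param path output CSV.
#' @return invisibly, `path`.
#' @export
write_eye_table <- function(eyes, path) {
  d <- do.call(rbind, lapply(eyes, function(e) {
    data.frame(eye_id = e$eye_id, group = e$group,
               lc_thickness_um = e$lc_thickness_um,
               n_pores = length(e$pores), stringsAsFactors = FALSE)
  }))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Rebuild eye records from an annotation file plus an eye table
#' @param annotation_path annotations (`.json`/`.csv`).
#' @param eye_table_path CSV from [write_eye_table()].
#' @param slice_interval_um passed to [read_annotations()] for CSV input.
#' @return list of [eye_record()] objects.
#' @export
read_cohort <- function(annotation_path, eye_table_path,
                        slice_interval_um = 2.6) {
  anns <- read_annotations(annotation_path, slice_interval_um)
  eyes <- read.csv(eye_table_path, stringsAsFactors = FALSE)
  need <- c("eye_id", "group", "lc_thickness_um")
  if (!all(need %in% colnames(eyes))) {
    stop("eye table must have columns: ", paste(need, collapse = ", "))
  }
  by_eye <- split(anns, vapply(anns, function(a) a$eye_id, character(1)))
  lapply(seq_len(nrow(eyes)), function(i) {
    id <- eyes$eye_id[i]
    if (is.null(by_eye[[id]])) stop("no annotations found for eye ", id)
    eye_record(id, eyes$group[i], eyes$lc_thickness_um[i], by_eye[[id]])
  })
}

#' Write / read a binary pore mask
#'
#' NIfTI (`.nii` / `.nii.gz`) stores the voxel spacing in the header; TIFF
#' (`.tif` / `.tiff`) stacks do not, so reading a TIFF requires `spacing`.
#'
#' @param mask an [pore_mask()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lp_mask"))
  arr <- array(as.integer(mask$occupancy), mask$grid$dims)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- mask$grid$spacing
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- lapply(seq_len(dim(arr)[3]), function(k) {
      t(arr[, , k]) * 1.0  # rows = y for image convention; writeTIFF wants real
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    stop("unsupported mask format: ", path, " (use .nii, .nii.gz or .tif)")
  }
  invisible(path)
}

#' @rdname write_mask
#' @param spacing voxel spacing (dx, dy, dz) in micrometres; required for
#'   TIFF, overrides the header for NIfTI when given.
#' @param origin physical origin of the grid (default 0; not stored by either
#'   format).
#' @return `read_mask()`: an [pore_mask()].
#' @export
read_mask <- function(path, spacing = NULL, origin = c(0, 0, 0)) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L) {
      stop("expected a 3D mask volume, got ", length(dim(arr)), "D")
    }
    if (is.null(spacing)) {
      spacing <- RNifti::pixdim(img)[1:3]
      if (any(!is.finite(spacing)) || any(spacing <= 0)) {
        stop("NIfTI header carries no usable voxel spacing; pass `spacing`")
      }
    }
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (is.null(spacing)) {
      stop("TIFF stacks carry no spacing metadata; pass `spacing = c(dx, dy, dz)`")
    }
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L) {
      stop("expected a multi-page TIFF stack, got a single 2D image")
    }
    arr <- array(0L, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- as.integer(round(t(pages[[k]])))
  } else {
    stop("unsupported mask format: ", path)
  }
  grid <- voxel_grid(spacing, origin, dim(arr))
  pore_mask(grid, array(arr > 0.5, dim(arr)))
}

#' Write / read a generator profile as JSON
#' @param profile an [generator_profile()].
#' @param path JSON file path.
#' @return invisibly `path`; `read_profile()` returns the profile.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "lp_profile"))
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(generator_profile))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown profile fields: ", paste(bad, collapse = ", "))
  }
  do.call(generator_profile, raw)
}

#' Write ground-truth sidecar for a generated cohort
#'
#' Collects the per-pore ground truths attached by
#' `generate_cohort(truth = TRUE)` into one JSON sidecar (true volume,
#' covariance eigenvalues, principal values).
#'
#' @param eyes cohort from [generate_cohort()] with `truth = TRUE`.
#' @param path output JSON.
#' @return invisibly, `path`.
#' @export
write_ground_truth <- function(eyes, path) {
  recs <- list()
  for (e in eyes) {
    for (p in e$pores) {
      tr <- attr(p, "truth")
      if (is.null(tr)) {
        stop("pore ", p$pore_id, " has no ground truth attached; ",
             "generate the cohort with truth = TRUE")
      }
      recs[[length(recs) + 1L]] <- list(
        pore_id = p$pore_id, eye_id = e$eye_id,
        volume_um3 = tr$volume_um3,
        cov_eigenvalues_um2 = tr$cov_eigenvalues_um2,
        principal_values_mm = tr$principal_values_mm)
    }
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' Reads a YAML or JSON configuration and validates it: unknown keys are
#' rejected, known keys are type-checked and merged over defaults.
#'
#' @param path `.yaml`/`.yml`/`.json` config file, or `NULL` for defaults.
#' @return an object of class `lp_config`.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(lateral_pitch_um = 1.0, smooth_radius_voxels = 0,
                   pool_thresholds = TRUE, alpha = 0.05, by_eye = FALSE,
                   bonferroni = FALSE, normal_profile = NULL,
                   glaucoma_profile = NULL, output_dir = ".", seed = 1L,
                   log_level = "info")
  if (is.null(path)) {
    cfg <- defaults
  } else {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    } else {
      stop("unsupported config format: ", path)
    }
    bad <- setdiff(names(raw), names(defaults))
    if (length(bad) > 0) {
      stop("unknown config keys: ", paste(bad, collapse = ", "))
    }
    cfg <- modifyList(defaults, raw)
  }
  stopifnot(cfg$lateral_pitch_um > 0, cfg$smooth_radius_voxels >= 0,
            cfg$alpha > 0, cfg$alpha < 1)
  structure(cfg, class = "lp_config")
}

# small stable FNV-1a hash of the canonical config serialization, for run logs
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
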