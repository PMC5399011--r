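#' 3D scalar volumes and binary masks
#'
#' `scalar_volume()` wraps a 3D numeric array together with its voxel
#' spacing (mm), the physical position of the centre of voxel (1,1,1)
#' ("origin", mm) and a units tag. `voi_mask()` is the binary companion
#' used for tumour volumes of interest. Grids are axis-aligned: the
#' physical centre of 0-based voxel index `(i,j,k)` is
#' `origin + c(i,j,k) * spacing`; oblique orientation matrices are out
#' of scope.
#'
#' @param data 3D numeric (or logical for masks) array; all values finite.
#' @param spacing length-3 positive numeric, mm per voxel on each axis.
#' @param origin length-3 numeric, mm position of the first voxel centre.
#' @param units one of `"ACTIVITY_BQ_ML"`, `"SUV"`, `"ARBITRARY"`.
#' @return An object of class `scalar_volume` (resp. `voi_mask`): a list
#'   with elements `data`, `spacing`, `origin` (and `units` for volumes).
#' @examples
#' v <- scalar_volume(array(1, c(4, 4, 2)), spacing = c(4.7, 4.7, 3.27))
#' dim(v$data)
#' @export
scalar_volume <- function(data, spacing, origin = c(0, 0, 0),
                          units = c("ARBITRARY", "ACTIVITY_BQ_ML", "SUV")) {
  units <- match.arg(units)
  data <- validate_grid(data, spacing, origin, what = "scalar_volume")
  if (!all(is.finite(data))) {
    stop("scalar_volume: data contains non-finite values", call. = FALSE)
  }
  structure(
    list(data = data, spacing = as.numeric(spacing),
         origin = as.numeric(origin), units = units),
    class = "scalar_volume"
  )
}

#' @rdname scalar_volume
#' @export
voi_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- validate_grid(data, spacing, origin, what = "voi_mask")
  storage.mode(data) <- "integer"
  if (!all(data %in% c(0L, 1L))) {
    stop("voi_mask: mask values must be 0 or 1", call. = FALSE)
  }
  structure(
    list(data = data, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "voi_mask"
  )
}

validate_grid <- function(data, spacing, origin, what) {
  if (is.logical(data)) storage.mode(data) <- "integer"
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop(what, ": data must be a 3D array", call. = FALSE)
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop(what, ": spacing must be 3 strictly positive values", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop(what, ": origin must be 3 finite values", call. = FALSE)
  }
  data
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s, spacing %s mm, units %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), x$units))
  invisible(x)
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %s, %d foreground voxels\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

n_foreground <- function(mask) sum(mask$data != 0L)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Read and write NIfTI-1 volumes
#'
#' Volumes and masks are stored as NIfTI-1 files with a diagonal sform
#' (spacing on the diagonal, origin in the translation column). Masks
#' are written as 8-bit images with values {0, 1}.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param units units tag to attach to the volume on read.
#' @return `read_volume()` returns a [scalar_volume()]; `read_mask()` a
#'   [voi_mask()]. The writers return `path` invisibly.
#' @export
read_volume <- function(path, units = "ARBITRARY") {
  img <- read_nifti_checked(path)
  arr <- strip_nifti_attrs(img)
  if (!all(is.finite(arr))) {
    stop("read_volume: non-finite voxel values in ", path, call. = FALSE)
  }
  hdr <- nifti_geometry(img)
  scalar_volume(arr, spacing = hdr$spacing, origin = hdr$origin, units = units)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  img <- read_nifti_checked(path)
  arr <- strip_nifti_attrs(img)
  hdr <- nifti_geometry(img)
  voi_mask((arr > 0.5) * 1L, spacing = hdr$spacing, origin = hdr$origin)
}

strip_nifti_attrs <- function(img) {
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) > 3L) d <- d[1:3]
  array(as.numeric(arr), dim = d)
}

read_nifti_checked <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read NIfTI file (not found): ", path, call. = FALSE)
  }
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) {
                    stop("cannot read NIfTI file ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  img
}

nifti_geometry <- function(img) {
  sp <- abs(RNifti::pixdim(img))[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- c(0, 0, 0)
  if (!inherits(xf, "try-error") && is.matrix(xf)) org <- abs(xf[1:3, 4]) * sign(xf[1:3, 4])
  list(spacing = sp, origin = org)
}

#' @rdname read_volume
#' @param x a [scalar_volume()] or [voi_mask()].
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "scalar_volume") || inherits(x, "voi_mask"))
  dt <- if (inherits(x, "voi_mask")) "uint8" else "double"
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  m <- diag(c(x$spacing, 1))
  m[1:3, 4] <- x$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Map a CT-space mask onto a PET grid
#'
#' Resamples a binary mask defined on one axis-aligned grid onto the
#' grid of a target volume by nearest-neighbour lookup at the target
#' voxel centres, assuming the two grids share a physical frame
#' (accurate co-registration, no patient motion). A target voxel is
#' foreground when the source voxel whose centre is nearest to the
#' target voxel centre is foreground.
#'
#' @param mask a [voi_mask()] on the source (e.g. CT) grid.
#' @param target a [scalar_volume()] defining the output grid.
#' @return A [voi_mask()] on `target`'s grid.
#' @export
map_mask_to_grid <- function(mask, target) {
  stopifnot(inherits(mask, "voi_mask"), inherits(target, "scalar_volume"))
  if (same_grid(mask, target)) {
    out <- voi_mask(mask$data, target$spacing, target$origin)
  } else {
    dt <- dim(target$data)
    ds <- dim(mask$data)
    # nearest source voxel index (1-based) per target axis position;
    # target centres falling outside the source grid map to background
    idx <- lapply(1:3, function(a) {
      pos <- target$origin[a] + (seq_len(dt[a]) - 1) * target$spacing[a]
      i <- as.integer(round((pos - mask$origin[a]) / mask$spacing[a])) + 1L
      i[i < 1L | i > ds[a]] <- NA_integer_
      i
    })
    arr <- array(0L, dt)
    in1 <- which(!is.na(idx[[1]])); in2 <- which(!is.na(idx[[2]]))
    in3 <- which(!is.na(idx[[3]]))
    if (length(in1) && length(in2) && length(in3)) {
      arr[in1, in2, in3] <-
        mask$data[idx[[1]][in1], idx[[2]][in2], idx[[3]][in3], drop = FALSE]
    }
    out <- voi_mask(arr, target$spacing, target$origin)
  }
  if (n_foreground(out) == 0L) {
    stop("map_mask_to_grid: tumour outside PET field of view (empty mask after mapping)",
         call. = FALSE)
  }
  out
}

#' Study manifests
#'
#' A manifest describes one patient study: the early and late PET
#' volumes, the tumour masks, and the acquisition metadata needed for
#' SUV conversion. `read_manifest()`/`write_manifest()` serialize a
#' list of studies to JSON.
#'
#' @param patient_id character scalar.
#' @param group `"benign"`, `"malignant"` or `"unknown"`.
#' @param early,late each a list with elements `pet` (path), `mask`
#'   (path) and `meta` (an [acquisition_meta()] or plain list).
#' @return A `study_manifest` list.
#' @export
study_manifest <- function(patient_id, group = "unknown", early, late) {
  group <- match.arg(group, c("benign", "malignant", "unknown"))
  for (tp in list(early, late)) {
    stopifnot(is.list(tp), all(c("pet", "mask", "meta") %in% names(tp)))
  }
  structure(list(patient_id = as.character(patient_id), group = group,
                 early = early, late = late),
            class = "study_manifest")
}

#' @rdname study_manifest
#' @param studies list of `study_manifest` objects.
#' @param path JSON file path.
#' @export
write_manifest <- function(studies, path) {
  if (inherits(studies, "study_manifest")) studies <- list(studies)
  jsonlite::write_json(lapply(studies, unclass), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname study_manifest
#' @export
read_manifest <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(s) {
    s$early$meta <- do.call(acquisition_meta, s$early$meta)
    s$late$meta <- do.call(acquisition_meta, s$late$meta)
    study_manifest(s$patient_id, s$group, s$early, s$late)
  })
}

#' Write and read per-scan feature tables
#'
#' One CSV row per (patient, time point) with the 99 feature columns in
#' catalogue order after the identifier columns.
#'
#' @param features tibble as returned by [extract_cohort_features()];
#'   must contain `patient_id`, `timepoint`, and all 99 catalogue
#'   feature columns.
#' @param path CSV path.
#' @export
write_feature_table <- function(features, path) {
  cat_names <- feature_catalog()$feature
  missing <- setdiff(cat_names, names(features))
  if (length(missing) > 0) {
    stop("write_feature_table: missing feature columns: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  id_cols <- intersect(c("patient_id", "timepoint", "group"), names(features))
  readr::write_csv(features[, c(id_cols, cat_names)], path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
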