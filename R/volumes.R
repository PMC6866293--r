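#' 4D BOLD volume container
#'
#' Couples a 4D (x, y, z, time) array of signal values with a 3D in-brain
#' mask and the repetition time. Synthetic runs are generated directly in
#' "registered" space; real runs are read from NIfTI with
#' [read_bold_volume()].
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param mask 3D logical array with the same spatial extents; at least one
#'   voxel must be in-mask.
#' @param tr Repetition time, seconds.
#' @return An object of class `volume4d`.
#' @export
volume4d <- function(data, mask, tr) {
  stopifnot(
    "data must be a 4D array" = is.array(data) && length(dim(data)) == 4,
    "mask must be a 3D array" = is.array(mask) && length(dim(mask)) == 3,
    "tr must be > 0" = is.numeric(tr) && length(tr) == 1 && tr > 0
  )
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(data)[1:3], dim(mask))) {
    stop("spatial dimensions of data and mask disagree", call. = FALSE)
  }
  if (!any(mask)) stop("mask contains no in-brain voxels", call. = FALSE)
  structure(list(data = data, mask = mask, tr = tr), class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %dx%dx%d voxels x %d volumes, TR %g s, %d in-mask\n",
              d[1], d[2], d[3], d[4], x$tr, sum(x$mask)))
  invisible(x)
}

#' @rdname volume4d
#' @param x Object to query.
#' @export
n_volumes <- function(x) {
  stopifnot(inherits(x, "volume4d"))
  dim(x$data)[4]
}

#' Z-statistic map container
#'
#' A 3D map of voxelwise Z statistics with its in-brain mask. Values inside
#' the mask must be finite; out-of-mask voxels carry `NA`.
#'
#' @param values 3D numeric array of Z statistics.
#' @param mask 3D logical array, same extents.
#' @return An object of class `zstat_map`.
#' @export
zstat_map <- function(values, mask) {
  stopifnot(
    "values must be a 3D array" = is.array(values) &&
      length(dim(values)) == 3,
    "mask must be a 3D array" = is.array(mask) && length(dim(mask)) == 3
  )
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(values), dim(mask))) {
    stop("dimensions of values and mask disagree", call. = FALSE)
  }
  if (!all(is.finite(values[mask]))) {
    stop("non-finite Z values inside the mask", call. = FALSE)
  }
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask), class = "zstat_map")
}

#' @export
print.zstat_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<zstat_map> %dx%dx%d, %d in-mask, Z range [%.2f, %.2f]\n",
              d[1], d[2], d[3], sum(x$mask),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Read and write BOLD volumes as NIfTI
#'
#' Thin wrappers around RNifti. `write_bold_volume()` stores the repetition
#' time in the standard header time-step slot (`pixdim[4]`);
#' `read_bold_volume()` recovers it. Round-trips preserve the voxel data
#' exactly. Masks travel as separate 3D NIfTI files of 0/1.
#'
#' @param x A [volume4d()] (or a 3D array for `write_mask_volume()`).
#' @param path File path (`.nii` or `.nii.gz`).
#' @param mask_path Path of the companion 3D mask file.
#' @return `read_bold_volume()` a `volume4d`; the writers return the path,
#'   invisibly.
#' @export
write_bold_volume <- function(x, path, mask_path = NULL) {
  stopifnot(inherits(x, "volume4d"))
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- c(1, 1, 1, x$tr)
  write_atomically(path, function(tmp) RNifti::writeNifti(img, tmp))
  if (!is.null(mask_path)) write_mask_volume(x$mask, mask_path)
  invisible(path)
}

#' @rdname write_bold_volume
#' @export
write_mask_volume <- function(x, path) {
  stopifnot(is.array(x), length(dim(x)) == 3)
  write_atomically(path, function(tmp) {
    RNifti::writeNifti(RNifti::asNifti(array(as.numeric(x), dim = dim(x))),
                       tmp)
  })
  invisible(path)
}

#' @rdname write_bold_volume
#' @export
read_bold_volume <- function(path, mask_path = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4) {
    stop("expected a 4D NIfTI file, got ", length(dim(img)), "D: ", path,
         call. = FALSE)
  }
  tr <- RNifti::pixdim(img)[4]
  if (!is.finite(tr) || tr <= 0) {
    stop("no valid repetition time in the NIfTI header of ", path,
         call. = FALSE)
  }
  data <- array(as.numeric(img), dim = dim(img))
  mask <- if (is.null(mask_path)) {
    array(TRUE, dim = dim(data)[1:3])
  } else {
    read_mask_volume(mask_path)
  }
  volume4d(data, mask, tr)
}

#' @rdname write_bold_volume
#' @export
read_mask_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) {
    stop("expected a 3D NIfTI mask, got ", length(dim(img)), "D: ", path,
         call. = FALSE)
  }
  array(as.numeric(img) != 0, dim = dim(img))
}

#' @rdname write_bold_volume
#' @param zmap A [zstat_map()].
#' @export
write_zstat_map <- function(zmap, path) {
  stopifnot(inherits(zmap, "zstat_map"))
  vals <- zmap$values
  vals[!zmap$mask] <- 0
  write_atomically(path, function(tmp) {
    RNifti::writeNifti(RNifti::asNifti(vals), tmp)
  })
  invisible(path)
}

# temp-then-rename so readers never observe a partial file
write_atomically <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path),
                  fileext = paste0(".", sub("^[^.]*\\.", "", basename(path))))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}
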