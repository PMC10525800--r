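#' 4D BOLD container
#'
#' Wraps a 4D scalar grid (x, y, z, t) together with the voxel geometry and
#' timing metadata needed downstream: voxel size in mm, repetition time in
#' seconds, and a 4x4 voxel-to-world affine.
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param voxel_size_mm Positive length-3 numeric, voxel edge lengths in mm.
#' @param tr_seconds Positive scalar, repetition time in seconds.
#' @param affine Optional 4x4 voxel-to-world transform; defaults to a scaled
#'   identity built from `voxel_size_mm` with the origin at voxel (1,1,1).
#' @return An object of class `bold4d`.
#' @export
bold4d <- function(data, voxel_size_mm = c(3, 3, 3), tr_seconds = 2,
                   affine = NULL) {
  stop_if_not(is.array(data) && length(dim(data)) == 4L,
              "`data` must be a 4D array (x, y, z, t)")
  stop_if_not(dim(data)[4] >= 1L, "need at least one volume")
  stop_if_not(length(voxel_size_mm) == 3L && all(voxel_size_mm > 0),
              "`voxel_size_mm` must be 3 positive values")
  stop_if_not(is.numeric(tr_seconds) && tr_seconds > 0,
              "`tr_seconds` must be positive")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 tr_seconds = as.numeric(tr_seconds), affine = affine),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold4d> %d x %d x %d grid, %d volumes, voxel %s mm, TR %.3g s\n",
              d[1], d[2], d[3], d[4],
              paste(format(x$voxel_size_mm), collapse = " x "),
              x$tr_seconds))
  invisible(x)
}

#' @export
dim.bold4d <- function(x) dim(x$data)

#' Binary brain mask
#'
#' @param data 3D logical or 0/1 numeric array.
#' @param voxel_size_mm Voxel size in mm (length 3).
#' @param affine Optional 4x4 voxel-to-world transform.
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(data, voxel_size_mm = c(3, 3, 3), affine = NULL) {
  stop_if_not(is.array(data) && length(dim(data)) == 3L,
              "`data` must be a 3D array")
  m <- array(as.logical(data != 0), dim = dim(data))
  stop_if_not(any(m), "mask must contain at least one voxel")
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  structure(list(data = m, voxel_size_mm = as.numeric(voxel_size_mm),
                 affine = affine),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %s grid, %d in-mask voxels\n",
              paste(dim(x$data), collapse = " x "), sum(x$data)))
  invisible(x)
}

#' Six-parameter rigid-body motion trace
#'
#' One row per volume: translations in mm along x, y, z, then rotations in
#' radians about x, y, z — the convention of realignment parameter files.
#'
#' @param params Numeric matrix with 6 columns.
#' @return An object of class `motion_trace` (a matrix with named columns).
#' @export
motion_trace <- function(params) {
  params <- as.matrix(params)
  stop_if_not(ncol(params) == 6L, "motion trace must have 6 columns")
  colnames(params) <- c("tx_mm", "ty_mm", "tz_mm", "rx_rad", "ry_rad", "rz_rad")
  class(params) <- c("motion_trace", class(params))
  params
}

# ---- NIfTI and text I/O -----------------------------------------------------

#' Read a 4D BOLD series from NIfTI-1
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [bold4d] object.
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stop_if_not(length(d) == 4L, "expected a 4D image")
  pd <- RNifti::pixdim(img)
  bold4d(array(as.numeric(img), dim = d),
         voxel_size_mm = pd[1:3],
         tr_seconds = if (length(pd) >= 4 && pd[4] > 0) pd[4] else 2,
         affine = unclass(RNifti::xform(img)))
}

#' Write a 4D BOLD series to NIfTI-1
#'
#' @param bold A [bold4d] object.
#' @param path Output path (`.nii` for uncompressed, `.nii.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(bold, path) {
  img <- RNifti::asNifti(bold$data)
  RNifti::pixdim(img) <- c(bold$voxel_size_mm, bold$tr_seconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D mask or map from NIfTI-1
#'
#' @param path Path to the image.
#' @param as_mask Logical; return a [brain_mask] (nonzero voxels) instead of a
#'   plain numeric array with geometry attributes.
#' @return A [brain_mask] or a 3D numeric array.
#' @export
read_map_nifti <- function(path, as_mask = FALSE) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stop_if_not(length(d) == 3L, "expected a 3D image")
  vox <- RNifti::pixdim(img)[1:3]
  if (as_mask) {
    brain_mask(array(as.numeric(img), dim = d), voxel_size_mm = vox,
               affine = unclass(RNifti::xform(img)))
  } else {
    arr <- array(as.numeric(img), dim = d)
    attr(arr, "voxel_size_mm") <- vox
    arr
  }
}

#' Write a 3D map or mask to NIfTI-1
#'
#' @param map 3D numeric/logical array, [brain_mask], or [reho_map].
#' @param path Output path.
#' @param voxel_size_mm Voxel size, used when `map` is a bare array.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path, voxel_size_mm = c(3, 3, 3)) {
  if (inherits(map, "brain_mask")) {
    arr <- map$data + 0
    voxel_size_mm <- map$voxel_size_mm
  } else if (inherits(map, "reho_map")) {
    arr <- map$data
    voxel_size_mm <- map$voxel_size_mm
  } else {
    arr <- map + 0
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read/write motion parameter files
#'
#' Whitespace-delimited text, 6 columns (translations mm, rotations rad), one
#' row per volume.
#'
#' @param path File path.
#' @return For `read_motion_params`, a [motion_trace].
#' @export
read_motion_params <- function(path) {
  motion_trace(as.matrix(utils::read.table(path)))
}

#' @rdname read_motion_params
#' @param motion A [motion_trace] or 6-column matrix.
#' @export
write_motion_params <- function(motion, path) {
  utils::write.table(format(unclass(motion), digits = 10), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
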