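#' Remove initial volumes
#'
#' Discards the first `k` volumes of a BOLD series (signal-equilibration
#' scans), preserving all metadata.
#'
#' @param bold A [bold4d].
#' @param k Number of leading volumes to drop (default 10).
#' @return A [bold4d] with `t - k` volumes.
#' @export
drop_initial_volumes <- function(bold, k = 10L) {
  stop_if_not(inherits(bold, "bold4d"), "`bold` must be a bold4d")
  nt <- dim(bold$data)[4]
  stop_if_not(k >= 0 && k < nt,
              sprintf("cannot drop %d of %d volumes", k, nt))
  if (k == 0L) return(bold)
  bold4d(bold$data[, , , (k + 1L):nt, drop = FALSE],
         voxel_size_mm = bold$voxel_size_mm,
         tr_seconds = bold$tr_seconds, affine = bold$affine)
}

#' Linear detrend and ideal band-pass filter
#'
#' Per in-mask voxel: removes the least-squares linear trend, then applies a
#' zero-phase frequency-domain ("ideal" / brick-wall) band-pass that retains
#' discrete frequencies in `[low_hz, high_hz]`, the classic resting-state
#' filter.  Out-of-mask voxels are zeroed.  The filtered series has mean
#' (numerically) zero because the DC component is outside the pass band.
#'
#' @param bold A [bold4d] (after volume removal).
#' @param mask A [brain_mask] of matching shape.
#' @param low_hz,high_hz Pass-band edges in Hz (defaults 0.01 and 0.1).
#' @param min_length Minimum series length accepted (default 32 volumes).
#' @return A filtered [bold4d].
#' @export
detrend_and_bandpass <- function(bold, mask, low_hz = 0.01, high_hz = 0.1,
                                 min_length = 32L) {
  stop_if_not(inherits(bold, "bold4d"), "`bold` must be a bold4d")
  stop_if_not(all(dim(bold$data)[1:3] == dim(mask$data)),
              "mask shape must match the volumes")
  nt <- dim(bold$data)[4]
  stop_if_not(nt >= min_length,
              sprintf("series too short for filtering (%d < %d volumes)",
                      nt, min_length))
  nyq <- 1 / (2 * bold$tr_seconds)
  stop_if_not(low_hz > 0 && low_hz < high_hz && high_hz <= nyq,
              sprintf("band must satisfy 0 < low < high <= Nyquist (%.4g Hz)",
                      nyq))
  inmask <- which(mask$data)
  nv <- prod(dim(bold$data)[1:3])
  y <- matrix(bold$data, nrow = nv, ncol = nt)[inmask, , drop = FALSE]
  # least-squares linear detrend: project out [1, t]
  tt <- seq_len(nt)
  X <- cbind(1, tt - mean(tt))
  coefs <- y %*% X %*% solve(crossprod(X))
  y <- y - tcrossprod(coefs, X)
  # brick-wall mask on the two-sided DFT (symmetric, hence zero-phase)
  freq <- (seq_len(nt) - 1) / (nt * bold$tr_seconds)
  freq <- pmin(freq, 1 / bold$tr_seconds - freq)  # fold to [0, Nyquist]
  keep <- freq >= low_hz & freq <= high_hz
  yf <- stats::mvfft(t(y))
  yf[!keep, ] <- 0
  y <- t(Re(stats::mvfft(yf, inverse = TRUE))) / nt
  out <- matrix(0, nv, nt)
  out[inmask, ] <- y
  bold4d(array(out, dim = dim(bold$data)),
         voxel_size_mm = bold$voxel_size_mm,
         tr_seconds = bold$tr_seconds, affine = bold$affine)
}

#' Framewise displacement
#'
#' Power-style FD: for each volume transition, the sum of absolute backward
#' differences of the six realignment parameters, with rotations (radians)
#' converted to arc length on a sphere of `head_radius_mm`.
#'
#' @param motion A [motion_trace] (>= 2 rows).
#' @param head_radius_mm Head radius used for rotations (default 50 mm).
#' @return List with `fd_series` (length `nrow - 1`) and `mean_fd`.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  m <- unclass(as.matrix(motion))
  stop_if_not(nrow(m) >= 2L, "need at least 2 motion rows")
  stop_if_not(ncol(m) == 6L, "motion trace must have 6 columns")
  d <- abs(diff(m))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  list(fd_series = as.numeric(fd), mean_fd = mean(fd))
}

#' Head-motion exclusion screening
#'
#' A subject is excluded when any translation exceeds `trans_mm` millimetres
#' or any rotation exceeds `rot_deg` degrees ("more than" is strict: values
#' exactly at the threshold are retained).  Rotations in the trace are
#' radians; the degree conversion happens here only.
#'
#' @param motion A [motion_trace].
#' @param trans_mm Translation threshold in mm (default 2).
#' @param rot_deg Rotation threshold in degrees (default 2).
#' @param head_radius_mm Passed to [framewise_displacement()].
#' @return An object of class `subject_qc`: list with
#'   `max_abs_translation_mm`, `max_abs_rotation_deg`, `fd_series`,
#'   `mean_fd`, `excluded`.
#' @export
motion_screen <- function(motion, trans_mm = 2, rot_deg = 2,
                          head_radius_mm = 50) {
  m <- unclass(as.matrix(motion))
  stop_if_not(ncol(m) == 6L, "motion trace must have 6 columns")
  max_t <- max(abs(m[, 1:3]))
  max_r <- max(abs(m[, 4:6])) * 180 / pi
  fd <- if (nrow(m) >= 2L) framewise_displacement(m, head_radius_mm) else
    list(fd_series = numeric(0), mean_fd = 0)
  structure(list(max_abs_translation_mm = max_t,
                 max_abs_rotation_deg = max_r,
                 fd_series = fd$fd_series, mean_fd = fd$mean_fd,
                 excluded = max_t > trans_mm || max_r > rot_deg),
            class = "subject_qc")
}

#' @export
print.subject_qc <- function(x, ...) {
  cat(sprintf("<subject_qc> max |trans| %.3f mm, max |rot| %.3f deg, mean FD %.4f mm — %s\n",
              x$max_abs_translation_mm, x$max_abs_rotation_deg, x$mean_fd,
              if (x$excluded) "EXCLUDED" else "retained"))
  invisible(x)
}

#' Motion QC summary table for several subjects
#'
#' @param motions Named list of [motion_trace] objects.
#' @param ... Passed to [motion_screen()].
#' @return Data frame: subject_id, max_abs_translation_mm,
#'   max_abs_rotation_deg, mean_fd, excluded.
#' @export
motion_qc_table <- function(motions, ...) {
  ids <- names(motions) %||% sprintf("sub-%03d", seq_along(motions))
  rows <- lapply(seq_along(motions), function(i) {
    q <- motion_screen(motions[[i]], ...)
    data.frame(subject_id = ids[i],
               max_abs_translation_mm = q$max_abs_translation_mm,
               max_abs_rotation_deg = q$max_abs_rotation_deg,
               mean_fd = q$mean_fd, excluded = q$excluded)
  })
  do.call(rbind, rows)
}
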