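# Neighborhood stencils: offsets within a 3x3x3 cube.
#   27 = center + faces + edges + corners (vertex connectivity)
#   19 = center + faces + edges
#    7 = center + faces
neighborhood_offsets <- function(k = 27L) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  s <- rowSums(abs(off))
  switch(as.character(k),
         "27" = off,
         "19" = off[s <= 2, , drop = FALSE],
         "7"  = off[s <= 1, , drop = FALSE],
         stop("neighborhood_k must be 7, 19 or 27", call. = FALSE))
}

# Add `src` shifted by (dx,dy,dz) into `acc` with zero padding; both arrays
# share the same first three dims (src may have a 4th).
shift_add <- function(acc, src, dx, dy, dz) {
  d <- dim(acc)
  xr <- max(1, 1 - dx):min(d[1], d[1] - dx)
  yr <- max(1, 1 - dy):min(d[2], d[2] - dy)
  zr <- max(1, 1 - dz):min(d[3], d[3] - dz)
  if (length(d) == 3L) {
    acc[xr, yr, zr] <- acc[xr, yr, zr] + src[xr + dx, yr + dy, zr + dz]
  } else {
    acc[xr, yr, zr, ] <- acc[xr, yr, zr, ] + src[xr + dx, yr + dy, zr + dz, ]
  }
  acc
}

neighbor_sum <- function(arr, offsets) {
  acc <- array(0, dim(arr))
  for (i in seq_len(nrow(offsets))) {
    acc <- shift_add(acc, arr, offsets[i, 1], offsets[i, 2], offsets[i, 3])
  }
  acc
}

#' Kendall's coefficient of concordance
#'
#' Measures agreement among `K` time series over `n` time points:
#' `W = 12 S / (K^2 (n^3 - n) - K * sum(T))`, where `S` is the sum of squared
#' deviations of the per-timepoint rank sums from their mean and `sum(T)` is
#' the optional tie-correction term (midranks are always used for ties; the
#' correction only affects the denominator).  `W = 1` for perfect
#' concordance, and the expectation under independent series is `1/K`.
#'
#' @param series_block Numeric matrix, `n` rows (time points) by `K` columns
#'   (series).
#' @param tie_correction Logical; include the tie term
#'   `T_j = sum(t^3 - t)` over tie groups of each series (default `FALSE`,
#'   the classic uncorrected form used by the standard ReHo toolboxes).
#' @return W in `[0, 1]`.  A degenerate block whose denominator is zero
#'   (all series constant) returns 0 with a warning.
#' @export
kendalls_w <- function(series_block, tie_correction = FALSE) {
  x <- as.matrix(series_block)
  n <- nrow(x)
  K <- ncol(x)
  stop_if_not(K >= 2L && n >= 2L, "need K >= 2 series of length n >= 2")
  ranks <- apply(x, 2, rank)
  Ri <- rowSums(ranks)
  S <- sum((Ri - mean(Ri))^2)
  Tsum <- if (tie_correction) {
    sum(apply(x, 2, function(col) {
      tab <- table(col)
      sum(tab^3 - tab)
    }))
  } else 0
  denom <- K^2 * (n^3 - n) - K * Tsum
  if (denom <= 0) {
    warning("degenerate series block (zero denominator); returning W = 0")
    return(0)
  }
  12 * S / denom
}

#' Voxelwise ReHo (Kendall's W) map
#'
#' For each in-mask voxel, Kendall's W over the voxel's own series and those
#' of its in-mask neighbors from the chosen stencil (26 neighbors for
#' `neighborhood_k = 27`).  Mask-boundary voxels use the available in-mask
#' neighbors with the effective series count `K`; voxels with no in-mask
#' neighbor get 0 with a warning.  Out-of-mask voxels are 0.
#'
#' @param bold A preprocessed [bold4d].
#' @param mask A [brain_mask] of matching shape.
#' @param neighborhood_k Stencil size: 7, 19 or 27 (default 27).
#' @param tie_correction Logical, as in [kendalls_w()].
#' @return An object of class `reho_map` (`stage = "raw"`) with the W grid in
#'   `$data`, the effective-K grid in `$k_eff`, and metadata.
#' @export
reho_map <- function(bold, mask, neighborhood_k = 27L, tie_correction = FALSE) {
  stop_if_not(inherits(bold, "bold4d"), "`bold` must be a bold4d")
  stop_if_not(all(dim(bold$data)[1:3] == dim(mask$data)),
              "mask shape must match the volumes")
  off <- neighborhood_offsets(neighborhood_k)
  g <- dim(bold$data)[1:3]
  nt <- dim(bold$data)[4]
  stop_if_not(nt >= 2L, "need at least 2 time points")
  nv <- prod(g)
  inmask <- which(mask$data)

  y <- matrix(bold$data, nv, nt)
  ranks <- matrix(0, nv, nt)
  ranks[inmask, ] <- t(apply(y[inmask, , drop = FALSE], 1, rank))
  R4 <- array(ranks, c(g, nt))
  Ssum <- neighbor_sum(R4, off)
  Kmap <- neighbor_sum(mask$data + 0, off)

  Tnb <- 0
  if (tie_correction) {
    tie_term <- numeric(nv)
    tie_term[inmask] <- apply(y[inmask, , drop = FALSE], 1, function(row) {
      tab <- table(row)
      sum(tab^3 - tab)
    })
    Tnb <- neighbor_sum(array(tie_term, g), off)
  }

  SS <- rowSums(matrix(Ssum, nv, nt)^2)
  Rbar <- as.numeric(Kmap) * (nt + 1) / 2
  S <- SS - nt * Rbar^2
  denom <- as.numeric(Kmap)^2 * (nt^3 - nt) - as.numeric(Kmap) * as.numeric(Tnb)
  W <- numeric(nv)
  ok <- rep(FALSE, nv)
  ok[inmask] <- TRUE
  valid <- ok & as.numeric(Kmap) >= 2 & denom > 0
  W[valid] <- 12 * S[valid] / denom[valid]
  n_bad <- sum(ok & !valid)
  if (n_bad > 0) {
    warning(sprintf("%d in-mask voxel(s) with no usable neighborhood set to 0",
                    n_bad))
  }
  keff <- array(as.numeric(Kmap), g)
  keff[!mask$data] <- 0
  structure(list(data = array(W, g), stage = "raw",
                 neighborhood_k = as.integer(neighborhood_k),
                 n_timepoints_used = nt,
                 k_eff = keff,
                 voxel_size_mm = bold$voxel_size_mm,
                 tie_correction = tie_correction),
            class = "reho_map")
}

#' @export
print.reho_map <- function(x, ...) {
  v <- x$data[x$k_eff > 0]
  cat(sprintf("<reho_map> stage '%s', K = %d, n = %d; in-mask mean %.4f (range %.4f-%.4f)\n",
              x$stage, x$neighborhood_k, x$n_timepoints_used,
              mean(v), min(v), max(v)))
  invisible(x)
}

#' Normalize a ReHo map by the whole-brain mean
#'
#' Divides every in-mask value by the in-mask mean, so the normalized map has
#' mean 1 over the mask (reduces between-subject global differences).
#'
#' @param map A raw-stage [reho_map].
#' @param mask The [brain_mask] used to compute it.
#' @return The map with `stage = "normalized"`.
#' @export
normalize_reho <- function(map, mask) {
  stop_if_not(inherits(map, "reho_map"), "`map` must be a reho_map")
  stop_if_not(map$stage == "raw", "map must be raw stage")
  mu <- mean(map$data[mask$data])
  stop_if_not(mu > 0, "in-mask mean must be positive")
  map$data <- map$data / mu
  map$data[!mask$data] <- 0
  map$stage <- "normalized"
  map
}

# Separable Gaussian smoothing of a 3D array with mask renormalization:
# smooth value*mask and mask with the same kernel, then divide, so out-of-mask
# zeros neither bleed in nor attenuate edge voxels.
gaussian_smooth3d <- function(arr, mask, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm <= 0) return(arr)
  m <- mask + 0
  num <- arr * m
  den <- m
  for (ax in 1:3) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm[ax]
    r <- max(1L, ceiling(3 * sigma))
    w <- exp(-((-r:r)^2) / (2 * sigma^2))
    w <- w / sum(w)
    acc_n <- array(0, dim(num))
    acc_d <- array(0, dim(den))
    for (k in -r:r) {
      sh <- c(0L, 0L, 0L)
      sh[ax] <- k
      wi <- w[k + r + 1]
      acc_n <- shift_add(acc_n, num * wi, sh[1], sh[2], sh[3])
      acc_d <- shift_add(acc_d, den * wi, sh[1], sh[2], sh[3])
    }
    num <- acc_n
    den <- acc_d
  }
  out <- array(0, dim(arr))
  inm <- mask & den > 0
  out[inm] <- num[inm] / den[inm]
  out
}

#' Smooth a ReHo map with a Gaussian kernel
#'
#' Separable Gaussian convolution of the given full width at half maximum,
#' renormalized within the mask so edge voxels are not attenuated and
#' out-of-mask zeros do not bleed in.  `fwhm_mm = 0` is the identity.
#'
#' @param map A [reho_map] (normalized or raw).
#' @param mask The companion [brain_mask].
#' @param fwhm_mm Kernel FWHM in millimetres (default 4).
#' @return The map with `stage = "smoothed"`.
#' @export
smooth_reho <- function(map, mask, fwhm_mm = 4) {
  stop_if_not(inherits(map, "reho_map"), "`map` must be a reho_map")
  map$data <- gaussian_smooth3d(map$data, mask$data, fwhm_mm,
                                map$voxel_size_mm)
  map$stage <- "smoothed"
  map
}

#' Whole-brain-mean normalization followed by Gaussian smoothing
#'
#' The standard "smReHo" order: divide by the in-mask mean first, smooth
#' last.
#'
#' @inheritParams smooth_reho
#' @param map A raw-stage [reho_map].
#' @return A smoothed, normalized [reho_map].
#' @export
normalize_and_smooth <- function(map, mask, fwhm_mm = 4) {
  smooth_reho(normalize_reho(map, mask), mask, fwhm_mm)
}
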