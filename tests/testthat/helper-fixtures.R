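# Shared fixture builders; everything is generated in code at test time.

# Full-grid mask with given voxel size.
cube_mask <- function(g, voxel_size = c(3, 3, 3)) {
  brain_mask(array(TRUE, g), voxel_size_mm = voxel_size)
}

# One smooth Gaussian-noise 3D map (mask-renormalized kernel).
smooth_noise_map <- function(g, fwhm_mm, voxel_size = c(3, 3, 3)) {
  rehopredict:::gaussian_smooth3d(array(stats::rnorm(prod(g)), g),
                                  array(TRUE, g), fwhm_mm, voxel_size)
}

# A list of smooth null maps for two groups with no effect.
null_group_maps <- function(n, g, fwhm_mm = 9, voxel_size = c(3, 3, 3)) {
  lapply(seq_len(n), function(i) smooth_noise_map(g, fwhm_mm, voxel_size))
}

# Per-voxel naive ReHo oracle mirroring the in-mask-neighbor policy.
naive_reho <- function(bold_arr, mask_arr, k = 27L) {
  off <- rehopredict:::neighborhood_offsets(k)
  d <- dim(bold_arr)[1:3]
  out <- array(0, d)
  for (v in which(mask_arr)) {
    co <- arrayInd(v, d)
    nb <- sweep(off, 2, as.integer(co), `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    keep <- mask_arr[nb]
    nb <- nb[keep, , drop = FALSE]
    if (nrow(nb) < 2) next
    block <- sapply(seq_len(nrow(nb)), function(j)
      bold_arr[nb[j, 1], nb[j, 2], nb[j, 3], ])
    out[v] <- kendalls_w(block)
  }
  out
}

# Planted-effect cohort fixture: one 100-voxel ROI, higher coherence in
# group 1, on a small grid.
planted_cohort_maps <- function(seed, n_per_group = 20, fwhm_mm = 4) {
  roi <- roi_box("planted", c(5, 5, 5), c(9, 9, 8), coherence = 0.7,
                 group_delta = -0.5)
  cfg <- cohort_config(grid_shape = c(16, 16, 16), n_timepoints = 70L,
                       n_per_group = n_per_group, rois = list(roi),
                       outcome_model = list(intercept = 0.5, coef = 0,
                                            noise_sd = 0.05),
                       seed = seed)
  mask <- cohort_mask(cfg)
  groups <- rep(1:2, each = n_per_group)
  maps <- vector("list", 2 * n_per_group)
  for (i in seq_along(maps)) {
    sub <- generate_bold_subject(cfg, groups[i], child_seed(seed, 1L, i))
    b <- drop_initial_volumes(sub$bold, 10L)
    b <- detrend_and_bandpass(b, mask)
    maps[[i]] <- normalize_and_smooth(reho_map(b, mask), mask, fwhm_mm)
  }
  truth_lin <- roi$voxel_set[, 1] + 16L * (roi$voxel_set[, 2] - 1L) +
    256L * (roi$voxel_set[, 3] - 1L)
  list(maps = maps, mask = mask, groups = groups, truth = truth_lin,
       cfg = cfg)
}
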