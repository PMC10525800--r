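test_that("subject generation is seed-deterministic", {
  cfg <- cohort_config(grid_shape = c(8, 8, 8), n_timepoints = 40L,
                       n_per_group = 2L, seed = 3L)
  a <- generate_bold_subject(cfg, 1, 11L)
  b <- generate_bold_subject(cfg, 1, 11L)
  expect_identical(a$bold$data, b$bold$data)
  expect_identical(unclass(a$motion), unclass(b$motion))
  c2 <- generate_bold_subject(cfg, 1, 12L)
  expect_false(identical(a$bold$data, c2$bold$data))
})

test_that("coherence controls within-neighborhood correlation", {
  # zero coherence: near-zero mean pairwise correlation at 240 volumes
  cfg0 <- cohort_config(grid_shape = c(8, 8, 8), n_timepoints = 240L,
                        n_per_group = 1L, drift_amplitude = 0)
  sub0 <- generate_bold_subject(cfg0, 1, 5L)
  block <- sapply(1:27, function(i) {
    co <- arrayInd(i, c(3, 3, 3)) + 2L
    sub0$bold$data[co[1], co[2], co[3], ]
  })
  cc <- cor(block)
  expect_lt(abs(mean(cc[upper.tri(cc)])), 0.05)

  # coherence 0.9: pairwise correlation ~0.9, averaged over 10 seeds
  roi <- roi_box("hot", c(3, 3, 3), c(6, 6, 5), coherence = 0.9)
  cfg9 <- cohort_config(grid_shape = c(8, 8, 8), n_timepoints = 240L,
                        n_per_group = 1L, rois = list(roi),
                        drift_amplitude = 0,
                        outcome_model = list(intercept = 0, coef = 0,
                                             noise_sd = 0))
  rbar <- mean(sapply(1:10, function(s) {
    sub <- generate_bold_subject(cfg9, 1, s)
    lin <- roi$voxel_set[, 1] + 8 * (roi$voxel_set[, 2] - 1) +
      64 * (roi$voxel_set[, 3] - 1)
    v <- matrix(sub$bold$data, 512, 240)[lin[1:12], ]
    cc <- cor(t(v))
    mean(cc[upper.tri(cc)])
  }))
  expect_equal(rbar, 0.9, tolerance = 0.05 / 0.9)
})

test_that("zero motion amplitude gives an identically zero trace", {
  cfg <- cohort_config(grid_shape = c(6, 6, 6), n_timepoints = 40L,
                       n_per_group = 1L, motion_amplitude = 0)
  sub <- generate_bold_subject(cfg, 2, 1L)
  expect_true(all(unclass(sub$motion) == 0))
  expect_equal(dim(unclass(sub$motion)), c(40L, 6L))
})

test_that("group must be 1 or 2 and ROIs must fit the grid", {
  cfg <- cohort_config(grid_shape = c(6, 6, 6), n_timepoints = 40L,
                       n_per_group = 1L)
  expect_error(generate_bold_subject(cfg, 3, 1L), "group")
  expect_error(
    cohort_config(grid_shape = c(6, 6, 6), n_timepoints = 40L,
                  n_per_group = 1L,
                  rois = list(roi_box("far", c(5, 5, 5), c(9, 9, 9), 0.5)),
                  outcome_model = list(intercept = 0, coef = 0,
                                       noise_sd = 0)),
    "outside the grid")
})

test_that("outcome model produces exact reduction rates without noise", {
  cfg <- cohort_config(grid_shape = c(6, 6, 6), n_timepoints = 40L,
                       n_per_group = 1L,
                       outcome_model = list(intercept = 0.5,
                                            coef = numeric(0),
                                            noise_sd = 0),
                       rois = list())
  clin <- generate_clinical_outcomes(cfg, matrix(0, 8, 0), 1:8)
  expect_equal(clin$rr_hama_exact, rep(0.5, 8))
  expect_equal(clin$rr_hamd_exact, rep(0.5, 8))

  # nonzero coefficients: RR recomputed from integer scores matches the
  # linear model up to the rounding of the week-4 score
  cfg2 <- cohort_config(grid_shape = c(6, 6, 6), n_timepoints = 40L,
                        n_per_group = 1L,
                        rois = list(roi_box("a", c(2, 2, 2), c(3, 3, 3), 0.2)),
                        outcome_model = list(intercept = 0.2, coef = 0.25,
                                             noise_sd = 0))
  set.seed(4)
  feats <- matrix(1 + 0.3 * rnorm(20), 20, 1)
  clin2 <- generate_clinical_outcomes(cfg2, feats, 1:20)
  rr_lin <- 0.2 + 0.25 * feats[, 1]
  rr_obs <- (clin2$hama_baseline - clin2$hama_week4) / clin2$hama_baseline
  expect_true(all(abs(rr_obs - rr_lin) <= 0.5 / clin2$hama_baseline + 1e-12))
  expect_equal(clin2$rr_hama_exact, rr_lin)

  # same seeds, same table
  clin3 <- generate_clinical_outcomes(cfg2, feats, 1:20)
  expect_identical(clin2, clin3)
  expect_error(generate_clinical_outcomes(cfg2, feats, 1:5), "match")
})

test_that("cohort construction fills subjects, mask and truth", {
  rois <- list(roi_box("a", c(3, 3, 3), c(5, 5, 4), 0.6, group_delta = -0.5),
               roi_box("b", c(7, 7, 7), c(9, 9, 8), 0.3))
  cfg <- cohort_config(grid_shape = c(12, 12, 12), n_timepoints = 40L,
                       n_per_group = 3L, rois = rois,
                       outcome_model = list(intercept = 0.4, coef = c(0.3, 0),
                                            noise_sd = 0.05),
                       seed = 21L)
  ch <- generate_cohort(cfg)
  expect_length(ch$subjects, 6L)
  expect_equal(ch$clinical$group, rep(1:2, each = 3))
  # mask excludes the 1-voxel border
  expect_false(any(ch$mask$data[1, , ]))
  expect_equal(sum(ch$mask$data), 10^3)
  # truth block reproducible and negative delta lowers group-2 ReHo in ROI a
  expect_equal(ch$truth$roi_coherence$coherence_group2[1], 0.1)
  f <- ch$truth$reho_features
  expect_lt(mean(f[4:6, "a"]), mean(f[1:3, "a"]))
  # determinism of the whole cohort
  ch2 <- generate_cohort(cfg)
  expect_identical(ch$clinical, ch2$clinical)
  expect_identical(ch$subjects[[2]]$bold$data, ch2$subjects[[2]]$bold$data)
})

test_that("empty ROI list yields a pure-noise cohort", {
  cfg <- cohort_config(grid_shape = c(8, 8, 8), n_timepoints = 40L,
                       n_per_group = 1L, rois = list(),
                       outcome_model = list(intercept = 0.5,
                                            coef = numeric(0),
                                            noise_sd = 0.05))
  ch <- generate_cohort(cfg)
  expect_length(ch$subjects, 2L)
  expect_equal(ncol(ch$truth$reho_features), 0L)
})

test_that("ROI-mean Kendall's W is nondecreasing in coherence", {
  roi <- roi_box("r", c(3, 3, 3), c(6, 6, 5), 0)
  for (s in 1:5) {
    w <- sapply(c(0, 0.3, 0.6, 0.9), function(cc) {
      roi$coherence <- cc
      cfg <- cohort_config(grid_shape = c(10, 10, 10), n_timepoints = 40L,
                           n_per_group = 1L, rois = list(roi),
                           drift_amplitude = 0,
                           outcome_model = list(intercept = 0, coef = 0,
                                                noise_sd = 0))
      sub <- generate_bold_subject(cfg, 1, s)
      rm0 <- reho_map(sub$bold, cohort_mask(cfg))
      mean(rm0$data[roi$voxel_set])
    })
    expect_true(all(diff(w) > 0))
  }
})

test_that("zero-noise outcomes are exactly recoverable by least squares", {
  cfg <- cohort_config(grid_shape = c(6, 6, 6), n_timepoints = 40L,
                       n_per_group = 1L,
                       rois = list(roi_box("a", c(2, 2, 2), c(3, 3, 3), 0.2),
                                   roi_box("b", c(4, 4, 4), c(5, 5, 5), 0.2)),
                       outcome_model = list(intercept = 0.3,
                                            coef = c(0.7, -0.4),
                                            noise_sd = 0))
  set.seed(9)
  feats <- matrix(1 + 0.2 * rnorm(60), 30, 2)
  clin <- generate_clinical_outcomes(cfg, feats, 1:30)
  fit <- lm(clin$rr_hama_exact ~ feats)
  expect_equal(unname(coef(fit)), c(0.3, 0.7, -0.4), tolerance = 1e-6)
})

test_that("cohorts round-trip through the on-disk layout", {
  cfg <- cohort_config(grid_shape = c(8, 8, 8), n_timepoints = 40L,
                       n_per_group = 1L, rois = list(),
                       outcome_model = list(intercept = 0.5,
                                            coef = numeric(0),
                                            noise_sd = 0.05))
  ch <- generate_cohort(cfg)
  d <- withr::local_tempdir()
  paths <- write_cohort(ch, d)
  b <- read_bold_nifti(paths$bold[1])
  expect_equal(b$data, ch$subjects[[1]]$bold$data, tolerance = 1e-6)
  expect_equal(b$tr_seconds, 2)
  m <- read_motion_params(paths$motion[1])
  expect_equal(unclass(m), unclass(ch$subjects[[1]]$motion),
               tolerance = 1e-8, ignore_attr = TRUE)
  mk <- read_map_nifti(paths$mask, as_mask = TRUE)
  expect_identical(mk$data, ch$mask$data)
})
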