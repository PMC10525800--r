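test_that("voxelwise GLM reduces to the pooled two-sample t", {
  set.seed(1)
  g <- c(4, 4, 4)
  mask <- cube_mask(g)
  n1 <- 5; n2 <- 6
  maps <- lapply(seq_len(n1 + n2), function(i) array(rnorm(prod(g)), g))
  clin <- data.frame(group = rep(c("a", "b"), c(n1, n2)))
  des <- build_design(clin, covariates = character(0))
  tm <- voxelwise_glm_contrast(maps, des, mask)
  expect_equal(tm$df, n1 + n2 - 2L)
  Y <- sapply(maps, function(m) m[2, 3, 4])
  tt <- t.test(Y[1:n1], Y[-(1:n1)], var.equal = TRUE)
  expect_equal(tm$data[2, 3, 4], unname(tt$statistic), tolerance = 1e-10)
  # every voxel, not just one
  for (v in sample(prod(g), 10)) {
    co <- arrayInd(v, g)
    Yv <- sapply(maps, function(m) m[co[1], co[2], co[3]])
    expect_equal(tm$data[co[1], co[2], co[3]],
                 unname(t.test(Yv[1:n1], Yv[-(1:n1)],
                               var.equal = TRUE)$statistic),
                 tolerance = 1e-10)
  }
})

test_that("GLM handles the textbook example, orthogonal covariates and ties", {
  mask <- cube_mask(c(1, 1, 1))
  maps <- lapply(1:6, function(v) array(v, c(1, 1, 1)))
  clin <- data.frame(group = rep(c("A", "B"), each = 3))
  des <- build_design(clin, covariates = character(0))
  tm <- voxelwise_glm_contrast(maps, des, mask)
  expect_equal(tm$data[1, 1, 1], -3.674235, tolerance = 1e-6)
  expect_equal(tm$df, 4L)

  # covariate orthogonal to intercept and group: contrast estimate intact,
  # df decremented
  des2 <- des
  des2$X <- cbind(des$X, cov = c(1, -1, 0, 1, -1, 0))
  des2$contrast <- c(des$contrast, 0)
  tm2 <- voxelwise_glm_contrast(maps, des2, mask)
  b <- solve(crossprod(des2$X)) %*% crossprod(des2$X, 1:6)
  expect_equal(unname((des2$contrast %*% b)[1]), -3)
  expect_equal(tm2$df, 3L)

  # identical groups: zero-variance residuals give t = 0 with a warning
  same <- lapply(rep(2, 6), function(v) array(v, c(1, 1, 1)))
  expect_warning(tm3 <- voxelwise_glm_contrast(same, des, mask),
                 "zero residual")
  expect_equal(tm3$data[1, 1, 1], 0)

  # rank-deficient design is rejected
  bad <- des
  bad$X <- cbind(des$X, dup = des$X[, 2])
  bad$contrast <- c(des$contrast, 0)
  expect_error(voxelwise_glm_contrast(maps, bad, mask), "rank")
})

test_that("paired t maps match the analytic example and are antisymmetric", {
  mask <- cube_mask(c(1, 1, 1))
  pre <- lapply(c(0, 0, 0), function(v) array(v, c(1, 1, 1)))
  post <- lapply(c(1, 2, 3), function(v) array(v, c(1, 1, 1)))
  tm <- paired_t_map(pre, post, mask)
  expect_equal(tm$data[1, 1, 1], 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(tm$df, 2L)
  tm_rev <- paired_t_map(post, pre, mask)
  expect_equal(tm_rev$data[1, 1, 1], -tm$data[1, 1, 1])
  expect_warning(tm0 <- paired_t_map(pre, pre, mask), "zero difference")
  expect_equal(tm0$data[1, 1, 1], 0)
  expect_error(paired_t_map(pre, post[1:2], mask), "differ")
})

test_that("smoothness estimation recovers the applied kernel", {
  g <- c(16, 16, 16)
  mask <- cube_mask(g)
  stdize <- function(maps) {
    A <- array(unlist(maps), c(g, length(maps)))
    mu <- apply(A, 1:3, mean)
    sdv <- apply(A, 1:3, sd)
    sweep(sweep(A, 1:3, mu), 1:3, sdv, "/")
  }
  set.seed(11)
  est6 <- sapply(1:5, function(s) {
    maps <- lapply(1:8, function(k) smooth_noise_map(g, 6))
    mean(estimate_smoothness_fwhm(stdize(maps), mask)$fwhm_mm)
  })
  expect_equal(mean(est6), 6, tolerance = 0.15)
  maps0 <- lapply(1:8, function(k) smooth_noise_map(g, 0))
  est0 <- mean(estimate_smoothness_fwhm(stdize(maps0), mask)$fwhm_mm)
  expect_equal(est0, 3, tolerance = 0.2)
  # doubling the voxel size doubles the millimetre FWHM on identical data
  A <- stdize(maps0)
  big <- estimate_smoothness_fwhm(A, mask, voxel_size_mm = c(6, 6, 6))
  small <- estimate_smoothness_fwhm(A, mask)
  expect_equal(big$fwhm_mm, 2 * small$fwhm_mm)
  expect_equal(big$resel_count, small$resel_count)
  expect_error(estimate_smoothness_fwhm(A[, , , 1:2, drop = FALSE], mask),
               "3 residual")
})

test_that("GRF corrected p decreases with extent and the table is sane", {
  u <- qnorm(1 - 0.0005)
  ps <- sapply(c(1, 5, 10, 20, 50, 100),
               function(k) rehopredict:::grf_cluster_p(k, u, 300, 6859))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= 1))

  # empty table when nothing is suprathreshold
  g <- c(8, 8, 8)
  mask <- cube_mask(g)
  tm <- structure(list(data = array(0.5, g), df = 30L, n = 32L,
                       resid_std = array(rnorm(prod(g) * 4), c(g, 4)),
                       voxel_size_mm = c(3, 3, 3), affine = diag(c(3, 3, 3, 1))),
                  class = "tstat_map")
  sm <- structure(list(fwhm_vox = c(2, 2, 2), fwhm_mm = c(6, 6, 6),
                       resel_count = 64, n_mask = 512),
                  class = "smoothness_estimate")
  tab <- grf_cluster_table(tm, sm, mask, n1 = 16, n2 = 16)
  expect_s3_class(tab, "cluster_table")
  expect_equal(nrow(tab), 0L)
})

test_that("planted effects produce signed clusters with correct geometry", {
  fix <- planted_cohort_maps(31, n_per_group = 12)
  des <- build_design(data.frame(group = fix$groups),
                      covariates = character(0))
  tm <- voxelwise_glm_contrast(fix$maps, des, fix$mask)
  sm <- estimate_smoothness_fwhm(tm, fix$mask)
  tab <- grf_cluster_table(tm, sm, fix$mask, n1 = 12, n2 = 12)
  expect_gt(nrow(tab), 0)
  pos <- tab[tab$sign == "+", ]
  expect_gt(nrow(pos), 0)
  best <- pos[which.max(pos$extent), ]
  # group 1 has the higher coherence, so the planted cluster is positive
  expect_gt(length(intersect(best$voxels[[1]], fix$truth)) /
              length(fix$truth), 0.5)
  # peak world coordinate maps back onto a truth voxel (3 mm voxels)
  vox <- round(c(best$peak_x, best$peak_y, best$peak_z) / 3) + 1
  lin <- vox[1] + 16 * (vox[2] - 1) + 256 * (vox[3] - 1)
  expect_true(lin %in% best$voxels[[1]])
  # deterministic given identical inputs
  tab2 <- grf_cluster_table(tm, sm, fix$mask, n1 = 12, n2 = 12)
  expect_identical(tab$extent, tab2$extent)
  expect_identical(tab$p_corrected, tab2$p_corrected)
})

test_that("permutation oracle needs two groups and ranks extents correctly", {
  fix <- planted_cohort_maps(32, n_per_group = 10)
  clin_same <- data.frame(group = rep("a", 20))
  expect_error(build_design(clin_same, character(0)), "two groups")
  des <- build_design(data.frame(group = fix$groups), character(0))
  expect_warning(
    tab <- permutation_cluster_oracle(fix$maps, des, fix$mask,
                                      n_perm = 60L, seed = 4L),
    "coarse")
  expect_gt(nrow(tab), 0)
  # the planted cluster dwarfs every permuted maximum
  expect_equal(min(tab$p_corrected), 1 / 61)
  tab2 <- suppressWarnings(
    permutation_cluster_oracle(fix$maps, des, fix$mask, n_perm = 60L,
                               seed = 4L))
  expect_identical(tab$p_corrected, tab2$p_corrected)
})

test_that("effect-size conversion matches published two-sample rows", {
  ref <- read.delim(system.file("extdata", "reference_clusters.tsv",
                                package = "rehopredict"))
  two <- ref[ref$contrast == "two_sample", ]
  d <- mapply(cohens_d_from_t, two$t_value, n1 = two$n1, n2 = two$n2,
              MoreArgs = list(kind = "two_sample"))
  expect_equal(round(d, 2), two$cohens_d)
  expect_equal(cohens_d_from_t(0, "two_sample", 10, 10), 0)
  expect_equal(cohens_d_from_t(3, "paired", 36), 0.5)
  expect_error(cohens_d_from_t(1, "two_sample", 0, 5), "positive")
})

test_that("2x2 chi-square matches hand evaluation", {
  res <- chi_square_2x2(matrix(c(25, 21, 29, 33), 2))
  expect_equal(round(res$statistic, 2), 0.61)
  expect_equal(res$df, 1L)
  expect_equal(res$cramers_v, sqrt(res$statistic / 108))
  expect_equal(chi_square_2x2(matrix(c(10, 0, 0, 10), 2))$statistic, 20)
  expect_equal(chi_square_2x2(matrix(c(10, 20, 30, 60), 2))$statistic, 0)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("symptom correlations pick the method and Bonferroni flag", {
  x <- 1:10
  out <- correlate_with_symptoms(data.frame(f = x), data.frame(s = 2 * x),
                                 method = "pearson", n_tests = 50)
  expect_equal(out$estimate, 1)
  expect_true(out$significant)
  out2 <- correlate_with_symptoms(data.frame(f = x), data.frame(s = x^3),
                                  method = "spearman", n_tests = 1)
  expect_equal(out2$estimate, 1)
  # auto mode: heavy-tailed data falls back to Spearman
  set.seed(8)
  xs <- exp(rnorm(40, sd = 2))
  out3 <- correlate_with_symptoms(data.frame(f = xs),
                                  data.frame(s = rnorm(40)), method = "auto")
  expect_equal(out3$method, "spearman")
  out4 <- correlate_with_symptoms(data.frame(f = rnorm(40)),
                                  data.frame(s = rnorm(40)), method = "auto")
  expect_equal(out4$method, "pearson")
  expect_error(correlate_with_symptoms(data.frame(f = c(1, 2, NA)),
                                       data.frame(s = c(1, NA, 3))),
               "complete pairs")
})
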