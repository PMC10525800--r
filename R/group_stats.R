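#' Build a group design matrix with nuisance covariates
#'
#' Columns: intercept, group indicator (second group level), then covariates
#' of no interest.  The default contrast estimates group1 minus group2, so a
#' negative t means the first group is lower.  Character/factor covariates
#' (e.g. sex) are coded as 0/1 indicators.
#'
#' @param clinical Data frame with a `group` column and the covariate
#'   columns.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return List with `X` (numeric matrix), `contrast` (numeric vector) and
#'   `groups` (the group factor).
#' @export
build_design <- function(clinical,
                         covariates = c("age", "sex", "education", "mean_fd")) {
  grp <- factor(clinical$group)
  stop_if_not(nlevels(grp) == 2L, "need exactly two groups")
  X <- cbind(intercept = 1, group2 = as.numeric(grp == levels(grp)[2]))
  for (cv in covariates) {
    stop_if_not(cv %in% names(clinical),
                sprintf("covariate '%s' missing from clinical table", cv))
    v <- clinical[[cv]]
    if (!is.numeric(v)) v <- as.numeric(factor(v)) - 1
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  stop_if_not(qr(X)$rank == ncol(X), "design matrix is rank deficient")
  contrast <- c(0, -1, rep(0, length(covariates)))
  list(X = X, contrast = contrast, groups = grp)
}

maps_to_matrix <- function(maps, inmask) {
  rows <- lapply(maps, function(m) {
    arr <- if (inherits(m, "reho_map")) m$data else m
    as.numeric(arr)[inmask]
  })
  do.call(rbind, rows)
}

#' Voxelwise GLM contrast t map
#'
#' Fits an ordinary-least-squares model at every in-mask voxel and returns
#' the contrast t statistic `t = c'b / sqrt(s2 c'(X'X)^-1 c)` with
#' `df = n - rank(X)`.  Voxels with zero residual variance get t = 0 with a
#' warning.  Standardized residuals are retained for smoothness estimation.
#'
#' @param maps List of per-subject 3D maps ([reho_map] or arrays), one per
#'   design row.
#' @param design A [build_design()] result, or a list with `X` and
#'   `contrast`.
#' @param mask A [brain_mask].
#' @return An object of class `tstat_map`: `data` (3D t grid), `df`, `n`,
#'   `resid_std` (x,y,z,subject array), and geometry.
#' @export
voxelwise_glm_contrast <- function(maps, design, mask) {
  X <- design$X
  ctr <- design$contrast
  stop_if_not(length(maps) == nrow(X), "one map per design row required")
  stop_if_not(length(ctr) == ncol(X), "contrast length must match design")
  stop_if_not(qr(X)$rank == ncol(X), "design matrix is rank deficient")
  inmask <- which(mask$data)
  Y <- maps_to_matrix(maps, inmask)
  n <- nrow(X)
  df <- n - ncol(X)
  stop_if_not(df >= 1L, "nonpositive residual degrees of freedom")
  XtXinv <- solve(crossprod(X))
  beta <- XtXinv %*% crossprod(X, Y)
  resid <- Y - X %*% beta
  sigma2 <- colSums(resid^2) / df
  cvar <- as.numeric(t(ctr) %*% XtXinv %*% ctr)
  est <- as.numeric(t(ctr) %*% beta)
  se <- sqrt(sigma2 * cvar)
  tval <- numeric(length(est))
  # relative floor: exact ties leave only solve() round-off in the residuals
  nz <- sigma2 > (colMeans(Y^2) + .Machine$double.eps) * 1e-20
  tval[nz] <- est[nz] / se[nz]
  if (any(!nz)) warning(sprintf("%d voxel(s) with zero residual variance set to t = 0",
                                sum(!nz)))
  g <- dim(mask$data)
  tarr <- array(0, g)
  tarr[inmask] <- tval
  sd_vox <- sqrt(sigma2)
  rs <- resid
  rs[, nz] <- sweep(resid[, nz, drop = FALSE], 2, sd_vox[nz], "/")
  rs[, !nz] <- 0
  resid_std <- array(0, c(g, n))
  step <- prod(g)
  for (i in seq_len(n)) resid_std[inmask + (i - 1) * step] <- rs[i, ]
  structure(list(data = tarr, df = df, n = n,
                 resid_std = resid_std,
                 design = list(X = X, contrast = ctr),
                 voxel_size_mm = mask$voxel_size_mm, affine = mask$affine),
            class = "tstat_map")
}

#' @export
print.tstat_map <- function(x, ...) {
  v <- x$data[x$data != 0]
  cat(sprintf("<tstat_map> df = %d, n = %d, |t| max %.3f\n", x$df, x$n,
              if (length(v)) max(abs(v)) else 0))
  invisible(x)
}

#' Paired (pre vs post) voxelwise t map
#'
#' One-sample t on per-subject difference maps (post minus pre),
#' `df = n - 1`.  Voxels whose differences have zero variance get t = 0 with
#' a warning.
#'
#' @param pre_maps,post_maps Lists of per-subject 3D maps in matched order.
#' @param mask A [brain_mask].
#' @return A `tstat_map`.
#' @export
paired_t_map <- function(pre_maps, post_maps, mask) {
  stop_if_not(length(pre_maps) == length(post_maps),
              "pre and post subject counts differ")
  n <- length(pre_maps)
  stop_if_not(n >= 2L, "need at least 2 subjects")
  inmask <- which(mask$data)
  D <- maps_to_matrix(post_maps, inmask) - maps_to_matrix(pre_maps, inmask)
  mu <- colMeans(D)
  sdv <- sqrt(colSums(sweep(D, 2, mu)^2) / (n - 1))
  tval <- numeric(length(mu))
  nz <- sdv^2 > (colMeans(D^2) + .Machine$double.eps) * 1e-20
  tval[nz] <- mu[nz] / (sdv[nz] / sqrt(n))
  if (any(!nz)) warning(sprintf("%d voxel(s) with zero difference variance set to t = 0",
                                sum(!nz)))
  g <- dim(mask$data)
  tarr <- array(0, g)
  tarr[inmask] <- tval
  rs <- sweep(D, 2, mu)
  rs[, nz] <- sweep(rs[, nz, drop = FALSE], 2, sdv[nz], "/")
  rs[, !nz] <- 0
  resid_std <- array(0, c(g, n))
  step <- prod(g)
  for (i in seq_len(n)) resid_std[inmask + (i - 1) * step] <- rs[i, ]
  structure(list(data = tarr, df = n - 1L, n = n, resid_std = resid_std,
                 design = list(kind = "paired"),
                 voxel_size_mm = mask$voxel_size_mm, affine = mask$affine),
            class = "tstat_map")
}

#' Estimate map smoothness from standardized residuals
#'
#' Classic residual-based estimator: along each axis, the variance of
#' first differences of the standardized residuals gives the roughness
#' `lambda = var(diff) / var`, from which the Gaussian-equivalent kernel is
#' `FWHM = sqrt(8 log 2) * sqrt(1 / (2 lambda))` voxels.  The resel count is
#' the mask volume divided by the product of the per-axis FWHMs in voxels.
#'
#' @param resid_maps 4D array (x, y, z, map) of standardized residuals, or a
#'   `tstat_map` (its `resid_std` is used).
#' @param mask A [brain_mask].
#' @param voxel_size_mm Voxel size; taken from the mask by default.
#' @return Object of class `smoothness_estimate`: `fwhm_mm`, `fwhm_vox`,
#'   `resel_count`, `n_mask`, `method`.
#' @export
estimate_smoothness_fwhm <- function(resid_maps, mask,
                                     voxel_size_mm = mask$voxel_size_mm) {
  if (inherits(resid_maps, "tstat_map")) resid_maps <- resid_maps$resid_std
  stop_if_not(length(dim(resid_maps)) == 4L, "resid_maps must be 4D")
  nmaps <- dim(resid_maps)[4]
  stop_if_not(nmaps >= 3L, "need at least 3 residual maps")
  m <- mask$data
  fwhm_vox <- numeric(3)
  for (ax in 1:3) {
    d <- dim(m)
    i1 <- seq_len(d[ax] - 1)
    idx_lo <- switch(ax, list(i1, TRUE, TRUE), list(TRUE, i1, TRUE),
                     list(TRUE, TRUE, i1))
    idx_hi <- switch(ax, list(i1 + 1, TRUE, TRUE), list(TRUE, i1 + 1, TRUE),
                     list(TRUE, TRUE, i1 + 1))
    pair <- do.call(`[`, c(list(m), idx_lo)) & do.call(`[`, c(list(m), idx_hi))
    ssd <- 0; ssv <- 0; npair <- 0
    for (j in seq_len(nmaps)) {
      v <- resid_maps[, , , j]
      lo <- do.call(`[`, c(list(v), idx_lo))[pair]
      hi <- do.call(`[`, c(list(v), idx_hi))[pair]
      ssd <- ssd + sum((hi - lo)^2)
      ssv <- ssv + sum(lo^2 + hi^2) / 2
      npair <- npair + length(lo)
    }
    stop_if_not(npair > 0, "mask has no neighbor pairs along an axis")
    lambda <- ssd / ssv
    stop_if_not(is.finite(lambda) && lambda > 0,
                "degenerate residual roughness")
    fwhm_vox[ax] <- sqrt(8 * log(2)) * sqrt(1 / (2 * lambda))
  }
  n_mask <- sum(m)
  structure(list(fwhm_vox = fwhm_vox,
                 fwhm_mm = fwhm_vox * voxel_size_mm,
                 resel_count = n_mask / prod(fwhm_vox),
                 n_mask = n_mask,
                 method = "standardized-residual first differences"),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("<smoothness_estimate> FWHM %.2f x %.2f x %.2f mm, %.1f resels over %d voxels\n",
              x$fwhm_mm[1], x$fwhm_mm[2], x$fwhm_mm[3], x$resel_count,
              x$n_mask))
  invisible(x)
}

# Connected-component labeling of a logical 3D array.
label_clusters <- function(arr, connectivity = 26L) {
  off <- switch(as.character(connectivity),
                "26" = neighborhood_offsets(27L),
                "18" = neighborhood_offsets(19L),
                "6"  = neighborhood_offsets(7L),
                stop("connectivity must be 6, 18 or 26", call. = FALSE))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  d <- dim(arr)
  lab <- array(0L, d)
  cand <- which(arr)
  if (!length(cand)) return(list(labels = lab, sizes = integer(0)))
  nlab <- 0L
  sizes <- integer(0)
  for (start in cand) {
    if (lab[start] != 0L) next
    nlab <- nlab + 1L
    queue <- start
    lab[start] <- nlab
    sz <- 0L
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      sz <- sz + 1L
      co <- arrayInd(cur, d)
      nb <- sweep(off, 2, as.integer(co), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      new <- lin[arr[lin] & lab[lin] == 0L]
      if (length(new)) {
        lab[new] <- nlab
        queue <- c(queue, new)
      }
    }
    sizes <- c(sizes, sz)
  }
  list(labels = lab, sizes = sizes)
}

# Gaussian-random-field cluster-extent corrected p value for a cluster of
# `k` voxels at z threshold `u`, given the resel count and mask size.
# E[clusters] from the 3D Euler-characteristic density; extent tail
# P(N >= k) = exp(-beta k^(2/3)); corrected p = 1 - exp(-E[m] P(N >= k)).
grf_cluster_p <- function(k, u, resel_count, n_mask) {
  rho3 <- (4 * log(2))^(3 / 2) / (2 * pi)^2 * (u^2 - 1) * exp(-u^2 / 2)
  Em <- max(resel_count * rho3, .Machine$double.xmin)
  EN <- n_mask * stats::pnorm(u, lower.tail = FALSE)
  nbar <- EN / Em
  beta <- (gamma(5 / 2) / nbar)^(2 / 3)
  Pk <- exp(-beta * k^(2 / 3))
  min(1, max(1 - exp(-Em * Pk), .Machine$double.xmin))
}

t_to_z <- function(tv, df) {
  z <- numeric(length(tv))
  pos <- tv >= 0
  z[pos] <- stats::qnorm(stats::pt(tv[pos], df, lower.tail = FALSE),
                         lower.tail = FALSE)
  z[!pos] <- stats::qnorm(stats::pt(tv[!pos], df))
  z
}

cluster_rows_for_tail <- function(zarr, tarr, supra, connectivity, u,
                                  smoothness, affine, sign_label, df,
                                  d_kind, n1, n2) {
  cl <- label_clusters(supra, connectivity)
  if (!length(cl$sizes)) return(NULL)
  rows <- lapply(seq_along(cl$sizes), function(j) {
    vox <- which(cl$labels == j)
    peak <- vox[which.max(abs(tarr[vox]))]
    co <- arrayInd(peak, dim(tarr))
    world <- as.numeric(affine %*% c(co - 1, 1))[1:3]
    pt <- tarr[peak]
    row <- data.frame(sign = sign_label,
                      peak_x = world[1], peak_y = world[2], peak_z = world[3],
                      extent = cl$sizes[j], peak_t = pt,
                      p_corrected = grf_cluster_p(cl$sizes[j], u,
                                                  smoothness$resel_count,
                                                  smoothness$n_mask),
                      cohens_d = cohens_d_from_t(pt, d_kind, n1, n2))
    row$voxels <- I(list(vox))
    row
  })
  do.call(rbind, rows)
}

#' GRF cluster-extent corrected cluster table
#'
#' Converts the t map to z scores by tail-probability matching, thresholds
#' each tail at its share of `voxel_p` (`voxel_p / 2` per tail when
#' two-tailed), labels connected components, computes each cluster's
#' Gaussian-random-field cluster-extent corrected p, and keeps clusters with
#' corrected p at or below the tail's share of `cluster_p`.  Positive and
#' negative clusters are reported separately with their sign; the peak
#' Cohen's d is derived from the peak t.
#'
#' @param tmap A `tstat_map`.
#' @param smoothness A `smoothness_estimate`.
#' @param mask A [brain_mask].
#' @param voxel_p Voxel-level threshold (default 0.001).
#' @param cluster_p Cluster-level alpha (default 0.05).
#' @param two_tailed Logical (default TRUE): split both thresholds over the
#'   two tails.
#' @param connectivity Cluster connectivity: 6, 18 or 26 (default 26).
#' @param d_kind `"two_sample"` or `"paired"` for the Cohen's d conversion.
#' @param n1,n2 Group sizes for the d conversion.
#' @return A `cluster_table` data frame: sign, peak world coordinates,
#'   extent, peak t, corrected p, Cohen's d.  Attributes record the z
#'   threshold and parameters.
#' @export
grf_cluster_table <- function(tmap, smoothness, mask, voxel_p = 0.001,
                              cluster_p = 0.05, two_tailed = TRUE,
                              connectivity = 26L, d_kind = "two_sample",
                              n1 = NULL, n2 = NULL) {
  stop_if_not(inherits(tmap, "tstat_map"), "`tmap` must be a tstat_map")
  stop_if_not(all(is.finite(smoothness$fwhm_vox)) &&
                smoothness$resel_count > 0, "invalid smoothness estimate")
  stop_if_not(voxel_p > 0 && voxel_p < 1, "voxel_p must be in (0,1)")
  stop_if_not(cluster_p > 0 && cluster_p < 1, "cluster_p must be in (0,1)")
  if (is.null(n1)) {
    n1 <- if (d_kind == "paired") tmap$n else floor(tmap$n / 2)
  }
  if (is.null(n2) && d_kind == "two_sample") n2 <- tmap$n - n1
  p_tail <- if (two_tailed) voxel_p / 2 else voxel_p
  a_tail <- if (two_tailed) cluster_p / 2 else cluster_p
  u <- stats::qnorm(1 - p_tail)
  m <- mask$data
  zarr <- array(0, dim(tmap$data))
  zarr[m] <- t_to_z(tmap$data[m], tmap$df)
  tab <- rbind(
    cluster_rows_for_tail(zarr, tmap$data, (zarr >= u) & m, connectivity, u,
                          smoothness, tmap$affine, "+", tmap$df, d_kind,
                          n1, n2),
    if (two_tailed)
      cluster_rows_for_tail(zarr, tmap$data, (-zarr >= u) & m, connectivity,
                            u, smoothness, tmap$affine, "-", tmap$df,
                            d_kind, n1, n2)
  )
  if (is.null(tab)) {
    tab <- data.frame(sign = character(), peak_x = numeric(),
                      peak_y = numeric(), peak_z = numeric(),
                      extent = integer(), peak_t = numeric(),
                      p_corrected = numeric(), cohens_d = numeric())
    tab$voxels <- I(list())
  } else {
    tab <- tab[tab$p_corrected <= a_tail, , drop = FALSE]
    tab <- tab[order(-tab$extent), , drop = FALSE]
    rownames(tab) <- NULL
  }
  attr(tab, "z_threshold") <- u
  attr(tab, "voxel_p") <- voxel_p
  attr(tab, "cluster_p") <- cluster_p
  attr(tab, "two_tailed") <- two_tailed
  attr(tab, "df") <- tmap$df
  class(tab) <- c("cluster_table", "data.frame")
  tab
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("Cluster table (z > %.2f, %d cluster(s)):\n",
              attr(x, "z_threshold") %||% NA_real_, nrow(x)))
  print.data.frame(x[, setdiff(names(x), "voxels"), drop = FALSE],
                   digits = 4)
  invisible(x)
}

#' Permutation cluster-extent cross-check
#'
#' Nonparametric analogue of [grf_cluster_table()]: builds the null
#' distribution of the maximum suprathreshold cluster extent by permuting
#' group labels (two-sample) or flipping difference signs (paired), and
#' assigns each observed cluster the corrected p
#' `(1 + #{null max >= extent}) / (n_perm + 1)`.
#'
#' @param maps List of per-subject 3D maps (difference maps for
#'   `kind = "paired"`).
#' @param design A [build_design()] result (ignored for paired).
#' @param mask A [brain_mask].
#' @param voxel_p Voxel threshold (split per tail when two-tailed).
#' @param cluster_p Cluster alpha used for the significance flag.
#' @param n_perm Number of permutations (warning below 100).
#' @param seed Integer seed.
#' @param kind `"two_sample"` or `"paired"`.
#' @param two_tailed,connectivity As in [grf_cluster_table()].
#' @return A `cluster_table` data frame with permutation-corrected p values
#'   and a `significant` flag at `cluster_p`.
#' @export
permutation_cluster_oracle <- function(maps, design = NULL, mask,
                                       voxel_p = 0.001, cluster_p = 0.05,
                                       n_perm = 1000L, seed = 1L,
                                       kind = c("two_sample", "paired"),
                                       two_tailed = TRUE,
                                       connectivity = 26L) {
  kind <- match.arg(kind)
  if (n_perm < 100) warning("n_perm < 100: permutation p values are coarse")
  p_tail <- if (two_tailed) voxel_p / 2 else voxel_p
  u <- stats::qnorm(1 - p_tail)
  m <- mask$data

  fit_extents <- function(tm) {
    zarr <- array(0, dim(tm$data))
    zarr[m] <- t_to_z(tm$data[m], tm$df)
    sup_p <- (zarr >= u) & m
    sup_n <- if (two_tailed) (-zarr >= u) & m else
      array(FALSE, dim(zarr))
    list(z = zarr,
         pos = label_clusters(sup_p, connectivity),
         neg = label_clusters(sup_n, connectivity))
  }

  if (kind == "two_sample") {
    grp <- design$groups
    stop_if_not(nlevels(factor(as.character(grp))) == 2L,
                "nothing to permute: all labels identical")
    fit <- function(perm) {
      X <- design$X
      X[, 2] <- X[perm, 2]
      voxelwise_glm_contrast(maps, list(X = X, contrast = design$contrast),
                             mask)
    }
    n <- length(maps)
    obs_tm <- voxelwise_glm_contrast(maps, design, mask)
  } else {
    n <- length(maps)
    stop_if_not(n >= 2L, "need at least 2 difference maps")
    zero <- lapply(maps, function(x) {
      arr <- if (inherits(x, "reho_map")) x$data else x
      array(0, dim(arr))
    })
    fit <- function(signs) {
      flipped <- lapply(seq_len(n), function(i) {
        arr <- if (inherits(maps[[i]], "reho_map")) maps[[i]]$data else
          maps[[i]]
        arr * signs[i]
      })
      paired_t_map(zero, flipped, mask)
    }
    obs_tm <- paired_t_map(zero, maps, mask)
  }

  obs <- fit_extents(obs_tm)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      tm <- if (kind == "two_sample") fit(sample.int(n)) else
        fit(sample(c(-1, 1), n, replace = TRUE))
      ex <- fit_extents(tm)
      max(0L, ex$pos$sizes, ex$neg$sizes)
    }, numeric(1))
  })

  one_tail <- function(cl, sign_label) {
    if (!length(cl$sizes)) return(NULL)
    rows <- lapply(seq_along(cl$sizes), function(j) {
      vox <- which(cl$labels == j)
      peak <- vox[which.max(abs(obs_tm$data[vox]))]
      co <- arrayInd(peak, dim(obs_tm$data))
      world <- as.numeric(obs_tm$affine %*% c(co - 1, 1))[1:3]
      k <- cl$sizes[j]
      row <- data.frame(sign = sign_label, peak_x = world[1],
                        peak_y = world[2], peak_z = world[3], extent = k,
                        peak_t = obs_tm$data[peak],
                        p_corrected = (1 + sum(null_max >= k)) / (n_perm + 1))
      row$voxels <- I(list(vox))
      row
    })
    do.call(rbind, rows)
  }
  tab <- rbind(one_tail(obs$pos, "+"), one_tail(obs$neg, "-"))
  if (is.null(tab)) {
    tab <- data.frame(sign = character(), peak_x = numeric(),
                      peak_y = numeric(), peak_z = numeric(),
                      extent = integer(), peak_t = numeric(),
                      p_corrected = numeric())
    tab$voxels <- I(list())
  } else {
    tab <- tab[order(-tab$extent), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab$significant <- tab$p_corrected <= cluster_p
  attr(tab, "z_threshold") <- u
  attr(tab, "n_perm") <- n_perm
  class(tab) <- c("cluster_table", "data.frame")
  tab
}

#' Cohen's d from a t statistic
#'
#' Two-sample: `d = t * sqrt(1/n1 + 1/n2)`.  Paired: `d = t / sqrt(n)`
#' (standardized mean difference of the paired differences); other published
#' paired conversions exist, so the kind is explicit.
#'
#' @param t t statistic.
#' @param kind `"two_sample"` or `"paired"`.
#' @param n1 First group size (or the pair count for paired).
#' @param n2 Second group size (two-sample only).
#' @return Cohen's d.
#' @export
cohens_d_from_t <- function(t, kind = c("two_sample", "paired"), n1,
                            n2 = NULL) {
  kind <- match.arg(kind)
  stop_if_not(n1 > 0, "n1 must be positive")
  if (kind == "two_sample") {
    stop_if_not(!is.null(n2) && n2 > 0, "n2 must be positive")
    t * sqrt(1 / n1 + 1 / n2)
  } else {
    t / sqrt(n1)
  }
}

#' Pearson chi-square for a 2x2 table
#'
#' Without continuity correction, plus Cramer's V (`sqrt(chi2 / N)`).
#'
#' @param table 2x2 matrix of nonnegative counts, or a length-4 vector
#'   (filled by column).
#' @return List: `statistic`, `df` (1), `p_value`, `cramers_v`.
#' @export
chi_square_2x2 <- function(table) {
  tab <- if (is.matrix(table)) table else matrix(table, 2, 2)
  stop_if_not(all(dim(tab) == c(2, 2)), "need a 2x2 table")
  stop_if_not(all(tab >= 0), "counts must be nonnegative")
  stop_if_not(all(rowSums(tab) > 0) && all(colSums(tab) > 0),
              "zero marginal in the table")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = 1L,
       p_value = unname(ct$p.value),
       cramers_v = sqrt(unname(ct$statistic) / sum(tab)))
}

#' Correlate cluster features with clinical scores
#'
#' For each feature-score pair, picks Pearson when both columns pass a
#' Shapiro-Wilk normality test at 0.05 (mode `"auto"`), otherwise Spearman,
#' and flags Bonferroni significance at `alpha / n_tests`.
#'
#' @param cluster_features Data frame or matrix of per-subject cluster-mean
#'   values.
#' @param scores Data frame or matrix of clinical score columns.
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @param n_tests Bonferroni divisor (default: number of pairs tested).
#' @param alpha Family-wise level (default 0.05).
#' @return Data frame: feature, score, method, estimate, p_value,
#'   significant.
#' @export
correlate_with_symptoms <- function(cluster_features, scores,
                                    method = c("auto", "pearson", "spearman"),
                                    n_tests = NULL, alpha = 0.05) {
  method <- match.arg(method)
  f <- as.data.frame(cluster_features)
  s <- as.data.frame(scores)
  if (is.null(n_tests)) n_tests <- ncol(f) * ncol(s)
  rows <- list()
  for (i in seq_len(ncol(f))) for (j in seq_len(ncol(s))) {
    x <- f[[i]]; y <- s[[j]]
    ok <- stats::complete.cases(x, y)
    stop_if_not(sum(ok) >= 3L, "fewer than 3 complete pairs")
    x <- x[ok]; y <- y[ok]
    use <- method
    if (method == "auto") {
      norm_ok <- stats::shapiro.test(x)$p.value > 0.05 &&
        stats::shapiro.test(y)$p.value > 0.05
      use <- if (norm_ok) "pearson" else "spearman"
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = use))
    rows[[length(rows) + 1L]] <- data.frame(
      feature = colnames(f)[i], score = colnames(s)[j], method = use,
      estimate = unname(ct$estimate), p_value = ct$p.value,
      significant = ct$p.value < alpha / n_tests)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
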