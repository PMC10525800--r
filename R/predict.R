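#' Treatment-response reduction rate
#'
#' `rr = (baseline - week4) / baseline`; positive values mean improvement,
#' negative values worsening.  Vectorized.
#'
#' @param baseline Baseline scale score(s), must be positive.
#' @param week4 Follow-up score(s).
#' @return Reduction rate(s).
#' @export
reduction_rate <- function(baseline, week4) {
  stop_if_not(all(baseline > 0),
              "reduction rate undefined for baseline <= 0; reject the subject")
  (baseline - week4) / baseline
}

#' SVR configuration
#'
#' Settings for the epsilon-insensitive RBF support vector regression:
#' power-of-two grids for cost C and kernel width gamma, fold count, and the
#' grid-search mode.  `"paper"` mode selects the (C, gamma) pair minimizing
#' the aggregated out-of-fold MSE over the fixed folds and reports that
#' pair's cross-validated predictions; `"nested"` mode runs the grid search
#' inside each training fold only (no selection leakage) and is the sound
#' default for new data.
#'
#' @param c_exponents,gamma_exponents Integer exponents; the grids are
#'   `2^exponents` (defaults -10..10).
#' @param epsilon Epsilon-insensitive tube width (default 0.1, the libsvm
#'   default).
#' @param n_folds Cross-validation folds (default 5).
#' @param mode `"paper"` or `"nested"`.
#' @param standardize Standardize features using training-fold statistics
#'   (default TRUE).
#' @param seed Integer seed for the fold shuffle.
#' @return An object of class `svr_config`.
#' @export
svr_config <- function(c_exponents = -10:10, gamma_exponents = -10:10,
                       epsilon = 0.1, n_folds = 5L,
                       mode = c("paper", "nested"), standardize = TRUE,
                       seed = 1L) {
  mode <- match.arg(mode)
  stop_if_not(length(c_exponents) >= 1 && length(gamma_exponents) >= 1,
              "parameter grids must be nonempty")
  stop_if_not(n_folds >= 2L, "n_folds must be at least 2")
  stop_if_not(epsilon > 0, "epsilon must be positive")
  structure(list(c_exponents = as.integer(c_exponents),
                 gamma_exponents = as.integer(gamma_exponents),
                 epsilon = epsilon, n_folds = as.integer(n_folds),
                 mode = mode, standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "svr_config")
}

# Seeded shuffle then contiguous split into k folds of near-equal size.
make_folds <- function(n, k, seed) {
  stop_if_not(k <= n, "more folds than subjects")
  sizes <- diff(round(seq(0, n, length.out = k + 1)))
  with_seed(seed, {
    perm <- sample.int(n)
    fold <- integer(n)
    fold[perm] <- rep(seq_len(k), times = sizes)
    fold
  })
}

# Out-of-fold SVR predictions for one (C, gamma) pair over fixed folds.
svr_oof <- function(X, y, fold, C, gamma, epsilon, standardize) {
  pred <- numeric(length(y))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[!tr, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2, stats::sd)
      sdv[sdv == 0] <- 1
      Xtr <- scale(Xtr, mu, sdv)
      Xte <- scale(Xte, mu, sdv)
    }
    pred[!tr] <- tryCatch({
      fitted <- e1071::svm(x = Xtr, y = y[tr], type = "eps-regression",
                           kernel = "radial", cost = C, gamma = gamma,
                           epsilon = epsilon, scale = FALSE)
      as.numeric(stats::predict(fitted, Xte))
    }, error = function(e) {
      # no support vectors (all residuals inside the epsilon tube):
      # libsvm cannot predict, so fall back to the flat fit at the mean
      if (grepl("empty", conditionMessage(e), ignore.case = TRUE)) {
        rep(mean(y[tr]), sum(!tr))
      } else {
        stop(e)
      }
    })
  }
  pred
}

#' Cross-validated SVR prediction of treatment response
#'
#' RBF-kernel epsilon-SVR with 5-fold cross-validation and a power-of-two
#' grid search over C and gamma.  Every subject is predicted exactly once
#' from folds not containing it; performance is the aggregated out-of-fold
#' MSE and the Pearson correlation between predicted and observed targets.
#' Deterministic given the config seed.
#'
#' @param features Numeric matrix or data frame, subjects x features.
#' @param targets Numeric vector of observed reduction rates.
#' @param config An [svr_config()].
#' @return An object of class `svr_run`: `predictions`, `mse`, `pearson_r`,
#'   `fold`, `chosen` (per-mode (C, gamma) exponents), `mode`, `config`,
#'   `features`, `targets`.
#' @export
svr_cv_predict <- function(features, targets, config = svr_config()) {
  X <- as.matrix(features)
  y <- as.numeric(targets)
  n <- length(y)
  stop_if_not(nrow(X) == n, "feature rows must match targets")
  stop_if_not(n >= 10L, "need at least 10 subjects")
  stop_if_not(!anyNA(X) && !anyNA(y), "missing features or targets")
  k <- config$n_folds
  stop_if_not(k <= n, "more folds than subjects")
  fold <- make_folds(n, k, config$seed)
  grid <- expand.grid(ce = config$c_exponents, ge = config$gamma_exponents)

  if (config$mode == "paper") {
    best <- NULL
    for (i in seq_len(nrow(grid))) {
      pred <- svr_oof(X, y, fold, 2^grid$ce[i], 2^grid$ge[i],
                      config$epsilon, config$standardize)
      mse <- mean((pred - y)^2)
      if (is.null(best) || mse < best$mse) {
        best <- list(mse = mse, pred = pred,
                     chosen = c(c_exp = grid$ce[i], gamma_exp = grid$ge[i]))
      }
    }
    pred <- best$pred
    chosen <- best$chosen
  } else {
    pred <- numeric(n)
    chosen <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- which(fold != f)
      inner_k <- min(k, length(tr))
      inner_fold <- make_folds(length(tr), inner_k,
                               child_seed(config$seed, 3L, f))
      best <- NULL
      for (i in seq_len(nrow(grid))) {
        ip <- svr_oof(X[tr, , drop = FALSE], y[tr], inner_fold,
                      2^grid$ce[i], 2^grid$ge[i], config$epsilon,
                      config$standardize)
        mse <- mean((ip - y[tr])^2)
        if (is.null(best) || mse < best$mse) {
          best <- list(mse = mse,
                       chosen = c(c_exp = grid$ce[i], gamma_exp = grid$ge[i]))
        }
      }
      chosen[[f]] <- best$chosen
      pred[fold == f] <- svr_oof(
        X, y, ifelse(fold == f, 1L, 2L), 2^best$chosen[1], 2^best$chosen[2],
        config$epsilon, config$standardize)[fold == f]
    }
    names(chosen) <- sprintf("fold%d", seq_len(k))
  }

  mse <- mean((pred - y)^2)
  r <- if (stats::sd(y) == 0 || stats::sd(pred) == 0) {
    warning("constant targets or predictions: Pearson r undefined (NaN)")
    NaN
  } else stats::cor(pred, y)
  structure(list(predictions = pred, mse = mse, pearson_r = r, fold = fold,
                 chosen = chosen, mode = config$mode, config = config,
                 features = X, targets = y),
            class = "svr_run")
}

#' @export
print.svr_run <- function(x, ...) {
  cat(sprintf("<svr_run> %s mode, n = %d, %d folds: MSE = %.4f, Pearson r = %.4f\n",
              x$mode, length(x$targets), x$config$n_folds, x$mse,
              x$pearson_r))
  invisible(x)
}

#' @export
summary.svr_run <- function(object, ...) {
  print(object)
  if (object$mode == "paper") {
    cat(sprintf("  chosen C = 2^%d, gamma = 2^%d\n",
                object$chosen["c_exp"], object$chosen["gamma_exp"]))
  } else {
    for (nm in names(object$chosen)) {
      cat(sprintf("  %s: C = 2^%d, gamma = 2^%d\n", nm,
                  object$chosen[[nm]]["c_exp"],
                  object$chosen[[nm]]["gamma_exp"]))
    }
  }
  invisible(object)
}

#' Scatter plot of predicted versus observed reduction rates
#'
#' @param x An `svr_run`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.svr_run <- function(x, ...) {
  graphics::plot(x$targets, x$predictions,
                 xlab = "observed reduction rate",
                 ylab = "predicted reduction rate",
                 main = sprintf("SVR (%s): r = %.3f, MSE = %.4f",
                                x$mode, x$pearson_r, x$mse), ...)
  graphics::abline(stats::lm(x$predictions ~ x$targets), lty = 2)
  invisible(x)
}

#' Permutation significance of the SVR performance
#'
#' Shuffles the targets `n_perm` times, reruns the identical
#' cross-validated grid-search procedure on each shuffle, and counts how
#' often the null beats the observed performance.  The default p value is
#' the plain count over `n_perm` (so a strong signal can yield p = 0); the
#' add-one form `(k + 1) / (n_perm + 1)` is also returned and is always at
#' least as large.
#'
#' @param features,targets,config As in [svr_cv_predict()].
#' @param n_perm Number of permutations (default 5000).
#' @return List: `p_r`, `p_mse` (plain rule), `p_r_add_one`,
#'   `p_mse_add_one`, `observed` (the real `svr_run`), `null_r`,
#'   `null_mse`.
#' @export
permutation_significance <- function(features, targets,
                                     config = svr_config(),
                                     n_perm = 5000L) {
  stop_if_not(n_perm >= 1L, "n_perm must be at least 1")
  stop_if_not(stats::sd(targets) > 0, "constant targets cannot be permuted")
  obs <- svr_cv_predict(features, targets, config)
  null_r <- numeric(n_perm)
  null_mse <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yb <- with_seed(child_seed(config$seed, 4L, b), sample(targets))
    run <- suppressWarnings(svr_cv_predict(features, yb, config))
    null_r[b] <- run$pearson_r
    null_mse[b] <- run$mse
  }
  k_r <- sum(null_r >= obs$pearson_r, na.rm = TRUE)
  k_m <- sum(null_mse <= obs$mse, na.rm = TRUE)
  list(p_r = k_r / n_perm, p_mse = k_m / n_perm,
       p_r_add_one = (k_r + 1) / (n_perm + 1),
       p_mse_add_one = (k_m + 1) / (n_perm + 1),
       observed = obs, null_r = null_r, null_mse = null_mse)
}

#' Per-cluster mean features from subject maps
#'
#' Extracts, for each subject, the mean map value within each cluster of a
#' cluster table — the feature matrix for treatment-response prediction.
#'
#' @param maps List of per-subject 3D maps ([reho_map] or arrays).
#' @param cluster_table A `cluster_table` carrying a `voxels` list column.
#' @return Numeric matrix, subjects x clusters.
#' @export
extract_cluster_features <- function(maps, cluster_table) {
  stop_if_not(!is.null(cluster_table$voxels),
              "cluster table has no voxel lists")
  n <- length(maps)
  out <- matrix(0, n, nrow(cluster_table))
  for (i in seq_len(n)) {
    arr <- if (inherits(maps[[i]], "reho_map")) maps[[i]]$data else maps[[i]]
    for (j in seq_len(nrow(cluster_table))) {
      out[i, j] <- mean(arr[cluster_table$voxels[[j]]])
    }
  }
  colnames(out) <- sprintf("cluster%02d", seq_len(nrow(cluster_table)))
  out
}
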