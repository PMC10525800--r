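#' Region-of-interest specification for the synthetic cohort
#'
#' An ROI plants local temporal coherence: all voxels in `voxel_set` share a
#' latent time series with mixing weight `coherence` (the fraction of each
#' voxel's variance carried by the shared series).  `group_delta` shifts the
#' coherence for group 2, creating a known between-group ReHo difference.
#'
#' @param name Character label.
#' @param voxel_set Integer matrix, one row per voxel, columns x, y, z
#'   (1-based grid indices).
#' @param coherence Shared-variance fraction in `[0, 1)` for group 1.
#' @param group_delta Signed offset added to `coherence` for group 2;
#'   `coherence + group_delta` must also lie in `[0, 1)`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, voxel_set, coherence, group_delta = 0) {
  voxel_set <- as.matrix(voxel_set)
  storage.mode(voxel_set) <- "integer"
  stop_if_not(nrow(voxel_set) >= 1L && ncol(voxel_set) == 3L,
              "`voxel_set` must be a nonempty n x 3 index matrix")
  stop_if_not(coherence >= 0 && coherence < 1, "`coherence` must be in [0, 1)")
  c2 <- coherence + group_delta
  stop_if_not(c2 >= 0 && c2 < 1, "`coherence + group_delta` must be in [0, 1)")
  structure(list(name = name, voxel_set = voxel_set,
                 coherence = coherence, group_delta = group_delta),
            class = "roi_spec")
}

#' Cuboid ROI helper
#'
#' @param name Character label.
#' @param from,to Length-3 integer corners (inclusive).
#' @inheritParams roi_spec
#' @return An [roi_spec].
#' @export
roi_box <- function(name, from, to, coherence, group_delta = 0) {
  g <- as.matrix(expand.grid(x = from[1]:to[1], y = from[2]:to[2],
                             z = from[3]:to[3]))
  roi_spec(name, g, coherence, group_delta)
}

#' Synthetic-cohort configuration
#'
#' Defines the study conditions the generator emulates: two groups of
#' `n_per_group` subjects, BOLD series of `n_timepoints` volumes at
#' `tr_seconds`, planted coherence ROIs, motion traces, and a linear outcome
#' model mapping ROI-mean ReHo to the treatment-response reduction rate.
#'
#' @param grid_shape Length-3 positive integers, the image grid.
#' @param n_timepoints Volumes per series (must exceed 10, so the series
#'   survives initial-volume removal).
#' @param tr_seconds Repetition time in seconds.
#' @param n_per_group Subjects per group.
#' @param rois List of [roi_spec] objects.
#' @param noise_sd Standard deviation of the voxel noise.
#' @param motion_amplitude Bound (mm) on the translation random walk;
#'   rotations use `motion_amplitude / 50` radians.  Zero gives a motionless
#'   trace.
#' @param drift_amplitude Amplitude of a deterministic linear drift added to
#'   every voxel, in units of `noise_sd` (exercises the detrending stage).
#' @param outcome_model List with `intercept`, `coef` (one per ROI) and
#'   `noise_sd`: reduction rate = intercept + coef . ROI-mean ReHo + noise.
#' @param voxel_size_mm Voxel size in mm.
#' @param seed Integer master seed; all randomness derives from it via
#'   [child_seed()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(grid_shape = c(24, 24, 24), n_timepoints = 120L,
                          tr_seconds = 2, n_per_group = 10L, rois = list(),
                          noise_sd = 1, motion_amplitude = 0.3,
                          drift_amplitude = 0.2,
                          outcome_model = list(intercept = 0.5,
                                               coef = rep(0, length(rois)),
                                               noise_sd = 0.05),
                          voxel_size_mm = c(3, 3, 3), seed = 1L) {
  cfg <- structure(list(grid_shape = as.integer(grid_shape),
                        n_timepoints = as.integer(n_timepoints),
                        tr_seconds = tr_seconds,
                        n_per_group = as.integer(n_per_group),
                        rois = rois, noise_sd = noise_sd,
                        motion_amplitude = motion_amplitude,
                        drift_amplitude = drift_amplitude,
                        outcome_model = outcome_model,
                        voxel_size_mm = voxel_size_mm,
                        seed = as.integer(seed)),
                   class = "cohort_config")
  check_cohort_config(cfg)
  cfg
}

check_cohort_config <- function(cfg) {
  stop_if_not(length(cfg$grid_shape) == 3L && all(cfg$grid_shape >= 3L),
              "grid_shape must be 3 integers >= 3")
  stop_if_not(cfg$n_timepoints > 10L, "n_timepoints must exceed 10")
  stop_if_not(cfg$tr_seconds > 0, "tr_seconds must be positive")
  stop_if_not(cfg$n_per_group >= 1L, "n_per_group must be positive")
  stop_if_not(cfg$noise_sd > 0, "noise_sd must be positive")
  stop_if_not(cfg$motion_amplitude >= 0, "motion_amplitude must be nonnegative")
  for (r in cfg$rois) {
    stop_if_not(inherits(r, "roi_spec"), "rois must be roi_spec objects")
    inside <- r$voxel_set >= 1L &
      r$voxel_set <= matrix(cfg$grid_shape, nrow(r$voxel_set), 3, byrow = TRUE)
    stop_if_not(all(inside), sprintf("ROI '%s' lies outside the grid", r$name))
  }
  om <- cfg$outcome_model
  stop_if_not(length(om$coef) == length(cfg$rois),
              "outcome_model$coef needs one coefficient per ROI")
  stop_if_not(om$noise_sd >= 0, "outcome noise sd must be nonnegative")
  invisible(cfg)
}

#' Default mask for a synthetic grid: the interior
#'
#' Excludes a 1-voxel border so every in-mask voxel has its full 27-voxel
#' neighborhood available.
#'
#' @param config A [cohort_config].
#' @return A [brain_mask].
#' @export
cohort_mask <- function(config) {
  g <- config$grid_shape
  m <- array(FALSE, g)
  m[2:(g[1] - 1), 2:(g[2] - 1), 2:(g[3] - 1)] <- TRUE
  brain_mask(m, voxel_size_mm = config$voxel_size_mm)
}

#' Generate one subject's BOLD series and motion trace
#'
#' Each voxel's series is `sqrt(1 - c) * noise + sqrt(c) * latent`, where
#' `latent` is a time series shared by all voxels of the voxel's ROI and `c`
#' its coherence (0 outside ROIs), all scaled by `noise_sd`; a deterministic
#' low-amplitude linear drift is added on top.  The motion trace is a bounded
#' random walk scaled by `motion_amplitude`.
#'
#' @param config A [cohort_config].
#' @param group Group label, 1 or 2 (group 2 uses `coherence + group_delta`).
#' @param subject_seed Integer seed for this subject.
#' @return A list with elements `bold` ([bold4d]) and `motion`
#'   ([motion_trace]).
#' @export
generate_bold_subject <- function(config, group, subject_seed) {
  check_cohort_config(config)
  stop_if_not(group %in% c(1L, 2L), "group must be 1 or 2")
  g <- config$grid_shape
  nt <- config$n_timepoints
  with_seed(subject_seed, {
    dat <- array(stats::rnorm(prod(g) * nt), dim = c(g, nt))
    for (r in config$rois) {
      cc <- r$coherence + if (group == 2L) r$group_delta else 0
      latent <- stats::rnorm(nt)
      lin <- (r$voxel_set[, 1] - 1L) +
        g[1] * (r$voxel_set[, 2] - 1L) +
        g[1] * g[2] * (r$voxel_set[, 3] - 1L) + 1L
      step <- prod(g)
      for (t in seq_len(nt)) {
        off <- (t - 1L) * step
        dat[lin + off] <- sqrt(1 - cc) * dat[lin + off] + sqrt(cc) * latent[t]
      }
    }
    dat <- dat * config$noise_sd
    if (config$drift_amplitude > 0) {
      drift <- config$drift_amplitude * config$noise_sd *
        seq(-1, 1, length.out = nt)
      dat <- dat + rep(drift, each = prod(g))
    }
    amp <- config$motion_amplitude
    walk1 <- function(scale) {
      if (scale <= 0) return(numeric(nt) * 0)
      w <- cumsum(stats::rnorm(nt, sd = scale / sqrt(nt)))
      pmin(pmax(w, -scale), scale)
    }
    mot <- cbind(walk1(amp), walk1(amp), walk1(amp),
                 walk1(amp / 50), walk1(amp / 50), walk1(amp / 50))
    if (amp <= 0) mot <- matrix(0, nt, 6)
    list(bold = bold4d(dat, voxel_size_mm = config$voxel_size_mm,
                       tr_seconds = config$tr_seconds),
         motion = motion_trace(mot))
  })
}

#' Generate clinical covariates and treatment outcomes
#'
#' Baseline HAMA/HAMD are drawn from fixed integer ranges (HAMA 10-25, HAMD
#' 7-21, matching moderate symptom severity); age from 18-60, education 6-19
#' years, sex balanced.  The week-4 score is set so that the reduction rate
#' equals the linear outcome model applied to the subject's ROI-mean ReHo
#' features plus Gaussian noise; week-4 scores are rounded to integers and
#' clipped at 0 (rating scales are integer-valued), and the exact pre-rounding
#' reduction rates are returned in `rr_hama_exact` / `rr_hamd_exact`.
#'
#' @param config A [cohort_config] (supplies the outcome model).
#' @param reho_features Numeric matrix, subjects x ROIs, of ROI-mean ReHo.
#' @param subject_seeds Integer vector, one seed per subject.
#' @return A data frame of clinical columns, one row per subject.
#' @export
generate_clinical_outcomes <- function(config, reho_features, subject_seeds) {
  reho_features <- as.matrix(reho_features)
  n <- length(subject_seeds)
  stop_if_not(nrow(reho_features) == n,
              "feature rows must match subject_seeds length")
  om <- config$outcome_model
  linear <- rep(om$intercept, n) +
    if (ncol(reho_features) > 0) as.numeric(reho_features %*% om$coef) else 0
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- with_seed(subject_seeds[i], {
      age <- sample(18:60, 1)
      sex <- sample(c("female", "male"), 1)
      edu <- sample(6:19, 1)
      hama0 <- sample(10:25, 1)
      hamd0 <- sample(7:21, 1)
      rr_a <- linear[i] + stats::rnorm(1, sd = om$noise_sd)
      rr_d <- linear[i] + stats::rnorm(1, sd = om$noise_sd)
      data.frame(age = age, sex = sex, education = edu,
                 hama_baseline = hama0,
                 hama_week4 = max(0, round(hama0 * (1 - rr_a))),
                 hamd_baseline = hamd0,
                 hamd_week4 = max(0, round(hamd0 * (1 - rr_d))),
                 rr_hama_exact = rr_a, rr_hamd_exact = rr_d)
    })
  }
  do.call(rbind, out)
}

#' Generate a full synthetic cohort
#'
#' Produces `n_per_group` subjects per group with BOLD series, motion traces,
#' clinical covariates and treatment outcomes, plus the ground-truth block
#' (per-ROI coherence per group, outcome-model coefficients, and the ReHo
#' features the outcomes were generated from).  Outcome features are the
#' ROI means of each subject's whole-brain-mean-normalized raw ReHo map.
#'
#' @param config A [cohort_config].
#' @return An object of class `synthetic_cohort`: list with `subjects` (each
#'   holding `bold`, `motion`, `subject_id`, `group`), `clinical` (data
#'   frame), `mask`, `truth`, and `config`.
#' @export
generate_cohort <- function(config) {
  check_cohort_config(config)
  mask <- cohort_mask(config)
  n <- 2L * config$n_per_group
  groups <- rep(1:2, each = config$n_per_group)
  subjects <- vector("list", n)
  nroi <- length(config$rois)
  feats <- matrix(0, n, max(nroi, 0))
  for (i in seq_len(n)) {
    sim <- generate_bold_subject(config, groups[i],
                                 child_seed(config$seed, 1L, i))
    subjects[[i]] <- list(subject_id = sprintf("sub-%03d", i),
                          group = groups[i],
                          bold = sim$bold, motion = sim$motion)
    if (nroi > 0) {
      rmap <- normalize_reho(reho_map(sim$bold, mask), mask)
      feats[i, ] <- vapply(config$rois, function(r) {
        mean(rmap$data[r$voxel_set])
      }, numeric(1))
    }
  }
  if (nroi > 0) colnames(feats) <- vapply(config$rois, `[[`, "", "name")
  clin <- generate_clinical_outcomes(
    config, feats, vapply(seq_len(n), function(i) child_seed(config$seed, 2L, i),
                          integer(1)))
  clin <- cbind(data.frame(subject_id = vapply(subjects, `[[`, "", "subject_id"),
                           group = groups), clin)
  truth <- list(
    roi_coherence = if (nroi > 0) {
      data.frame(roi = vapply(config$rois, `[[`, "", "name"),
                 coherence_group1 = vapply(config$rois, `[[`, 0, "coherence"),
                 coherence_group2 = vapply(config$rois, function(r)
                   r$coherence + r$group_delta, numeric(1)))
    } else data.frame(roi = character(), coherence_group1 = numeric(),
                      coherence_group2 = numeric()),
    outcome_model = config$outcome_model,
    reho_features = feats)
  structure(list(subjects = subjects, clinical = clin, mask = mask,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d per group), grid %s, %d volumes, %d ROI(s)\n",
              length(x$subjects), x$config$n_per_group,
              paste(x$config$grid_shape, collapse = "x"),
              x$config$n_timepoints, length(x$config$rois)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' BOLD series and mask as uncompressed NIfTI-1, motion traces as 6-column
#' text, the clinical table as TSV, and the configuration echo as YAML.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(bold = character(0), motion = character(0))
  for (s in cohort$subjects) {
    bp <- file.path(dir, paste0(s$subject_id, "_bold.nii"))
    mp <- file.path(dir, paste0(s$subject_id, "_motion.txt"))
    write_bold_nifti(s$bold, bp)
    write_motion_params(s$motion, mp)
    paths$bold <- c(paths$bold, bp)
    paths$motion <- c(paths$motion, mp)
  }
  paths$mask <- file.path(dir, "mask.nii")
  write_map_nifti(cohort$mask, paths$mask)
  paths$clinical <- file.path(dir, "clinical.tsv")
  utils::write.table(cohort$clinical, paths$clinical, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  paths$config <- file.path(dir, "cohort_config.yaml")
  cfg <- cohort$config
  yaml::write_yaml(list(grid_shape = cfg$grid_shape,
                        n_timepoints = cfg$n_timepoints,
                        tr_seconds = cfg$tr_seconds,
                        n_per_group = cfg$n_per_group,
                        noise_sd = cfg$noise_sd,
                        motion_amplitude = cfg$motion_amplitude,
                        seed = cfg$seed), paths$config)
  invisible(paths)
}
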