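default_pipeline_rois <- function() {
  list(
    roi_box("sensorimotor_A", c(4, 4, 4), c(8, 8, 7), coherence = 0.2,
            group_delta = 0.4),
    roi_box("frontal_B", c(11, 11, 10), c(15, 15, 13), coherence = 0.55,
            group_delta = -0.35)
  )
}

#' Pipeline run configuration
#'
#' Bundles every stage's parameters: the synthetic-cohort config (or paths
#' to existing data), preprocessing settings, ReHo settings, statistical
#' thresholds, SVR settings, the output directory and the global seed.
#'
#' @param out_dir Output directory for all artifacts.
#' @param cohort A [cohort_config()] used when no input paths are given.
#'   The default plants two coherence ROIs (one lower, one higher in group
#'   1) with an outcome model tied to their ReHo.
#' @param paths Optional list for pre-existing data: `bold` (vector of
#'   NIfTI paths), `motion` (vector), `mask` (one path), `clinical` (TSV
#'   path).  When given, the simulate stage ingests instead of generating.
#' @param drop_volumes Leading volumes to remove (default 10).
#' @param bandpass Length-2 pass band in Hz (default 0.01-0.1).
#' @param trans_mm,rot_deg Motion-screening thresholds.
#' @param neighborhood_k ReHo stencil (7/19/27).
#' @param fwhm_mm Smoothing kernel FWHM in mm.
#' @param voxel_p,cluster_p GRF thresholds.
#' @param covariates Nuisance covariates for the group GLM.
#' @param svr An [svr_config()].
#' @param n_perm Permutations for the SVR significance test (0 disables).
#' @param seed Global seed; expands into per-stage, per-subject seeds via
#'   [child_seed()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       cohort = NULL,
                       paths = NULL,
                       drop_volumes = 10L,
                       bandpass = c(0.01, 0.1),
                       trans_mm = 2, rot_deg = 2,
                       neighborhood_k = 27L,
                       fwhm_mm = 4,
                       voxel_p = 0.001, cluster_p = 0.05,
                       covariates = c("age", "sex", "education", "mean_fd"),
                       svr = svr_config(c_exponents = seq(-6L, 6L, 3L),
                                        gamma_exponents = seq(-6L, 6L, 3L)),
                       n_perm = 50L,
                       seed = 1L) {
  if (is.null(cohort) && is.null(paths)) {
    cohort <- cohort_config(grid_shape = c(18, 18, 18), n_timepoints = 80L,
                            n_per_group = 10L,
                            rois = default_pipeline_rois(),
                            outcome_model = list(intercept = 0.3,
                                                 coef = c(0.8, -0.5),
                                                 noise_sd = 0.05),
                            seed = child_seed(seed, 0L, 0L))
  }
  structure(list(out_dir = out_dir, cohort = cohort, paths = paths,
                 drop_volumes = as.integer(drop_volumes),
                 bandpass = bandpass, trans_mm = trans_mm, rot_deg = rot_deg,
                 neighborhood_k = as.integer(neighborhood_k),
                 fwhm_mm = fwhm_mm, voxel_p = voxel_p, cluster_p = cluster_p,
                 covariates = covariates, svr = svr,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Always returns (never stops): an empty character vector when the
#' configuration is valid, otherwise one message per violation naming the
#' offending key.
#'
#' @param config A [run_config()].
#' @return Character vector of violations.
#' @export
validate_run_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (is.null(config$out_dir) || !nzchar(config$out_dir))
    add("out_dir: missing output directory")
  if (!(config$voxel_p > 0 && config$voxel_p < 1))
    add("voxel_p: must be in (0, 1)")
  if (!(config$cluster_p > 0 && config$cluster_p < 1))
    add("cluster_p: must be in (0, 1)")
  if (config$drop_volumes < 0) add("drop_volumes: must be nonnegative")
  if (!(config$neighborhood_k %in% c(7L, 19L, 27L)))
    add("neighborhood_k: must be 7, 19 or 27")
  if (config$fwhm_mm < 0) add("fwhm_mm: must be nonnegative")
  if (length(config$bandpass) != 2L ||
      !(config$bandpass[1] > 0 && config$bandpass[1] < config$bandpass[2]))
    add("bandpass: need 0 < low < high")
  if (config$trans_mm <= 0) add("trans_mm: must be positive")
  if (config$rot_deg <= 0) add("rot_deg: must be positive")
  if (!is.null(config$svr) && config$svr$n_folds < 2)
    add("svr$n_folds: must be at least 2")
  if (config$n_perm < 0) add("n_perm: must be nonnegative")
  if (!is.null(config$cohort)) {
    ok <- tryCatch({ check_cohort_config(config$cohort); TRUE },
                   error = function(e) e$message)
    if (!isTRUE(ok)) add(sprintf("cohort: %s", ok))
    if (config$cohort$n_timepoints - config$drop_volumes < 32L)
      add("drop_volumes: fewer than 32 volumes would remain")
    nyq <- 1 / (2 * config$cohort$tr_seconds)
    if (length(config$bandpass) == 2L && config$bandpass[2] > nyq)
      add("bandpass: high edge exceeds the Nyquist frequency")
  }
  if (!is.null(config$paths)) {
    for (key in c("bold", "motion", "mask", "clinical")) {
      p <- config$paths[[key]]
      if (is.null(p)) {
        add(sprintf("paths$%s: missing", key))
      } else if (!all(file.exists(p))) {
        add(sprintf("paths$%s: file not found (%s)", key,
                    paste(p[!file.exists(p)], collapse = ", ")))
      }
    }
  }
  v
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

file_hashes <- function(paths, root) {
  h <- tools::md5sum(paths)
  rel <- sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", root), "/?"),
             "", normalizePath(paths, mustWork = FALSE))
  stats::setNames(unname(h), rel)
}

stage_is_done <- function(prev, name, params_hash, out_dir) {
  st <- prev$stages[[name]]
  if (is.null(st) || !identical(st$params_hash, params_hash)) return(FALSE)
  paths <- file.path(out_dir, names(st$outputs))
  if (!all(file.exists(paths))) return(FALSE)
  identical(as.character(tools::md5sum(paths)),
            as.character(unlist(st$outputs)))
}

log_line <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full pipeline end to end
#'
#' Executes simulate (or ingest) -> preprocess -> ReHo -> group stats ->
#' predict, writing every artifact under `config$out_dir` and a manifest
#' (`manifest.json`) with per-stage parameter hashes, output content hashes,
#' warnings and timestamps.  A stage whose parameters and outputs are
#' unchanged from a previous run in the same directory is skipped.  Subjects
#' excluded by motion screening are dropped from every downstream stage and
#' listed in the manifest.
#'
#' @param config A [run_config()]; validated first, aborting on any
#'   violation.
#' @return The manifest, invisibly (class `run_manifest`).
#' @export
run_end_to_end <- function(config) {
  viol <- validate_run_config(config)
  stop_if_not(length(viol) == 0,
              paste(c("invalid configuration:", viol), collapse = "\n  "))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  man_path <- file.path(out, "manifest.json")
  prev <- if (file.exists(man_path)) {
    jsonlite::read_json(man_path, simplifyVector = TRUE)
  } else NULL
  manifest <- list(package_version = as.character(utils::packageVersion("rehopredict")),
                   seed = config$seed, stages = list(), warnings = list())
  warns <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  root <- normalizePath(out)
  finish_stage <- function(name, outputs, skipped = FALSE) {
    manifest$stages[[name]] <<- list(
      params_hash = stage_hashes[[name]],
      outputs = as.list(file_hashes(outputs, root)),
      skipped = skipped,
      warnings = warns,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    warns <<- character(0)
    log_line(name, if (skipped) "skipped (up to date)" else "completed")
  }

  stage_hashes <- list(
    simulate = hash_object(list(config$cohort, config$paths)),
    preprocess = hash_object(list(config$cohort, config$paths,
                                  config$drop_volumes, config$bandpass,
                                  config$trans_mm, config$rot_deg)),
    reho = hash_object(list(config$cohort, config$paths,
                            config$drop_volumes, config$bandpass,
                            config$neighborhood_k, config$fwhm_mm)),
    group_stats = hash_object(list(config, "group_stats")),
    predict = hash_object(list(config, "predict")))

  # ---- stage 1: simulate or ingest ----------------------------------------
  data_dir <- file.path(out, "data")
  if (is.null(config$paths)) {
    sim_outputs <- function() {
      cohort <- generate_cohort(config$cohort)
      p <- write_cohort(cohort, data_dir)
      unlist(p, use.names = FALSE)
    }
    if (stage_is_done(prev, "simulate", stage_hashes$simulate, out)) {
      outs <- file.path(out, names(prev$stages$simulate$outputs))
      finish_stage("simulate", outs, skipped = TRUE)
    } else {
      outs <- collect(sim_outputs())
      finish_stage("simulate", outs)
    }
    clin_path <- file.path(data_dir, "clinical.tsv")
    mask_path <- file.path(data_dir, "mask.nii")
    ids <- utils::read.table(clin_path, header = TRUE, sep = "\t")$subject_id
    bold_paths <- file.path(data_dir, paste0(ids, "_bold.nii"))
    motion_paths <- file.path(data_dir, paste0(ids, "_motion.txt"))
  } else {
    clin_path <- config$paths$clinical
    mask_path <- config$paths$mask
    bold_paths <- config$paths$bold
    motion_paths <- config$paths$motion
    finish_stage("simulate", c(bold_paths, motion_paths, mask_path,
                               clin_path))
  }
  clinical <- utils::read.table(clin_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  mask <- read_map_nifti(mask_path, as_mask = TRUE)
  n <- nrow(clinical)
  stop_if_not(length(bold_paths) == n && length(motion_paths) == n,
              "stage simulate: file count does not match clinical table")

  # ---- stage 2: preprocess -------------------------------------------------
  prep_dir <- file.path(out, "preprocess")
  dir.create(prep_dir, showWarnings = FALSE)
  qc_path <- file.path(prep_dir, "qc.tsv")
  prep_paths <- file.path(prep_dir, paste0(clinical$subject_id, "_prep.nii"))
  if (stage_is_done(prev, "preprocess", stage_hashes$preprocess, out)) {
    finish_stage("preprocess", c(prep_paths, qc_path), skipped = TRUE)
  } else {
    collect(for (i in seq_len(n)) {
      bold <- read_bold_nifti(bold_paths[i])
      bold <- drop_initial_volumes(bold, config$drop_volumes)
      bold <- detrend_and_bandpass(bold, mask, config$bandpass[1],
                                   config$bandpass[2])
      write_bold_nifti(bold, prep_paths[i])
    })
    motions <- lapply(motion_paths, read_motion_params)
    names(motions) <- clinical$subject_id
    qc <- collect(motion_qc_table(motions, trans_mm = config$trans_mm,
                                  rot_deg = config$rot_deg))
    utils::write.table(qc, qc_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    finish_stage("preprocess", c(prep_paths, qc_path))
  }
  qc <- utils::read.table(qc_path, header = TRUE, sep = "\t")
  keep <- !qc$excluded
  if (any(!keep)) {
    log_line("preprocess",
             sprintf("excluded for motion: %s",
                     paste(qc$subject_id[!keep], collapse = ", ")))
  }
  manifest$excluded_subjects <- qc$subject_id[!keep]
  clinical <- cbind(clinical, mean_fd = qc$mean_fd)
  clinical <- clinical[keep, , drop = FALSE]
  prep_paths <- prep_paths[keep]

  # ---- stage 3: ReHo -------------------------------------------------------
  reho_dir <- file.path(out, "reho")
  dir.create(reho_dir, showWarnings = FALSE)
  reho_paths <- file.path(reho_dir,
                          paste0(clinical$subject_id, "_smreho.nii"))
  if (stage_is_done(prev, "reho", stage_hashes$reho, out)) {
    finish_stage("reho", reho_paths, skipped = TRUE)
  } else {
    collect(for (i in seq_along(prep_paths)) {
      bold <- read_bold_nifti(prep_paths[i])
      rm0 <- reho_map(bold, mask, config$neighborhood_k)
      rm1 <- normalize_and_smooth(rm0, mask, config$fwhm_mm)
      write_map_nifti(rm1, reho_paths[i])
    })
    finish_stage("reho", reho_paths)
  }
  maps <- lapply(reho_paths, read_map_nifti)

  # ---- stage 4: group statistics ------------------------------------------
  stats_dir <- file.path(out, "group_stats")
  dir.create(stats_dir, showWarnings = FALSE)
  tmap_path <- file.path(stats_dir, "tmap.nii")
  table_path <- file.path(stats_dir, "cluster_table.tsv")
  voxels_path <- file.path(stats_dir, "cluster_voxels.json")
  corr_path <- file.path(stats_dir, "correlations.tsv")
  design <- build_design(clinical, config$covariates)
  n1 <- sum(design$groups == levels(design$groups)[1])
  n2 <- sum(design$groups == levels(design$groups)[2])
  if (stage_is_done(prev, "group_stats", stage_hashes$group_stats, out)) {
    finish_stage("group_stats", c(tmap_path, table_path, voxels_path,
                                  corr_path), skipped = TRUE)
  } else {
    tmap <- collect(voxelwise_glm_contrast(maps, design, mask))
    sm <- estimate_smoothness_fwhm(tmap, mask)
    tab <- grf_cluster_table(tmap, sm, mask, config$voxel_p,
                             config$cluster_p, n1 = n1, n2 = n2)
    write_map_nifti(tmap$data, tmap_path, mask$voxel_size_mm)
    utils::write.table(tab[, setdiff(names(tab), "voxels")], table_path,
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(lapply(tab$voxels, as.integer), voxels_path)
    if (nrow(tab) > 0) {
      feats_all <- extract_cluster_features(maps, tab)
      pat <- design$groups == levels(design$groups)[1]
      corr <- collect(correlate_with_symptoms(
        feats_all[pat, , drop = FALSE],
        clinical[pat, c("hama_baseline", "hamd_baseline"), drop = FALSE]))
      utils::write.table(corr, corr_path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    } else {
      utils::write.table(
        data.frame(feature = character(), score = character(),
                   method = character(), estimate = numeric(),
                   p_value = numeric(), significant = logical()),
        corr_path, sep = "\t", row.names = FALSE, quote = FALSE)
    }
    finish_stage("group_stats", c(tmap_path, table_path, voxels_path,
                                  corr_path))
  }
  cluster_voxels <- lapply(jsonlite::read_json(voxels_path,
                                               simplifyVector = TRUE),
                           as.integer)

  # ---- stage 5: predict ----------------------------------------------------
  pred_dir <- file.path(out, "predict")
  dir.create(pred_dir, showWarnings = FALSE)
  pred_paths <- file.path(pred_dir, c("svr_hama.json", "svr_hamd.json"))
  if (stage_is_done(prev, "predict", stage_hashes$predict, out)) {
    finish_stage("predict", pred_paths, skipped = TRUE)
  } else if (length(cluster_voxels) == 0) {
    log_line("predict", "no significant clusters: writing empty reports")
    for (p in pred_paths) jsonlite::write_json(list(skipped = TRUE), p,
                                               auto_unbox = TRUE)
    finish_stage("predict", pred_paths)
  } else {
    pat <- design$groups == levels(design$groups)[1]
    fake_tab <- data.frame(extent = vapply(cluster_voxels, length, 0L))
    fake_tab$voxels <- I(cluster_voxels)
    feats <- extract_cluster_features(maps[pat], fake_tab)
    for (j in 1:2) {
      scale_name <- c("hama", "hamd")[j]
      rr <- reduction_rate(clinical[pat, paste0(scale_name, "_baseline")],
                           clinical[pat, paste0(scale_name, "_week4")])
      run <- collect(svr_cv_predict(feats, rr, config$svr))
      rep <- list(scale = toupper(scale_name), mode = run$mode,
                  n = length(rr), fold = run$fold,
                  chosen = run$chosen, predictions = run$predictions,
                  observed = rr, mse = run$mse, pearson_r = run$pearson_r,
                  seed = config$svr$seed)
      if (config$n_perm > 0) {
        perm <- collect(permutation_significance(feats, rr, config$svr,
                                                 config$n_perm))
        rep$n_perm <- config$n_perm
        rep$p_r <- perm$p_r
        rep$p_mse <- perm$p_mse
      }
      jsonlite::write_json(rep, pred_paths[j], auto_unbox = TRUE,
                           digits = NA)
    }
    finish_stage("predict", pred_paths)
  }

  manifest$stages <- manifest$stages
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest), man_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  summary_path <- file.path(out, "summary.md")
  writeLines(c("# Pipeline run summary", "",
               sprintf("- seed: %d", config$seed),
               sprintf("- subjects analysed: %d (excluded: %d)",
                       sum(keep), sum(!keep)),
               sprintf("- significant clusters: %d", length(cluster_voxels)),
               sprintf("- stages: %s",
                       paste(names(manifest$stages), collapse = ", "))),
             summary_path)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-12s %s  (%d output file(s)%s)\n", nm,
                if (isTRUE(st$skipped)) "skipped " else "completed",
                length(st$outputs),
                if (length(st$warnings)) sprintf(", %d warning(s)",
                                                 length(st$warnings)) else ""))
  }
  invisible(x)
}
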