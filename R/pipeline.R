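#' Configuration for an end-to-end pipeline run
#'
#' Bundles the data paths (or an in-memory synthetic cohort), model
#' configuration, and analysis parameters for [run_pipeline()]. Every random
#' procedure derives its seed from the single `seed` entry.
#'
#' @param cohort A `synthetic_cohort`, or `NULL` if reading from disk.
#' @param volume_dir,cohort_csv,atlas_path Input paths (used when `cohort` is
#'   `NULL`); all must exist at load time.
#' @param output_dir Output directory.
#' @param model A [sexnet_config()].
#' @param cv_folds Cross-validation folds (default 5).
#' @param screen_alpha GLM screening level (default 0.05).
#' @param saliency_tau Saliency threshold for the binary pattern mask
#'   (default 0.1).
#' @param mediation_n_perm Permutations for the mediation condition-3 test.
#' @param mediation_test Cognitive column used as mediator.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = NULL, volume_dir = NULL, cohort_csv = NULL,
                       atlas_path = NULL, output_dir = tempfile("sexdiffmri_"),
                       model = sexnet_config(), cv_folds = 5,
                       screen_alpha = 0.05, saliency_tau = 0.1,
                       mediation_n_perm = 10000,
                       mediation_test = "list_sorting", seed = 1) {
  if (is.null(cohort)) {
    for (p in c(volume_dir, cohort_csv, atlas_path)) {
      if (is.null(p) || !file.exists(p))
        stop("run_config: missing input path: ",
             if (is.null(p)) "(not set)" else p)
    }
  }
  structure(list(cohort = cohort, volume_dir = volume_dir,
                 cohort_csv = cohort_csv, atlas_path = atlas_path,
                 output_dir = output_dir, model = model, cv_folds = cv_folds,
                 screen_alpha = screen_alpha, saliency_tau = saliency_tau,
                 mediation_n_perm = mediation_n_perm,
                 mediation_test = mediation_test, seed = as.integer(seed)),
            class = "run_config")
}

load_pipeline_cohort <- function(cfg) {
  if (!is.null(cfg$cohort)) return(cfg$cohort)
  records <- read_cohort(cfg$cohort_csv)
  atlas <- read_volume(cfg$atlas_path)
  files <- file.path(cfg$volume_dir, paste0(records$subject_id, ".nii.gz"))
  miss <- !file.exists(files)
  if (any(miss))
    stop("missing volume file(s) for subject(s): ",
         paste(records$subject_id[miss], collapse = ", "))
  volumes <- lapply(files, read_volume)
  structure(list(records = records, volumes = volumes,
                 atlas = array(as.integer(round(atlas)), dim = dim(atlas)),
                 grid = dim(atlas)[1], truth = list(), seed = cfg$seed),
            class = "synthetic_cohort")
}

#' Run the full confounder-aware analysis pipeline
#'
#' Executes, in order: subject-level cross-validation (prediction CSV and
#' metrics), re-training on the entire dataset, GLM predictor screening,
#' confounder-free and confounded cohort saliency patterns (NIfTI), ROI
#' saliency statistics, prediction-score correlations with available
#' cognitive columns plus partial mediation for the configured mediator,
#' and per-PDS-stratum accuracy. Artifacts are written under
#' `cfg$output_dir`; a stage failure halts with the stage name while
#' completed artifacts persist. A log with per-stage wall time, the seeds,
#' and the configuration echo is written alongside.
#'
#' @param cfg A [run_config()].
#' @return The output directory, invisibly; the returned value carries the
#'   computed objects as attribute `results`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  cohort <- load_pipeline_cohort(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$output_dir, "log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cfg_echo <- cfg[setdiff(names(cfg), "cohort")]
  cfg_echo$model <- unclass(cfg$model)
  yaml::write_yaml(cfg_echo, file.path(cfg$output_dir, "config.yaml"))
  logf("seed: %d", cfg$seed)

  results <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    logf("stage %s: %.1f s", name, proc.time()[["elapsed"]] - t0)
    out
  }

  results$cv <- stage("crossvalidate", {
    cv <- crossvalidate(cohort, cfg$model, k = cfg$cv_folds, seed = cfg$seed)
    utils::write.csv(cv$predictions,
                     file.path(cfg$output_dir, "predictions.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(cv$metrics),
                     file.path(cfg$output_dir, "metrics.csv"),
                     row.names = FALSE)
    cv
  })

  results$model <- stage("retrain_full", train_full(cohort, cfg$model))

  results$screen <- stage("screen", {
    pred_out <- sexnet_predict(
      results$model,
      unlist(lapply(cohort$volumes,
                    function(v) list(v, flip_volume(v))), recursive = FALSE))
    idx <- rep(seq_len(nrow(cohort$records)), each = 2)
    sc <- screen_predictors(pred_out$predictors, pred_out$scores,
                            cohort$records[idx, c("age", "pds", "ses")],
                            alpha = cfg$screen_alpha)
    utils::write.csv(as.data.frame(sc),
                     file.path(cfg$output_dir, "screen.csv"),
                     row.names = FALSE)
    sc
  })

  results$patterns <- stage("saliency_patterns", {
    free <- cohort_pattern(results$model, cohort$volumes, results$screen,
                           mode = "confounder_free")
    write_volume(free,
                 file.path(cfg$output_dir, "saliency_confounder_free.nii.gz"))
    write_volume(threshold_pattern(minmax_scale(free), cfg$saliency_tau) * 1,
                 file.path(cfg$output_dir, "saliency_mask.nii.gz"))
    conf <- tryCatch(
      cohort_pattern(results$model, cohort$volumes, results$screen,
                     mode = "confounded"),
      error = function(e) NULL)
    if (!is.null(conf))
      write_volume(conf,
                   file.path(cfg$output_dir, "saliency_confounded.nii.gz"))
    list(confounder_free = free, confounded = conf)
  })

  results$roi <- stage("roi_statistics", {
    keep <- results$screen$predictor[!results$screen$confounded]
    maps <- subject_saliency_batch(results$model, cohort$volumes, keep)
    tab <- roi_statistics(maps, cohort$atlas, cohort$records$sex)
    utils::write.csv(tab, file.path(cfg$output_dir, "roi_saliency.csv"),
                     row.names = FALSE)
    tab
  })

  results$stats <- stage("cohort_statistics", {
    tests <- intersect(names(nih_test_specs()), names(cohort$records))
    out <- list()
    if (length(tests) > 0) {
      out$correlations <- score_correlations(results$cv$predictions$score,
                                             cohort$records[tests])
      utils::write.csv(out$correlations,
                       file.path(cfg$output_dir, "correlations.csv"),
                       row.names = FALSE)
      if (cfg$mediation_test %in% tests) {
        out$mediation <- partial_mediation(
          cohort$records$sex, results$cv$predictions$score,
          cohort$records[[cfg$mediation_test]],
          n_perm = cfg$mediation_n_perm, seed = cfg$seed)
        utils::write.csv(
          data.frame(test = cfg$mediation_test,
                     condition1_p = out$mediation$condition1_p,
                     condition2_p = out$mediation$condition2_p,
                     condition3_p = out$mediation$condition3_p,
                     verdict = out$mediation$verdict),
          file.path(cfg$output_dir, "mediation.csv"), row.names = FALSE)
      }
    }
    out$strata <- per_stratum_accuracy(
      as.integer(results$cv$predictions$score > 0.5),
      cohort$records$sex, cohort$records$pds_level)
    utils::write.csv(out$strata,
                     file.path(cfg$output_dir, "stratum_accuracy.csv"),
                     row.names = FALSE)
    out
  })

  out <- cfg$output_dir
  attr(out, "results") <- results
  invisible(out)
}
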