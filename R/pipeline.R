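#' Run the full classifier-development pipeline
#'
#' Orchestrates simulate/read -> preprocess (prevalence filter, LOD
#' imputation, log2) -> RFE marker selection -> repeated stratified
#' resampling -> evaluation, and writes every intermediate artifact as
#' plain CSV/JSON so any stage can be inspected or rerun independently:
#' cohort files, feature matrix with provenance mask, the RFE pAUC
#' profile and selected marker set, per-subject mean held-out scores,
#' per-split thresholds, the performance report, the mean ROC curve, the
#' importance table, and a run manifest (config, seed, timings, input
#' digests) sufficient to reproduce the run bit-exactly.
#'
#' @param config a [pipeline_config()]; its `seed` drives every random
#'   draw.
#' @param outdir output directory (created if needed).
#' @param cohort an in-memory [cohort()], or `NULL` to read/simulate.
#' @param measurements,subjects,markers paths of the three cohort files
#'   (used when `cohort` is `NULL` and `simulate` is `FALSE`).
#' @param simulate when `TRUE`, generate the cohort from `spec`.
#' @param spec a [sim_spec()] for simulation (default
#'   `study_like_spec(config$seed)`).
#' @return Invisibly, a list with the fitted objects (`cohort`,
#'   `retained`, `rfe`, `resample`, `report`) and `paths` of all written
#'   files.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         cohort = NULL,
                         measurements = NULL, subjects = NULL,
                         markers = NULL,
                         simulate = is.null(cohort) && is.null(measurements),
                         spec = NULL) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  paths <- list()
  input_digests <- list()
  ground_truth <- NULL

  if (!is.null(cohort)) {
    co <- validate_cohort(cohort)
  } else if (simulate) {
    if (is.null(spec)) spec <- study_like_spec(seed = config$seed)
    sim <- simulate_cohort(spec)
    co <- sim$cohort
    ground_truth <- sim$ground_truth
    paths$cohort <- write_cohort(co, file.path(outdir, "cohort"))
    paths$ground_truth <- file.path(outdir, "ground_truth.json")
    jsonlite::write_json(ground_truth, paths$ground_truth, pretty = TRUE)
  } else {
    if (is.null(measurements) || is.null(subjects) || is.null(markers)) {
      stop("supply a cohort, a simulation spec, or the three cohort files",
           call. = FALSE)
    }
    co <- read_cohort(measurements, subjects, markers)
    input_digests <- as.list(tools::md5sum(c(measurements, subjects,
                                             markers)))
  }
  tick("input")

  retained <- filter_markers(co, config$marker_missing_max_frac)
  if (!length(retained)) {
    stop("preprocess: no marker passed the missing/below-LOD filter",
         call. = FALSE)
  }
  fm <- impute_and_log2(co, retained, include_age = config$include_age)
  labels <- as.integer(co$subjects$group != "control")
  strata <- as.character(co$subjects$group)
  paths$feature_matrix <- file.path(outdir, "feature_matrix.csv")
  paths$provenance <- file.path(outdir, "feature_provenance.csv")
  write_feature_matrix(fm, paths$feature_matrix, paths$provenance)
  tick("preprocess")

  rfe <- rfe_select(fm, labels, config, seed = config$seed + 1L,
                    strata = strata)
  paths$rfe_profile <- file.path(outdir, "rfe_pauc_profile.csv")
  write.csv(data.frame(size = rfe$sizes, mean_pauc = rfe$mean_pauc),
            paths$rfe_profile, row.names = FALSE)
  paths$selected_markers <- file.path(outdir, "selected_markers.json")
  jsonlite::write_json(list(selected_size = rfe$selected_size,
                            markers = rfe$selected_markers,
                            ranks = rfe$ranks),
                       paths$selected_markers, pretty = TRUE,
                       auto_unbox = TRUE, digits = NA)
  tick("rfe_select")

  fm_sel <- select_features(fm, rfe$selected_markers)
  res <- resample_fit(fm_sel, labels, strata, config,
                      seed = config$seed + 2L)
  paths$subject_scores <- file.path(outdir, "subject_mean_scores.csv")
  write.csv(res$subject, paths$subject_scores, row.names = FALSE)
  paths$thresholds <- file.path(outdir, "split_thresholds.csv")
  write.csv(data.frame(split = seq_along(res$splits),
                       tau = vapply(res$splits, `[[`, numeric(1), "tau")),
            paths$thresholds, row.names = FALSE)
  tick("resample")

  report <- evaluate(res, co$subjects, config, seed = config$seed + 3L)
  paths$report_csv <- file.path(outdir, "performance_report.csv")
  write.csv(report$table, paths$report_csv, row.names = FALSE)
  paths$report_json <- file.path(outdir, "performance_report.json")
  jsonlite::write_json(list(auc = report$auc,
                            auc_ci = as.list(report$auc_ci),
                            tau_bar = report$tau_bar,
                            table = report$table),
                       paths$report_json, pretty = TRUE, auto_unbox = TRUE,
                       digits = NA)
  paths$mean_roc <- file.path(outdir, "mean_roc.csv")
  write.csv(report$mean_roc, paths$mean_roc, row.names = FALSE)
  paths$importance <- file.path(outdir, "importance.csv")
  write.csv(report$importance, paths$importance, row.names = FALSE)
  tick("evaluate")

  manifest <- list(package_version = as.character(utils::packageVersion("evmced")),
                   config = unclass(config),
                   seed = config$seed,
                   simulated = simulate && is.null(cohort),
                   input_digests = input_digests,
                   n_subjects = nrow(co$subjects),
                   n_markers = nrow(co$markers),
                   retained_markers = retained,
                   selected_markers = rfe$selected_markers,
                   tau_bar = res$tau_bar,
                   split_sizes = as.list(res$split_sizes),
                   timings_sec = as.list(timings),
                   outputs = lapply(paths, unname))
  paths$manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, pretty = TRUE,
                       auto_unbox = TRUE, digits = NA)

  message(sprintf(
    "pipeline complete: %d/%d markers retained, %d selected; tau_bar = %.4f; AUC = %.3f",
    length(retained), nrow(co$markers), rfe$selected_size, res$tau_bar,
    report$auc))
  invisible(list(cohort = co, ground_truth = ground_truth,
                 retained = retained, feature_matrix = fm, rfe = rfe,
                 resample = res, report = report, paths = paths))
}
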