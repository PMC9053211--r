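#' Pipeline configuration
#'
#' All tunables of the classifier-development pipeline in one validated
#' object. Defaults mirror the reference protocol: 5-fold cross-validation
#' repeated 100 times for marker selection, 100 stratified 2/3-1/3
#' train/test resamples, pAUC optimized over the specificity band
#' \[0.75, 1.00\], threshold calibration at 99% target specificity,
#' bias-corrected bootstrap with B = 2000, and 95% confidence level.
#'
#' @param cv_folds folds K for RFE cross-validation (default 5).
#' @param rfe_reps repetitions of the K-fold CV inside RFE (default 100).
#' @param resamples number R of train/test resamples (default 100).
#' @param train_fraction fraction of each stratum used for training
#'   (default 2/3).
#' @param pauc_spec_lo,pauc_spec_hi specificity band over which partial AUC
#'   is computed (defaults 0.75, 1.00).
#' @param target_specificity specificity anchor for per-split threshold
#'   calibration (default 0.99; "> 99% specificity").
#' @param bootstrap_B bootstrap replicates for the AUC interval
#'   (default 2000).
#' @param ci_level confidence level for all intervals (default 0.95).
#' @param marker_missing_max_frac drop markers whose fraction of missing or
#'   below-LOD values is not below this (default 0.5).
#' @param seed root seed; every random draw in the pipeline traces to it.
#' @param include_age include age as an always-kept covariate (default TRUE).
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(cv_folds = 5L,
                            rfe_reps = 100L,
                            resamples = 100L,
                            train_fraction = 2 / 3,
                            pauc_spec_lo = 0.75,
                            pauc_spec_hi = 1.00,
                            target_specificity = 0.99,
                            bootstrap_B = 2000L,
                            ci_level = 0.95,
                            marker_missing_max_frac = 0.5,
                            seed = 1L,
                            include_age = TRUE) {
  cfg <- list(cv_folds = as.integer(cv_folds),
              rfe_reps = as.integer(rfe_reps),
              resamples = as.integer(resamples),
              train_fraction = train_fraction,
              pauc_spec_lo = pauc_spec_lo,
              pauc_spec_hi = pauc_spec_hi,
              target_specificity = target_specificity,
              bootstrap_B = as.integer(bootstrap_B),
              ci_level = ci_level,
              marker_missing_max_frac = marker_missing_max_frac,
              seed = as.integer(seed),
              include_age = isTRUE(include_age))
  stopifnot(cfg$cv_folds >= 2L,
            cfg$rfe_reps >= 1L,
            cfg$resamples >= 1L,
            cfg$train_fraction > 0, cfg$train_fraction < 1,
            cfg$pauc_spec_lo >= 0, cfg$pauc_spec_hi <= 1,
            cfg$pauc_spec_lo < cfg$pauc_spec_hi,
            cfg$target_specificity > 0, cfg$target_specificity <= 1,
            cfg$bootstrap_B >= 1L,
            cfg$ci_level > 0, cfg$ci_level < 1,
            cfg$marker_missing_max_frac > 0,
            cfg$marker_missing_max_frac <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or key=value file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error. Uses the `yaml` package when available for `.yml`/`.yaml` files,
#' otherwise expects flat `key = value` / `key: value` lines.
#'
#' @param path configuration file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml") && requireNamespace("yaml", quietly = TRUE)) {
    vals <- yaml::read_yaml(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "\\s*[:=]\\s*")
    vals <- stats::setNames(
      lapply(kv, function(x) utils::type.convert(x[2], as.is = TRUE)),
      vapply(kv, `[`, "", 1))
  }
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}
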