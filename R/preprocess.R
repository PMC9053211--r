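#' Filter markers by missing/below-LOD prevalence
#'
#' Retains markers whose fraction of values that are missing *or strictly
#' below* the marker's limit of detection, computed over the full cohort
#' (cases and controls pooled), is below `max_frac`. Values exactly equal
#' to the LOD count as observed.
#'
#' @param x a [cohort()].
#' @param max_frac retention requires missing/below-LOD fraction
#'   `< max_frac` (default 0.5).
#' @return Character vector of retained marker names, in panel order.
#' @export
filter_markers <- function(x, max_frac = 0.5) {
  validate_cohort(x)
  lod <- x$markers$lod
  frac <- vapply(seq_len(ncol(x$values)), function(j) {
    v <- x$values[, j]
    mean(is.na(v) | v < lod[j])
  }, numeric(1))
  x$markers$name[frac < max_frac]
}

#' Impute left-censored values to the LOD and log2-transform
#'
#' Every missing or below-LOD measurement of a retained marker is set to
#' that marker's LOD; all marker values are then log2-transformed. Age is
#' appended untransformed as a covariate column when requested. Each cell
#' carries a provenance flag (`"observed"` or `"imputed_lod"`).
#'
#' @param x a [cohort()].
#' @param retained marker names to keep (subset of the cohort's markers),
#'   e.g. from [filter_markers()].
#' @param include_age append the age column as a covariate (default TRUE).
#' @return An object of class `feature_matrix`: list with `values`
#'   (subjects x features, log2 scale for markers), `provenance`
#'   (character matrix over the marker columns), `subject_ids`,
#'   `feature_names`, `marker_features`, `covariates`.
#' @export
impute_and_log2 <- function(x, retained, include_age = TRUE) {
  validate_cohort(x)
  if (!all(retained %in% x$markers$name)) {
    stop("retained markers must be a subset of the cohort's markers",
         call. = FALSE)
  }
  idx <- match(retained, x$markers$name)
  lod <- x$markers$lod[idx]
  if (any(lod <= 0)) stop("LOD must be > 0", call. = FALSE)
  v <- x$values[, idx, drop = FALSE]
  prov <- matrix("observed", nrow(v), ncol(v),
                 dimnames = dimnames(v))
  for (j in seq_along(idx)) {
    cens <- is.na(v[, j]) | v[, j] < lod[j]
    v[cens, j] <- lod[j]
    prov[cens, j] <- "imputed_lod"
  }
  v <- log2(v)
  covariates <- character(0)
  if (include_age) {
    v <- cbind(v, age = x$subjects$age)
    covariates <- "age"
  }
  structure(list(values = v,
                 provenance = prov,
                 subject_ids = x$subjects$id,
                 feature_names = colnames(v),
                 marker_features = retained,
                 covariates = covariates),
            class = "feature_matrix")
}

#' Marker-marker Pearson correlation matrix
#'
#' Computed over the marker columns of a feature matrix (covariates such
#' as age are excluded). A zero-variance marker yields `NA` correlations
#' with a warning.
#'
#' @param fm a [impute_and_log2()] feature matrix.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  v <- fm$values[, fm$marker_features, drop = FALSE]
  if (nrow(v) < 3) stop("need at least 3 subjects", call. = FALSE)
  sds <- apply(v, 2, sd)
  if (any(sds == 0)) {
    warning("zero-variance marker(s): ",
            paste(colnames(v)[sds == 0], collapse = ", "),
            "; correlations reported as NA")
  }
  suppressWarnings(cor(v))
}

#' Write a feature matrix and its provenance mask as CSV
#'
#' @param fm a feature matrix.
#' @param values_path,provenance_path output CSV paths.
#' @return The two paths, invisibly.
#' @export
write_feature_matrix <- function(fm, values_path, provenance_path) {
  write.csv(data.frame(subject_id = fm$subject_ids, fm$values,
                       check.names = FALSE),
            values_path, row.names = FALSE)
  write.csv(data.frame(subject_id = fm$subject_ids, fm$provenance,
                       check.names = FALSE),
            provenance_path, row.names = FALSE)
  invisible(c(values_path, provenance_path))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects x %d features (%d markers%s)\n",
              nrow(x$values), ncol(x$values), length(x$marker_features),
              if (length(x$covariates))
                paste0(" + ", paste(x$covariates, collapse = ", "))
              else ""))
  cat(sprintf("  imputed cells: %d of %d\n",
              sum(x$provenance == "imputed_lod"), length(x$provenance)))
  invisible(x)
}
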