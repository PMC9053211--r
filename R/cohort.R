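#' Construct a case-control biomarker cohort
#'
#' A `cohort` bundles subject metadata, marker metadata (including each
#' assay's limit of detection, LOD) and the subject-by-marker measurement
#' matrix. Measurements are non-negative concentrations in assay units;
#' `NA` is the missing sentinel. Values below a marker's LOD are stored
#' as reported -- left-censoring is handled downstream by
#' [impute_and_log2()].
#'
#' @param subjects data.frame with columns `id`, `group` (one of
#'   `"control"`, `"pancreatic"`, `"ovarian"`, `"bladder"`), `stage`
#'   (`"I"`/`"II"`, `NA` for controls), optional `sub_stage` (e.g. `"IA"`),
#'   optional `histology` (e.g. `"serous"`), `age` (years), `sex`.
#' @param markers data.frame with columns `name`, `lod` (> 0, assay units),
#'   `units`, `panel`.
#' @param values numeric matrix, one row per subject (in `subjects` order),
#'   one column per marker (in `markers` order). `NA` marks missing.
#' @return An object of class `cohort`.
#' @export
cohort <- function(subjects, markers, values) {
  subjects <- as.data.frame(subjects)
  markers <- as.data.frame(markers)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- subjects$id
  colnames(values) <- markers$name
  obj <- structure(list(subjects = subjects, markers = markers,
                        values = values),
                   class = "cohort")
  validate_cohort(obj)
}

#' Validate a cohort's structural invariants
#'
#' Checks dimension agreement, unique identifiers, positive LODs,
#' non-negative measurements, legal group labels, and the staging rule:
#' controls carry no stage, every case has one.
#'
#' @param x a [cohort()] object.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_cohort <- function(x) {
  s <- x$subjects
  m <- x$markers
  v <- x$values
  need_s <- c("id", "group", "age", "sex")
  if (!all(need_s %in% names(s))) {
    stop("subjects table must have columns: ",
         paste(setdiff(need_s, names(s)), collapse = ", "), call. = FALSE)
  }
  need_m <- c("name", "lod", "units", "panel")
  if (!all(need_m %in% names(m))) {
    stop("markers table must have columns: ",
         paste(setdiff(need_m, names(m)), collapse = ", "), call. = FALSE)
  }
  if (nrow(v) != nrow(s) || ncol(v) != nrow(m)) {
    stop(sprintf(
      "measurement matrix is %d x %d but metadata describe %d subjects and %d markers",
      nrow(v), ncol(v), nrow(s), nrow(m)), call. = FALSE)
  }
  if (anyDuplicated(s$id)) stop("subject ids must be unique", call. = FALSE)
  if (anyDuplicated(m$name)) stop("marker names must be unique", call. = FALSE)
  if (any(is.na(m$lod)) || any(m$lod <= 0)) {
    stop("every marker needs a finite LOD > 0 (log2 of the LOD must be finite)",
         call. = FALSE)
  }
  bad_group <- setdiff(unique(as.character(s$group)), GROUP_LEVELS)
  if (length(bad_group)) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  if (any(v < 0, na.rm = TRUE)) {
    stop("negative measurement values are not allowed", call. = FALSE)
  }
  if (!"stage" %in% names(s)) s$stage <- NA_character_
  is_case <- s$group != "control"
  if (any(is_case & (is.na(s$stage) | s$stage == ""))) {
    stop("every case must carry a stage (I or II)", call. = FALSE)
  }
  if (any(!is_case & !(is.na(s$stage) | s$stage == ""))) {
    stop("controls must not carry a stage", call. = FALSE)
  }
  x$subjects$stage <- ifelse(is.na(s$stage) | s$stage == "",
                             NA_character_, as.character(s$stage))
  invisible(x)
}

#' Read a cohort from three delimited text files
#'
#' `measurements` holds one row per subject *or* per subject-replicate
#' (repeated `subject_id`); replicate rows are averaged per marker over
#' non-missing values before any LOD comparison. Empty fields and the
#' literal `NA` map to missing.
#'
#' @param measurements_path CSV with column `subject_id` then one column
#'   per marker.
#' @param subjects_path CSV of subject metadata (see [cohort()]).
#' @param markers_path CSV of marker metadata (see [cohort()]).
#' @return A validated [cohort()].
#' @export
read_cohort <- function(measurements_path, subjects_path, markers_path) {
  meas <- read.csv(measurements_path, check.names = FALSE,
                   na.strings = c("NA", ""))
  subjects <- read.csv(subjects_path, check.names = FALSE,
                       na.strings = c("NA", ""))
  markers <- read.csv(markers_path, check.names = FALSE,
                      na.strings = c("NA", ""))
  if (!"subject_id" %in% names(meas)) {
    stop("measurements file must have a 'subject_id' column", call. = FALSE)
  }
  marker_cols <- setdiff(names(meas), "subject_id")
  if (!setequal(marker_cols, markers$name)) {
    stop("measurement columns do not match the marker metadata", call. = FALSE)
  }
  extra <- setdiff(unique(meas$subject_id), subjects$id)
  if (length(extra)) {
    stop("measurement rows for unknown subject id(s): ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  # replicate reduction: arithmetic mean of non-missing replicate values
  mm <- as.matrix(meas[, markers$name, drop = FALSE])
  storage.mode(mm) <- "double"
  gid <- factor(meas$subject_id, levels = subjects$id)
  if (anyNA(gid)) stop("measurement rows with missing subject id", call. = FALSE)
  if (any(tabulate(gid, nbins = nlevels(gid)) == 0)) {
    stop("subjects without any measurement row: ",
         paste(utils::head(levels(gid)[tabulate(gid, nlevels(gid)) == 0], 5),
               collapse = ", "), call. = FALSE)
  }
  vals <- apply(mm, 2, function(col) {
    out <- tapply(col, gid, function(x) {
      x <- x[!is.na(x)]
      if (length(x)) mean(x) else NA_real_
    })
    as.numeric(out)
  })
  vals <- matrix(vals, nrow = nrow(subjects),
                 dimnames = list(subjects$id, markers$name))
  cohort(subjects, markers, vals)
}

#' Write a cohort as the three delimited files `read_cohort()` accepts
#'
#' Measurement values are formatted with 17 significant digits so that a
#' write/read round trip reproduces every double bit-exactly. Missing
#' values are written as empty fields.
#'
#' @param x a [cohort()].
#' @param dir output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(x, dir) {
  validate_cohort(x)
  if (nrow(x$markers) == 0) stop("cohort has no markers", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(measurements = file.path(dir, "measurements.csv"),
             subjects = file.path(dir, "subjects.csv"),
             markers = file.path(dir, "markers.csv"))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  meas <- data.frame(subject_id = x$subjects$id,
                     apply(x$values, 2, fmt),
                     check.names = FALSE)
  write.csv(meas, paths["measurements"], row.names = FALSE, quote = FALSE,
            na = "")
  write.csv(x$subjects, paths["subjects"], row.names = FALSE, na = "")
  write.csv(x$markers, paths["markers"], row.names = FALSE, na = "")
  invisible(paths)
}

#' @export
print.cohort <- function(x, ...) {
  grp <- table(factor(x$subjects$group, levels = GROUP_LEVELS))
  cat(sprintf("<cohort> %d subjects x %d markers\n",
              nrow(x$subjects), nrow(x$markers)))
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
      "\n")
  n_miss <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", n_miss,
              100 * n_miss / length(x$values)))
  invisible(x)
}
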