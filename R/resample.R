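#' Repeated stratified train/test resampling of the logistic classifier
#'
#' Draws `config$resamples` independent train/test partitions, each
#' stratified by the supplied strata (cancer type, with controls their
#' own stratum): within each stratum, `round(n_s * train_fraction)`
#' subjects train and the rest test -- with 184 controls and a 2/3
#' fraction this puts exactly 61 controls in every test set. Each split
#' fits the logistic model on its training subjects, scores its test
#' subjects, and calibrates a threshold tau_t at the target specificity
#' on the test-set *control* scores. Per subject, held-out probabilities
#' are averaged over every split in which the subject was tested (the
#' "average fit"); the global threshold tau_bar is the arithmetic mean of
#' the tau_t, and the final call is mean score > tau_bar.
#'
#' @param fm a [impute_and_log2()] feature matrix restricted to the
#'   selected features (see [select_features()]).
#' @param labels binary labels (1 = case).
#' @param strata per-subject stratification labels (e.g. `"control"`,
#'   `"pancreatic"`, ...).
#' @param config a [pipeline_config()].
#' @param seed root seed (default `config$seed`).
#' @return An object of class `resample_result`: `splits` (per split:
#'   train/test indices, fit, test probabilities, threshold `tau`),
#'   `subject` (data.frame: id, label, stratum, n_heldout, mean_prob,
#'   call), `tau_bar`, `split_sizes`, `seed`, `config`.
#' @export
resample_fit <- function(fm, labels, strata, config = pipeline_config(),
                         seed = config$seed) {
  stopifnot(inherits(fm, "feature_matrix"))
  labels <- as_binary_labels(labels)
  n <- nrow(fm$values)
  stopifnot(length(labels) == n, length(strata) == n)
  strata <- as.factor(strata)
  R <- config$resamples
  if (!any(labels == 0L)) stop("no controls present", call. = FALSE)

  n_train_s <- vapply(levels(strata), function(s) {
    ns <- sum(strata == s)
    nt <- round(ns * config$train_fraction)
    if (nt < 1L || nt >= ns) {
      stop(sprintf("stratum '%s' (n=%d) is too small to split", s, ns),
           call. = FALSE)
    }
    as.integer(nt)
  }, integer(1))

  split_seeds <- draw_seeds(R, seed)
  prob_sum <- numeric(n)
  prob_cnt <- integer(n)
  splits <- vector("list", R)
  for (t in seq_len(R)) {
    train <- withr::with_seed(split_seeds[t], {
      tr <- logical(n)
      for (s in levels(strata)) {
        idx <- which(strata == s)
        tr[sample(idx, n_train_s[s])] <- TRUE
      }
      tr
    })
    fit <- suppressWarnings(
      fit_logistic(fm$values[train, , drop = FALSE], labels[train]))
    test <- which(!train)
    pr <- predict_prob(fit, fm$values[test, , drop = FALSE])
    names(pr) <- fm$subject_ids[test]
    tau <- threshold_at_specificity(pr[labels[test] == 0L],
                                    config$target_specificity)
    prob_sum[test] <- prob_sum[test] + pr
    prob_cnt[test] <- prob_cnt[test] + 1L
    splits[[t]] <- list(train = which(train), test = test, fit = fit,
                        probs = pr, tau = tau)
  }

  never <- prob_cnt == 0L
  if (any(never)) {
    warning(sum(never), " subject(s) never appeared in a test set; ",
            "they receive no call and are excluded from metrics")
  }
  mean_prob <- ifelse(never, NA_real_, prob_sum / pmax(prob_cnt, 1L))
  tau_bar <- mean(vapply(splits, `[[`, numeric(1), "tau"))
  subject <- data.frame(id = fm$subject_ids,
                        label = labels,
                        stratum = as.character(strata),
                        n_heldout = prob_cnt,
                        mean_prob = mean_prob,
                        call = !never & mean_prob > tau_bar,
                        stringsAsFactors = FALSE)
  structure(list(splits = splits,
                 subject = subject,
                 tau_bar = tau_bar,
                 split_sizes = n_train_s,
                 seed = as.integer(seed),
                 config = config),
            class = "resample_result")
}

#' Restrict a feature matrix to a set of features
#'
#' Convenience step between [rfe_select()] and [resample_fit()]: keeps
#' the given markers (plus the covariates) in the stored column order.
#'
#' @param fm a feature matrix.
#' @param markers marker names to keep.
#' @return A `feature_matrix` over the reduced feature set.
#' @export
select_features <- function(fm, markers) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!all(markers %in% fm$marker_features)) {
    stop("unknown marker(s): ",
         paste(setdiff(markers, fm$marker_features), collapse = ", "),
         call. = FALSE)
  }
  keep <- fm$marker_features[fm$marker_features %in% markers]
  cols <- c(keep, fm$covariates)
  structure(list(values = fm$values[, cols, drop = FALSE],
                 provenance = fm$provenance[, keep, drop = FALSE],
                 subject_ids = fm$subject_ids,
                 feature_names = cols,
                 marker_features = keep,
                 covariates = fm$covariates),
            class = "feature_matrix")
}

#' Cohort and sub-cohort performance of a resampling run
#'
#' Applies the final call rule (per-subject mean held-out probability >
#' tau_bar) and reports, for the full cohort and every sub-cohort
#' (per cancer type, per stage, stage within cancer, and any sub-stage /
#' histology strata in the subject table): n, sensitivity (cases) or
#' specificity (controls) with Wilson confidence intervals; plus the AUC
#' of the mean scores (cases vs controls) with its bias-corrected
#' bootstrap interval, the mean ROC across splits, and the
#' standardized-coefficient importance table over the per-split fits.
#'
#' @param result a [resample_fit()] result.
#' @param subjects the cohort's subject table (matched by `id`).
#' @param config a [pipeline_config()].
#' @param seed seed for the bootstrap interval (default `result$seed`).
#' @return An object of class `performance_report`: `table` (one row per
#'   cohort/sub-cohort), `auc`, `auc_ci`, `tau_bar`, `mean_roc`,
#'   `importance`, `per_split_auc`.
#' @export
evaluate <- function(result, subjects, config = result$config,
                     seed = result$seed) {
  stopifnot(inherits(result, "resample_result"))
  sub <- result$subject
  meta <- subjects[match(sub$id, subjects$id), , drop = FALSE]
  if (anyNA(meta$id)) {
    stop("subject table does not cover all scored subjects", call. = FALSE)
  }
  ok <- sub$n_heldout > 0L
  sub <- sub[ok, , drop = FALSE]
  meta <- meta[ok, , drop = FALSE]
  is_case <- sub$label == 1L

  row_for <- function(category, idx, positive) {
    n <- sum(idx)
    if (n == 0L) {
      warning("empty sub-cohort omitted: ", category)
      return(NULL)
    }
    k <- if (positive) sum(sub$call[idx]) else sum(!sub$call[idx])
    ci <- wilson_ci(k, n, config$ci_level)
    data.frame(category = category, n = n, k = k,
               metric = if (positive) "sensitivity" else "specificity",
               estimate = 100 * ci$estimate,
               lower = 100 * ci$lower, upper = 100 * ci$upper,
               stringsAsFactors = FALSE)
  }

  rows <- list(row_for("Controls", !is_case, positive = FALSE),
               row_for("All cancer cases", is_case, positive = TRUE))
  for (st in c("I", "II")) {
    rows <- c(rows, list(row_for(paste("Stage", st),
                                 is_case & !is.na(meta$stage) &
                                   meta$stage == st, TRUE)))
  }
  for (g in intersect(CANCER_LEVELS, unique(meta$group))) {
    gi <- meta$group == g
    rows <- c(rows, list(row_for(paste0(toupper(substring(g, 1, 1)),
                                        substring(g, 2), " cancer"),
                                 gi, TRUE)))
    for (st in c("I", "II")) {
      si <- gi & !is.na(meta$stage) & meta$stage == st
      if (any(si)) {
        rows <- c(rows, list(row_for(sprintf("%s%s cancer stage %s",
                                             toupper(substring(g, 1, 1)),
                                             substring(g, 2), st), si, TRUE)))
      }
    }
    if ("sub_stage" %in% names(meta)) {
      for (ss in setdiff(unique(meta$sub_stage[gi]), NA)) {
        rows <- c(rows, list(row_for(
          sprintf("%s%s cancer stage %s", toupper(substring(g, 1, 1)),
                  substring(g, 2), ss),
          gi & !is.na(meta$sub_stage) & meta$sub_stage == ss, TRUE)))
      }
    }
    if ("histology" %in% names(meta)) {
      for (h in setdiff(unique(meta$histology[gi]), NA)) {
        rows <- c(rows, list(row_for(
          sprintf("%s%s cancer, %s", toupper(substring(g, 1, 1)),
                  substring(g, 2), h),
          gi & !is.na(meta$histology) & meta$histology == h, TRUE)))
      }
    }
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(tab) <- NULL

  auc_ci <- bootstrap_auc_ci(sub$mean_prob, sub$label,
                             B = config$bootstrap_B,
                             level = config$ci_level, seed = seed)
  per_split_auc <- vapply(result$splits, function(sp) {
    fast_auc(sp$probs, sub$label[match(names(sp$probs), sub$id)])
  }, numeric(1))
  mean_roc <- mean_roc_curve(result, sub)
  imp <- standardized_importance(lapply(result$splits, `[[`, "fit"))

  structure(list(table = tab,
                 auc = auc_ci$auc,
                 auc_ci = c(lower = auc_ci$lower, upper = auc_ci$upper),
                 tau_bar = result$tau_bar,
                 mean_roc = mean_roc,
                 importance = imp,
                 per_split_auc = per_split_auc),
            class = "performance_report")
}

# Vertical average of the per-split ROC curves on a common FPR grid.
mean_roc_curve <- function(result, sub, grid = seq(0, 1, by = 0.01)) {
  tprs <- vapply(result$splits, function(sp) {
    lab <- sub$label[match(names(sp$probs), sub$id)]
    rc <- roc_curve(sp$probs, lab)
    stats::approx(rc$fpr, rc$tpr, xout = grid, ties = max,
                  yleft = 0, yright = 1)$y
  }, numeric(length(grid)))
  data.frame(fpr = grid, tpr = rowMeans(tprs))
}

#' Compare two feature sets under identical resampling splits
#'
#' Runs [resample_fit()] and [evaluate()] on each feature matrix with the
#' same seed, so both runs share the exact train/test memberships, and
#' reports the two AUCs side by side (e.g. EV-protein panel vs plasma
#' free-protein panel).
#'
#' @param fm_a,fm_b two feature matrices over the same subjects.
#' @param labels binary labels.
#' @param strata per-subject strata (see [resample_fit()]).
#' @param config a [pipeline_config()].
#' @param seed shared root seed.
#' @param subjects subject table for [evaluate()].
#' @return List with `auc_a`, `auc_b`, `report_a`, `report_b`.
#' @export
compare_feature_sets <- function(fm_a, fm_b, labels, strata,
                                 config = pipeline_config(),
                                 seed = config$seed, subjects) {
  if (!identical(fm_a$subject_ids, fm_b$subject_ids)) {
    stop("the two feature matrices must cover the same subjects",
         call. = FALSE)
  }
  ra <- resample_fit(fm_a, labels, strata, config, seed)
  rb <- resample_fit(fm_b, labels, strata, config, seed)
  ea <- evaluate(ra, subjects, config, seed)
  eb <- evaluate(rb, subjects, config, seed)
  list(auc_a = ea$auc, auc_b = eb$auc, report_a = ea, report_b = eb)
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("Overall AUC of mean held-out scores: %.2f (%.0f%% CI: %.2f-%.2f)\n",
              x$auc, 100 * 0.95, x$auc_ci["lower"], x$auc_ci["upper"]))
  cat(sprintf("Average threshold tau_bar: %.4f\n\n", x$tau_bar))
  tab <- x$table
  cat(sprintf("%-28s %10s  %-11s %s\n", "Category", "# Subjects", "Metric",
              "Estimate (95% CI)"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("%-28s %10d  %-11s %.1f (%.1f-%.1f)\n",
                tab$category[i], tab$n[i], tab$metric[i],
                tab$estimate[i], tab$lower[i], tab$upper[i]))
  }
  invisible(x)
}
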