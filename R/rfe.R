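#' Recursive feature elimination with repeated stratified cross-validation
#'
#' For each of `config$rfe_reps` repetitions a class-stratified
#' `config$cv_folds`-fold partition is drawn. With each fold held out in
#' turn, backwards elimination runs on the remaining folds: fit the full
#' logistic model, rank markers by their absolute standardized
#' coefficient (|beta| x training SD), drop the weakest, refit, down to a
#' single marker -- recording the nested marker set of every size and
#' scoring each size's model on the held-out fold by partial AUC over the
#' configured specificity band. Covariates (age) sit in every model and
#' are exempt from elimination.
#'
#' The selected size maximizes the mean held-out pAUC over all
#' repetitions x folds (ties break toward the smaller size). The final
#' marker set is the top `selected_size` markers by mean elimination-order
#' rank across all runs (rank 1 = last survivor; ties alphabetical).
#' Deterministic given `seed`: one root seed spawns per-repetition
#' substreams, so repetition results are independent of execution order.
#'
#' @param fm a [impute_and_log2()] feature matrix.
#' @param labels binary labels (1 = case).
#' @param config a [pipeline_config()].
#' @param seed root seed (default `config$seed`).
#' @param strata optional finer stratification labels (e.g. cancer type);
#'   folds are stratified by label x strata when supplied.
#' @return An object of class `rfe_result`: `sizes`, `mean_pauc` (per
#'   size), `pauc` (reps x folds x sizes array), `selected_size`,
#'   `selected_markers`, `ranks` (per-marker mean elimination rank),
#'   `band` (the pAUC specificity band), `chance_pauc`.
#' @export
rfe_select <- function(fm, labels, config = pipeline_config(),
                       seed = config$seed, strata = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  labels <- as_binary_labels(labels)
  markers <- fm$marker_features
  p <- length(markers)
  if (p < 2L) stop("need at least 2 markers for elimination", call. = FALSE)
  K <- config$cv_folds
  reps <- config$rfe_reps
  if (min(table(labels)) < K) {
    stop("each class needs at least K subjects for K-fold CV", call. = FALSE)
  }
  fold_strata <- if (is.null(strata)) labels else
    interaction(labels, strata, drop = TRUE)
  X <- fm$values
  cov <- fm$covariates

  pauc <- array(NA_real_, dim = c(reps, K, p))
  rank_sum <- stats::setNames(numeric(p), markers)
  rep_seeds <- draw_seeds(reps, seed)

  for (r in seq_len(reps)) {
    fold <- withr::with_seed(rep_seeds[r],
                             stratified_folds(fold_strata, K))
    for (k in seq_len(K)) {
      test <- fold == k
      run <- rfe_single_run(X, labels, markers, cov, train = !test,
                            test = test, config = config)
      pauc[r, k, ] <- run$pauc
      rank_sum <- rank_sum + run$rank[markers]
    }
  }

  mean_pauc <- apply(pauc, 3, mean)
  selected_size <- which.max(mean_pauc)   # ties -> smaller size
  mean_rank <- rank_sum / (reps * K)
  ord <- order(mean_rank, names(mean_rank))
  selected_markers <- sort(names(mean_rank)[ord][seq_len(selected_size)])

  structure(list(sizes = seq_len(p),
                 mean_pauc = mean_pauc,
                 pauc = pauc,
                 selected_size = selected_size,
                 selected_markers = selected_markers,
                 ranks = data.frame(marker = names(mean_rank)[ord],
                                    mean_rank = mean_rank[ord],
                                    row.names = NULL),
                 band = c(config$pauc_spec_lo, config$pauc_spec_hi),
                 chance_pauc = (config$pauc_spec_hi -
                                  config$pauc_spec_lo)^2 / 2),
            class = "rfe_result")
}

# One backwards-elimination pass on a train/test split. Returns the
# held-out pAUC of every subset size and the elimination rank of every
# marker (rank s = eliminated from the size-s model; survivor rank 1).
# Also used by tests as the unit of hand-enumerable behaviour.
rfe_single_run <- function(X, labels, markers, cov, train, test, config) {
  p <- length(markers)
  S <- markers
  pauc_by_size <- numeric(p)
  rank <- stats::setNames(integer(p), markers)
  y_tr <- labels[train]
  y_te <- labels[test]
  for (s in seq(p, 1L)) {
    feats <- c(S, cov)
    fit <- suppressWarnings(fit_logistic(X[train, feats, drop = FALSE], y_tr))
    pr <- predict_prob(fit, X[test, feats, drop = FALSE])
    pauc_by_size[s] <- partial_auc(roc_curve(pr, y_te),
                                   config$pauc_spec_lo, config$pauc_spec_hi)
    if (s > 1L) {
      imp <- abs(fit$beta[S] * fit$sds[S])
      weakest <- S[order(imp, S)][1L]     # tie -> alphabetically first out
      rank[weakest] <- s
      S <- setdiff(S, weakest)
    } else {
      rank[S] <- 1L
    }
  }
  list(pauc = pauc_by_size, rank = rank)
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf("<rfe_result> selected %d markers (mean held-out pAUC %.4f over specificity band [%.2f, %.2f], chance %.4f)\n",
              x$selected_size, x$mean_pauc[x$selected_size],
              x$band[1], x$band[2], x$chance_pauc))
  cat("  markers:", paste(x$selected_markers, collapse = ", "), "\n")
  invisible(x)
}
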