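#' Fit an unpenalized binomial logistic regression
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (convergence when the relative deviance change is below 1e-8, at most
#' 100 iterations). Quasi-separated fits -- any training linear predictor
#' beyond +/-30 -- are kept but flagged `converged = FALSE`, and linear
#' predictors are capped at +/-30 at prediction time. Constant features
#' are dropped with a warning (their coefficient is reported as 0 so fits
#' over a common feature set stay comparable).
#'
#' @param fm a [impute_and_log2()] feature matrix, or a plain numeric
#'   matrix with column names.
#' @param labels binary labels, one per row (1 = case).
#' @return An object of class `logistic_fit`: `intercept`, `beta` (named,
#'   one per feature), `feature_names`, `means`/`sds` (training-set
#'   feature moments, for standardization), `converged`, `n_iter`,
#'   `dropped` (constant features).
#' @export
fit_logistic <- function(fm, labels) {
  X <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  labels <- as_binary_labels(labels)
  stopifnot(nrow(X) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("labels contain a single class; cannot fit", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
  means <- colMeans(X)
  sds <- apply(X, 2, sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "))
  }
  keep <- colnames(X)[sds > 0]
  Xk <- X[, keep, drop = FALSE]
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, Xk), labels,
                   family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  co <- fit$coefficients
  beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
  beta[keep] <- co[-1]
  separated <- any(abs(fit$linear.predictors) > 30)
  structure(list(intercept = unname(co[1]),
                 beta = beta,
                 feature_names = colnames(X),
                 means = means,
                 sds = sds,
                 converged = isTRUE(fit$converged) && !separated,
                 n_iter = fit$iter,
                 dropped = dropped),
            class = "logistic_fit")
}

#' Predicted case probabilities from a logistic fit
#'
#' Logistic of the linear predictor, with the linear predictor capped at
#' +/-30 (guards quasi-separated fits).
#'
#' @param fit a [fit_logistic()] object.
#' @param fm feature matrix whose features match the fit.
#' @return Numeric vector of probabilities in (0, 1), named by subject id
#'   when available.
#' @export
predict_prob <- function(fit, fm) {
  stopifnot(inherits(fit, "logistic_fit"))
  ids <- NULL
  if (inherits(fm, "feature_matrix")) {
    ids <- fm$subject_ids
    X <- fm$values
  } else {
    X <- as.matrix(fm)
  }
  if (is.null(colnames(X)) || !all(fit$feature_names %in% colnames(X))) {
    stop("feature names of the matrix do not match the fit", call. = FALSE)
  }
  X <- X[, fit$feature_names, drop = FALSE]
  eta <- drop(fit$intercept + X %*% fit$beta)
  eta <- pmin(30, pmax(-30, eta))
  p <- plogis(eta)
  if (!is.null(ids)) names(p) <- ids
  p
}

#' Standardized-coefficient importance across fits
#'
#' Per fit, a feature's standardized coefficient is `beta_j * sd_j` with
#' `sd_j` the training-set standard deviation of feature j. Importance is
#' the mean absolute standardized coefficient across fits, rescaled so
#' the maximum equals 100 (the rescaling is presentation only; relative
#' ordering is the contract).
#'
#' @param fits non-empty list of [fit_logistic()] objects sharing one
#'   feature set.
#' @return data.frame with `feature`, `mean_abs_std_coef`, `importance`,
#'   sorted by decreasing importance.
#' @export
standardized_importance <- function(fits) {
  if (!length(fits)) stop("need at least one fit", call. = FALSE)
  feats <- fits[[1]]$feature_names
  for (f in fits) {
    if (!identical(f$feature_names, feats)) {
      stop("all fits must share the same feature set", call. = FALSE)
    }
  }
  sc <- vapply(fits, function(f) abs(f$beta * f$sds), numeric(length(feats)))
  sc <- matrix(sc, nrow = length(feats))
  m <- rowMeans(sc)
  imp <- if (max(m) > 0) m / max(m) * 100 else m
  out <- data.frame(feature = feats, mean_abs_std_coef = m,
                    importance = imp, stringsAsFactors = FALSE)
  out[order(-out$importance, out$feature), , drop = FALSE]
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> %d features, %sconverged in %d iterations\n",
              length(x$beta), if (x$converged) "" else "NOT ", x$n_iter))
  invisible(x)
}
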