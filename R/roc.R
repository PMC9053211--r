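#' Empirical ROC curve
#'
#' Builds the receiver-operator characteristic of a score vector against
#' binary labels under the call rule "score > threshold is positive".
#' Tied scores are grouped into a single step, so the curve has one point
#' per distinct score plus the two endpoints (0,0) and (1,1); thresholds
#' are midpoints between adjacent distinct scores, with +/-Inf at the
#' ends.
#'
#' @param scores numeric classifier scores (higher means more case-like).
#' @param labels binary labels (1/TRUE = case, 0/FALSE = control).
#' @return An object of class `roc_curve`: data.frame-like list with
#'   `fpr`, `tpr`, `threshold` (non-decreasing fpr/tpr from (0,0) to
#'   (1,1)) and counts `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores)) stop("scores must not contain NA", call. = FALSE)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  grp <- cumsum(!duplicated(s))          # 1..m, groups of tied scores
  tp <- cumsum(y)[!duplicated(s, fromLast = TRUE)]   # at end of each group
  fp <- cumsum(1L - y)[!duplicated(s, fromLast = TRUE)]
  u <- unique(s)
  m <- length(u)
  thr <- c(Inf, if (m > 1) (u[-m] + u[-1]) / 2, -Inf)
  structure(list(fpr = c(0, fp / n_neg),
                 tpr = c(0, tp / n_pos),
                 threshold = thr,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' Area under the ROC curve
#'
#' Trapezoidal area; equals the tie-corrected Mann-Whitney probability
#' ((#case>control pairs + 0.5 #ties) / (n1 n0)).
#'
#' @param roc a [roc_curve()].
#' @return AUC in \[0, 1\].
#' @export
auc <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  x <- roc$fpr
  y <- roc$tpr
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Partial AUC over a specificity band
#'
#' Unnormalized trapezoidal area of TPR over FPR in
#' \[1 - spec_hi, 1 - spec_lo\], with linear interpolation of the curve at
#' the band edges. The maximum attainable value is the band width
#' (`spec_hi - spec_lo`); the chance diagonal over \[0.75, 1\] scores
#' 0.25^2/2 = 0.03125.
#'
#' @param roc a [roc_curve()].
#' @param spec_lo,spec_hi specificity band, `0 <= spec_lo < spec_hi <= 1`.
#' @return Partial area (raw, not normalized).
#' @export
partial_auc <- function(roc, spec_lo, spec_hi) {
  stopifnot(inherits(roc, "roc_curve"))
  if (!(spec_lo >= 0 && spec_hi <= 1 && spec_lo < spec_hi)) {
    stop("need 0 <= spec_lo < spec_hi <= 1", call. = FALSE)
  }
  xlo <- 1 - spec_hi
  xhi <- 1 - spec_lo
  x <- roc$fpr
  y <- roc$tpr
  area <- 0
  for (i in seq_len(length(x) - 1L)) {
    x1 <- x[i]; x2 <- x[i + 1L]
    if (x2 <= xlo || x1 >= xhi || x1 == x2) next
    a <- max(x1, xlo); b <- min(x2, xhi)
    ya <- y[i] + (y[i + 1L] - y[i]) * (a - x1) / (x2 - x1)
    yb <- y[i] + (y[i + 1L] - y[i]) * (b - x1) / (x2 - x1)
    area <- area + (b - a) * (ya + yb) / 2
  }
  area
}

#' Threshold achieving a target specificity on control scores
#'
#' Returns the smallest threshold t such that the fraction of controls
#' with score > t is at most `1 - target` (call rule: score > t is
#' positive; ties at the threshold are negative). With n controls this is
#' the (floor(n (1 - target)) + 1)-th largest control score, so with 61
#' controls at target 0.99 it is the maximum control score and all 61
#' controls are called negative.
#'
#' @param control_scores scores of the control (negative) class.
#' @param target target specificity in (0, 1\].
#' @return The calibrated threshold.
#' @export
threshold_at_specificity <- function(control_scores, target) {
  n <- length(control_scores)
  if (n == 0L) stop("control scores must be non-empty", call. = FALSE)
  stopifnot(target > 0, target <= 1)
  m <- floor(n * (1 - target) + 1e-9)    # allowed false positives
  if (m >= n) return(-Inf)
  unname(sort(control_scores, decreasing = TRUE)[m + 1L])
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Two-sided Wilson interval (no continuity correction) with
#' `z = qnorm(1 - (1-level)/2)`; at `level = 0.95`, z = 1.959964. The
#' interval always contains k/n, and the upper bound is exactly 1 when
#' k = n (lower exactly 0 when k = 0).
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `n >= 1`.
#' @param level confidence level (default 0.95).
#' @return An object of class `binomial_ci`: list with `k`, `n`, `level`,
#'   `estimate`, `lower`, `upper`.
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n, level > 0, level < 1)
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  lower <- max(0, center - half)
  upper <- min(1, center + half)
  if (k == n) upper <- 1
  if (k == 0) lower <- 0
  structure(list(k = k, n = n, level = level, estimate = p,
                 lower = lower, upper = upper),
            class = "binomial_ci")
}

#' @export
print.binomial_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%d%% CI: %.1f-%.1f) [Wilson]\n",
              x$k, x$n, 100 * x$estimate, round(100 * x$level),
              100 * x$lower, 100 * x$upper))
  invisible(x)
}

#' Bias-corrected bootstrap confidence interval for the AUC
#'
#' Stratified bootstrap: cases and controls are resampled separately with
#' replacement, preserving class counts; the AUC is computed on each of B
#' replicates. The interval is the bias-corrected (BC, no acceleration)
#' percentile interval with
#' `z0 = qnorm(mean(bootstrap AUC < observed AUC))`.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels.
#' @param B bootstrap replicates (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; the interval is deterministic given it.
#' @return List with `lower`, `upper`, `auc` (observed), `B`, `level`.
#' @export
bootstrap_auc_ci <- function(scores, labels, B = 2000L, level = 0.95,
                             seed = 1L) {
  labels <- as_binary_labels(labels)
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (!length(pos) || !length(neg)) {
    stop("both classes must be present", call. = FALSE)
  }
  obs <- fast_auc(scores, labels)
  lab_b <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  boot <- withr::with_seed(seed, vapply(seq_len(B), function(b) {
    i1 <- pos[sample.int(length(pos), replace = TRUE)]
    i0 <- neg[sample.int(length(neg), replace = TRUE)]
    fast_auc(c(scores[i1], scores[i0]), lab_b)
  }, numeric(1)))
  if (all(boot == boot[1])) {
    warning("degenerate bootstrap distribution; interval collapses to a point")
    return(list(lower = boot[1], upper = boot[1], auc = obs,
                B = as.integer(B), level = level))
  }
  frac <- mean(boot < obs)
  frac <- min(max(frac, 1 / (B + 1)), B / (B + 1))  # keep z0 finite
  z0 <- qnorm(frac)
  z <- qnorm(1 - (1 - level) / 2)
  probs <- pnorm(c(2 * z0 - z, 2 * z0 + z))
  qs <- quantile(boot, probs, names = FALSE)
  list(lower = qs[1], upper = qs[2], auc = obs,
       B = as.integer(B), level = level)
}

#' Export an ROC curve as a data frame (fpr, tpr, threshold)
#'
#' @param x a [roc_curve()].
#' @param ... unused.
#' @return data.frame with one row per curve point.
#' @export
as.data.frame.roc_curve <- function(x, ...) {
  data.frame(fpr = x$fpr, tpr = x$tpr, threshold = x$threshold)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, %d cases vs %d controls, AUC = %.3f\n",
              length(x$fpr), x$n_pos, x$n_neg, auc(x)))
  invisible(x)
}
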