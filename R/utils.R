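# Internal helpers shared across modules.

#' @importFrom stats qnorm pnorm plogis quantile rnorm runif rbinom sd cor
#' @importFrom utils read.csv write.csv
NULL

GROUP_LEVELS <- c("control", "pancreatic", "ovarian", "bladder")
CANCER_LEVELS <- GROUP_LEVELS[-1]

# Draw n independent substream seeds from one root seed without disturbing
# the caller's RNG state. Seeds stay below 2^31 (R integers).
draw_seeds <- function(n, seed) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Rank-based AUC (tie-corrected Mann-Whitney probability). Used in hot loops
# (bootstrap, RFE scoring); equals the trapezoidal area under the empirical
# ROC curve.
fast_auc <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos)
  n0 <- length(labels) - n1
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Coerce a label vector (logical, 0/1 numeric, or 2-level factor) to 0/1 int.
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be binary (0/1, logical, or a 2-level factor)",
         call. = FALSE)
  }
  labels
}

# Class-stratified K-fold assignment; returns integer fold id per element.
# Consumes the current RNG stream.
stratified_folds <- function(strata, k) {
  strata <- as.factor(strata)
  fold <- integer(length(strata))
  for (s in levels(strata)) {
    idx <- which(strata == s)
    if (length(idx) < k) {
      stop(sprintf("stratum '%s' has %d subjects, fewer than %d folds",
                   s, length(idx), k), call. = FALSE)
    }
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
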