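# Fixtures built in code: tiny cohorts and score sets shared across tests.

# A minimal valid cohort: n_control controls + n_case pancreatic cases,
# p markers with LOD 2, values drawn log-normal above the LOD.
make_toy_cohort <- function(n_control = 6, n_case = 4, p = 3, seed = 42,
                            lod = 2) {
  withr::with_seed(seed, {
    n <- n_control + n_case
    subjects <- data.frame(
      id = sprintf("T%02d", seq_len(n)),
      group = c(rep("control", n_control), rep("pancreatic", n_case)),
      stage = c(rep(NA_character_, n_control),
                rep(c("I", "II"), length.out = n_case)),
      age = sample(45:70, n, replace = TRUE),
      sex = sample(c("M", "F"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    markers <- data.frame(name = sprintf("MK%d", seq_len(p)),
                          lod = rep(lod, p),
                          units = "pg/mL", panel = "toy",
                          stringsAsFactors = FALSE)
    values <- matrix(2^runif(n * p, 2, 8), n, p)
    cohort(subjects, markers, values)
  })
}

# Plain feature_matrix wrapper for hand-built matrices (markers only).
make_fm <- function(values, covariates = character(0)) {
  stopifnot(!is.null(colnames(values)))
  structure(list(values = values,
                 provenance = matrix("observed", nrow(values),
                                     ncol(values) - length(covariates)),
                 subject_ids = rownames(values) %||%
                   sprintf("S%03d", seq_len(nrow(values))),
                 feature_names = colnames(values),
                 marker_features = setdiff(colnames(values), covariates),
                 covariates = covariates),
            class = "feature_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force pair-counting AUC oracle: ((#case>control) + 0.5 #ties)/(n1 n0).
auc_pair_oracle <- function(scores, labels) {
  ps <- scores[labels == 1]
  cs <- scores[labels == 0]
  tot <- 0
  for (a in ps) tot <- tot + sum(a > cs) + 0.5 * sum(a == cs)
  tot / (length(ps) * length(cs))
}

# Bernoulli log-likelihood of a logistic model, for optimizer oracles.
logistic_loglik <- function(theta, X, y) {
  eta <- drop(cbind(1, X) %*% theta)
  sum(y * eta - log1p(exp(eta)))
}
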