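# Shared study-sized fixture: 184 controls + 139 cases over three strata,
# two markers (one informative), built directly as a feature matrix.
make_resample_fixture <- function(seed = 1, effect = 2, p_noise = 1) {
  withr::with_seed(seed, {
    strata <- c(rep("control", 184), rep("pancreatic", 47),
                rep("ovarian", 44), rep("bladder", 48))
    y <- as.integer(strata != "control")
    n <- length(y)
    X <- matrix(rnorm(n * (1 + p_noise)), n, 1 + p_noise,
                dimnames = list(sprintf("S%03d", 1:n),
                                c("SIG", paste0("N", seq_len(p_noise)))))
    X[, "SIG"] <- X[, "SIG"] + effect * y
    list(fm = make_fm(X), y = y, strata = strata)
  })
}

test_that("a 2/3 stratified split of 184 controls puts 61 controls in every test set", {
  fx <- make_resample_fixture(seed = 2)
  cfg <- pipeline_config(resamples = 20, seed = 2)
  res <- resample_fit(fx$fm, fx$y, fx$strata, cfg)
  for (sp in res$splits) {
    expect_equal(sum(fx$y[sp$test] == 0), 61)
    expect_equal(length(sp$test), 323 - 215)
    # calibrated at target 0.99: every test control is called negative
    ctrl_scores <- sp$probs[fx$y[sp$test] == 0]
    expect_equal(sum(ctrl_scores > sp$tau), 0)
  }
  expect_equal(unname(res$split_sizes["control"]), 123L)
  # stratified split counts are constant across splits by construction
  sizes <- vapply(res$splits, function(sp) length(sp$train), integer(1))
  expect_true(all(sizes == 215))
})

test_that("a perfectly separating marker yields thresholds between the classes and perfect per-split calls", {
  withr::with_seed(3, {
    strata <- c(rep("control", 30), rep("pancreatic", 20))
    y <- as.integer(strata != "control")
    X <- cbind(SEP = c(rnorm(30, 0), rnorm(20, 20)))
    rownames(X) <- sprintf("S%02d", 1:50)
  })
  fm <- make_fm(X)
  cfg <- pipeline_config(resamples = 10, seed = 3)
  res <- suppressWarnings(resample_fit(fm, y, strata, cfg))
  for (sp in res$splits) {
    # every per-split threshold sits between the two classes: within each
    # split every control is negative and every case positive
    lo <- max(sp$probs[y[sp$test] == 0])
    hi <- min(sp$probs[y[sp$test] == 1])
    expect_gte(sp$tau, lo)
    expect_lt(sp$tau, hi)
  }
  sub <- res$subject[res$subject$n_heldout > 0, ]
  expect_true(all(sub$call[sub$label == 1]))        # sensitivity 100%
  # mean held-out scores separate the classes perfectly
  expect_equal(auc(roc_curve(sub$mean_prob, sub$label)), 1.0)
})

test_that("per-subject mean scores equal a hand average of held-out probabilities", {
  fx <- make_resample_fixture(seed = 4)
  cfg <- pipeline_config(resamples = 2, seed = 4)
  res <- suppressWarnings(resample_fit(fx$fm, fx$y, fx$strata, cfg))
  acc <- list()
  for (sp in res$splits) {
    for (id in names(sp$probs)) acc[[id]] <- c(acc[[id]], sp$probs[[id]])
  }
  sub <- res$subject
  for (i in seq_len(nrow(sub))) {
    id <- sub$id[i]
    if (sub$n_heldout[i] == 0) {
      expect_true(is.na(sub$mean_prob[i]))
    } else {
      expect_equal(sub$mean_prob[i], mean(acc[[id]]))
      expect_length(acc[[id]], sub$n_heldout[i])
    }
  }
  expect_equal(res$tau_bar,
               mean(vapply(res$splits, `[[`, numeric(1), "tau")))
})

test_that("evaluation partitions sub-cohorts and computes Wilson rows", {
  sim <- simulate_cohort(study_like_spec(seed = 5))
  co <- sim$cohort
  fm <- impute_and_log2(co, filter_markers(co))
  fm <- select_features(fm, sort(unique(unlist(sim$ground_truth))))
  y <- as.integer(co$subjects$group != "control")
  cfg <- pipeline_config(resamples = 20, bootstrap_B = 200, seed = 5)
  res <- resample_fit(fm, y, co$subjects$group, cfg)
  rep <- suppressWarnings(evaluate(res, co$subjects, cfg))
  tab <- rep$table
  g <- function(cat) tab$n[tab$category == cat]
  expect_equal(g("Stage I") + g("Stage II"), g("All cancer cases"))
  expect_equal(g("Pancreatic cancer") + g("Ovarian cancer") +
                 g("Bladder cancer"), g("All cancer cases"))
  expect_equal(g("Pancreatic cancer stage I") +
                 g("Pancreatic cancer stage II"), g("Pancreatic cancer"))
  expect_equal(g("Controls"), 184)
  # every row's interval is a Wilson interval of its own counts
  for (i in seq_len(nrow(tab))) {
    ci <- wilson_ci(tab$k[i], tab$n[i], cfg$ci_level)
    expect_equal(tab$lower[i], 100 * ci$lower)
    expect_equal(tab$upper[i], 100 * ci$upper)
  }
  expect_true(rep$auc_ci["lower"] <= rep$auc &&
                rep$auc <= rep$auc_ci["upper"])
  # report reproducible bit-exactly from the stored resample result
  rep2 <- suppressWarnings(evaluate(res, co$subjects, cfg))
  expect_identical(rep$table, rep2$table)
  expect_identical(rep$auc_ci, rep2$auc_ci)
})

test_that("final-call specificity stays near the calibration target on null data", {
  hits <- vapply(1:12, function(s) {
    withr::with_seed(s + 500, {
      strata <- c(rep("control", 120), rep("pancreatic", 60))
      y <- as.integer(strata != "control")
      X <- matrix(rnorm(180 * 2), 180, 2,
                  dimnames = list(sprintf("S%03d", 1:180), c("N1", "N2")))
    })
    cfg <- pipeline_config(resamples = 20, seed = s + 500)
    res <- suppressWarnings(resample_fit(make_fm(X), y, strata, cfg))
    sub <- res$subject[res$subject$n_heldout > 0 & res$subject$label == 0, ]
    mean(!sub$call)
  }, numeric(1))
  expect_gte(mean(hits >= 0.98), 10 / 12)
})

test_that("identical seeds give identical split memberships across feature sets", {
  fx <- make_resample_fixture(seed = 6, p_noise = 3)
  fm_a <- fx$fm
  fm_b <- make_fm(fx$fm$values[, c("SIG", "N1"), drop = FALSE])
  subjects <- data.frame(id = fx$fm$subject_ids,
                         group = fx$strata,
                         stage = ifelse(fx$strata == "control", NA, "I"),
                         age = 60, sex = "F", stringsAsFactors = FALSE)
  cfg <- pipeline_config(resamples = 8, bootstrap_B = 100, seed = 6)
  cmp <- suppressWarnings(
    compare_feature_sets(fm_a, fm_b, fx$y, fx$strata, cfg,
                         subjects = subjects))
  # same matrix twice -> identical AUC
  cmp_same <- suppressWarnings(
    compare_feature_sets(fm_a, fm_a, fx$y, fx$strata, cfg,
                         subjects = subjects))
  expect_identical(cmp_same$auc_a, cmp_same$auc_b)
  # adding pure-noise features never buys a large AUC gain
  expect_lte(cmp$auc_a, cmp$auc_b + 0.05)
  # shared seed -> identical memberships
  ra <- suppressWarnings(resample_fit(fm_a, fx$y, fx$strata, cfg))
  rb <- suppressWarnings(resample_fit(fm_b, fx$y, fx$strata, cfg))
  for (t in seq_along(ra$splits)) {
    expect_identical(ra$splits[[t]]$train, rb$splits[[t]]$train)
  }
})

test_that("a stratum too small to split is rejected", {
  fx <- make_resample_fixture(seed = 7)
  strata <- fx$strata
  strata[1] <- "tiny"
  expect_error(resample_fit(fx$fm, fx$y, strata,
                            pipeline_config(resamples = 2, seed = 7)),
               "too small")
})
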