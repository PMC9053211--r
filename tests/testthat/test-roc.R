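test_that("the ROC curve is monotone from (0,0) to (1,1) with grouped ties", {
  scores <- c(3, 1, 2, 2, 4, 0.5)
  labels <- c(1, 0, 1, 0, 1, 0)
  rc <- roc_curve(scores, labels)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[length(rc$fpr)], 1)
  expect_equal(rc$tpr[length(rc$tpr)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
  # 5 distinct scores -> 6 points (ties at 2 grouped into one step)
  expect_length(rc$fpr, 6)
  # perfectly separated scores pass through (0, 1)
  rc2 <- roc_curve(c(3, 4, 1, 2), c(1, 1, 0, 0))
  expect_true(any(rc2$fpr == 0 & rc2$tpr == 1))
  expect_equal(auc(rc2), 1.0)
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("labels independent of scores give AUC near 0.5", {
  aucs <- vapply(1:10, function(s) withr::with_seed(s, {
    auc(roc_curve(rnorm(10000), rbinom(10000, 1, 0.5)))
  }), numeric(1))
  expect_true(all(abs(aucs - 0.5) < 0.02))
})

test_that("reversing the score sign maps AUC a to 1 - a", {
  withr::with_seed(2, {
    scores <- rnorm(60)
    labels <- rbinom(60, 1, 0.4)
  })
  a <- auc(roc_curve(scores, labels))
  expect_equal(auc(roc_curve(-scores, labels)), 1 - a, tolerance = 1e-12)
})

test_that("AUC equals the brute-force pair-counting oracle, ties included", {
  expect_equal(auc(roc_curve(c(3, 4, 1, 2), c(1, 1, 0, 0))), 1.0)
  expect_equal(auc(roc_curve(rep(1, 10), rep(c(0, 1), 5))), 0.5)
  for (s in 1:200) {
    withr::with_seed(s, {
      n <- sample(4:50, 1)
      scores <- round(rnorm(n), 1)    # coarse rounding forces ties
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    })
    expect_equal(auc(roc_curve(scores, labels)),
                 auc_pair_oracle(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  for (s in 1:20) {
    withr::with_seed(s, {
      scores <- round(rnorm(40), 1)
      labels <- c(0, 1, rbinom(38, 1, 0.5))
    })
    expect_equal(auc(roc_curve(scores, labels)),
                 as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                direction = "<",
                                                levels = c(0, 1)))),
                 tolerance = 1e-12)
  }
})

test_that("partial AUC has the exact textbook geometry", {
  # chance diagonal: all scores tied -> curve is the diagonal
  rc <- roc_curve(rep(1, 20), rep(c(0, 1), 10))
  expect_identical(partial_auc(rc, 0.75, 1.00), 0.25^2 / 2)
  # perfect classifier: full band height
  rc2 <- roc_curve(c(5, 6, 1, 2), c(1, 1, 0, 0))
  expect_equal(partial_auc(rc2, 0.75, 1.00), 0.25)
  expect_error(partial_auc(rc, 0.9, 0.5), "spec_lo")
})

test_that("partial AUC matches fine-grid numeric integration of the curve", {
  for (s in 1:20) {
    pts <- withr::with_seed(s, {
      x <- c(0, sort(runif(18)), 1)
      y <- c(0, sort(runif(18)), 1)
      list(x = x, y = y)
    })
    rc <- structure(list(fpr = pts$x, tpr = pts$y,
                         threshold = rep(NA_real_, 20),
                         n_pos = 10L, n_neg = 10L), class = "roc_curve")
    band <- withr::with_seed(s + 1000, sort(runif(2)))
    grid <- seq(1 - band[2], 1 - band[1], length.out = 2^20 + 1)
    fy <- approx(pts$x, pts$y, xout = grid, ties = max)$y
    oracle <- sum((fy[-1] + fy[-length(fy)]) / 2 * diff(grid))
    expect_equal(partial_auc(rc, band[1], band[2]), oracle,
                 tolerance = 1e-9)
  }
})

test_that("partial AUC over [0,1] equals AUC and is additive over bands", {
  for (s in 1:20) {
    withr::with_seed(s, {
      scores <- round(rnorm(30), 1)
      labels <- c(0, 1, rbinom(28, 1, 0.5))
    })
    rc <- roc_curve(scores, labels)
    expect_equal(partial_auc(rc, 0, 1), auc(rc), tolerance = 1e-12)
    expect_equal(partial_auc(rc, 0, 0.4) + partial_auc(rc, 0.4, 1),
                 partial_auc(rc, 0, 1), tolerance = 1e-12)
    expect_equal(partial_auc(rc, 0.75, 0.9) + partial_auc(rc, 0.9, 1),
                 partial_auc(rc, 0.75, 1), tolerance = 1e-12)
  }
})

test_that("threshold_at_specificity returns the smallest workable threshold", {
  # forced by the rule: 3 controls at target 0.99 -> max control score
  thr <- threshold_at_specificity(c(0.1, 0.2, 0.3), 0.99)
  expect_equal(thr, 0.3)
  expect_true(0.31 > thr)   # a case at 0.31 is called positive
  expect_false(0.3 > thr)   # a tie at the threshold is negative
  # 200 controls at 0.99: exactly floor(200 * 0.01) = 2 may exceed it
  ctrl <- withr::with_seed(5, rnorm(200))
  thr200 <- threshold_at_specificity(ctrl, 0.99)
  expect_equal(sum(ctrl > thr200), 2)
  expect_equal(thr200, sort(ctrl, decreasing = TRUE)[3])
})

test_that("the calibrated threshold achieves the target and no smaller one does", {
  for (s in 1:50) {
    withr::with_seed(s, {
      n <- sample(10:300, 1)
      ctrl <- round(rnorm(n), 2)
      target <- runif(1, 0.8, 1)
    })
    thr <- threshold_at_specificity(ctrl, target)
    expect_gte(mean(ctrl <= thr), target)
    smaller <- max(ctrl[ctrl < thr], -Inf)  # next candidate below
    if (is.finite(smaller)) {
      expect_lt(mean(ctrl <= smaller), target)
    }
  }
})

test_that("Wilson intervals reproduce closed-form checks and base R", {
  ci <- wilson_ci(99, 139, 0.95)
  expect_equal(round(c(ci$lower, ci$upper), 3), c(0.632, 0.781))
  ci2 <- wilson_ci(45, 47, 0.95)
  expect_equal(round(c(ci2$lower, ci2$upper), 3), c(0.858, 0.988))
  # boundary: k = n pins the upper limit at exactly 1
  expect_identical(wilson_ci(20, 20, 0.9)$upper, 1)
  expect_identical(wilson_ci(0, 20, 0.9)$lower, 0)
  # cross-check against the base implementation of the same interval
  for (kn in list(c(5, 10), c(1, 33), c(62, 88), c(183, 184))) {
    ci <- wilson_ci(kn[1], kn[2], 0.95)
    pt <- prop.test(kn[1], kn[2], correct = FALSE)$conf.int
    expect_equal(c(ci$lower, ci$upper), as.numeric(pt), tolerance = 1e-10)
  }
})

test_that("Wilson interval width shrinks monotonically in n at fixed k/n", {
  widths <- vapply(c(10, 20, 50, 100, 400, 1000), function(n) {
    ci <- wilson_ci(round(0.7 * n), n, 0.95)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("the BC bootstrap AUC interval behaves at the extremes and is seeded", {
  scores <- c(1, 2, 3, 11, 12, 13)
  labels <- c(0, 0, 0, 1, 1, 1)
  expect_warning(ci <- bootstrap_auc_ci(scores, labels, B = 200, seed = 1),
                 "degenerate")
  expect_equal(c(ci$lower, ci$upper), c(1, 1))
  withr::with_seed(3, {
    sc <- c(rnorm(60, 1), rnorm(60))
    lb <- rep(c(1, 0), each = 60)
  })
  a <- bootstrap_auc_ci(sc, lb, B = 500, seed = 7)
  b <- bootstrap_auc_ci(sc, lb, B = 500, seed = 7)
  expect_identical(a, b)
  d <- bootstrap_auc_ci(sc, lb, B = 500, seed = 8)
  expect_false(identical(a$lower, d$lower))
  expect_true(a$lower <= a$auc && a$auc <= a$upper)
})
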