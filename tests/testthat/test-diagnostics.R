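test_that("ratio features enumerate induced x repressed pairs", {
  set.seed(31)
  lv <- matrix(runif(20 * 9, 0.5, 4), 20,
               dimnames = list(NULL, c("miR-34a", "miR-27b", "miR-22",
                                       "miR-122", "miR-192", "miR-21",
                                       "miR-30c", "miR-16", "miR-197")))
  rt <- build_ratio_features(lv)
  expect_identical(ncol(rt), 18L)
  expect_true(all(c("miR-34a/197", "miR-192/197", "miR-192/30c",
                    "miR-27b/30c", "miR-27b/197") %in% colnames(rt)))
  expect_equal(unname(rt[, "miR-34a/197"]),
               unname(lv[, "miR-34a"] / lv[, "miR-197"]))
  # x/x is identically 1
  self <- build_ratio_features(lv, "miR-122", "miR-122")
  expect_equal(unname(self[, 1]), rep(1, 20))
  expect_error(build_ratio_features(lv, "miR-999", "miR-16"), "miR-999")
  # missing on either side propagates
  lv[3, "miR-16"] <- NA
  expect_true(is.na(build_ratio_features(lv)[3, "miR-34a/16"]))
})

test_that("empirical ROC covers the canonical cases", {
  # perfect separation
  r <- empirical_roc(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auroc, 1)
  # all tied scores: one simultaneous step, AUROC one half
  r2 <- empirical_roc(rep(3, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r2$auroc, 0.5)
  # worked 2x2 example: 3 of 4 pairs concordant
  r3 <- empirical_roc(c(2, 3, 1, 2.5), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r3$auroc, 0.75)
  expect_error(empirical_roc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("auto direction flips an inverted marker and records it", {
  scores <- c(5, 4, 1, 2)
  labels <- c(FALSE, FALSE, TRUE, TRUE)  # low score = positive
  r <- empirical_roc(scores, labels)
  expect_identical(r$direction, "lower_is_positive")
  expect_equal(r$auroc, 1)
  # fixed direction is never flipped
  rf <- empirical_roc(scores, labels, direction = "higher_is_positive")
  expect_equal(rf$auroc, 0)
})

test_that("trapezoidal AUROC equals the rescaled Mann-Whitney U", {
  set.seed(32)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    scores <- sample(1:5, n, replace = TRUE)  # ties on purpose
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    r <- empirical_roc(scores, labels, direction = "higher_is_positive")
    expect_equal(r$auroc, auc_from_u(scores, labels), tolerance = 1e-12)
  }
})

test_that("Youden cut-off matches the exhaustive oracle with tie rules", {
  # worked example: J = 0.5 tie resolved toward higher sensitivity
  r <- empirical_roc(c(2, 3, 1, 2.5), c(TRUE, TRUE, FALSE, FALSE))
  y <- youden_optimal_cutoff(r)
  expect_equal(y$cutoff, 2)
  expect_equal(y$j, 0.5)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 0.5)
  # perfect marker reaches J = 1
  rp <- empirical_roc(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(youden_optimal_cutoff(rp)$j, 1)
  # randomized instances against the brute-force search
  set.seed(33)
  for (rep in 1:100) {
    n <- sample(5:12, 1)
    scores <- round(runif(n, 0, 4), 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    r <- empirical_roc(scores, labels, direction = "higher_is_positive")
    y <- youden_optimal_cutoff(r)
    o <- youden_oracle(scores, labels)
    expect_equal(y$j, o$j, tolerance = 1e-12)
    expect_equal(y$cutoff, o$cutoff)
  }
})

test_that("confusion metrics satisfy their defining identities", {
  r <- confusion_metrics(36, 7, 14, 35)
  e <- r$estimates
  expect_equal(e$sensitivity, 36 / 50)
  expect_equal(e$specificity, 35 / 42)
  expect_equal(e$ppv, 36 / 43)
  expect_equal(e$npv, 35 / 49)
  expect_equal(e$plr, e$sensitivity / (1 - e$specificity))
  expect_equal(e$nlr, (1 - e$sensitivity) / e$specificity)
  expect_equal(e$accuracy, 71 / 92)
  # accuracy identity via prevalence, PPV/NPV via Bayes rule
  set.seed(34)
  for (rep in 1:20) {
    cnt <- rpois(4, 10) + 1
    r <- confusion_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    e <- r$estimates
    prev <- (cnt[1] + cnt[3]) / sum(cnt)
    expect_equal(e$accuracy,
                 e$sensitivity * prev + e$specificity * (1 - prev),
                 tolerance = 1e-12)
    b <- metrics_from_rates(e$sensitivity, e$specificity,
                            cnt[1] + cnt[3], cnt[2] + cnt[4])
    expect_equal(e$ppv, b$ppv, tolerance = 1e-12)
    expect_equal(e$npv, b$npv, tolerance = 1e-12)
  }
  # perfect classifier
  p <- confusion_metrics(10, 0, 0, 10)$estimates
  expect_equal(p$sensitivity, 1)
  expect_equal(p$plr, Inf)
  expect_equal(p$nlr, 0)
  # degenerate margins flagged, not errors
  d <- confusion_metrics(0, 0, 0, 10)
  expect_true("sensitivity" %in% d$flags)
  expect_true(is.na(d$estimates$sensitivity))
})

test_that("published sens/spec pairs imply the published likelihood ratios", {
  expect_equal(round(metrics_from_rates(0.73, 0.83, 50, 42)$nlr, 2), 0.33)
  expect_equal(round(metrics_from_rates(0.87, 0.69, 38, 54)$nlr, 2), 0.19)
})

test_that("Clopper-Pearson intervals are exact at the boundary", {
  r <- metric_confidence_intervals(confusion_metrics(10, 5, 0, 20))
  ci <- r$ci$sensitivity
  expect_equal(unname(ci["upper"]), 1)
  expect_equal(unname(ci["lower"]), qbeta(0.025, 10, 1), tolerance = 1e-12)
  expect_equal(unname(ci["lower"]), 0.025^(1 / 10), tolerance = 1e-9)
  # all intervals contain their point estimate
  r2 <- metric_confidence_intervals(confusion_metrics(30, 12, 9, 25))
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy",
              "plr", "nlr")) {
    est <- r2$estimates[[m]]
    expect_gte(est, r2$ci[[m]]["lower"])
    expect_lte(est, r2$ci[[m]]["upper"])
  }
})

test_that("sensitivity interval coverage is at least nominal-ish at n = 50", {
  set.seed(35)
  true_sens <- 0.8
  n <- 50
  covered <- replicate(2000, {
    tp <- rbinom(1, n, true_sens)
    ci <- metric_confidence_intervals(
      confusion_metrics(tp, 0, n - tp, 1))$ci$sensitivity
    ci["lower"] <= true_sens && true_sens <= ci["upper"]
  })
  expect_gte(mean(covered), 0.93)
})

test_that("interval width shrinks like one over root n", {
  w <- vapply(c(50, 200, 800), function(n) {
    ci <- metric_confidence_intervals(
      confusion_metrics(n / 2, 0, n / 2, 1))$ci$sensitivity
    unname(diff(ci))
  }, numeric(1))
  expect_equal(w[1] / w[2], 2, tolerance = 0.15)
  expect_equal(w[2] / w[3], 2, tolerance = 0.15)
})

test_that("marker evaluation is direction-invariant and self-consistent", {
  set.seed(36)
  scores <- c(rnorm(25, 1), rnorm(25))
  labels <- rep(c(TRUE, FALSE), each = 25)
  ev <- evaluate_marker(scores, labels)
  ev_neg <- evaluate_marker(-scores, labels)
  expect_equal(ev$roc$auroc, ev_neg$roc$auroc, tolerance = 1e-12)
  expect_equal(ev$report$estimates, ev_neg$report$estimates, tolerance = 1e-12)
  expect_equal(ev$cutoff, -ev_neg$cutoff, tolerance = 1e-12)
  # report counts reproduce the Youden sens/spec
  y <- youden_optimal_cutoff(ev$roc)
  expect_equal(ev$report$estimates$sensitivity, y$sensitivity)
  expect_equal(ev$report$estimates$specificity, y$specificity)
  # perfect marker
  evp <- evaluate_marker(c(1, 2, 9, 10), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(evp$roc$auroc, 1)
  expect_equal(evp$report$estimates$accuracy, 1)
})

test_that("AUROC tracks the binormal closed form on simulated markers", {
  set.seed(37)
  delta <- 1
  aucs <- replicate(200, {
    evaluate_marker(c(rnorm(50, delta), rnorm(42)),
                    rep(c(TRUE, FALSE), c(50, 42)))$roc$auroc
  })
  expect_lt(abs(mean(aucs) - pnorm(delta / sqrt(2))), 0.02)
})

test_that("empirical ROC and AUROC agree with the pROC oracle", {
  skip_if_not_installed("pROC")
  set.seed(38)
  for (rep in 1:5) {
    scores <- round(rnorm(40), 1)
    labels <- rep(c(TRUE, FALSE), each = 20)
    r <- empirical_roc(scores, labels, direction = "higher_is_positive")
    pr <- pROC::roc(response = labels, predictor = scores,
                    direction = "<", quiet = TRUE)
    expect_equal(r$auroc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  }
})
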