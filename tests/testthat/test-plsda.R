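make_toy <- function(n = 30, p = 5, seed = 41, informative = TRUE) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  drift <- if (p > 1) x[, 2] else 0
  y <- if (informative) as.numeric(x[, 1] - drift + rnorm(n, 0, 0.8) > 0)
  else rep(c(0, 1), length.out = n)[sample(n)]
  list(x = x, y = y)
}

test_that("the NIPALS fit is deterministic with orthogonal scores", {
  d <- make_toy()
  f1 <- plsda(d$x, d$y, ncomp = 3)
  f2 <- plsda(d$x, d$y, ncomp = 3)
  expect_identical(f1$coef_path, f2$coef_path)
  g <- crossprod(f1$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  expect_s3_class(f1, "plsda")
  expect_identical(f1$ncomp, 3L)
})

test_that("a single predictor with one LV equals univariate least squares", {
  d <- make_toy(p = 1)
  f <- plsda(d$x, d$y, ncomp = 1)
  ls <- lm(d$y ~ d$x[, 1])
  expect_equal(unname(predict(f, d$x)), unname(fitted(ls)), tolerance = 1e-10)
})

test_that("full-rank PLS reproduces ordinary least squares", {
  for (seed in c(42, 43)) {
    d <- make_toy(n = 40, p = 6, seed = seed)
    f <- plsda(d$x, d$y, ncomp = 6)
    ols <- lm.fit(cbind(1, d$x), d$y)$fitted.values
    expect_equal(unname(predict(f, d$x, ncomp = f$ncomp)), unname(ols),
                 tolerance = 1e-8)
  }
})

test_that("predictions match an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  d <- make_toy(n = 40, p = 6, seed = 44)
  f <- plsda(d$x, d$y, ncomp = 3)
  m <- mixOmics::pls(d$x, d$y, ncomp = 3, mode = "regression", scale = TRUE)
  for (k in 1:3) {
    expect_equal(unname(predict(f, d$x, ncomp = k)),
                 unname(predict(m, d$x)$predict[, 1, k]), tolerance = 1e-8)
  }
})

test_that("training-set predictions follow the coefficient identity", {
  d <- make_toy()
  f <- plsda(d$x, d$y, ncomp = 2)
  xs <- sweep(sweep(d$x, 2, f$x_center), 2, f$x_scale, "/")
  expect_equal(unname(predict(f, d$x)),
               unname(drop(f$y_mean + xs %*% f$coefficients)),
               tolerance = 1e-12)
  # class calls at the 0.5 midpoint
  pr <- predict(f, d$x, type = "both")
  expect_identical(pr$class, f$levels[(pr$score >= 0.5) + 1L])
  # perfectly separable toy problem trains to 100% accuracy
  xsep <- matrix(c(runif(20, -5, -4), runif(20, 4, 5)), 40, 1)
  ysep <- rep(c(0, 1), each = 20)
  fs <- plsda(xsep, ysep, ncomp = 1)
  expect_identical(predict(fs, xsep, type = "class"), as.character(ysep))
  # residuals + fitted reconstruct the class coding at full depth
  expect_equal(fitted(f) + residuals(f), f$y, tolerance = 1e-10)
})

test_that("uninformative labels give relatively tiny coefficients", {
  set.seed(45)
  x <- matrix(rnorm(60 * 5), 60, 5)
  y_info <- as.numeric(x[, 1] > 0)
  y_null <- sample(y_info)
  b_info <- sqrt(sum(coef(plsda(x, y_info, ncomp = 1))^2))
  b_null <- sqrt(sum(coef(plsda(x, y_null, ncomp = 1))^2))
  expect_lt(b_null, b_info / 2)
})

test_that("fit guards its preconditions", {
  d <- make_toy()
  xz <- cbind(d$x, vz = 0)
  expect_error(plsda(xz, d$y, ncomp = 2), "vz")
  expect_error(plsda(d$x, rep(1, nrow(d$x)), ncomp = 2), "two-class")
  expect_error(plsda(d$x, d$y, ncomp = 50), "ncomp")
  expect_error(predict(plsda(d$x, d$y, 2), d$x[, 1:3]), "v4")
})

test_that("LOO selection counts errors per latent variable and breaks ties low", {
  # widely separable in every column: each candidate count classifies
  # cleanly, tie -> 1
  set.seed(46)
  ctr <- c(runif(15, -8, -6), runif(15, 6, 8))
  x <- outer(ctr, rep(1, 4)) + matrix(runif(30 * 4, -1, 1), 30, 4)
  y <- rep(c(0, 1), each = 15)
  sel <- loocv_select_lv(x, y, max_lv = 4)
  expect_identical(sel$n_lv, 1L)
  expect_equal(unname(sel$errors[1]), 0)
  # error curve covers every candidate and out-of-fold scores are complete
  expect_length(sel$errors, 4)
  expect_false(anyNA(sel$cv_scores))
  expect_warning(loocv_select_lv(x[c(1:6, 16:21), ], y[c(1:6, 16:21)],
                                 max_lv = 10),
                 "reduced")
})

test_that("one informative direction usually selects one latent variable", {
  set.seed(47)
  picks <- replicate(40, {
    signal <- rnorm(40)
    signal <- signal + sign(signal) * 0.4  # a margin keeps classes apart
    x <- matrix(rnorm(40 * 8, 0, 0.4), 40, 8) + outer(signal, rep(1, 8))
    y <- as.numeric(signal > 0)
    loocv_select_lv(x, y, max_lv = 4)$n_lv
  })
  expect_gte(mean(picks == 1L), 0.9)
})

test_that("cross-validation re-estimates scaling inside every fold", {
  d <- make_toy(n = 24, p = 4, seed = 48)
  cv <- loocv_evaluate(d$x, d$y, n_lv = 2)
  # manual leave-one-out oracle with fold-internal autoscaling
  manual <- vapply(seq_len(nrow(d$x)), function(i) {
    xt <- d$x[-i, , drop = FALSE]
    ctr <- colMeans(xt); scl <- apply(xt, 2, sd)
    f <- plsda(xt, d$y[-i], ncomp = 2)
    unname(predict(f, d$x[i, , drop = FALSE], ncomp = 2))
  }, numeric(1))
  expect_equal(unname(cv$cv_scores), manual, tolerance = 1e-10)
  # every subject predicted exactly once
  expect_length(cv$cv_scores, nrow(d$x))
})

test_that("an outlier in a held-out sample cannot leak into its fold", {
  d <- make_toy(n = 20, p = 4, seed = 49)
  cv1 <- loocv_evaluate(d$x, d$y, n_lv = 1)
  x2 <- d$x
  x2[7, ] <- x2[7, ] + 50  # wreck subject 7's predictors
  cv2 <- loocv_evaluate(x2, d$y, n_lv = 1)
  # fold-7 training data identical, so only the score of subject 7 moves
  # through its own (standardized) predictors, not through the model;
  # all other folds see the outlier in training and may shift
  f7a <- plsda(d$x[-7, ], d$y[-7], ncomp = 1)
  f7b <- plsda(x2[-7, ], d$y[-7], ncomp = 1)
  expect_equal(f7a$coefficients, f7b$coefficients, tolerance = 1e-12)
})

test_that("cross-validated evaluation reports a coherent metric panel", {
  set.seed(50)
  x <- cbind(c(runif(20, -6, -4), runif(20, 4, 6)),
             matrix(rnorm(40 * 2, 0, 0.5), 40, 2))
  y <- rep(c(0, 1), each = 20)
  cv <- loocv_evaluate(x, y, n_lv = 1)
  expect_equal(cv$auroc, 1)
  expect_equal(cv$report$estimates$accuracy, 1)
  expect_identical(sum(cv$report$counts), 40L)
  # midpoint threshold is recorded
  expect_equal(cv$cutoff, 0.5)
})

test_that("variable panels assemble to the documented sizes", {
  sim <- generate_cohort(default_cohort_spec(), seed = 51)
  sc <- score_cohort(sim$cohort)
  qc <- detection_qc(sim$ct, refs = sim$refs)
  rl <- normalize_ddct(qc$ct, sim$refs, "NL", sim$cohort$group)
  panels <- build_variable_panels(sc, rl)
  expect_identical(ncol(panels$clinical), 16L)
  expect_identical(ncol(panels$mirna), 33L)
  expect_identical(ncol(panels$combined), 49L)
  expect_setequal(colnames(panels$combined),
                  union(colnames(panels$clinical), colnames(panels$mirna)))
  # removing one ratio pair propagates through the sizes
  pairs <- seromir:::.default_panel_ratio_pairs()
  panels2 <- build_variable_panels(sc, rl, ratio_pairs = pairs[-1, ])
  expect_identical(ncol(panels2$mirna), 32L)
  expect_identical(ncol(panels2$combined), 48L)
  expect_error(build_variable_panels(sc[, -match("ast", names(sc))], rl),
               "ast")
})
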