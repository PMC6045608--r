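make_ct <- function(n_sub, assays, value = 30) {
  matrix(value, n_sub, length(assays),
         dimnames = list(sprintf("S%02d", seq_len(n_sub)), assays))
}

test_that("detection QC applies the confidence threshold per assay", {
  ct <- make_ct(10, c("a", "b", "r1", "r2"))
  qc <- detection_qc(ct, refs = c("r1", "r2"))
  expect_length(qc$excluded, 0)
  expect_true(all(qc$mask))

  ct[, "a"] <- NA
  qc <- detection_qc(ct, refs = c("r1", "r2"))
  expect_identical(qc$excluded, "a")
  expect_equal(unname(qc$detection["a"]), 0)
  expect_false("a" %in% colnames(qc$ct))

  # 85/92 detected (0.924) retained; 80/92 (0.870) excluded
  ct <- make_ct(92, c("keep", "drop", "r1", "r2"))
  ct[1:7, "keep"] <- NA
  ct[1:12, "drop"] <- NA
  qc <- detection_qc(ct, refs = c("r1", "r2"))
  expect_identical(qc$excluded, "drop")
  expect_true("keep" %in% colnames(qc$ct))

  # values at the threshold count as undetected and are censored to missing
  ct <- make_ct(10, c("a", "r1", "r2"))
  ct[1, "a"] <- 38
  qc <- detection_qc(ct, refs = c("r1", "r2"))
  expect_true(is.na(qc$ct[1, "a"]))
  qc2 <- detection_qc(ct, refs = c("r1", "r2"), mode = "impute")
  expect_equal(unname(qc2$ct[1, "a"]), 38)

  # failing reference is a hard error
  ct[, "r1"] <- NA
  expect_error(detection_qc(ct, refs = c("r1", "r2")), "r1")
})

test_that("detection QC is idempotent", {
  set.seed(5)
  ct <- make_ct(30, c("a", "b", "c", "r1", "r2")) +
    matrix(rnorm(150, 0, 4), 30)
  ct[ct >= 44.9] <- 44.5
  ct[ct <= 1] <- 1.5
  qc1 <- detection_qc(ct, refs = c("r1", "r2"))
  qc2 <- detection_qc(qc1$ct, refs = c("r1", "r2"))
  expect_identical(qc1$ct, qc2$ct)
  expect_length(qc2$excluded, 0)
})

test_that("geNorm M values match the brute-force pairwise-SD oracle", {
  set.seed(11)
  for (rep in 1:5) {
    ct <- matrix(rnorm(24, 30, 2), 6, 4,
                 dimnames = list(paste0("S", 1:6), paste0("g", 1:4)))
    gn <- genorm_rank(ct)
    expect_equal(gn$M, genorm_oracle(ct), tolerance = 1e-10)
  }
})

test_that("proportional assays contribute zero pairwise variation", {
  ct <- cbind(a = c(28, 30, 31, 29), b = c(29, 31, 32, 30),
              c = c(25, 33, 28, 35))
  rownames(ct) <- paste0("S", 1:4)
  gn <- genorm_rank(ct)
  # the a-b pair has constant difference: its SD contributes 0 to both
  expect_equal(unname(gn$M["a"]), mean(c(0, sd(ct[, "c"] - ct[, "a"]))))
  expect_equal(unname(gn$M["b"]), mean(c(0, sd(ct[, "c"] - ct[, "b"]))))
})

test_that("geNorm ranking is equivariant and offset-invariant", {
  set.seed(12)
  ct <- matrix(rnorm(50, 30, 1.5), 10, 5,
               dimnames = list(paste0("S", 1:10), paste0("g", 1:5)))
  gn <- genorm_rank(ct)
  perm <- c(3, 1, 5, 2, 4)
  gnp <- genorm_rank(ct[, perm])
  expect_equal(gn$M[colnames(ct)[perm]], gnp$M, tolerance = 1e-12)
  # adding a per-assay constant offset changes nothing
  gno <- genorm_rank(sweep(ct, 2, c(1, -2, 0.5, 3, 0), "+"))
  expect_equal(gn$M, gno$M, tolerance = 1e-12)
  # stepwise trace removes down to the final pair
  expect_identical(nrow(gn$trace), 3L)
})

test_that("designated references win the stability ranking in simulation", {
  spec <- default_cohort_spec(target_noise_sd = 1, reference_noise_sd = 0.1)
  wins <- 0L
  for (r in 1:50) {
    sim <- generate_cohort(spec, seed = 700 + r)
    gn <- genorm_rank(detection_qc(sim$ct, refs = sim$refs)$ct)
    if (all(sim$refs %in% gn$ranking[1:2])) wins <- wins + 1L
  }
  expect_gte(wins / 50, 0.95)
})

test_that("2^-ddCt reproduces the hand-worked example", {
  ct <- rbind(S1 = c(tgt = 30, r1 = 25, r2 = 27),
              S2 = c(tgt = 30, r1 = 25, r2 = 27),
              S3 = c(tgt = 28, r1 = 25, r2 = 27))
  rl <- normalize_ddct(ct, refs = c("r1", "r2"), control_group = "ctl",
                       groups = c("ctl", "ctl", "case"))
  expect_equal(unname(rl$delta_ct[, "tgt"]), c(4, 4, 2))
  expect_equal(unname(rl$levels["S3", "tgt"]), 4)
  expect_equal(unname(rl$levels["S1", "tgt"]), 1)
})

test_that("2^-ddCt satisfies its defining identities", {
  set.seed(13)
  ct <- matrix(rnorm(80, 31, 2), 20, 4,
               dimnames = list(paste0("S", 1:20),
                               c("t1", "t2", "r1", "r2")))
  groups <- rep(c("ctl", "case"), each = 10)
  rl <- normalize_ddct(ct, c("r1", "r2"), "ctl", groups)
  # control-group geometric mean of levels is exactly 1 per assay
  gm <- exp(colMeans(log(rl$levels[groups == "ctl", , drop = FALSE])))
  expect_equal(unname(gm), c(1, 1), tolerance = 1e-9)
  # a global per-subject Ct shift (efficiency offset) leaves levels unchanged
  shifted <- ct + matrix(runif(20, -3, 3), 20, 4)
  rl2 <- normalize_ddct(shifted, c("r1", "r2"), "ctl", groups)
  expect_equal(rl$levels, rl2$levels, tolerance = 1e-12)
  # ddCt of -1 means level 2, +2 means level 0.25
  expect_equal(unname(2^(-(-1))), 2)
  idx <- which(!is.na(rl$ddct), arr.ind = TRUE)[1, ]
  expect_equal(rl$levels[idx[1], idx[2]],
               2^(-rl$ddct[idx[1], idx[2]]), tolerance = 1e-12)
})

test_that("normalization handles missing references and empty controls", {
  ct <- make_ct(4, c("t", "r1", "r2"))
  ct[2, "r1"] <- NA
  expect_warning(
    rl <- normalize_ddct(ct, c("r1", "r2"), "ctl",
                         groups = c("ctl", "ctl", "case", "case")),
    "S02")
  expect_identical(nrow(rl$levels), 3L)
  expect_error(normalize_ddct(make_ct(2, c("t", "r1", "r2")),
                              c("r1", "r2"), "nope", c("a", "b")),
               "empty")
})

test_that("fold-change tables report ratio, test and direction", {
  set.seed(14)
  ct <- matrix(rnorm(120, 30, 0.5), 30, 4,
               dimnames = list(paste0("S", 1:30),
                               c("t1", "t2", "r1", "r2")))
  groups <- rep(c("ctl", "case"), each = 15)
  ct[groups == "case", "t1"] <- ct[groups == "case", "t1"] - 2  # 4-fold up
  rl <- normalize_ddct(ct, c("r1", "r2"), "ctl", groups)
  fc <- fold_change_table(rl, groups == "case")
  expect_identical(fc$direction[fc$assay == "t1"], "induced")
  expect_gt(fc$fold_change[fc$assay == "t1"], 2)
  expect_identical(fc$direction[fc$assay == "t2"], "ns")
  expect_true(all(fc$test_used %in% c("student_t", "mann_whitney_u")))
  # degenerate side is skipped with a warning per assay
  w <- capture_warnings(fold_change_table(rl, c(TRUE, rep(FALSE, 29))))
  expect_true(length(w) >= 1 && all(grepl("degenerate", w)))
})
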