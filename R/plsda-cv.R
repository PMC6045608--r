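# Leave-one-out cross-validation for PLS-DA: latent-variable selection by
# misclassification count and leakage-free generalization assessment.
# Autoscaling and median imputation are recomputed inside every training
# fold.

# Train-fold preprocessing: median imputation and autoscaling constants
# estimated on the training rows only. Zero-variance training columns get
# unit scale (a centered constant column contributes nothing).
.fold_prepare <- function(x_train) {
  med <- apply(x_train, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in seq_len(ncol(x_train))) {
    nas <- is.na(x_train[, j])
    if (any(nas)) x_train[nas, j] <- med[j]
  }
  ctr <- colMeans(x_train)
  scl <- apply(x_train, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(x = sweep(sweep(x_train, 2, ctr), 2, scl, "/"),
       median = med, center = ctr, scale = scl)
}

.fold_apply <- function(prep, x_new) {
  for (j in seq_len(ncol(x_new))) {
    nas <- is.na(x_new[, j])
    if (any(nas)) x_new[nas, j] <- prep$median[j]
  }
  sweep(sweep(x_new, 2, prep$center), 2, prep$scale, "/")
}

# Out-of-fold LOO score matrix: row i = predictions for held-out sample i at
# 1..max_lv latent variables (training on the other n-1 samples). A training
# fold with a single class still yields a prediction (the class-mean score).
.loo_scores <- function(x, y01, max_lv) {
  n <- nrow(x)
  scores <- matrix(NA_real_, n, max_lv)
  for (i in seq_len(n)) {
    prep <- .fold_prepare(x[-i, , drop = FALSE])
    yt <- y01[-i]
    ym <- mean(yt)
    Xnew <- .fold_apply(prep, x[i, , drop = FALSE])
    if (stats::var(yt) == 0) {
      scores[i, ] <- ym
      next
    }
    core <- tryCatch(.nipals_pls1(prep$x, yt - ym, max_lv),
                     error = function(e) NULL)
    if (is.null(core)) {
      scores[i, ] <- ym
      next
    }
    pred <- ym + Xnew %*% core$coef_path
    k <- ncol(core$coef_path)
    scores[i, seq_len(k)] <- pred
    if (k < max_lv) scores[i, (k + 1L):max_lv] <- pred[k]
  }
  scores
}

#' Select the number of latent variables by leave-one-out cross-validation
#'
#' For every candidate count of latent variables, each subject is classified
#' (continuous score thresholded at 0.5) by a PLS-DA model trained on the
#' remaining subjects, with median imputation and autoscaling recomputed
#' inside each training fold. The selected count minimizes the total number
#' of misclassifications; ties go to the smallest count.
#'
#' @param x numeric samples x variables matrix (missing values allowed;
#'   imputed per fold).
#' @param y binary response.
#' @param max_lv maximum latent variables to consider (default 10; reduced
#'   with a warning when infeasible for the fold size).
#' @return List with `n_lv` (selected count), `errors` (misclassification
#'   count per candidate) and `cv_scores` (out-of-fold score matrix,
#'   subjects x candidates).
#' @export
loocv_select_lv <- function(x, y, max_lv = 10) {
  x <- as.matrix(x)
  enc <- .encode_class(y)
  n <- nrow(x)
  if (n < 10L) stop("leave-one-out selection needs at least 10 samples")
  feasible <- min(n - 2L, ncol(x))
  if (max_lv > feasible) {
    warning("'max_lv' reduced to ", feasible, " (fold-size limit)")
    max_lv <- feasible
  }
  scores <- .loo_scores(x, enc$y01, max_lv)
  errors <- colSums((scores >= 0.5) != enc$y01)
  n_lv <- which.min(errors)  # ties resolve to the smallest count
  list(n_lv = n_lv, errors = errors, cv_scores = scores)
}

#' Cross-validated performance of a PLS-DA model
#'
#' Collects the out-of-fold continuous predictions of a leave-one-out
#' cross-validation (every subject predicted exactly once by a model that
#' never saw it) and computes the cross-validated AUROC, the confusion
#' metrics at the 0.5 class-code midpoint (or at a Youden-optimal threshold
#' on the CV scores) and their confidence intervals. The ROC direction is
#' fixed (higher score = positive class), so a null model is honestly
#' assessed at AUROC 0.5.
#'
#' @param x numeric samples x variables matrix.
#' @param y binary response.
#' @param n_lv number of latent variables; `NULL` (default) selects it with
#'   [loocv_select_lv()].
#' @param max_lv passed to the selection step.
#' @param threshold `"midpoint"` (0.5, default) or `"youden"` (optimized on
#'   the CV scores).
#' @param level confidence level for the intervals.
#' @param panel optional panel name carried into the result.
#' @return A `cv_performance` object: `cv_scores`, `auroc` with `auroc_ci`,
#'   the diagnostic `report` (with CIs), `n_lv`, `threshold` and `panel`.
#' @export
loocv_evaluate <- function(x, y, n_lv = NULL, max_lv = 10,
                           threshold = c("midpoint", "youden"),
                           level = 0.95, panel = NULL) {
  threshold <- match.arg(threshold)
  x <- as.matrix(x)
  enc <- .encode_class(y)
  sel_errors <- NULL
  if (is.null(n_lv)) {
    sel <- loocv_select_lv(x, y, max_lv = max_lv)
    n_lv <- sel$n_lv
    sel_errors <- sel$errors
    cv <- sel$cv_scores[, n_lv]
  } else {
    feasible <- min(nrow(x) - 2L, ncol(x))
    if (n_lv > feasible) {
      warning("'n_lv' reduced to ", feasible, " (fold-size limit)")
      n_lv <- feasible
    }
    cv <- .loo_scores(x, enc$y01, n_lv)[, n_lv]
  }
  roc <- empirical_roc(cv, enc$y01 == 1, direction = "higher_is_positive")
  cut <- if (threshold == "midpoint") 0.5 else youden_optimal_cutoff(roc)$cutoff
  cnt <- .roc_counts_at(roc, cut)
  report <- metric_confidence_intervals(
    confusion_metrics(cnt["tp"], cnt["fp"], cnt["fn"], cnt["tn"]),
    level = level)
  structure(list(cv_scores = cv, auroc = roc$auroc,
                 auroc_ci = .auroc_ci_hanley(roc$auroc, roc$n_pos, roc$n_neg,
                                             level),
                 report = report, n_lv = n_lv, errors = sel_errors,
                 cutoff = cut, threshold = threshold, panel = panel),
            class = "cv_performance")
}

#' @export
print.cv_performance <- function(x, digits = 3, ...) {
  cat("Leave-one-out cross-validated PLS-DA performance")
  if (!is.null(x$panel)) cat(" [", x$panel, " panel]", sep = "")
  cat("\n")
  cat(sprintf("  AUROC %.3f (%.3f-%.3f), %d latent variable(s), cut-off %.3g\n",
              x$auroc, x$auroc_ci[1], x$auroc_ci[2], x$n_lv, x$cutoff))
  print(x$report, digits = digits)
  invisible(x)
}

# 16 serum-based clinical variables used in the multivariate panels.
.default_clinical_vars <- c("age", "bmi", "glucose", "triglycerides",
                            "cholesterol", "hdl", "ldl", "bilirubin",
                            "albumin", "platelets", "alt", "ast", "ggt",
                            "alp", "ferritin", "hb")

# 17 ratio features for the miRNA panel: the full induced x repressed cross
# minus miR-21/16, whose numerator and denominator are both general
# liver-injury responders (altered in DILI), making it the least
# NAFLD-specific ratio of the 18.
.default_panel_ratio_pairs <- function() {
  pairs <- expand.grid(den = .default_denominators,
                       num = .default_numerators,
                       stringsAsFactors = FALSE)[, c("num", "den")]
  pairs[!(pairs$num == "miR-21" & pairs$den == "miR-16"), ]
}

#' Assemble clinical, miRNA and combined variable panels
#'
#' Builds the three predictor matrices used by the multivariate models:
#' `clinical` (16 serum-based laboratory/anthropometric variables), `mirna`
#' (the detected miRNA levels plus 17 induced/repressed ratio features,
#' 33 variables with the default 16-assay panel) and `combined` (their
#' union, 49 variables).
#'
#' @param cohort cohort data frame holding the clinical columns.
#' @param rl a `relative_levels` object with the detected assays.
#' @param clinical_vars clinical column names (default: the 16-variable
#'   serum panel).
#' @param ratio_pairs data frame with columns `num` and `den` naming the
#'   ratio features (default: 17 pairs).
#' @return Named list of numeric matrices `clinical`, `mirna`, `combined`.
#' @export
build_variable_panels <- function(cohort, rl,
                                  clinical_vars = .default_clinical_vars,
                                  ratio_pairs = .default_panel_ratio_pairs()) {
  miss <- setdiff(clinical_vars, names(cohort))
  if (length(miss))
    stop("clinical variable(s) missing from cohort: ",
         paste(miss, collapse = ", "))
  if (!inherits(rl, "relative_levels"))
    stop("'rl' must come from normalize_ddct()")
  clinical <- as.matrix(cohort[, clinical_vars, drop = FALSE])
  rownames(clinical) <- cohort$subject_id
  keep <- intersect(rownames(rl$levels), rownames(clinical))
  if (!length(keep)) stop("no overlapping subjects between cohort and levels")
  clinical <- clinical[keep, , drop = FALSE]
  lvl <- rl$levels[keep, , drop = FALSE]
  ratios <- build_ratio_features(lvl, numerators = unique(ratio_pairs$num),
                                 denominators = unique(ratio_pairs$den))
  want <- paste0(ratio_pairs$num, "/", sub("^miR-", "", ratio_pairs$den))
  ratios <- ratios[, want, drop = FALSE]
  mirna <- cbind(lvl, ratios)
  combined <- cbind(clinical, mirna)
  if (anyDuplicated(colnames(combined)))
    stop("duplicate variable names across panels")
  list(clinical = clinical, mirna = mirna, combined = combined)
}
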