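# Ratio-biomarker construction and single-marker diagnostic evaluation:
# empirical ROC, AUROC, Youden-optimal cut-off and the full confusion-metric
# panel with confidence intervals.

.default_numerators <- c("miR-34a", "miR-27b", "miR-22", "miR-122",
                         "miR-192", "miR-21")
.default_denominators <- c("miR-30c", "miR-16", "miR-197")

#' Build induced/repressed miRNA ratio features
#'
#' One feature per (numerator, denominator) pair, `level_num / level_den`,
#' named in the `miR-34a/197` style. Ratios of an induced over a repressed
#' miRNA amplify the severity signal of both. The default pairing crosses
#' the six induced markers with the three repressed ones (18 features).
#'
#' @param levels a `relative_levels` object or a positive subjects x assays
#'   matrix of normalized levels.
#' @param numerators,denominators assay names; all must be present.
#' @return Numeric matrix of ratio features; a ratio is missing where either
#'   side is missing.
#' @export
build_ratio_features <- function(levels,
                                 numerators = .default_numerators,
                                 denominators = .default_denominators) {
  if (inherits(levels, "relative_levels")) levels <- levels$levels
  miss <- setdiff(c(numerators, denominators), colnames(levels))
  if (length(miss)) stop("assay(s) not present: ", paste(miss, collapse = ", "))
  if (any(levels[, denominators] <= 0, na.rm = TRUE))
    stop("denominator levels must be positive")
  pairs <- expand.grid(den = denominators, num = numerators,
                       stringsAsFactors = FALSE)[, c("num", "den")]
  out <- mapply(function(nu, de) levels[, nu] / levels[, de],
                pairs$num, pairs$den)
  colnames(out) <- paste0(pairs$num, "/", sub("^miR-", "", pairs$den))
  rownames(out) <- rownames(levels)
  out
}

#' Empirical ROC curve
#'
#' Computes the receiver operating characteristic at every observed marker
#' value, with ties handled as simultaneous steps, and the AUROC by the
#' trapezoidal rule (equal to the Mann-Whitney U statistic over `n1*n0`,
#' counting ties one half). `direction = "auto"` orients the marker so that
#' the AUROC is at least 0.5 and records the chosen orientation.
#'
#' @param scores numeric marker values.
#' @param labels logical (or 0/1) class labels, `TRUE` = positive.
#' @param direction `"auto"`, `"higher_is_positive"` or
#'   `"lower_is_positive"`. Fixed directions are never flipped (use them for
#'   cross-validated scores, where auto-orientation would bias a null AUROC
#'   upward).
#' @return A `mir_roc` object: `thresholds` (observed values, original
#'   scale), `tpr`, `fpr` (per threshold, positive call at
#'   threshold-or-beyond in the resolved direction), `auroc`, `direction`,
#'   class counts and the complete-case scores/labels used.
#' @export
empirical_roc <- function(scores, labels,
                          direction = c("auto", "higher_is_positive",
                                        "lower_is_positive")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels) & is.finite(scores)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be non-empty")

  curve <- function(s) {
    thr <- sort(unique(s), decreasing = TRUE)
    tpr <- vapply(thr, function(cc) sum(s[labels] >= cc) / n1, numeric(1))
    fpr <- vapply(thr, function(cc) sum(s[!labels] >= cc) / n0, numeric(1))
    # trapezoid over points (0,0), (fpr, tpr)..., (1,1)
    xs <- c(0, fpr, 1); ys <- c(0, tpr, 1)
    auc <- sum(diff(xs) * (utils::head(ys, -1) + ys[-1]) / 2)
    list(thr = thr, tpr = tpr, fpr = fpr, auc = auc)
  }

  if (direction == "auto") {
    hi <- curve(scores)
    if (hi$auc >= 0.5) {
      direction <- "higher_is_positive"
      cv <- hi
    } else {
      direction <- "lower_is_positive"
      cv <- curve(-scores)
      cv$thr <- -cv$thr
    }
  } else if (direction == "higher_is_positive") {
    cv <- curve(scores)
  } else {
    cv <- curve(-scores)
    cv$thr <- -cv$thr
  }
  structure(list(thresholds = cv$thr, tpr = cv$tpr, fpr = cv$fpr,
                 auroc = cv$auc, direction = direction,
                 n_pos = n1, n_neg = n0, scores = scores, labels = labels),
            class = "mir_roc")
}

#' @export
print.mir_roc <- function(x, ...) {
  cat(sprintf("Empirical ROC: AUROC = %.3f (%d positives, %d negatives, %s)\n",
              x$auroc, x$n_pos, x$n_neg, x$direction))
  invisible(x)
}

#' @export
plot.mir_roc <- function(x, ...) {
  plot(c(0, x$fpr, 1), c(0, x$tpr, 1), type = "s",
       xlab = "False positive rate", ylab = "True positive rate",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

# sens/spec at an observed cut-off, positive call at threshold-or-beyond in
# the ROC's direction.
.roc_counts_at <- function(roc, cutoff) {
  s <- roc$scores
  pos_call <- if (roc$direction == "lower_is_positive") s <= cutoff else s >= cutoff
  tp <- sum(pos_call & roc$labels); fn <- roc$n_pos - tp
  fp <- sum(pos_call & !roc$labels); tn <- roc$n_neg - fp
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Youden-optimal cut-off
#'
#' Maximizes the Youden index `J = sensitivity + specificity - 1` over the
#' observed thresholds of an empirical ROC. Ties are broken toward higher
#' sensitivity and then toward the lower cut-off value.
#'
#' @param roc a `mir_roc` object.
#' @return List with `cutoff`, `j`, `sensitivity` and `specificity` at the
#'   optimum.
#' @export
youden_optimal_cutoff <- function(roc) {
  if (!inherits(roc, "mir_roc")) stop("'roc' must come from empirical_roc()")
  sens <- roc$tpr
  spec <- 1 - roc$fpr
  j <- sens + spec - 1
  best <- abs(j - max(j)) < 1e-12
  cand <- which(best)
  cand <- cand[sens[cand] == max(sens[cand])]
  cutoff <- min(roc$thresholds[cand])
  at <- which(roc$thresholds == cutoff)[1]
  list(cutoff = cutoff, j = j[at], sensitivity = sens[at],
       specificity = spec[at])
}

#' Confusion-matrix diagnostic metrics
#'
#' Sensitivity, specificity, PPV, NPV, accuracy, and the positive/negative
#' likelihood ratios from the four confusion counts. Degenerate margins give
#' flagged `NA` metrics instead of errors; a perfect specificity with
#' positive sensitivity yields `PLR = Inf` explicitly.
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return A `diagnostic_report` object: `counts`, `estimates` (named list)
#'   and `flags` (names of undefined metrics).
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn); tn <- unname(tn)
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("empty confusion matrix")
  flags <- character()
  rate <- function(num, den, what) {
    if (den == 0) { flags <<- c(flags, what); return(NA_real_) }
    num / den
  }
  sens <- rate(tp, tp + fn, "sensitivity")
  spec <- rate(tn, tn + fp, "specificity")
  ppv <- rate(tp, tp + fp, "ppv")
  npv <- rate(tn, tn + fn, "npv")
  acc <- (tp + tn) / n
  plr <- if (is.na(sens) || is.na(spec)) {
    flags <- c(flags, "plr"); NA_real_
  } else if (spec == 1) {
    if (sens > 0) Inf else { flags <- c(flags, "plr"); NA_real_ }
  } else sens / (1 - spec)
  nlr <- if (is.na(sens) || is.na(spec)) {
    flags <- c(flags, "nlr"); NA_real_
  } else if (spec == 0) {
    flags <- c(flags, "nlr"); NA_real_
  } else (1 - sens) / spec
  structure(list(counts = counts,
                 estimates = list(sensitivity = sens, specificity = spec,
                                  ppv = ppv, npv = npv, plr = plr, nlr = nlr,
                                  accuracy = acc),
                 flags = unique(flags)),
            class = "diagnostic_report")
}

#' Diagnostic metrics implied by sensitivity, specificity and prevalence
#'
#' Bayes'-rule recomputation of the predictive values, likelihood ratios and
#' accuracy from a (sensitivity, specificity) pair and the class sizes, on
#' the continuous scale (no integer rounding of counts). Useful for checking
#' the internal consistency of published diagnostic panels.
#'
#' @param sensitivity,specificity proportions in `[0, 1]`.
#' @param n_pos,n_neg positive/negative class sizes.
#' @return Named list with `ppv`, `npv`, `plr`, `nlr` and `accuracy`.
#' @examples
#' metrics_from_rates(0.73, 0.83, 50, 42)$nlr  # ~0.33
#' @export
metrics_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  p <- n_pos / (n_pos + n_neg)
  ppv <- (sensitivity * p) / (sensitivity * p + (1 - specificity) * (1 - p))
  npv <- (specificity * (1 - p)) /
    (specificity * (1 - p) + (1 - sensitivity) * p)
  list(ppv = ppv, npv = npv,
       plr = if (specificity == 1) Inf else sensitivity / (1 - specificity),
       nlr = (1 - sensitivity) / specificity,
       accuracy = sensitivity * p + specificity * (1 - p))
}

# Clopper-Pearson exact interval for a binomial proportion.
.clopper_pearson <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lo, upper = hi)
}

# Simel log-method interval for a likelihood ratio; Haldane 0.5 correction
# when any cell is zero.
.lr_ci <- function(tp, fp, fn, tn, which = c("plr", "nlr"), level = 0.95) {
  which <- match.arg(which)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (any(c(tp, fp, fn, tn) == 0)) {
    tp <- tp + 0.5; fp <- fp + 0.5; fn <- fn + 0.5; tn <- tn + 0.5
  }
  n1 <- tp + fn; n0 <- fp + tn
  sens <- tp / n1; spec <- tn / n0
  if (which == "plr") {
    est <- sens / (1 - spec)
    se <- sqrt((1 - sens) / (sens * n1) + spec / ((1 - spec) * n0))
  } else {
    est <- (1 - sens) / spec
    se <- sqrt(sens / ((1 - sens) * n1) + (1 - spec) / (spec * n0))
  }
  exp(log(est) + c(lower = -1, upper = 1) * z * se)
}

# Hanley-McNeil standard-error interval for the AUROC.
.auroc_ci_hanley <- function(auc, n1, n0, level = 0.95) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = max(0, auc - z * se), upper = min(1, auc + z * se))
}

# DeLong placement-value interval for the AUROC.
.auroc_ci_delong <- function(roc, level = 0.95) {
  xs <- roc$scores
  if (roc$direction == "lower_is_positive") xs <- -xs
  pos <- xs[roc$labels]; neg <- xs[!roc$labels]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), numeric(1))
  auc <- mean(v10)
  se <- sqrt(stats::var(v10) / length(pos) + stats::var(v01) / length(neg))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = max(0, auc - z * se), upper = min(1, auc + z * se))
}

#' Attach confidence intervals to a diagnostic report
#'
#' Clopper-Pearson exact intervals for the proportions (sensitivity,
#' specificity, PPV, NPV, accuracy) and Simel log-method intervals for the
#' likelihood ratios (with a 0.5 continuity correction when a cell is zero,
#' giving effectively one-sided exact behaviour at the boundary).
#'
#' @param report a `diagnostic_report` from [confusion_metrics()].
#' @param level confidence level (default 0.95).
#' @return The report with a `ci` list (lower/upper per metric) and `level`.
#' @export
metric_confidence_intervals <- function(report, level = 0.95) {
  if (!inherits(report, "diagnostic_report"))
    stop("'report' must come from confusion_metrics()")
  ct <- as.list(report$counts)
  ci <- list()
  with_ci <- function(x, n) if (n > 0) .clopper_pearson(x, n, level) else
    c(lower = NA_real_, upper = NA_real_)
  ci$sensitivity <- with_ci(ct$tp, ct$tp + ct$fn)
  ci$specificity <- with_ci(ct$tn, ct$tn + ct$fp)
  ci$ppv <- with_ci(ct$tp, ct$tp + ct$fp)
  ci$npv <- with_ci(ct$tn, ct$tn + ct$fn)
  ci$accuracy <- with_ci(ct$tp + ct$tn, sum(report$counts))
  ci$plr <- .lr_ci(ct$tp, ct$fp, ct$fn, ct$tn, "plr", level)
  ci$nlr <- .lr_ci(ct$tp, ct$fp, ct$fn, ct$tn, "nlr", level)
  report$ci <- ci
  report$level <- level
  report
}

#' @export
print.diagnostic_report <- function(x, digits = 3, ...) {
  cat("Diagnostic report (tp/fp/fn/tn = ",
      paste(x$counts, collapse = "/"), ")\n", sep = "")
  for (m in names(x$estimates)) {
    cat(sprintf("  %-12s %s", m, format(round(x$estimates[[m]], digits))))
    if (!is.null(x$ci) && !anyNA(x$ci[[m]]))
      cat(sprintf("  (%s-%s)", format(round(x$ci[[m]][1], digits)),
                  format(round(x$ci[[m]][2], digits))))
    cat("\n")
  }
  invisible(x)
}

#' Evaluate a single diagnostic marker
#'
#' Composes the single-marker pipeline: empirical ROC with auto direction,
#' Youden-optimal cut-off, confusion metrics at that cut-off and confidence
#' intervals, plus an AUROC interval (Hanley-McNeil by default, DeLong as an
#' option). Subjects with a missing marker value are excluded
#' (complete-case).
#'
#' @param scores numeric marker values.
#' @param labels logical outcome, `TRUE` = diseased.
#' @param level confidence level.
#' @param direction passed to [empirical_roc()].
#' @param auroc_ci `"hanley"` (default) or `"delong"`.
#' @return A `marker_eval` object: `roc`, `cutoff`, `youden`, `report` (with
#'   CIs) and `auroc_ci`.
#' @export
evaluate_marker <- function(scores, labels, level = 0.95,
                            direction = "auto",
                            auroc_ci = c("hanley", "delong")) {
  auroc_ci <- match.arg(auroc_ci)
  roc <- empirical_roc(scores, labels, direction = direction)
  yj <- youden_optimal_cutoff(roc)
  cnt <- .roc_counts_at(roc, yj$cutoff)
  report <- metric_confidence_intervals(
    confusion_metrics(cnt["tp"], cnt["fp"], cnt["fn"], cnt["tn"]),
    level = level)
  aci <- if (auroc_ci == "hanley") {
    .auroc_ci_hanley(roc$auroc, roc$n_pos, roc$n_neg, level)
  } else {
    .auroc_ci_delong(roc, level)
  }
  structure(list(roc = roc, cutoff = yj$cutoff, youden = yj$j,
                 report = report, auroc_ci = aci, level = level),
            class = "marker_eval")
}

#' @export
print.marker_eval <- function(x, digits = 3, ...) {
  cat(sprintf("AUROC %.3f (%.3f-%.3f), Youden cut-off %.4g (J = %.3f)\n",
              x$roc$auroc, x$auroc_ci[1], x$auroc_ci[2], x$cutoff, x$youden))
  print(x$report, digits = digits)
  invisible(x)
}
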