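# Univariate statistical toolkit: adaptive two-group test, one-way ANOVA with
# Tukey HSD, chi-square, and Pearson/Spearman correlation. Every result
# records which test was actually used, so the adaptive policy is auditable.

.mir_test <- function(statistic, p_value, test_used, df = NA_real_,
                      n = NA_integer_, estimate = NA_real_, note = NULL) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 test_used = test_used, df = unname(df), n = n,
                 estimate = unname(estimate), note = note),
            class = "mir_test")
}

#' @export
print.mir_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g", x$test_used,
              x$statistic, x$p_value))
  if (!is.na(x$df)) cat(sprintf(", df = %.3g", x$df))
  if (!is.na(x$estimate)) cat(sprintf(", estimate = %.4g", x$estimate))
  cat("\n")
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

.shapiro_p <- function(x) {
  if (length(unique(x)) < 3L) return(0)
  tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
}

#' Adaptive two-sample test
#'
#' Applies the pooled-variance Student t-test when both samples look normal
#' (Shapiro-Wilk p > `alpha_assumptions` in each) and the variances look
#' equal (F-test p > `alpha_assumptions`); otherwise falls back to the
#' Mann-Whitney U test (exact for small samples without ties, normal
#' approximation with tie and continuity correction otherwise). Constant
#' samples go to the Mann-Whitney branch. Both branches can be forced via
#' `test`.
#'
#' @param x,y numeric samples, at least 3 non-missing values each.
#' @param alpha_assumptions level for the normality and variance-equality
#'   screens (default 0.05).
#' @param test `"auto"` (default), `"t"` or `"wilcox"`.
#' @return A `mir_test` result with the statistic, two-sided p-value and the
#'   branch actually used (`student_t` or `mann_whitney_u`).
#' @examples
#' auto_two_sample_test(c(1, 2, 3), c(4, 5, 6), test = "t")
#' @export
auto_two_sample_test <- function(x, y, alpha_assumptions = 0.05,
                                 test = c("auto", "t", "wilcox")) {
  test <- match.arg(test)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L)
    stop("each sample needs at least 3 non-missing values")
  use_t <- switch(test, t = TRUE, wilcox = FALSE, auto = {
    normal <- .shapiro_p(x) > alpha_assumptions &&
      .shapiro_p(y) > alpha_assumptions
    eqvar <- if (normal) {
      p <- tryCatch(stats::var.test(x, y)$p.value, error = function(e) 0)
      !is.na(p) && p > alpha_assumptions
    } else FALSE
    normal && eqvar
  })
  if (use_t) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    .mir_test(tt$statistic, tt$p.value, "student_t",
              df = tt$parameter, n = length(x) + length(y))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                              correct = TRUE))
    p <- wt$p.value
    if (is.na(p)) p <- 1  # fully tied degenerate case
    .mir_test(wt$statistic, p, "mann_whitney_u",
              n = length(x) + length(y))
  }
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' @param groups named list of at least 3 numeric samples, each with at least
#'   2 non-missing values.
#' @return List with `omnibus` (a `mir_test` with the F statistic) and
#'   `pairwise` (data frame of Tukey honest-significant-difference adjusted
#'   comparisons: difference of means and adjusted p-value).
#' @export
anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 3L)
    stop("'groups' must be a list of at least 3 samples")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs at least 2 non-missing values")
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  if (stats::var(dat$value) == 0) {
    omnibus <- .mir_test(0, 1, "anova_f", df = length(groups) - 1L,
                         n = nrow(dat))
    pairs <- t(utils::combn(names(groups), 2))
    pairwise <- data.frame(comparison = paste(pairs[, 2], pairs[, 1], sep = "-"),
                           diff = 0, p_adj = 1, stringsAsFactors = FALSE)
    return(list(omnibus = omnibus, pairwise = pairwise))
  }
  fit <- stats::aov(value ~ g, data = dat)
  an <- summary(fit)[[1]]
  omnibus <- .mir_test(an[["F value"]][1], an[["Pr(>F)"]][1], "anova_f",
                       df = an[["Df"]][1], n = nrow(dat))
  tk <- stats::TukeyHSD(fit)$g
  pairwise <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         p_adj = tk[, "p adj"], stringsAsFactors = FALSE,
                         row.names = NULL)
  list(omnibus = omnibus, pairwise = pairwise)
}

#' Pearson chi-square test of independence
#'
#' Pearson X^2 on an r x c contingency table with df = (r-1)(c-1), without
#' continuity correction.
#'
#' @param table matrix of non-negative counts, at least 2 x 2.
#' @return A `mir_test` with the X^2 statistic.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("'table' must have at least 2 rows and 2 columns")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in 'table'")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  .mir_test(ct$statistic, ct$p.value, "chi_square", df = ct$parameter,
            n = sum(table))
}

#' Correlation with adaptive method choice
#'
#' `method = "auto"` uses Pearson when both variables pass the Shapiro-Wilk
#' normality screen (p > `alpha_assumptions`) and Spearman rank correlation
#' otherwise; Spearman p-values use the t-approximation.
#'
#' @param x,y numeric vectors of equal length, at least 4 complete pairs.
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @param alpha_assumptions normality screen level (default 0.05).
#' @return A `mir_test` with the correlation in `estimate`. Constant input is
#'   flagged (`NA` estimate with an explanatory note), not an error.
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman"),
                      alpha_assumptions = 0.05) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("at least 4 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(.mir_test(NA_real_, NA_real_, "pearson", n = length(x),
                     note = "correlation undefined for constant input"))
  if (method == "auto") {
    method <- if (.shapiro_p(x) > alpha_assumptions &&
                  .shapiro_p(y) > alpha_assumptions) "pearson" else "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  .mir_test(ct$statistic, ct$p.value, method,
            df = if (!is.null(ct$parameter)) ct$parameter else NA_real_,
            n = length(x), estimate = ct$estimate)
}
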