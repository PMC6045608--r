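# PLS-DA by NIPALS (PLS1) with leave-one-out cross-validation for
# latent-variable selection and generalization assessment.

# Core NIPALS PLS1 on a pre-scaled matrix and centered response. Returns
# weights W, X-loadings P, y-loadings q, scores T and the coefficient path
# B[, k] for models truncated at k latent variables.
.nipals_pls1 <- function(Xs, yc, ncomp) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  X <- Xs
  k_used <- 0L
  for (k in seq_len(ncomp)) {
    w <- crossprod(X, yc)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break  # response variance exhausted
    w <- w / wn
    tt <- X %*% w
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) break
    pk <- crossprod(X, tt) / tt2
    q[k] <- sum(yc * tt) / tt2
    X <- X - tcrossprod(tt, pk)
    W[, k] <- w; P[, k] <- pk; Tm[, k] <- tt
    k_used <- k
  }
  if (k_used == 0L)
    stop("no latent variable could be extracted (response uncorrelated with X)")
  W <- W[, seq_len(k_used), drop = FALSE]
  P <- P[, seq_len(k_used), drop = FALSE]
  Tm <- Tm[, seq_len(k_used), drop = FALSE]
  q <- q[seq_len(k_used)]
  coef_path <- matrix(0, p, k_used)
  for (k in seq_len(k_used)) {
    Wk <- W[, seq_len(k), drop = FALSE]
    Pk <- P[, seq_len(k), drop = FALSE]
    coef_path[, k] <- Wk %*% solve(crossprod(Pk, Wk), q[seq_len(k)])
  }
  list(weights = W, x_loadings = P, y_loadings = q, scores = Tm,
       coef_path = coef_path, ncomp = k_used)
}

.encode_class <- function(y) {
  if (is.logical(y)) y <- factor(y, levels = c(FALSE, TRUE))
  if (!is.factor(y)) y <- factor(y)
  if (nlevels(y) != 2L)
    stop("'y' must be a two-class response (both classes present)")
  list(y01 = as.numeric(y) - 1, levels = levels(y))
}

#' Fit a PLS-DA classifier by NIPALS
#'
#' Partial least squares discriminant analysis for a binary response:
#' predictors are autoscaled (centered, unit variance), the class is coded
#' 0/1, and latent variables are extracted by NIPALS so that each explains
#' the maximal remaining covariance with the class vector. The fit is
#' deterministic. With as many latent variables as the predictor rank the
#' fitted values coincide with ordinary least squares.
#'
#' @param x numeric samples x variables matrix (no missing values).
#' @param y binary response: logical, 0/1, or a two-level factor.
#' @param ncomp number of latent variables, between 1 and
#'   `min(nrow(x) - 1, ncol(x))`.
#' @param center,scale autoscaling switches (default both `TRUE`).
#' @return A `plsda` object with standardization constants (`x_center`,
#'   `x_scale`), `weights`, `x_loadings`, `y_loadings`, orthogonal component
#'   `scores`, the coefficient path over component counts, `coefficients`
#'   (at `ncomp`, on the standardized scale), `ncomp` and the class coding.
#' @seealso [predict.plsda()], [loocv_select_lv()], [loocv_evaluate()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 20, 3)
#' y <- x[, 1] + rnorm(20) > 0
#' fit <- plsda(x, y, ncomp = 2)
#' fit
#' @export
plsda <- function(x, y, ncomp = 2, center = TRUE, scale = TRUE) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("'x' must not contain missing values (impute first)")
  enc <- .encode_class(y)
  n <- nrow(x); p <- ncol(x)
  if (length(enc$y01) != n) stop("'x' and 'y' lengths differ")
  max_comp <- min(n - 1L, p)
  if (ncomp < 1L || ncomp > max_comp)
    stop("'ncomp' must be between 1 and min(n - 1, p) = ", max_comp)
  x_center <- if (center) colMeans(x) else rep(0, p)
  x_scale <- if (scale) apply(x, 2, stats::sd) else rep(1, p)
  zero_var <- x_scale == 0
  if (any(zero_var))
    stop("zero-variance variable(s): ",
         paste(colnames(x)[zero_var], collapse = ", "))
  Xs <- sweep(sweep(x, 2, x_center), 2, x_scale, "/")
  y_mean <- mean(enc$y01)
  core <- .nipals_pls1(Xs, enc$y01 - y_mean, ncomp)
  structure(c(core,
              list(x_center = x_center, x_scale = x_scale, y_mean = y_mean,
                   y = enc$y01,
                   coefficients = core$coef_path[, core$ncomp],
                   class_codes = c(0, 1), levels = enc$levels,
                   variables = colnames(x), call = match.call())),
            class = "plsda")
}

#' Predict method for PLS-DA fits
#'
#' New samples are standardized with the training constants; the continuous
#' score is the regression prediction of the 0/1 class code and the class
#' call is made at the midpoint 0.5.
#'
#' @param object a `plsda` fit.
#' @param newdata numeric matrix with the training variables (matched by
#'   name when column names are present).
#' @param ncomp number of latent variables to use (default: the fitted
#'   number).
#' @param type `"response"` for continuous scores, `"class"` for class
#'   labels, `"both"` for a data frame with both.
#' @param ... unused.
#' @return Numeric scores, class labels, or a data frame of both.
#' @export
predict.plsda <- function(object, newdata, ncomp = object$ncomp,
                          type = c("response", "class", "both"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$variables) && !is.null(colnames(newdata))) {
    miss <- setdiff(object$variables, colnames(newdata))
    if (length(miss))
      stop("newdata is missing variable(s): ", paste(miss, collapse = ", "))
    newdata <- newdata[, object$variables, drop = FALSE]
  } else if (ncol(newdata) != length(object$x_center)) {
    stop("newdata has ", ncol(newdata), " variables; expected ",
         length(object$x_center))
  }
  if (ncomp < 1L || ncomp > object$ncomp)
    stop("'ncomp' must be between 1 and the fitted ", object$ncomp)
  Xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
  score <- drop(object$y_mean + Xs %*% object$coef_path[, ncomp])
  if (type == "response") return(score)
  cls <- object$levels[(score >= 0.5) + 1L]
  if (type == "class") return(cls)
  data.frame(score = score, class = cls, stringsAsFactors = FALSE)
}

#' @export
print.plsda <- function(x, ...) {
  cat("PLS-DA fit (NIPALS): ", length(x$x_center), " variables, ",
      x$ncomp, " latent variable(s)\n", sep = "")
  cat("  classes: ", paste(x$levels, collapse = " vs "),
      " (coded 0/1, threshold 0.5)\n", sep = "")
  invisible(x)
}

#' @export
summary.plsda <- function(object, ...) {
  tt2 <- colSums(object$scores^2)
  yvar <- object$y_loadings^2 * tt2
  total <- sum((object$y - object$y_mean)^2)
  out <- data.frame(LV = seq_len(object$ncomp),
                    cum_class_variance = cumsum(yvar) / total)
  cat("PLS-DA (NIPALS), ", object$ncomp, " latent variable(s)\n", sep = "")
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
coef.plsda <- function(object, ncomp = object$ncomp, ...) {
  b <- object$coef_path[, ncomp]
  names(b) <- object$variables
  b
}

#' @export
fitted.plsda <- function(object, ...) {
  drop(object$y_mean +
         rowSums(sweep(object$scores, 2, object$y_loadings, "*")))
}

#' @export
residuals.plsda <- function(object, ...) {
  object$y - fitted(object)
}

#' @export
plot.plsda <- function(x, y_labels = NULL, ...) {
  if (x$ncomp >= 2L) {
    plot(x$scores[, 1], x$scores[, 2], xlab = "LV1 score",
         ylab = "LV2 score", ...)
  } else {
    plot(x$scores[, 1], xlab = "sample", ylab = "LV1 score", ...)
  }
  invisible(x)
}
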