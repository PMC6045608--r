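# Ct-level quality control, geNorm stability ranking, and 2^-ddCt relative
# quantification against the geometric mean of reference miRNAs.

.check_ct_matrix <- function(ct) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("'ct' must be a numeric subjects x assays matrix")
  if (is.null(colnames(ct))) stop("'ct' must have assay column names")
  if (anyDuplicated(rownames(ct))) stop("subject ids (rownames) must be unique")
  if (any(!is.na(ct) & (ct <= 0 | ct >= 45)))
    stop("Ct values must lie within (0, 45) cycles")
  invisible(ct)
}

#' Detection quality control for a Ct matrix
#'
#' A measurement is detected when its Ct is below `max_ct` (undetected values
#' and missing cells count as not detected). Assays detected in fewer than
#' `min_detection` of subjects are excluded from downstream analysis, mirroring
#' the fate of assays that fail to amplify in most of a cohort. A reference
#' assay failing QC is a hard error: normalization cannot proceed without it.
#'
#' Undetected cells are censored to missing in the returned matrix by default
#' (censoring-as-value biases fold-changes); `mode = "impute"` instead sets
#' them to `max_ct` for sensitivity analysis.
#'
#' @param ct numeric subjects x assays Ct matrix (`NA` = not amplified).
#' @param max_ct detection threshold in cycles (default 38; detected means
#'   `Ct < max_ct`).
#' @param min_detection minimum fraction of subjects detected for an assay to
#'   be retained (default 0.9).
#' @param refs reference assay names that may never be excluded.
#' @param mode `"missing"` (default) or `"impute"` (undetected set to
#'   `max_ct`).
#' @return A `detection_qc` object: list with `mask` (logical detected
#'   matrix), `detection` (per-assay detected fraction), `excluded` (dropped
#'   assay names) and `ct` (retained matrix, undetected handled per `mode`).
#' @export
detection_qc <- function(ct, max_ct = 38, min_detection = 0.9,
                         refs = character(), mode = c("missing", "impute")) {
  mode <- match.arg(mode)
  .check_ct_matrix(ct)
  mask <- !is.na(ct) & ct < max_ct
  detection <- colMeans(mask)
  excluded <- colnames(ct)[detection < min_detection]
  bad_refs <- intersect(refs, excluded)
  if (length(bad_refs))
    stop("reference assay(s) failed detection QC: ",
         paste(bad_refs, collapse = ", "))
  keep <- setdiff(colnames(ct), excluded)
  out <- ct[, keep, drop = FALSE]
  if (mode == "missing") {
    out[!mask[, keep, drop = FALSE]] <- NA_real_
  } else {
    out[is.na(out) | out >= max_ct] <- max_ct
  }
  structure(list(mask = mask, detection = detection, excluded = excluded,
                 ct = out, max_ct = max_ct, min_detection = min_detection),
            class = "detection_qc")
}

#' @export
print.detection_qc <- function(x, ...) {
  cat("Detection QC: ", ncol(x$ct), " assays retained, ",
      length(x$excluded), " excluded (detection < ",
      x$min_detection, " at Ct < ", x$max_ct, ")\n", sep = "")
  if (length(x$excluded))
    cat("  excluded: ", paste(x$excluded, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' geNorm stability ranking of candidate reference assays
#'
#' For each assay i, the geNorm stability measure is
#' `M_i = mean_{j != i} sd_subjects(Ct_j - Ct_i)`: the average standard
#' deviation of its pairwise log2 expression ratios (log2 expression = -Ct,
#' so Ct differences are log ratios up to sign, which leaves the SD
#' unchanged). Lower M means more stable. A stepwise exclusion trace
#' repeatedly removes the least stable assay and recomputes M down to the
#' final pair, following geNorm convention. Missing values are handled
#' pairwise-complete; a pair with fewer than two complete observations is
#' skipped with a warning.
#'
#' @param ct numeric subjects x assays Ct matrix with at least 3 assays.
#' @return A `genorm_rank` object: list with `M` (named stability values),
#'   `ranking` (assay names, most stable first) and `trace` (data frame of
#'   the stepwise exclusions: step, removed assay, its M at removal).
#' @export
genorm_rank <- function(ct) {
  .check_ct_matrix(ct)
  if (ncol(ct) < 3L) stop("geNorm needs at least 3 assays")
  m_values <- function(x) {
    k <- ncol(x)
    sds <- matrix(NA_real_, k, k, dimnames = list(colnames(x), colnames(x)))
    skipped <- character()
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        d <- x[, j] - x[, i]
        d <- d[!is.na(d)]
        if (length(d) < 2L) {
          skipped <- c(skipped, paste0(colnames(x)[i], "/", colnames(x)[j]))
          next
        }
        sds[i, j] <- sds[j, i] <- stats::sd(d)
      }
    }
    if (length(skipped))
      warning("assay pair(s) skipped (fewer than 2 complete observations): ",
              paste(skipped, collapse = ", "))
    M <- rowMeans(sds, na.rm = TRUE)
    if (any(is.nan(M)))
      stop("no assay pair with at least 2 complete observations for: ",
           paste(names(M)[is.nan(M)], collapse = ", "))
    M
  }
  M <- m_values(ct)
  trace <- data.frame(step = integer(), removed = character(),
                      M = numeric(), stringsAsFactors = FALSE)
  cur <- ct
  step <- 0L
  while (ncol(cur) > 2L) {
    Mc <- if (step == 0L) M else m_values(cur)
    worst <- names(Mc)[which.max(Mc)]
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = worst,
                                     M = unname(Mc[worst]),
                                     stringsAsFactors = FALSE))
    cur <- cur[, setdiff(colnames(cur), worst), drop = FALSE]
  }
  structure(list(M = M, ranking = names(sort(M)), trace = trace),
            class = "genorm_rank")
}

#' @export
print.genorm_rank <- function(x, ...) {
  cat("geNorm stability ranking (lower M = more stable)\n")
  print(round(sort(x$M), 4))
  invisible(x)
}

#' Relative quantification by 2^-ddCt
#'
#' Normalizes each target Ct by the arithmetic mean of the subject's
#' reference Cts (equivalent to the log2 of the geometric mean of reference
#' abundances), references the result to the control-group mean, and
#' exponentiates: `dCt = Ct_target - mean(Ct_refs)`,
#' `ddCt = dCt - mean(dCt | control)`, `level = 2^-ddCt`. Levels are
#' fold-changes relative to the control-group geometric mean, which is
#' therefore exactly 1 for every assay with complete control data.
#'
#' Subjects missing any reference Ct are dropped with a warning; subjects
#' missing a target Ct get a missing level for that assay only.
#'
#' @param ct numeric subjects x assays Ct matrix.
#' @param refs reference assay names (at least 2, present in `ct`).
#' @param control_group label of the reference population.
#' @param groups per-subject group labels (same order as `rownames(ct)`).
#' @return A `relative_levels` object: list with `levels` (subjects x target
#'   assays fold-changes), `delta_ct`, `ddct`, `log2_levels` (= `-ddct`),
#'   `groups`, `control_group` and `refs`.
#' @examples
#' ct <- rbind(S1 = c(t = 30, r1 = 25, r2 = 27), S2 = c(t = 30, r1 = 25, r2 = 27),
#'             S3 = c(t = 28, r1 = 25, r2 = 27))
#' normalize_ddct(ct, refs = c("r1", "r2"), control_group = "ctl",
#'                groups = c("ctl", "ctl", "case"))$levels
#' @export
normalize_ddct <- function(ct, refs, control_group, groups) {
  .check_ct_matrix(ct)
  if (length(refs) < 2L) stop("at least two reference assays are required")
  miss_ref <- setdiff(refs, colnames(ct))
  if (length(miss_ref))
    stop("reference assay(s) not in 'ct': ", paste(miss_ref, collapse = ", "))
  if (length(groups) != nrow(ct))
    stop("'groups' must have one label per subject")
  groups <- as.character(groups)

  ref_mean <- rowMeans(ct[, refs, drop = FALSE])
  drop <- is.na(ref_mean)
  if (any(drop)) {
    warning("subject(s) dropped for missing reference Ct: ",
            paste(rownames(ct)[drop], collapse = ", "))
    ct <- ct[!drop, , drop = FALSE]
    ref_mean <- ref_mean[!drop]
    groups <- groups[!drop]
  }
  ctrl <- groups == control_group
  if (!any(ctrl)) stop("control group '", control_group, "' is empty")

  targets <- setdiff(colnames(ct), refs)
  delta <- ct[, targets, drop = FALSE] - ref_mean
  ctrl_mean <- colMeans(delta[ctrl, , drop = FALSE], na.rm = TRUE)
  ddct <- sweep(delta, 2, ctrl_mean)
  levels <- 2^(-ddct)
  structure(list(levels = levels, delta_ct = delta, ddct = ddct,
                 log2_levels = -ddct, groups = groups,
                 control_group = control_group, refs = refs),
            class = "relative_levels")
}

#' @export
print.relative_levels <- function(x, ...) {
  cat("Relative serum miRNA levels (2^-ddCt vs group '",
      x$control_group, "')\n", sep = "")
  cat("  ", nrow(x$levels), " subjects x ", ncol(x$levels),
      " target assays; refs: ", paste(x$refs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-assay fold-change table between two subject strata
#'
#' For each assay, computes the fold-change as the ratio of mean normalized
#' levels (positive stratum over negative stratum) and a two-sided p-value
#' from the adaptive two-sample policy of [auto_two_sample_test()] applied to
#' the log2 levels (2^-ddCt levels are log-normal by construction, so testing
#' is done on the ddCt scale). Direction is `induced` / `repressed` when the
#' fold-change departs from 1 at `sig_level`, otherwise `ns`.
#'
#' @param rl a `relative_levels` object from [normalize_ddct()].
#' @param positive logical vector (one per subject in `rl`) defining the
#'   comparison, e.g. SAF activity >= 2.
#' @param assays assays to test (default all).
#' @param test `"auto"` (adaptive), `"t"` or `"wilcox"`, passed to
#'   [auto_two_sample_test()].
#' @param sig_level significance level for the direction call (default 0.05).
#' @return Data frame with one row per assay: group sizes, fold-change, log2
#'   fold-change (difference of mean log2 levels), p-value, test used and
#'   direction. Degenerate comparisons (fewer than 2 complete values on
#'   either side) are skipped with a warning and reported as `NA`.
#' @export
fold_change_table <- function(rl, positive, assays = colnames(rl$levels),
                              test = c("auto", "t", "wilcox"),
                              sig_level = 0.05) {
  test <- match.arg(test)
  if (!inherits(rl, "relative_levels"))
    stop("'rl' must come from normalize_ddct()")
  if (length(positive) != nrow(rl$levels))
    stop("'positive' must have one value per subject")
  miss <- setdiff(assays, colnames(rl$levels))
  if (length(miss)) stop("unknown assay(s): ", paste(miss, collapse = ", "))
  out <- lapply(assays, function(a) {
    lv <- rl$levels[, a]
    lg <- rl$log2_levels[, a]
    ok <- !is.na(lv) & !is.na(positive)
    xp <- lv[ok & positive]; xn <- lv[ok & !positive]
    if (length(xp) < 2L || length(xn) < 2L) {
      warning("comparison skipped for assay ", a, ": degenerate group")
      return(data.frame(assay = a, n_pos = length(xp), n_neg = length(xn),
                        fold_change = NA_real_, log2_fc = NA_real_,
                        p_value = NA_real_, test_used = NA_character_,
                        direction = NA_character_, stringsAsFactors = FALSE))
    }
    fc <- mean(xp) / mean(xn)
    tr <- auto_two_sample_test(lg[ok & positive], lg[ok & !positive],
                               test = test)
    dir <- if (tr$p_value < sig_level) {
      if (fc > 1) "induced" else "repressed"
    } else "ns"
    data.frame(assay = a, n_pos = length(xp), n_neg = length(xn),
               fold_change = fc,
               log2_fc = mean(lg[ok & positive]) - mean(lg[ok & !positive]),
               p_value = tr$p_value, test_used = tr$test_used,
               direction = dir, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
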