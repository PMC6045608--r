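# End-to-end composition: QC -> geNorm check -> normalization -> severity
# scoring -> univariate fold-changes -> ratio features -> single-marker ROC
# -> cross-validated PLS-DA panels.

# Resolve a marker name to a per-subject score vector: ratio feature,
# normalized miRNA level, or (scored) cohort column.
.resolve_marker <- function(name, scored, ratios, levels) {
  if (name %in% colnames(ratios)) return(ratios[scored$subject_id, name])
  if (name %in% colnames(levels)) return(levels[scored$subject_id, name])
  if (name %in% names(scored)) return(scored[[name]])
  stop("marker '", name, "' not found among ratio features, assays or cohort columns")
}

#' Run the full serum-miRNA severity pipeline
#'
#' Executes the whole analysis on a cohort table plus Ct matrix: detection
#' quality control (reference assays protected), geNorm stability ranking of
#' the retained assays, 2^-ddCt normalization against the control group,
#' histological severity scoring and serum algorithms, per-comparison
#' univariate fold-change tables, induced/repressed ratio features,
#' single-marker ROC/Youden reports, and leave-one-out cross-validated
#' PLS-DA over the clinical, miRNA and combined panels. Stage failures abort
#' with an error naming the stage.
#'
#' @param cohort cohort data frame (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param ct numeric subjects x assays Ct matrix.
#' @param config configuration list from [default_pipeline_config()].
#' @param out_dir optional directory; when given, the result bundle is also
#'   written as TSV/JSON files.
#' @param run_plsda set `FALSE` to skip the (slower) cross-validated
#'   multivariate stage.
#' @return A `pipeline_result` list: `qc`, `genorm`, `levels`, `scored`
#'   cohort, `fold_changes` (per comparison), `ratios`, `markers` (per
#'   comparison, named `marker_eval`s), `plsda` (per comparison, per panel
#'   `cv_performance`s) and a `log` with per-stage counts and the seed.
#' @export
run_pipeline <- function(cohort, ct, config = default_pipeline_config(),
                         out_dir = NULL, run_plsda = TRUE) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log <- list(seed = config$seed, n_subjects = nrow(cohort),
              n_assays = ncol(ct))

  qc <- stage("detection_qc",
              detection_qc(ct, max_ct = config$max_ct,
                           min_detection = config$min_detection,
                           refs = config$refs))
  log$excluded_assays <- qc$excluded

  gn <- stage("genorm", genorm_rank(qc$ct))

  groups <- cohort$group[match(rownames(qc$ct), cohort$subject_id)]
  rl <- stage("normalize",
              normalize_ddct(qc$ct, refs = config$refs,
                             control_group = config$control_group,
                             groups = groups))

  scored <- stage("scoring", score_cohort(cohort))

  ratios <- stage("ratio_features",
                  build_ratio_features(rl,
                                       numerators = config$ratio_numerators,
                                       denominators = config$ratio_denominators))

  sub_idx <- match(rownames(rl$levels), scored$subject_id)
  fold_changes <- list()
  markers <- list()
  for (cmp in names(config$comparisons)) {
    col <- config$comparisons[[cmp]]
    if (!col %in% names(scored))
      stop("pipeline stage 'comparisons' failed: no outcome column '", col, "'")
    outcome <- scored[[col]]
    fold_changes[[cmp]] <- stage(paste0("fold_change:", cmp),
                                 fold_change_table(rl, outcome[sub_idx]))
    markers[[cmp]] <- lapply(config$markers[[cmp]], function(m) {
      sc <- .resolve_marker(m, scored, ratios, rl$levels)
      stage(paste0("marker:", cmp, ":", m),
            evaluate_marker(sc[sub_idx], outcome[sub_idx],
                            level = config$ci_level))
    })
    names(markers[[cmp]]) <- config$markers[[cmp]]
  }

  plsda_res <- NULL
  if (run_plsda) {
    panels <- stage("panels",
                    build_variable_panels(scored, rl,
                                          clinical_vars = config$clinical_vars,
                                          ratio_pairs = config$panel_ratio_pairs))
    plsda_res <- list()
    for (cmp in names(config$comparisons)) {
      outcome <- scored[[config$comparisons[[cmp]]]]
      names(outcome) <- scored$subject_id
      plsda_res[[cmp]] <- lapply(names(panels), function(pn) {
        X <- panels[[pn]]
        y <- outcome[rownames(X)]
        ok <- !is.na(y)
        stage(paste0("plsda:", cmp, ":", pn),
              loocv_evaluate(X[ok, , drop = FALSE], y[ok],
                             max_lv = config$max_lv,
                             level = config$ci_level, panel = pn))
      })
      names(plsda_res[[cmp]]) <- names(panels)
    }
  }

  res <- structure(list(qc = qc, genorm = gn, levels = rl, scored = scored,
                        fold_changes = fold_changes, ratios = ratios,
                        markers = markers, plsda = plsda_res,
                        config = config, log = log),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' Write a pipeline result bundle to disk
#'
#' Emits the QC report (JSON), geNorm ranking (TSV), normalized levels
#' (TSV), per-comparison fold-change tables (TSV), single-marker diagnostic
#' reports (JSON), cross-validated PLS-DA performance (JSON) and a run log
#' (JSON).
#'
#' @param res a `pipeline_result`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(detection = as.list(res$qc$detection), excluded = res$qc$excluded,
         M = as.list(res$genorm$M)),
    file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(assay = names(res$genorm$M), M = unname(res$genorm$M)),
    file.path(out_dir, "genorm.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_relative_levels(res$levels, file.path(out_dir, "levels.tsv"))
  for (cmp in names(res$fold_changes)) {
    utils::write.table(res$fold_changes[[cmp]],
                       file.path(out_dir, paste0("fold_change_", cmp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  marker_json <- lapply(res$markers, function(cmps) {
    lapply(cmps, function(ev) list(
      auroc = ev$roc$auroc, auroc_ci = unname(ev$auroc_ci),
      cutoff = ev$cutoff, youden = ev$youden,
      estimates = ev$report$estimates,
      ci = lapply(ev$report$ci, unname)))
  })
  jsonlite::write_json(marker_json, file.path(out_dir, "markers.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(res$plsda)) {
    cv_json <- lapply(res$plsda, function(cmps) {
      lapply(cmps, function(cv) list(
        auroc = cv$auroc, auroc_ci = unname(cv$auroc_ci), n_lv = cv$n_lv,
        estimates = cv$report$estimates,
        ci = lapply(cv$report$ci, unname)))
    })
    jsonlite::write_json(cv_json, file.path(out_dir, "plsda_cv.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(res$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Serum-miRNA severity pipeline result\n")
  cat("  subjects: ", x$log$n_subjects, "; assays retained: ",
      ncol(x$qc$ct), " (excluded: ",
      if (length(x$qc$excluded)) paste(x$qc$excluded, collapse = ", ") else "none",
      ")\n", sep = "")
  cat("  geNorm most stable: ",
      paste(utils::head(x$genorm$ranking, 2), collapse = ", "), "\n", sep = "")
  for (cmp in names(x$fold_changes)) {
    fc <- x$fold_changes[[cmp]]
    sig <- fc$assay[!is.na(fc$direction) & fc$direction != "ns"]
    cat("  ", cmp, ": ", length(sig), " significantly altered assay(s)\n",
        sep = "")
  }
  if (!is.null(x$plsda)) {
    for (cmp in names(x$plsda)) {
      aucs <- vapply(x$plsda[[cmp]], `[[`, numeric(1), "auroc")
      cat("  CV AUROC [", cmp, "]: ",
          paste(sprintf("%s %.2f", names(aucs), aucs), collapse = ", "),
          "\n", sep = "")
    }
  }
  invisible(x)
}
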