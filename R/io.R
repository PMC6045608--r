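# Delimited-text readers/writers and YAML pipeline configuration.
# Convention: TSV, UTF-8, dot decimal, empty field = missing, Ct columns
# prefixed "ct_".

#' Write a cohort and its Ct matrix to TSV
#'
#' One row per subject: clinical/histology columns followed by the Ct
#' columns prefixed `ct_`. Missing values are written as empty fields.
#'
#' @param sim a `sim_cohort` object, or a list with `cohort` and `ct`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(sim, path) {
  ct <- sim$ct
  colnames(ct) <- paste0("ct_", colnames(ct))
  tab <- cbind(sim$cohort, as.data.frame(ct, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table with Ct columns
#'
#' Parses a TSV written by [write_cohort()] (or hand-assembled with the same
#' conventions): mandatory `subject_id` and `group` columns, Ct columns
#' prefixed `ct_`, empty fields as missing. Malformed numeric cells raise an
#' error naming the row and column.
#'
#' @param path input file path.
#' @return List with `cohort` (data frame without the Ct columns) and `ct`
#'   (numeric matrix, subject ids as rownames).
#' @export
read_cohort <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, na.strings = "",
                           stringsAsFactors = FALSE)
  mandatory <- c("subject_id", "group")
  miss <- setdiff(mandatory, names(tab))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  ct_cols <- grep("^ct_", names(tab), value = TRUE)
  ct <- matrix(NA_real_, nrow(tab), length(ct_cols),
               dimnames = list(tab$subject_id, sub("^ct_", "", ct_cols)))
  for (cc in ct_cols) {
    raw <- tab[[cc]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric Ct value in row %d, column %s: '%s'",
                   bad[1], cc, raw[bad[1]]))
    ct[, sub("^ct_", "", cc)] <- num
  }
  cohort <- tab[, setdiff(names(tab), ct_cols), drop = FALSE]
  if ("group" %in% names(cohort))
    cohort$group <- factor(cohort$group, levels = unique(cohort$group))
  list(cohort = cohort, ct = ct)
}

#' Write normalized relative levels to TSV
#'
#' @param rl a `relative_levels` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_relative_levels <- function(rl, path) {
  tab <- data.frame(subject_id = rownames(rl$levels), group = rl$groups,
                    rl$levels, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Default pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: reference assays and
#' control group, detection thresholds, the severity comparisons (SAF
#' activity >= 2, NAS >= 5, fibrosis > 2), the single markers evaluated per
#' comparison, the ratio feature pairs, the multivariate panel composition,
#' confidence level and the maximum latent variables for cross-validation.
#'
#' @param seed integer seed recorded in the configuration.
#' @return A named list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    refs = c("miR-15a", "miR-25"),
    control_group = "NL",
    max_ct = 38,
    min_detection = 0.9,
    comparisons = list(saf_activity = "saf_at_risk",
                       nas = "definite_nash",
                       fibrosis = "advanced_fibrosis"),
    markers = list(
      saf_activity = c("miR-34a/197", "miR-192/197", "ast"),
      nas = c("miR-192/30c", "miR-27b/30c", "ast"),
      fibrosis = c("miR-27b/197", "miR-27b/30c", "fib4")),
    ratio_numerators = .default_numerators,
    ratio_denominators = .default_denominators,
    clinical_vars = .default_clinical_vars,
    panel_ratio_pairs = .default_panel_ratio_pairs(),
    max_lv = 10L,
    ci_level = 0.95,
    seed = as.integer(seed)
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips the [default_pipeline_config()] list through a YAML file;
#' fields absent from the file keep their defaults.
#'
#' @param path YAML file path.
#' @return For `read_pipeline_config`, the merged configuration list; for
#'   `write_pipeline_config`, `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  for (nm in names(user)) {
    if (identical(nm, "panel_ratio_pairs")) {
      cfg[[nm]] <- as.data.frame(user[[nm]], stringsAsFactors = FALSE)
    } else cfg[[nm]] <- user[[nm]]
  }
  cfg$ci_level <- as.numeric(cfg$ci_level)
  if (cfg$ci_level <= 0 || cfg$ci_level >= 1)
    stop("'ci_level' must lie in (0, 1)")
  cfg
}

#' @rdname read_pipeline_config
#' @param config a configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- config
  cfg$panel_ratio_pairs <- as.list(cfg$panel_ratio_pairs)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
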