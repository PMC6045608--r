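# Cohort specification: group-level clinical/histology distributions and the
# per-assay generative model for serum miRNA Ct values.

# Per-group clinical (mean, sd) on the variable's clinical units.
# Insulin is not measured in normal-liver controls of the reference cohort;
# a normal fasting value (8 +/- 4 uU/mL) is used so HOMA-IR stays computable.
# The DILI group reuses control lipid/ferritin parameters for variables its
# work-up does not include.
.clinical_params <- list(
  NL = list(
    age = c(42.9, 9.3), bmi = c(26.2, 3.6), glucose = c(89.9, 10.7),
    triglycerides = c(106.7, 36.3), cholesterol = c(203.7, 37.4),
    hdl = c(55.0, 18.2), ldl = c(128.1, 34.7), bilirubin = c(0.6, 0.2),
    albumin = c(4.5, 0.5), platelets = c(245.2, 75.1), alt = c(29.8, 16.7),
    ast = c(26.0, 8.8), ggt = c(50.8, 51.4), alp = c(86.1, 32.7),
    ferritin = c(66.8, 54.7), hb = c(13.9, 0.9), insulin = c(8.0, 4.0)),
  NAFL = list(
    age = c(51.6, 10.4), bmi = c(29.6, 5.2), glucose = c(118.1, 39.7),
    triglycerides = c(126.3, 66.3), cholesterol = c(202.6, 43.6),
    hdl = c(52.5, 11.2), ldl = c(123.7, 41.5), bilirubin = c(0.7, 0.3),
    albumin = c(4.6, 0.3), platelets = c(260.1, 74.2), alt = c(51.8, 32.1),
    ast = c(36.0, 15.1), ggt = c(134.0, 144.8), alp = c(106.4, 48.2),
    ferritin = c(113.1, 58.7), hb = c(14.7, 1.2), insulin = c(17.4, 11.1)),
  NASH = list(
    age = c(57.4, 10.4), bmi = c(32.4, 4.6), glucose = c(126.7, 62.3),
    triglycerides = c(190.8, 104.4), cholesterol = c(199.0, 39.2),
    hdl = c(45.6, 13.4), ldl = c(122.9, 33.7), bilirubin = c(0.6, 0.3),
    albumin = c(4.6, 0.3), platelets = c(218.4, 66.5), alt = c(64.7, 52.6),
    ast = c(54.6, 35.4), ggt = c(122.8, 128.1), alp = c(95.4, 35.5),
    ferritin = c(283.8, 325.7), hb = c(14.4, 1.1), insulin = c(32.5, 37.3)),
  DILI = list(
    age = c(53.3, 19.3), bmi = c(24.6, 2.7), glucose = c(91.6, 14.2),
    triglycerides = c(211.9, 138.2), cholesterol = c(188.9, 76.9),
    hdl = c(55.0, 18.2), ldl = c(128.1, 34.7), bilirubin = c(11.2, 15.4),
    albumin = c(3.8, 0.5), platelets = c(341.0, 125.0), alt = c(94.6, 48.7),
    ast = c(72.7, 39.8), ggt = c(347.8, 275.2), alp = c(320.6, 184.9),
    ferritin = c(66.8, 54.7), hb = c(13.1, 1.9), insulin = c(8.0, 4.0))
)

.sex_female <- c(NL = 0.588, NAFL = 0.56, NASH = 0.62, DILI = 0.353)

# Categorical histology distributions (relative frequencies per group):
# steatosis grade 0-3, ballooning 0-2, lobular inflammation 0-2, fibrosis 0-4.
.histology_probs <- list(
  NL = list(steatosis = c(1, 0, 0, 0), ballooning = c(1, 0, 0),
            inflammation = c(1, 0, 0), fibrosis = c(1, 0, 0, 0, 0)),
  NAFL = list(steatosis = c(0, 0.80, 0.12, 0.08), ballooning = c(0.72, 0.28, 0),
              inflammation = c(0.52, 0.48, 0), fibrosis = c(0.84, 0.16, 0, 0, 0)),
  NASH = list(steatosis = c(0, 0.08, 0.46, 0.46), ballooning = c(0, 0.40, 0.60),
              inflammation = c(0.02, 0.70, 0.28),
              fibrosis = c(0.08, 0.18, 0.16, 0.32, 0.26))
)

# 18 previously postulated target miRNAs plus the two reference miRNAs.
# base_ct is the normal-liver mean threshold cycle; most assays sit in the
# 28-37 cycle serum band, miR-16/miR-451a are the most abundant, miR-34a among
# the least, and miR-99a/miR-1290 lie beyond the detection threshold so they
# drop out in quality control.
.mirna_assays <- c("miR-16", "miR-451a", "miR-122", "miR-21", "miR-192",
                   "miR-27b", "miR-22", "miR-146b", "miR-29a", "miR-30c",
                   "miR-331", "miR-197", "miR-181d", "miR-375", "miR-34a",
                   "miR-663a", "miR-99a", "miR-1290", "miR-15a", "miR-25")
.mirna_base_ct <- c(24, 25, 29, 29.5, 30, 31, 31.5, 32, 32.5, 33,
                    34, 34.5, 35, 35.5, 36, 36.5, 38.5, 39.5, 27, 28.5)
.reference_assays <- c("miR-15a", "miR-25")

.nafld_induced <- c("miR-34a", "miR-27b", "miR-22", "miR-122", "miR-192", "miR-21")
.nafld_repressed <- c("miR-30c", "miR-16", "miR-197")
.dili_induced <- c("miR-34a", "miR-122", "miR-21", "miR-451a", "miR-663a",
                   "miR-146b", "miR-331", "miR-197")
.dili_repressed <- c("miR-16")

.make_group_spec <- function(name, n, dili = FALSE) {
  hist <- if (dili) NULL else .histology_probs[[name]]
  list(name = name, n = n,
       clinical_params = .clinical_params[[name]],
       sex_female = unname(.sex_female[[name]]),
       histology_probs = hist,
       dili_flag = dili)
}

#' Default NAFLD cohort specification
#'
#' Builds the generative specification for a synthetic three-group NAFLD
#' cohort: 17 normal-liver controls (NL), 25 NAFL and 50 NASH subjects, with
#' group-wise clinical means/SDs and histology grade frequencies matching the
#' published cohort characteristics, and a panel of 18 target plus 2 reference
#' miRNA assays whose Ct values shift with disease group.
#'
#' Positive `log2_effect` means the miRNA is induced (lower Ct) in that group
#' relative to controls. Defaults: the six validated induced miRNAs
#' (miR-34a, -27b, -22, -122, -192, -21) get `+nash_log2_effect` in NASH and
#' `+nafl_log2_effect` in NAFL; the three repressed miRNAs
#' (miR-30c, -16, -197) get the negated values. Reference assays
#' (miR-15a, miR-25) carry no group effect and lower residual noise.
#'
#' @param nash_log2_effect absolute log2 abundance shift in NASH (default 1).
#' @param nafl_log2_effect absolute log2 abundance shift in NAFL (default 0.3).
#' @param target_noise_sd residual Ct standard deviation of target assays,
#'   in cycles (default 1).
#' @param reference_noise_sd residual Ct standard deviation of reference
#'   assays (default 0.3; reference miRNAs are abundant and low-variability).
#' @param dropout_ct censoring threshold in cycles: draws at or above it are
#'   reported as missing (default 38).
#' @param seed optional integer stored in the spec and used by
#'   [generate_cohort()] when no explicit seed is given.
#' @return A `cohort_spec` object: list with `groups` (per-group clinical and
#'   histology parameters), `mirnas` (per-assay generative parameters),
#'   `effects` (assay x group matrix of log2 shifts) and `seed`.
#' @seealso [generate_cohort()], [default_dili_spec()]
#' @examples
#' spec <- default_cohort_spec()
#' vapply(spec$groups, `[[`, numeric(1), "n")
#' @export
default_cohort_spec <- function(nash_log2_effect = 1, nafl_log2_effect = 0.3,
                                target_noise_sd = 1, reference_noise_sd = 0.3,
                                dropout_ct = 38, seed = NULL) {
  groups <- list(.make_group_spec("NL", 17L),
                 .make_group_spec("NAFL", 25L),
                 .make_group_spec("NASH", 50L))
  mirnas <- data.frame(
    assay = .mirna_assays,
    base_ct = .mirna_base_ct,
    ct_noise_sd = ifelse(.mirna_assays %in% .reference_assays,
                         reference_noise_sd, target_noise_sd),
    is_reference = .mirna_assays %in% .reference_assays,
    dropout_ct = dropout_ct,
    stringsAsFactors = FALSE
  )
  effects <- matrix(0, nrow = length(.mirna_assays), ncol = 3,
                    dimnames = list(.mirna_assays, c("NL", "NAFL", "NASH")))
  effects[.nafld_induced, "NASH"] <- nash_log2_effect
  effects[.nafld_induced, "NAFL"] <- nafl_log2_effect
  effects[.nafld_repressed, "NASH"] <- -nash_log2_effect
  effects[.nafld_repressed, "NAFL"] <- -nafl_log2_effect
  spec <- structure(list(groups = groups, mirnas = mirnas, effects = effects,
                         seed = seed),
                    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Default DILI comparator specification
#'
#' Two-group specification contrasting the 17 normal-liver controls with 17
#' drug-induced liver injury (DILI) patients. DILI direction defaults:
#' induced miR-34a, -122, -21, -451a, -663a, -146b, -331 and -197; decreased
#' miR-16; no change for miR-27b, -192, -22 and -30c (the NAFLD-specific
#' markers). DILI subjects carry no liver histology (no biopsy), so histology
#' fields are generated as missing.
#'
#' @inheritParams default_cohort_spec
#' @param dili_log2_effect absolute log2 shift of DILI-responsive assays.
#' @return A `cohort_spec` object with groups NL and DILI.
#' @seealso [generate_dili_cohort()]
#' @export
default_dili_spec <- function(dili_log2_effect = 1, target_noise_sd = 1,
                              reference_noise_sd = 0.3, dropout_ct = 38,
                              seed = NULL) {
  groups <- list(.make_group_spec("NL", 17L),
                 .make_group_spec("DILI", 17L, dili = TRUE))
  mirnas <- data.frame(
    assay = .mirna_assays,
    base_ct = .mirna_base_ct,
    ct_noise_sd = ifelse(.mirna_assays %in% .reference_assays,
                         reference_noise_sd, target_noise_sd),
    is_reference = .mirna_assays %in% .reference_assays,
    dropout_ct = dropout_ct,
    stringsAsFactors = FALSE
  )
  effects <- matrix(0, nrow = length(.mirna_assays), ncol = 2,
                    dimnames = list(.mirna_assays, c("NL", "DILI")))
  effects[.dili_induced, "DILI"] <- dili_log2_effect
  effects[.dili_repressed, "DILI"] <- -dili_log2_effect
  spec <- structure(list(groups = groups, mirnas = mirnas, effects = effects,
                         seed = seed),
                    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks the structural invariants of a `cohort_spec`: non-negative group
#' sizes and standard deviations, categorical histology distributions summing
#' to one, all-zero histology for the NL group, base Ct within 15-40 cycles,
#' zero group effects for reference assays, and at least two reference assays.
#'
#' @param spec a `cohort_spec` object.
#' @return `spec`, invisibly; signals an error naming the offending field
#'   otherwise.
#' @export
validate_cohort_spec <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("not a 'cohort_spec' object")
  if (length(spec$groups) < 1L) stop("invalid spec: 'groups' must be non-empty")
  for (g in spec$groups) {
    if (is.null(g$name) || !nzchar(g$name)) stop("invalid spec: group 'name' missing")
    if (g$n < 0) stop(sprintf("invalid spec: 'n' < 0 in group %s", g$name))
    for (v in names(g$clinical_params)) {
      p <- g$clinical_params[[v]]
      if (length(p) != 2L || anyNA(p))
        stop(sprintf("invalid spec: 'clinical_params$%s' in group %s must be (mean, sd)",
                     v, g$name))
      if (p[2] < 0)
        stop(sprintf("invalid spec: negative sd for 'clinical_params$%s' in group %s",
                     v, g$name))
    }
    if (!is.null(g$histology_probs)) {
      for (f in names(g$histology_probs)) {
        pr <- g$histology_probs[[f]]
        if (any(pr < 0) || abs(sum(pr) - 1) > 1e-9)
          stop(sprintf("invalid spec: 'histology_probs$%s' in group %s must be a distribution",
                       f, g$name))
        if (identical(g$name, "NL") && pr[1] != 1)
          stop(sprintf("invalid spec: 'histology_probs$%s' must put mass 1 on 0 for NL", f))
      }
    }
  }
  m <- spec$mirnas
  if (any(m$base_ct < 15 | m$base_ct > 40))
    stop("invalid spec: 'base_ct' outside [15, 40]")
  if (any(m$ct_noise_sd < 0)) stop("invalid spec: negative 'ct_noise_sd'")
  if (sum(m$is_reference) < 2L)
    stop("invalid spec: at least two reference assays ('is_reference') required")
  if (any(abs(spec$effects[m$is_reference, ]) > 0))
    stop("invalid spec: 'log2_effect' must be 0 for reference assays")
  if (!setequal(rownames(spec$effects), m$assay))
    stop("invalid spec: 'effects' rows must match 'mirnas$assay'")
  group_names <- vapply(spec$groups, `[[`, character(1), "name")
  if (!all(group_names %in% colnames(spec$effects)))
    stop("invalid spec: 'effects' columns must cover all group names")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  sizes <- vapply(x$groups, `[[`, numeric(1), "n")
  names(sizes) <- vapply(x$groups, `[[`, character(1), "name")
  cat("Synthetic serum-miRNA cohort specification\n")
  cat("  groups: ", paste(sprintf("%s (n = %d)", names(sizes), sizes),
                          collapse = ", "), "\n", sep = "")
  cat("  assays: ", nrow(x$mirnas), " (",
      sum(x$mirnas$is_reference), " reference)\n", sep = "")
  cat("  dropout threshold: Ct >= ", x$mirnas$dropout_ct[1], "\n", sep = "")
  invisible(x)
}
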