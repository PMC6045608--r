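# Histological severity scores and serum-based clinical fibrosis algorithms.
#
# The named serum algorithms (FIB-4, APRI, BARD, NAFLD fibrosis score,
# HOMA-IR) follow their standard published formulas; category boundaries
# follow the printed inequality conventions (scores exactly at a "<"/">"
# cut-off fall in the lower bin, ">=" bins are inclusive).

#' Grade steatosis from the percentage of steatotic hepatocytes
#'
#' Grade 0: < 5%; grade 1: 5-33%; grade 2: > 33-66%; grade 3: > 66%.
#'
#' @param pct percentage of steatotic hepatocytes, 0-100. Vectorized.
#' @return Integer grade 0-3.
#' @examples
#' grade_steatosis(c(4, 33, 33.5, 100))
#' @export
grade_steatosis <- function(pct) {
  if (any(!is.na(pct) & (pct < 0 | pct > 100)))
    stop("'pct' must be within [0, 100]")
  g <- ifelse(pct < 5, 0L, ifelse(pct <= 33, 1L, ifelse(pct <= 66, 2L, 3L)))
  as.integer(g)
}

#' Severity labels from histology grades
#'
#' Computes the NAFLD activity score (NAS = steatosis + lobular inflammation
#' + ballooning, 0-8) with category bins NAS 0-2 / 3-4 / 5-8, the SAF
#' activity score (ballooning + lobular inflammation, 0-4) with the at-risk
#' flag A >= 2, and advanced fibrosis (stage F3 or F4).
#'
#' Lobular inflammation is stored on the 0-2 scale; a grade of 3 is accepted
#' with a warning (some NAS conventions allow it).
#'
#' @param steatosis steatosis grade 0-3.
#' @param ballooning hepatocellular ballooning grade 0-2.
#' @param inflammation lobular inflammation grade 0-2 (3 tolerated with a
#'   warning).
#' @param fibrosis fibrosis stage 0-4.
#' @return Data frame with columns `nas`, `nas_class`, `saf_activity`,
#'   `saf_at_risk`, `advanced_fibrosis`. Missing grades yield missing labels.
#' @examples
#' compute_severity(2, 1, 2, 1)
#' @export
compute_severity <- function(steatosis, ballooning, inflammation, fibrosis) {
  chk <- function(x, lo, hi, what) {
    bad <- !is.na(x) & (x < lo | x > hi | x != floor(x))
    if (any(bad)) stop(sprintf("'%s' must be integer in %d..%d", what, lo, hi))
  }
  chk(steatosis, 0L, 3L, "steatosis")
  chk(ballooning, 0L, 2L, "ballooning")
  if (any(!is.na(inflammation) & inflammation == 3))
    warning("lobular inflammation grade 3 supplied; NAS computed, but the 0-2 scale is used throughout")
  chk(inflammation, 0L, 3L, "inflammation")
  chk(fibrosis, 0L, 4L, "fibrosis")
  nas <- steatosis + inflammation + ballooning
  saf <- ballooning + inflammation
  data.frame(
    nas = as.integer(nas),
    nas_class = cut(nas, breaks = c(-0.5, 2.5, 4.5, 8.5),
                    labels = c("NAS_0-2", "NAS_3-4", "NAS_5-8")),
    saf_activity = as.integer(saf),
    saf_at_risk = saf >= 2,
    advanced_fibrosis = fibrosis > 2
  )
}

#' FIB-4 index
#'
#' `FIB-4 = (age * AST) / (platelets * sqrt(ALT))` with platelets in
#' 10^3/uL. Categories split at 1.30; a score exactly at the cut-off goes to
#' the lower bin (printed-inequality convention).
#'
#' @param age years.
#' @param ast,alt aspartate/alanine aminotransferase, IU/L; `alt` must be
#'   positive.
#' @param platelets platelet count, 10^3/uL; must be positive.
#' @return Data frame with `fib4` and `fib4_class` (`"<1.30"` / `">1.30"`).
#' @examples
#' fib4(60, 80, 64, 200)
#' @export
fib4 <- function(age, ast, alt, platelets) {
  if (any(!is.na(alt) & alt <= 0)) stop("'alt' must be positive for FIB-4")
  if (any(!is.na(platelets) & platelets <= 0))
    stop("'platelets' must be positive for FIB-4")
  score <- (age * ast) / (platelets * sqrt(alt))
  data.frame(fib4 = score,
             fib4_class = ifelse(score > 1.30, ">1.30", "<1.30"))
}

#' AST-to-platelet ratio index (APRI)
#'
#' `APRI = 100 * (AST / AST_ULN) / platelets` with platelets in 10^3/uL.
#' Categories split at 1 (scores exactly at the cut-off go to the lower bin).
#'
#' @param ast aspartate aminotransferase, IU/L.
#' @param platelets platelet count, 10^3/uL; must be positive.
#' @param ast_uln upper limit of normal for AST (default 40 IU/L;
#'   configurable).
#' @return Data frame with `apri` and `apri_class` (`"<1"` / `">1"`).
#' @export
apri <- function(ast, platelets, ast_uln = 40) {
  if (any(!is.na(platelets) & platelets <= 0))
    stop("'platelets' must be positive for APRI")
  score <- 100 * (ast / ast_uln) / platelets
  data.frame(apri = score, apri_class = ifelse(score > 1, ">1", "<1"))
}

#' BARD score
#'
#' `BARD = 1*[BMI >= 28] + 2*[AST/ALT >= 0.8] + 1*[diabetes]` (0-4), with the
#' at-risk category at score >= 2.
#'
#' @param bmi body mass index, kg/m^2.
#' @param ast,alt transaminases, IU/L; `alt` must be positive.
#' @param diabetes logical: diabetes (or impaired fasting glucose) present.
#' @return Data frame with `bard` (integer) and `bard_class`
#'   (`"<2"` / `">=2"`).
#' @export
bard <- function(bmi, ast, alt, diabetes) {
  if (any(!is.na(alt) & alt <= 0)) stop("'alt' must be positive for BARD")
  score <- (bmi >= 28) + 2 * (ast / alt >= 0.8) + as.integer(diabetes)
  data.frame(bard = as.integer(score),
             bard_class = ifelse(score >= 2, ">=2", "<2"))
}

#' NAFLD fibrosis score (NFS)
#'
#' `NFS = -1.675 + 0.037*age + 0.094*BMI + 1.13*[IFG or diabetes] +
#' 0.99*(AST/ALT) - 0.013*platelets - 0.66*albumin`, binned at -1.455,
#' -0.675 and 0.676 (scores exactly at a boundary fall in the lower bin).
#'
#' @param age years.
#' @param bmi kg/m^2.
#' @param diabetes logical: impaired fasting glucose or diabetes.
#' @param ast,alt transaminases, IU/L; `alt` must be positive.
#' @param platelets platelet count, 10^3/uL; must be positive.
#' @param albumin g/dL.
#' @return Data frame with `nfs` and the four-bin `nfs_class`.
#' @export
nfs <- function(age, bmi, diabetes, ast, alt, platelets, albumin) {
  args <- list(age = age, bmi = bmi, diabetes = diabetes, ast = ast,
               alt = alt, platelets = platelets, albumin = albumin)
  for (nm in names(args)) if (is.null(args[[nm]]))
    stop(sprintf("'%s' is required for NFS", nm))
  if (any(!is.na(alt) & alt <= 0)) stop("'alt' must be positive for NFS")
  if (any(!is.na(platelets) & platelets <= 0))
    stop("'platelets' must be positive for NFS")
  score <- -1.675 + 0.037 * age + 0.094 * bmi + 1.13 * as.integer(diabetes) +
    0.99 * (ast / alt) - 0.013 * platelets - 0.66 * albumin
  cls <- cut(score, breaks = c(-Inf, -1.455, -0.675, 0.676, Inf),
             labels = c("<-1.455", "-1.455..-0.675", "-0.675..0.676", ">0.676"))
  data.frame(nfs = score, nfs_class = cls)
}

#' HOMA-IR insulin-resistance index
#'
#' `HOMA-IR = glucose [mg/dL] * insulin [uU/mL] / 405`.
#'
#' @param glucose fasting glucose, mg/dL (non-negative).
#' @param insulin fasting insulin, uU/mL (non-negative).
#' @return Numeric index.
#' @export
homa_ir <- function(glucose, insulin) {
  if (any(!is.na(glucose) & glucose < 0) || any(!is.na(insulin) & insulin < 0))
    stop("'glucose' and 'insulin' must be non-negative")
  glucose * insulin / 405
}

#' Score a cohort table
#'
#' Adds histological severity labels ([compute_severity()]) and the serum
#' algorithms FIB-4, APRI, BARD, NFS and HOMA-IR to a cohort data frame, plus
#' the outcome flags used downstream: `saf_at_risk` (SAF activity >= 2),
#' `definite_nash` (NAS >= 5) and `advanced_fibrosis` (F > 2). Rows without
#' histology (e.g. DILI patients) get missing severity labels but keep their
#' serum scores.
#'
#' @param cohort data frame with the clinical and histology columns produced
#'   by [generate_cohort()] / [read_cohort()].
#' @param ast_uln AST upper limit of normal passed to [apri()].
#' @return The cohort with score and label columns appended.
#' @export
score_cohort <- function(cohort, ast_uln = 40) {
  need <- c("age", "bmi", "ast", "alt", "platelets", "albumin", "glucose",
            "insulin", "diabetes", "steatosis", "ballooning", "inflammation",
            "fibrosis")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing required columns: ", paste(miss, collapse = ", "))
  sev <- compute_severity(cohort$steatosis, cohort$ballooning,
                          cohort$inflammation, cohort$fibrosis)
  out <- cbind(cohort, sev,
               fib4(cohort$age, cohort$ast, cohort$alt, cohort$platelets),
               apri(cohort$ast, cohort$platelets, ast_uln = ast_uln),
               bard(cohort$bmi, cohort$ast, cohort$alt, cohort$diabetes),
               nfs(cohort$age, cohort$bmi, cohort$diabetes, cohort$ast,
                   cohort$alt, cohort$platelets, cohort$albumin))
  out$homa <- homa_ir(cohort$glucose, cohort$insulin)
  out$definite_nash <- out$nas >= 5
  out
}
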