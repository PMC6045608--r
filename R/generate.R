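# Synthetic cohort generation: clinical variables, histology grades under
# group-label constraints, and censored qPCR Ct values.

# Truncated-normal draw: redraw until strictly positive (all clinical
# quantities here live on positive scales).
.rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  for (iter in seq_len(1000L)) {
    bad <- x <= 0
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  stop("could not draw positive values for mean ", mean, ", sd ", sd)
}

# Histology grades drawn independently per feature from the group's marginal
# distributions, resampled until the group's defining constraints hold:
# NASH requires steatosis >= 1, ballooning >= 1 and inflammation >= 1 (so SAF
# activity >= 2); NAFL requires activity < 2 and NAS <= 4.
.draw_histology <- function(group, probs) {
  draw1 <- function(p) sample.int(length(p), 1L, prob = p) - 1L
  for (iter in seq_len(10000L)) {
    st <- draw1(probs$steatosis)
    ba <- draw1(probs$ballooning)
    lo <- draw1(probs$inflammation)
    fb <- draw1(probs$fibrosis)
    ok <- switch(group,
      NASH = st >= 1L && ba >= 1L && lo >= 1L,
      NAFL = st >= 1L && (ba + lo) < 2L && (st + ba + lo) <= 4L,
      TRUE)
    if (ok) return(c(steatosis = st, ballooning = ba,
                     inflammation = lo, fibrosis = fb))
  }
  stop("histology constraints for group ", group,
       " incompatible with its marginal distributions")
}

#' Generate a synthetic cohort
#'
#' Draws a per-subject clinical/histology table and a subjects x assays Ct
#' matrix from a [default_cohort_spec()]-style specification. Clinical
#' variables are sampled independently from truncated normals (redraw at the
#' physiologic floor 0); sex is Bernoulli from the group's female fraction;
#' histology grades come from the group's marginal distributions with
#' resampling until group-defining constraints hold (NASH implies ballooning
#' and inflammation of at least grade 1, NAFL implies SAF activity < 2 and
#' NAS < 5). Ct values follow
#' `Ct = base_ct - log2_effect(group) + Normal(0, ct_noise_sd)` and are
#' censored to missing at `Ct >= dropout_ct`. Diabetes/impaired fasting
#' glucose is derived deterministically as fasting glucose >= 100 mg/dL.
#'
#' The same `(spec, seed)` pair always reproduces the identical cohort.
#'
#' @param spec a `cohort_spec`; validated before use.
#' @param seed integer RNG seed; defaults to `spec$seed`, or 1 when neither
#'   is set.
#' @return A `sim_cohort` object: list with `cohort` (data frame of subject
#'   id, group, sex, clinical variables, histology grades and the derived
#'   diabetes flag), `ct` (numeric matrix of threshold cycles, `NA` =
#'   undetected), and `refs` (reference assay names).
#' @examples
#' sim <- generate_cohort(default_cohort_spec(), seed = 1)
#' table(sim$cohort$group)
#' @export
generate_cohort <- function(spec, seed = NULL) {
  validate_cohort_spec(spec)
  if (is.null(seed)) seed <- if (!is.null(spec$seed)) spec$seed else 1L
  set.seed(seed)

  group_names <- vapply(spec$groups, `[[`, character(1), "name")
  rows <- list()
  ct_blocks <- list()
  n_assay <- nrow(spec$mirnas)
  for (gi in seq_along(spec$groups)) {
    g <- spec$groups[[gi]]
    if (g$n == 0L) next
    clin <- vapply(g$clinical_params,
                   function(p) .rnorm_pos(g$n, p[1], p[2]),
                   numeric(g$n))
    if (g$n == 1L) clin <- matrix(clin, nrow = 1L,
                                  dimnames = list(NULL, names(g$clinical_params)))
    sex <- ifelse(stats::runif(g$n) < g$sex_female, "F", "M")
    hist <- if (is.null(g$histology_probs)) {
      matrix(NA_integer_, g$n, 4L,
             dimnames = list(NULL, c("steatosis", "ballooning",
                                     "inflammation", "fibrosis")))
    } else {
      t(vapply(seq_len(g$n),
               function(i) .draw_histology(g$name, g$histology_probs),
               integer(4)))
    }
    rows[[gi]] <- data.frame(group = g$name, sex = sex,
                             as.data.frame(clin), as.data.frame(hist),
                             stringsAsFactors = FALSE)
    # Ct draws subject-by-row; assays vary fastest within a subject
    eff <- spec$effects[spec$mirnas$assay, g$name]
    noise <- matrix(stats::rnorm(g$n * n_assay, 0, spec$mirnas$ct_noise_sd),
                    nrow = g$n, byrow = TRUE)
    ct_g <- matrix(spec$mirnas$base_ct - eff, nrow = g$n, ncol = n_assay,
                   byrow = TRUE) + noise
    ct_g[ct_g >= matrix(spec$mirnas$dropout_ct, g$n, n_assay,
                        byrow = TRUE)] <- NA_real_
    ct_blocks[[gi]] <- ct_g
  }
  cohort <- do.call(rbind, rows)
  cohort <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(cohort))),
                  cohort, stringsAsFactors = FALSE)
  cohort$group <- factor(cohort$group, levels = group_names)
  cohort$diabetes <- cohort$glucose >= 100
  ct <- do.call(rbind, ct_blocks)
  dimnames(ct) <- list(cohort$subject_id, spec$mirnas$assay)
  structure(list(cohort = cohort, ct = ct,
                 refs = spec$mirnas$assay[spec$mirnas$is_reference],
                 seed = seed),
            class = "sim_cohort")
}

#' Generate a synthetic DILI comparator cohort
#'
#' Convenience wrapper around [generate_cohort()] using the drug-induced
#' liver injury specification from [default_dili_spec()]: 17 normal-liver
#' controls versus 17 DILI patients, with DILI-direction miRNA effects and no
#' liver histology in the DILI group.
#'
#' @param spec a `cohort_spec`; defaults to [default_dili_spec()].
#' @inheritParams generate_cohort
#' @return A `sim_cohort` object (see [generate_cohort()]).
#' @export
generate_dili_cohort <- function(spec = default_dili_spec(), seed = NULL) {
  generate_cohort(spec, seed = seed)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic serum-miRNA cohort\n")
  tab <- table(x$cohort$group)
  cat("  subjects: ", nrow(x$cohort), " (",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), ")\n", sep = "")
  cat("  assays: ", ncol(x$ct), "; missing Ct: ",
      sum(is.na(x$ct)), "\n", sep = "")
  cat("  reference assays: ", paste(x$refs, collapse = ", "), "\n", sep = "")
  invisible(x)
}
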