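# Shared fixtures: deterministic specs and small oracle helpers.

# Spec with no Ct noise and no group effects: every downstream fold-change
# must be exactly 1.
zero_noise_spec <- function(effects = NULL, dili = FALSE) {
  spec <- if (dili) default_dili_spec() else default_cohort_spec()
  spec$mirnas$ct_noise_sd <- 0
  spec$effects[] <- 0
  # keep every assay detectable so the zero-noise matrix is complete
  spec$mirnas$base_ct[spec$mirnas$base_ct >= spec$mirnas$dropout_ct] <- 35
  if (!is.null(effects)) {
    for (nm in names(effects)) {
      spec$effects[names(effects[[nm]]), nm] <- effects[[nm]]
    }
  }
  validate_cohort_spec(spec)
  spec
}

# Brute-force geNorm oracle: double loop over assay pairs.
genorm_oracle <- function(ct) {
  k <- ncol(ct)
  M <- numeric(k)
  for (i in seq_len(k)) {
    sds <- numeric(0)
    for (j in seq_len(k)) {
      if (j == i) next
      sds <- c(sds, sd(ct[, j] - ct[, i]))
    }
    M[i] <- mean(sds)
  }
  names(M) <- colnames(ct)
  M
}

# Exhaustive Youden oracle over every observed threshold.
youden_oracle <- function(scores, labels) {
  thr <- sort(unique(scores))
  best <- NULL
  for (cc in thr) {
    sens <- mean(scores[labels] >= cc)
    spec <- mean(scores[!labels] < cc)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
         (sens > best$sensitivity + 1e-12 ||
          (abs(sens - best$sensitivity) <= 1e-12 && cc < best$cutoff)))) {
      best <- list(cutoff = cc, j = j, sensitivity = sens)
    }
  }
  best
}

# Mann-Whitney U divided by n1*n0 with ties counted one half: the
# probabilistic definition of the AUROC.
auc_from_u <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
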