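# Shared fixtures: small cohorts and toy tables built in code.

small_cohort <- function(seed = 1, n_malignant = 30, n_benign = 15,
                         n_compounds = 80, effect_size = 1.0,
                         postop_fraction = 0, ...) {
  generate_cohort(synthetic_config(
    n_malignant = n_malignant, n_benign = n_benign,
    n_compounds = n_compounds, n_planted = 5, n_excluded = 2,
    effect_size = effect_size, postop_fraction = postop_fraction,
    seed = seed, ...))
}

# QC + normalization + preop subset, returning the pieces screening needs.
prepared_training <- function(cohort) {
  qc <- apply_qc(cohort$peaks, cohort$snr)
  sheet <- cohort$sheet[cohort$sheet$sample_id %in%
                          qc$report$retained_samples, , drop = FALSE]
  nm <- normalize_peaks(qc$peaks)
  pre <- sheet$timepoint == "preop"
  list(X = nm[sheet$sample_id[pre], , drop = FALSE],
       y = sheet$class[pre], sheet = sheet, norm = nm, qc = qc)
}

# 2x2 toy tables with fully valid SNR.
toy_tables <- function() {
  a <- matrix(c(10, 20, 30, 40), 2, 2,
              dimnames = list(c("s1", "s2"), c("c1", "c2")))
  list(peaks = peak_table(a), snr = snr_table(a * 10))
}

# Brute-force pairwise AUC oracle (independent of roc_auc's rank formula).
pairwise_auc <- function(scores, y01) {
  sp <- scores[y01 == 1]; sn <- scores[y01 == 0]
  total <- 0
  for (a in sp) for (b in sn) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(sp) * length(sn))
}
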