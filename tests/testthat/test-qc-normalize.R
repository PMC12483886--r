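test_that("SNR validity is strict and missing-aware", {
  m <- matrix(c(10, 10.01, NA, 0), 2, 2,
              dimnames = list(c("s1", "s2"), c("c1", "c2")))
  mask <- compute_validity(m)
  expect_identical(as.vector(mask), c(FALSE, TRUE, FALSE, FALSE))
  zero <- matrix(0, 3, 2, dimnames = list(paste0("s", 1:3), c("a", "b")))
  expect_false(any(compute_validity(zero)))
})

test_that("response-rate filtering follows the sample-then-compound order", {
  # 5 samples x 10 compounds, all valid except the marked entries
  snr <- matrix(100, 5, 10, dimnames = list(paste0("s", 1:5),
                                            paste0("c", 1:10)))
  snr["s5", c(paste0("c", 1:4), "c8")] <- 5  # s5 rate 0.5 < 0.8: dropped
  snr[c("s1", "s2"), c("c9", "c10")] <- 5  # s1/s2 rate exactly 0.8: kept
  snr["s3", c("c8", "c9")] <- 5
  snr["s4", "c8"] <- 5
  peaks <- peak_table(matrix(1, 5, 10, dimnames = dimnames(snr)))
  res <- apply_qc(peaks, snr_table(snr))
  expect_identical(res$report$retained_samples, paste0("s", 1:4))
  expect_equal(unname(res$report$sample_response_rate["s5"]), 0.5)
  # c9 valid in 1/4 retained samples: dropped; c10 at exactly 0.5: kept
  expect_identical(res$report$retained_compounds,
                   c(paste0("c", 1:8), "c10"))
  # c8 is valid in 2/5 samples overall (rate 0.4) but 2/4 retained samples
  # (rate 0.5): kept only because compounds are rated after sample filtering
  expect_lt(mean(snr[, "c8"] > 10), 0.5)
  expect_true("c8" %in% res$report$retained_compounds)
  # invalid-but-retained entries are NA in the output
  expect_true(is.na(unclass(res$peaks)["s1", "c10"]))
  expect_true(is.na(unclass(res$peaks)["s4", "c8"]))
})

test_that("retained sets match a brute-force recount on random masks", {
  set.seed(42)
  n <- 50; p <- 200
  snr <- matrix(ifelse(runif(n * p) < 0.75, 100, 1), n, p,
                dimnames = list(sprintf("s%02d", 1:n), sprintf("c%03d", 1:p)))
  peaks <- peak_table(matrix(1, n, p, dimnames = dimnames(snr)))
  res <- apply_qc(peaks, snr_table(snr))

  valid <- snr > 10
  keep_s <- rownames(snr)[sapply(seq_len(n), function(i)
    mean(valid[i, ]) >= 0.8)]
  keep_c <- colnames(snr)[sapply(seq_len(p), function(j)
    mean(valid[keep_s, j]) >= 0.5)]
  expect_identical(res$report$retained_samples, keep_s)
  expect_identical(res$report$retained_compounds, keep_c)

  # idempotence: filtering the filtered table changes nothing
  snr_kept <- snr_table(snr[keep_s, keep_c, drop = FALSE])
  res2 <- apply_qc(res$peaks, snr_kept)
  expect_identical(res2$report$retained_samples, keep_s)
  expect_identical(res2$report$retained_compounds, keep_c)
  expect_equal(unclass(res2$peaks), unclass(res$peaks), ignore_attr = TRUE)
})

test_that("degenerate QC input raises a clear error", {
  snr <- matrix(1, 3, 3, dimnames = list(paste0("s", 1:3), paste0("c", 1:3)))
  peaks <- peak_table(matrix(1, 3, 3, dimnames = dimnames(snr)))
  expect_error(apply_qc(peaks, snr_table(snr)), "no sample")
})

test_that("normalization matches a hand-computed worked example", {
  # areas chosen so log10 values are integers
  a <- matrix(c(100, 10, 1000,
                1000, 10000, 100000), 3, 2,
              dimnames = list(c("s1", "s2", "s3"), c("c1", "c2")))
  nm <- normalize_peaks(peak_table(a))
  # log10: c1 = (2,1,3), c2 = (3,4,5); sample medians 2.5, 2.5, 4
  # centered: c1 = (-0.5,-1.5,-1), c2 = (0.5,1.5,1)
  # c1: mean -1, sd 0.5 -> z = (1,-1,0); c2: mean 1, sd 0.5 -> z = (-1,1,0)
  expect_equal(unclass(nm)[, "c1"], c(s1 = 1, s2 = -1, s3 = 0),
               tolerance = 1e-12)
  expect_equal(unclass(nm)[, "c2"], c(s1 = -1, s2 = 1, s3 = 0),
               tolerance = 1e-12)
})

test_that("reference columns have mean 0 and sd 1; loading is removed", {
  co <- small_cohort(seed = 2, n_malignant = 12, n_benign = 8,
                     n_compounds = 20)
  qc <- apply_qc(co$peaks, co$snr)
  nm <- normalize_peaks(qc$peaks)
  expect_equal(unname(colMeans(nm)), rep(0, ncol(nm)), tolerance = 1e-9)
  expect_equal(unname(apply(nm, 2, sd)), rep(1, ncol(nm)), tolerance = 1e-9)

  # multiplying one sample's raw areas by 1000 changes nothing downstream
  a <- matrix(10^runif(60, 3, 6), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("c", 1:6)))
  scaled <- a
  scaled["s4", ] <- scaled["s4", ] * 1000
  n1 <- normalize_peaks(peak_table(a))
  n2 <- normalize_peaks(peak_table(scaled))
  expect_equal(unclass(n1), unclass(n2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("imputation, degenerate variance and bad input are handled", {
  a <- matrix(c(8, 2, NA, 5, 5, 5), 3, 2,
              dimnames = list(paste0("s", 1:3), c("c1", "c2")))
  nm <- normalize_peaks(peak_table(a), reference_samples = paste0("s", 1:3))
  expect_equal(attr(nm, "impute_values")[["c1"]], 1)  # half of min(8, 2)

  # both columns constant: centered log values have zero variance
  const <- matrix(c(1, 1, 1, 10, 10, 10), 3, 2,
                  dimnames = list(paste0("s", 1:3), c("c1", "c2")))
  expect_warning(normalize_peaks(peak_table(const)), "zero variance")

  bad <- matrix(c(0, 1, 1, 1), 2, 2,
                dimnames = list(c("s1", "s2"), c("c1", "c2")))
  expect_error(normalize_peaks(peak_table(bad)), "zero or negative")
  expect_error(normalize_peaks(peak_table(a), reference_samples = "nope"),
               "reference_samples")
})

test_that("row permutation permutes outputs identically", {
  co <- small_cohort(seed = 9, n_malignant = 10, n_benign = 6,
                     n_compounds = 15)
  perm <- sample(rownames(co$peaks))
  qc1 <- apply_qc(co$peaks, co$snr)
  qc2 <- apply_qc(peak_table(unclass(co$peaks)[perm, ]),
                  snr_table(unclass(co$snr)[perm, ]))
  expect_setequal(qc1$report$retained_samples, qc2$report$retained_samples)
  expect_identical(qc1$report$retained_compounds,
                   qc2$report$retained_compounds)
  common <- intersect(rownames(qc1$peaks), rownames(qc2$peaks))
  n1 <- normalize_peaks(qc1$peaks, reference_samples = common)
  n2 <- normalize_peaks(qc2$peaks, reference_samples = common)
  expect_equal(unclass(n1)[common, ], unclass(n2)[common, ],
               tolerance = 1e-12, ignore_attr = TRUE)
})
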