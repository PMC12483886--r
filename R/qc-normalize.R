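# Pre-analysis quality control and normalization of GC-MS peak tables.
#
# Protocol: (1) a measurement is valid iff its SNR strictly exceeds 10;
# (2) samples with a valid-response rate below 80% are dropped; (3) compound
# response rates are then recomputed over the retained samples and compounds
# below 50% are dropped; (4) the surviving "valid VOC area matrix" is
# half-minimum imputed, log10-transformed, per-sample median centered, and
# per-compound z-scaled against a designated reference (training) subset.

#' Validity mask from an SNR table
#'
#' An entry is valid iff its SNR strictly exceeds `snr_min`; missing SNR
#' values are invalid.
#'
#' @param snr An [snr_table()] (or plain numeric matrix).
#' @param snr_min Validity threshold; the default 10 means SNR = 10 exactly
#'   is invalid.
#' @return Logical matrix with the same dimnames.
#' @export
compute_validity <- function(snr, snr_min = 10) {
  mask <- !is.na(snr) & snr > snr_min
  dimnames(mask) <- dimnames(snr)
  mask
}

#' Apply sample- and compound-level response-rate QC
#'
#' Sample response rates are computed over all compounds; samples below
#' `sample_min` are dropped. Compound response rates are then computed over
#' the *retained* samples only; compounds below `compound_min` are dropped.
#' Both thresholds are inclusive (a rate exactly at the threshold is
#' retained). Invalid entries in the returned peak table are set to `NA`.
#'
#' @param peaks A [peak_table()].
#' @param snr The paired [snr_table()].
#' @param snr_min,sample_min,compound_min QC thresholds (defaults 10, 0.80,
#'   0.50).
#' @return List with `report` (class `qc_report`: validity mask, per-axis
#'   response rates, retained ids, thresholds) and `peaks` (the filtered
#'   [peak_table()] with invalid entries `NA`).
#' @export
apply_qc <- function(peaks, snr, snr_min = 10, sample_min = 0.80,
                     compound_min = 0.50) {
  check_paired_tables(peaks, snr)
  mask <- compute_validity(snr, snr_min)
  sample_rate <- rowMeans(mask)
  retained_samples <- rownames(peaks)[sample_rate >= sample_min]
  if (length(retained_samples) == 0) {
    stop("apply_qc: no sample reaches a response rate of ", sample_min,
         call. = FALSE)
  }
  compound_rate <- colMeans(mask[retained_samples, , drop = FALSE])
  retained_compounds <- colnames(peaks)[compound_rate >= compound_min]
  if (length(retained_compounds) == 0) {
    stop("apply_qc: no compound reaches a response rate of ", compound_min,
         call. = FALSE)
  }
  out <- unclass(peaks)[retained_samples, retained_compounds, drop = FALSE]
  out[!mask[retained_samples, retained_compounds, drop = FALSE]] <- NA_real_
  rt <- attr(peaks, "retention_times")
  if (!is.null(rt)) rt <- rt[retained_compounds]
  report <- structure(list(validity_mask = mask,
                           sample_response_rate = sample_rate,
                           compound_response_rate = compound_rate,
                           retained_samples = retained_samples,
                           retained_compounds = retained_compounds,
                           thresholds = c(snr_min = snr_min,
                                          sample_min = sample_min,
                                          compound_min = compound_min)),
                      class = "qc_report")
  list(report = report, peaks = peak_table(out, retention_times = rt))
}

#' Normalize a QC-filtered peak table
#'
#' Pipeline, in fixed order: (a) impute each missing entry with half the
#' minimum valid area of its compound; (b) log10 transform; (c) per-sample
#' loading correction (subtract the sample's median log10 area, or its total
#' log-signal mean with `method = "total"`); (d) per-compound z-scaling with
#' mean and standard deviation estimated on `reference_samples` only and
#' applied to all samples, so no information from evaluation samples enters
#' the scaling parameters.
#'
#' @param peaks_valid A QC-filtered [peak_table()]: entries strictly positive
#'   or `NA`.
#' @param reference_samples Sample ids on which scaling parameters are
#'   learned (typically the training split). Defaults to all samples.
#' @param method Loading correction: `"median"` (default) or `"total"`
#'   (mean log10 signal).
#' @return An object of class `normalized_matrix`: the numeric matrix with
#'   attributes `scaling` (per-compound mean/sd on the reference),
#'   `impute_values` (per-compound half-minimum areas) and
#'   `reference_samples`.
#' @export
normalize_peaks <- function(peaks_valid, reference_samples = rownames(peaks_valid),
                            method = c("median", "total")) {
  method <- match.arg(method)
  m <- unclass(peaks_valid)
  if (any(m <= 0, na.rm = TRUE)) {
    stop("normalize_peaks: zero or negative area not marked missing",
         call. = FALSE)
  }
  if (length(reference_samples) == 0 ||
      !all(reference_samples %in% rownames(m))) {
    stop("normalize_peaks: reference_samples must be a non-empty subset of ",
         "the sample ids", call. = FALSE)
  }
  # (a) half-minimum imputation, per compound
  half_min <- apply(m, 2, function(col) {
    v <- col[!is.na(col)]
    if (length(v) == 0) {
      stop("normalize_peaks: compound with no valid measurement", call. = FALSE)
    }
    min(v) / 2
  })
  imp <- which(is.na(m), arr.ind = TRUE)
  if (nrow(imp) > 0) m[imp] <- half_min[imp[, 2]]
  # (b) log10
  lg <- log10(m)
  # (c) per-sample loading correction
  center <- switch(method,
                   median = apply(lg, 1, stats::median),
                   total = rowMeans(lg))
  lg <- lg - center
  # (d) per-compound z-scaling learned on the reference subset
  ref <- lg[reference_samples, , drop = FALSE]
  mu <- colMeans(ref)
  sd <- apply(ref, 2, stats::sd)
  if (any(is.na(sd))) sd[is.na(sd)] <- 0
  zero_var <- sd <= 0
  if (any(zero_var)) {
    warning("normalize_peaks: ", sum(zero_var),
            " compound(s) with zero variance on the reference; sd set to 1")
    sd[zero_var] <- 1
  }
  z <- sweep(sweep(lg, 2, mu, "-"), 2, sd, "/")
  structure(z,
            scaling = list(mean = mu, sd = sd, zero_variance = zero_var),
            impute_values = half_min,
            reference_samples = reference_samples,
            loading_method = method,
            class = c("normalized_matrix", "matrix", "array"))
}
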