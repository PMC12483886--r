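#' Peak-area table
#'
#' Container for a samples x compounds matrix of GC-MS peak areas, as produced
#' by upstream peak detection/alignment software. Rows are samples, columns
#' compounds; entries are non-negative areas in arbitrary units, with `NA`
#' marking measurements flagged invalid (or never observed).
#'
#' @param areas Numeric matrix with unique rownames (sample ids) and unique
#'   colnames (compound ids). Negative entries are rejected.
#' @param retention_times Optional numeric vector of per-compound retention
#'   times in minutes, same length and order as `colnames(areas)`.
#' @return An object of class `peak_table`: the matrix with a
#'   `retention_times` attribute.
#' @export
peak_table <- function(areas, retention_times = NULL) {
  areas <- as.matrix(areas)
  .check_axes(areas, "peak_table")
  if (any(areas < 0, na.rm = TRUE)) {
    stop("peak_table: negative areas are not allowed", call. = FALSE)
  }
  if (!is.null(retention_times)) {
    if (length(retention_times) != ncol(areas)) {
      stop("peak_table: retention_times must have one entry per compound",
           call. = FALSE)
    }
    retention_times <- as.numeric(retention_times)
    names(retention_times) <- colnames(areas)
  }
  structure(areas, retention_times = retention_times,
            class = c("peak_table", "matrix", "array"))
}

#' Signal-to-noise table
#'
#' Container for the SNR matrix paired with a [peak_table()]: same axes, same
#' ordering. SNR values gate the validity of each area measurement (an entry
#' is valid when its SNR strictly exceeds the threshold, 10 by default).
#'
#' @param snr Numeric matrix of non-negative signal-to-noise ratios with the
#'   same dimnames discipline as [peak_table()].
#' @return An object of class `snr_table`.
#' @export
snr_table <- function(snr) {
  snr <- as.matrix(snr)
  .check_axes(snr, "snr_table")
  if (any(snr < 0, na.rm = TRUE)) {
    stop("snr_table: negative SNR values are not allowed", call. = FALSE)
  }
  structure(snr, class = c("snr_table", "matrix", "array"))
}

.check_axes <- function(m, what) {
  if (!is.numeric(m)) stop(what, ": matrix must be numeric", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(what, ": sample ids (rownames) and compound ids (colnames) required",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop(what, ": sample and compound ids must be unique", call. = FALSE)
  }
  invisible(m)
}

#' Check that a peak table and an SNR table share axes
#'
#' @param peaks A [peak_table()].
#' @param snr An [snr_table()].
#' @return Invisibly `TRUE`; errors on any mismatch.
#' @export
check_paired_tables <- function(peaks, snr) {
  if (!identical(dim(peaks), dim(snr)) ||
      !identical(rownames(peaks), rownames(snr)) ||
      !identical(colnames(peaks), colnames(snr))) {
    stop("peak table and SNR table must share sample and compound ids ",
         "in identical order", call. = FALSE)
  }
  invisible(TRUE)
}

#' Sample sheet constructor
#'
#' Per-sample labels and serum marker values. `class` is the diagnosis
#' (malignant/benign), `subtype` the histological group, `stage` the AJCC
#' stage, `timepoint` pre- or post-operative; `pair_id` links a subject's
#' pre-op and post-op samples. Serum markers (CA125, ProGRP, CEA, CYFRA21-1)
#' are numeric with `NA` for not measured.
#'
#' @param sample_id,class,subtype,stage,timepoint,pair_id Character vectors.
#' @param ca125,progrp,cea,cyfra211 Numeric vectors (or `NA`).
#' @return A `data.frame` of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, class, subtype, stage, timepoint, pair_id,
                         ca125 = NA_real_, progrp = NA_real_,
                         cea = NA_real_, cyfra211 = NA_real_) {
  class <- as.character(class)
  if (!all(class %in% c("malignant", "benign"))) {
    stop("sample_sheet: class must be 'malignant' or 'benign'", call. = FALSE)
  }
  timepoint <- as.character(timepoint)
  if (!all(timepoint %in% c("preop", "postop"))) {
    stop("sample_sheet: timepoint must be 'preop' or 'postop'", call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    stop("sample_sheet: sample ids must be unique", call. = FALSE)
  }
  out <- data.frame(
    sample_id = as.character(sample_id),
    class = class,
    subtype = as.character(subtype),
    stage = as.character(stage),
    timepoint = timepoint,
    pair_id = as.character(pair_id),
    ca125 = as.numeric(ca125), progrp = as.numeric(progrp),
    cea = as.numeric(cea), cyfra211 = as.numeric(cyfra211),
    stringsAsFactors = FALSE
  )
  class(out) <- c("sample_sheet", "data.frame")
  out
}

# Internal: coerce a class label vector to 0/1 with malignant = 1.
.class01 <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop("numeric labels must be 0/1", call. = FALSE)
    }
    return(as.integer(labels))
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("malignant", "benign"))) {
    stop("labels must be 'malignant'/'benign', logical, or 0/1", call. = FALSE)
  }
  as.integer(labels == "malignant")
}
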