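# Synthetic breath-cohort generator.
#
# Emulates the statistical structure of a TD-GC-MS breath study of thoracic
# lesions: log-normal peak areas with per-sample loading offsets, SNR coupled
# to abundance, per-compound invalid-measurement rates, a planted subset of
# compounds elevated in malignancy, paired pre/post-operative samples, and
# low-sensitivity serum tumor markers.

SERUM_MARKERS <- c(ca125 = 35, progrp = 46, cea = 5, cyfra211 = 3)

#' Configuration for the synthetic breath cohort
#'
#' @param n_malignant,n_benign Number of malignant / benign subjects.
#' @param n_compounds Total number of VOC compounds in the peak table.
#' @param n_planted Number of true marker compounds elevated in malignancy.
#' @param effect_size Shift, in log10 area units, added to planted compounds
#'   in malignant pre-operative samples. See [effect_size_for_auc()] to
#'   express it as a target per-compound univariate AUC.
#' @param snr_scale Multiplier linking peak area to SNR; at the default a
#'   compound at its baseline abundance has median SNR around `snr_scale`.
#' @param missing_rate_range Length-2 numeric; each compound's probability of
#'   a forced-invalid measurement is drawn uniformly from this interval.
#' @param n_excluded Number of contaminant compounds placed on the exclusion
#'   list (disjoint from the planted set).
#' @param subtype_props Proportions of lung cancer / thymoma / esophageal
#'   cancer within the malignant class (named `LC`, `thymoma`, `EC`).
#' @param stage_props Proportions over AJCC stages for malignant subjects
#'   (named `0`, `I`, `II`, `III`, `IV`, `unknown`).
#' @param postop_fraction Fraction of subjects with a paired post-operative
#'   sample.
#' @param postop_effect_removal Fraction of the planted effect removed in
#'   post-operative malignant samples (1 = complete normalization).
#' @param serum_sensitivity Named per-marker true-positive rate in malignant
#'   subjects (`ca125`, `progrp`, `cea`, `cyfra211`).
#' @param seed Integer RNG seed; identical configs produce identical cohorts.
#'
#' @details Defaults mirror the structure of a 132-subject thoracic-lesion
#' cohort: 97 malignant (lung cancer : thymoma : esophageal cancer roughly
#' 77:13:7) versus 35 benign, 13 planted markers, and serum marker
#' sensitivities of a few percent to ~24%. Baseline log10 areas are drawn
#' per compound from U(4, 7) with compound standard deviations from
#' U(0.3, 0.6).
#'
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_malignant = 97, n_benign = 35,
                             n_compounds = 200, n_planted = 13,
                             effect_size = effect_size_for_auc(0.6),
                             snr_scale = 100,
                             missing_rate_range = c(0, 0.25),
                             n_excluded = 5,
                             subtype_props = c(LC = 77, thymoma = 13, EC = 7) / 97,
                             stage_props = c(`0` = 4, I = 57, II = 13,
                                             III = 7, IV = 13, unknown = 3) / 97,
                             postop_fraction = 0.55,
                             postop_effect_removal = 0.8,
                             serum_sensitivity = c(ca125 = 0.061, progrp = 0.121,
                                                   cea = 0.152, cyfra211 = 0.242),
                             seed = 1L) {
  cfg <- list(n_malignant = as.integer(n_malignant),
              n_benign = as.integer(n_benign),
              n_compounds = as.integer(n_compounds),
              n_planted = as.integer(n_planted),
              effect_size = as.numeric(effect_size),
              snr_scale = as.numeric(snr_scale),
              missing_rate_range = as.numeric(missing_rate_range),
              n_excluded = as.integer(n_excluded),
              subtype_props = subtype_props,
              stage_props = stage_props,
              postop_fraction = as.numeric(postop_fraction),
              postop_effect_removal = as.numeric(postop_effect_removal),
              serum_sensitivity = serum_sensitivity,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(is.list(cfg))
  for (f in c("n_malignant", "n_benign", "n_compounds", "n_planted")) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0L) {
      stop("synthetic_config: ", f, " must be a positive count", call. = FALSE)
    }
  }
  if (cfg$n_excluded < 0L) {
    stop("synthetic_config: n_excluded must be non-negative", call. = FALSE)
  }
  if (cfg$n_planted + cfg$n_excluded > cfg$n_compounds) {
    stop("synthetic_config: planted plus excluded compounds exceed n_compounds",
         call. = FALSE)
  }
  if (cfg$effect_size < 0) {
    stop("synthetic_config: effect_size must be >= 0", call. = FALSE)
  }
  mr <- cfg$missing_rate_range
  if (length(mr) != 2L || any(mr < 0) || any(mr > 1) || mr[1] > mr[2]) {
    stop("synthetic_config: missing_rate_range must be an ordered pair in [0,1]",
         call. = FALSE)
  }
  # Every compound draws its invalid rate >= mr[1]; if even the best case
  # leaves an expected response rate below 50%, the downstream compound
  # filter would discard the entire table.
  if (mr[1] > 0.5) {
    stop("synthetic_config: missing_rate_range would push every compound's ",
         "expected response rate below 50%", call. = FALSE)
  }
  for (f in c("postop_fraction", "postop_effect_removal")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("synthetic_config: ", f, " must lie in [0,1]", call. = FALSE)
    }
  }
  if (abs(sum(cfg$subtype_props) - 1) > 1e-9 || any(cfg$subtype_props < 0)) {
    stop("synthetic_config: subtype_props must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (abs(sum(cfg$stage_props) - 1) > 1e-9 || any(cfg$stage_props < 0)) {
    stop("synthetic_config: stage_props must be non-negative and sum to 1",
         call. = FALSE)
  }
  ss <- cfg$serum_sensitivity
  if (!all(names(SERUM_MARKERS) %in% names(ss)) || any(ss < 0) || any(ss > 1)) {
    stop("synthetic_config: serum_sensitivity needs rates in [0,1] for ",
         paste(names(SERUM_MARKERS), collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

#' Effect size (log10 shift) for a target univariate AUC
#'
#' For a normal location shift of `delta` against within-group standard
#' deviation `sd_log10`, the population AUC of the single compound is
#' `pnorm(delta / (sd_log10 * sqrt(2)))`. This inverts that relation, using
#' the generator's mean compound standard deviation by default.
#'
#' @param auc Target per-compound univariate AUC in (0.5, 1).
#' @param sd_log10 Within-group standard deviation on the log10 scale.
#' @return The log10 shift producing that separability.
#' @export
effect_size_for_auc <- function(auc, sd_log10 = 0.45) {
  stopifnot(auc >= 0.5, auc < 1, sd_log10 > 0)
  stats::qnorm(auc) * sqrt(2) * sd_log10
}

# Run code under a seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic integer allocation of n into groups by largest remainder.
.largest_remainder <- function(n, props) {
  target <- n * props / sum(props)
  base <- floor(target)
  rem <- n - sum(base)
  if (rem > 0) {
    order_by_frac <- order(target - base, decreasing = TRUE)
    base[order_by_frac[seq_len(rem)]] <- base[order_by_frac[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Generate a synthetic breath cohort
#'
#' Draws a samples x compounds peak-area matrix, a coupled SNR matrix, a
#' sample sheet with diagnosis/subtype/stage/timepoint labels and serum
#' markers, and a ground-truth record of the planted marker compounds.
#'
#' Peak areas are log-normal: for sample \eqn{i}, compound \eqn{j}, the
#' log10 area is \eqn{\mu_j + u_i + b_{sj} + \delta_{ij} + \epsilon}, where
#' \eqn{u_i} is a per-sample loading offset, \eqn{b_{sj}} a subject-level
#' deviation shared by a subject's pre/post pair, and \eqn{\delta_{ij}} the
#' planted shift (`effect_size` for malignant pre-op samples on planted
#' compounds, attenuated by `postop_effect_removal` after surgery). SNR is
#' `snr_scale * area / noise` with per-entry log-normal noise around the
#' compound baseline, so low-abundance measurements drift below the SNR = 10
#' validity gate; in addition each compound invalidates entries at its own
#' rate drawn from `missing_rate_range`.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `breath_cohort` with elements `peaks`
#'   ([peak_table()]), `snr` ([snr_table()]), `sheet` ([sample_sheet()]), and
#'   `truth` (list: `planted_compound_ids`, `excluded_compound_ids`,
#'   `design_auc`, `config`).
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  .with_seed(config$seed, {
    p <- config$n_compounds
    compound_ids <- sprintf("voc_%03d", seq_len(p))
    rt <- sort(stats::runif(p, 2, 13))
    mu <- stats::runif(p, 4, 7)
    sigma <- stats::runif(p, 0.3, 0.6)
    planted <- sort(sample(compound_ids, config$n_planted))
    excluded <- if (config$n_excluded > 0) {
      sort(sample(setdiff(compound_ids, planted), config$n_excluded))
    } else character(0)

    n_subj <- config$n_malignant + config$n_benign
    subject_id <- sprintf("S%03d", seq_len(n_subj))
    cls <- c(rep("malignant", config$n_malignant),
             rep("benign", config$n_benign))
    # Subtypes by largest-remainder allocation, then a deterministic shuffle
    # within class so subtype is not confounded with subject index.
    mal_counts <- .largest_remainder(config$n_malignant, config$subtype_props)
    ben_counts <- .largest_remainder(config$n_benign,
                                     c(benign_nodule = 20, benign_other = 15) / 35)
    subtype <- c(sample(rep(names(mal_counts), mal_counts)),
                 sample(rep(names(ben_counts), ben_counts)))
    stage <- rep("unknown", n_subj)
    stage_counts <- .largest_remainder(config$n_malignant, config$stage_props)
    stage[cls == "malignant"] <- sample(rep(names(stage_counts), stage_counts))

    has_post <- stats::runif(n_subj) < config$postop_fraction
    n_samples <- n_subj + sum(has_post)

    post_ids <- if (any(has_post)) {
      paste0(subject_id[has_post], "_post")
    } else character(0)
    sample_id <- c(paste0(subject_id, "_pre"), post_ids)
    samp_subject <- c(subject_id, subject_id[has_post])
    timepoint <- c(rep("preop", n_subj), rep("postop", sum(has_post)))
    idx <- match(samp_subject, subject_id)
    samp_class <- cls[idx]
    samp_subtype <- subtype[idx]
    samp_stage <- stage[idx]

    # Log10 areas: baseline + loading + subject deviation + shift + residual.
    loading <- stats::rnorm(n_samples, 0, 0.15)
    subj_dev <- matrix(stats::rnorm(n_subj * p), n_subj, p) *
      rep(sigma / sqrt(2), each = n_subj)
    resid <- matrix(stats::rnorm(n_samples * p), n_samples, p) *
      rep(sigma / sqrt(2), each = n_samples)
    shift <- matrix(0, n_samples, p)
    planted_col <- compound_ids %in% planted
    pre_mal <- samp_class == "malignant" & timepoint == "preop"
    post_mal <- samp_class == "malignant" & timepoint == "postop"
    shift[pre_mal, planted_col] <- config$effect_size
    shift[post_mal, planted_col] <-
      config$effect_size * (1 - config$postop_effect_removal)
    log_area <- matrix(rep(mu, each = n_samples), n_samples, p) +
      loading + subj_dev[idx, , drop = FALSE] + resid + shift
    areas <- 10^log_area

    # SNR coupled to abundance: snr_scale * 10^(log_area - mu - eta).
    eta <- matrix(stats::rnorm(n_samples * p, 0, 0.3), n_samples, p)
    snr <- config$snr_scale *
      10^(log_area - matrix(rep(mu, each = n_samples), n_samples, p) - eta)
    # Forced-invalid entries at a per-compound rate.
    m_rate <- stats::runif(p, config$missing_rate_range[1],
                           config$missing_rate_range[2])
    forced <- matrix(stats::runif(n_samples * p), n_samples, p) <
      rep(m_rate, each = n_samples)
    snr[forced] <- stats::runif(sum(forced), 0, 9.5)

    dimnames(areas) <- dimnames(snr) <- list(sample_id, compound_ids)

    # Serum markers, measured once per subject at the pre-operative visit.
    serum <- matrix(NA_real_, n_samples, length(SERUM_MARKERS),
                    dimnames = list(sample_id, names(SERUM_MARKERS)))
    for (m in names(SERUM_MARKERS)) {
      upper <- SERUM_MARKERS[[m]]
      rate <- ifelse(cls == "malignant", config$serum_sensitivity[[m]], 0.02)
      pos <- stats::runif(n_subj) < rate
      val <- ifelse(pos, upper * stats::runif(n_subj, 1.05, 3),
                    upper * stats::runif(n_subj, 0.1, 0.95))
      val[stats::runif(n_subj) < 0.05] <- NA_real_  # occasionally unmeasured
      serum[seq_len(n_subj), m] <- val
    }

    sheet <- sample_sheet(sample_id = sample_id, class = samp_class,
                          subtype = samp_subtype, stage = samp_stage,
                          timepoint = timepoint, pair_id = samp_subject,
                          ca125 = serum[, "ca125"], progrp = serum[, "progrp"],
                          cea = serum[, "cea"], cyfra211 = serum[, "cyfra211"])

    design_auc <- stats::pnorm(
      sqrt(sum((config$effect_size / sigma[planted_col])^2)) / sqrt(2))

    truth <- list(planted_compound_ids = planted,
                  excluded_compound_ids = excluded,
                  design_auc = design_auc,
                  config = unclass(config))
    structure(list(peaks = peak_table(areas, retention_times = rt),
                   snr = snr_table(snr),
                   sheet = sheet,
                   truth = truth),
              class = "breath_cohort")
  })
}

#' Write a cohort to disk as plain-text files
#'
#' Writes `peak_areas.tsv` and `snr.tsv` (samples as rows, first column
#' `sample_id`, header row of compound ids), `sample_sheet.csv`, and
#' `ground_truth.json` into `dir`. Files round-trip losslessly through
#' [read_cohort()].
#'
#' @param cohort A `breath_cohort` (or a list with the same elements).
#' @param dir Output directory, created if absent.
#' @param overwrite Refuse to overwrite existing files unless `TRUE`.
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  check_paired_tables(cohort$peaks, cohort$snr)
  if (!all(rownames(cohort$peaks) == cohort$sheet$sample_id)) {
    stop("write_cohort: sample ids differ between tables and sample sheet",
         call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("peak_areas.tsv", "snr.tsv",
                            "sample_sheet.csv", "ground_truth.json"))
  names(paths) <- c("peaks", "snr", "sheet", "truth")
  if (!overwrite && any(file.exists(paths))) {
    stop("write_cohort: output files exist; use overwrite = TRUE",
         call. = FALSE)
  }
  .write_matrix_tsv(cohort$peaks, paths["peaks"])
  .write_matrix_tsv(cohort$snr, paths["snr"])
  utils::write.csv(as.data.frame(cohort$sheet), paths["sheet"],
                   row.names = FALSE, quote = FALSE, na = "")
  writeLines(jsonlite::toJSON(cohort$truth, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), paths["truth"])
  invisible(paths)
}

.write_matrix_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the four cohort files.
#' @return A list of class `breath_cohort` (ground truth is `NULL` when
#'   `ground_truth.json` is absent, as for real data).
#' @export
read_cohort <- function(dir) {
  peaks <- .read_matrix_tsv(file.path(dir, "peak_areas.tsv"))
  snr <- .read_matrix_tsv(file.path(dir, "snr.tsv"))
  sheet_df <- utils::read.csv(file.path(dir, "sample_sheet.csv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(sample_id = "character",
                                             pair_id = "character"))
  sheet <- sample_sheet(sample_id = sheet_df$sample_id, class = sheet_df$class,
                        subtype = sheet_df$subtype, stage = sheet_df$stage,
                        timepoint = sheet_df$timepoint,
                        pair_id = sheet_df$pair_id,
                        ca125 = sheet_df$ca125, progrp = sheet_df$progrp,
                        cea = sheet_df$cea, cyfra211 = sheet_df$cyfra211)
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::fromJSON(truth_path, simplifyVector = TRUE)
  } else NULL
  structure(list(peaks = peak_table(peaks), snr = snr_table(snr),
                 sheet = sheet, truth = truth),
            class = "breath_cohort")
}

.read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}
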