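# Orchestration: ties QC, normalization, screening, selection, model
# fitting and evaluation into reproducible end-to-end runs driven by a
# single configuration and master seed.

#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end pipeline. Defaults are
#' the protocol values: SNR validity > 10, sample response >= 0.80, compound
#' response >= 0.50, a 60% discovery split, screening at p < 0.05 and
#' VIP > 1, forward selection with delta = 0.005 and patience 2 under
#' 5-fold stratified CV, the [default_grid()] hyperparameter grid, and 95%
#' confidence intervals.
#'
#' @param snr_min,sample_min,compound_min QC thresholds.
#' @param train_fraction Discovery-set fraction.
#' @param alpha,vip_cutoff,n_orthogonal Screening parameters.
#' @param delta,patience,folds Forward-selection parameters.
#' @param grid Hyperparameter grid data.frame.
#' @param ci_level Confidence level for reported intervals.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(snr_min = 10, sample_min = 0.80,
                            compound_min = 0.50, train_fraction = 0.60,
                            alpha = 0.05, vip_cutoff = 1, n_orthogonal = 1,
                            delta = 0.005, patience = 2, folds = 5,
                            grid = default_grid(), ci_level = 0.95,
                            seed = 1L) {
  stopifnot(snr_min >= 0, sample_min >= 0, sample_min <= 1,
            compound_min >= 0, compound_min <= 1,
            train_fraction > 0, train_fraction < 1,
            alpha > 0, alpha < 1, vip_cutoff >= 0, n_orthogonal >= 0,
            delta >= 0, patience >= 1, folds >= 2,
            ci_level > 0, ci_level < 1)
  structure(list(snr_min = snr_min, sample_min = sample_min,
                 compound_min = compound_min,
                 train_fraction = train_fraction, alpha = alpha,
                 vip_cutoff = vip_cutoff, n_orthogonal = n_orthogonal,
                 delta = delta, patience = patience, folds = folds,
                 grid = grid, ci_level = ci_level, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Derived per-stage seeds keep stages independent under one master seed.
.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 101L + stage * 7919L) %% 2147483629L
}

#' Generate and write a synthetic cohort (simulate stage)
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory.
#' @param overwrite Passed to [write_cohort()].
#' @return Invisibly, the written file paths (including `manifest.json`
#'   recording the configuration and file checksums).
#' @export
run_simulate <- function(config, dir, overwrite = FALSE) {
  cohort <- generate_cohort(config)
  paths <- write_cohort(cohort, dir, overwrite = overwrite)
  manifest <- list(config = unclass(config),
                   files = as.list(tools::md5sum(unname(paths))))
  manifest_path <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), manifest_path)
  invisible(c(paths, manifest = manifest_path))
}

#' Train the classifier on a normalized matrix (split onward)
#'
#' The training path from the split onward: screening, AUC ranking, forward
#' selection, hyperparameter grid search, final fit and Youden threshold.
#' Only rows named in `split$train_ids` are ever read, so evaluation samples
#' cannot leak into any training decision.
#'
#' @param X Normalized matrix covering at least the training samples.
#' @param sheet Sample sheet.
#' @param split A [stratified_split()] result.
#' @param exclusion Compound exclusion list.
#' @param config A [pipeline_config()].
#' @return List: `screening`, `ranked`, `trace`, `tuning`, `model`,
#'   `train_report`.
#' @export
train_classifier <- function(X, sheet, split, exclusion = character(),
                             config = pipeline_config()) {
  train_ids <- split$train_ids
  X_train <- X[train_ids, , drop = FALSE]
  y_train <- sheet$class[match(train_ids, sheet$sample_id)]

  screening <- screen_compounds(X_train, y_train, exclusion = exclusion,
                                alpha = config$alpha,
                                vip_cutoff = config$vip_cutoff,
                                n_orthogonal = config$n_orthogonal)
  candidates <- screening$compound_id[screening$candidate]
  if (length(candidates) == 0) {
    stop("train_classifier [screening]: no compound passed the dual ",
         "criterion (p < ", config$alpha, ", VIP > ", config$vip_cutoff, ")",
         call. = FALSE)
  }
  pvals <- stats::setNames(screening$p_value, screening$compound_id)
  ranked <- rank_features(X_train, y_train, candidates, p_values = pvals)
  trace <- forward_select(X_train, y_train, ranked$feature,
                          folds = config$folds, delta = config$delta,
                          patience = config$patience,
                          seed = .stage_seed(config$seed, 2L))
  tuning <- grid_search_cv(X_train, y_train, trace$features,
                           grid = config$grid, folds = config$folds,
                           seed = .stage_seed(config$seed, 3L))
  model <- fit_final(X_train, y_train, trace$features, tuning$best)
  train_report <- performance_report(model$train_scores, y_train,
                                     model$threshold, level = config$ci_level,
                                     subgroup = "training")
  list(screening = screening, ranked = ranked, trace = trace,
       tuning = tuning, model = model, train_report = train_report)
}

#' Run the full training pipeline on a cohort
#'
#' Executes QC, the stratified split of pre-operative samples, normalization
#' with scaling parameters learned on the discovery set, and the training
#' path of [train_classifier()].
#'
#' @param cohort A `breath_cohort` (from [generate_cohort()] or
#'   [read_cohort()]) or a list with `peaks`, `snr`, `sheet`.
#' @param exclusion Compound exclusion list (ids of drug metabolites /
#'   contaminants).
#' @param config A [pipeline_config()].
#' @return List of class `breath_pipeline`: `qc`, `split`, `normalized`,
#'   `sheet` (QC-retained rows), plus all [train_classifier()] outputs and
#'   the `config`.
#' @export
run_train <- function(cohort, exclusion = character(),
                      config = pipeline_config()) {
  qc <- withCallingHandlers(
    apply_qc(cohort$peaks, cohort$snr, snr_min = config$snr_min,
             sample_min = config$sample_min,
             compound_min = config$compound_min),
    error = function(e) stop("run_train [qc]: ", conditionMessage(e),
                             call. = FALSE))
  message(sprintf("[qc] retained %d/%d samples, %d/%d compounds",
                  length(qc$report$retained_samples), nrow(cohort$peaks),
                  length(qc$report$retained_compounds), ncol(cohort$peaks)))
  sheet <- cohort$sheet[cohort$sheet$sample_id %in%
                          qc$report$retained_samples, , drop = FALSE]
  split <- stratified_split(sheet, train_fraction = config$train_fraction,
                            seed = .stage_seed(config$seed, 1L))
  message(sprintf("[split] discovery n = %d, testing n = %d",
                  length(split$train_ids), length(split$test_ids)))
  normalized <- normalize_peaks(qc$peaks, reference_samples = split$train_ids)
  core <- train_classifier(normalized, sheet, split, exclusion = exclusion,
                           config = config)
  message(sprintf("[screen] %d candidate compounds",
                  sum(core$screening$candidate)))
  message(sprintf("[select] chose k = %d features; threshold %.3f",
                  core$trace$chosen_k, core$model$threshold))
  structure(c(list(qc = qc$report, split = split, normalized = normalized,
                   sheet = sheet, config = config), core),
            class = "breath_pipeline")
}

#' Evaluate a trained pipeline on its held-out testing set
#'
#' Produces the test-set performance report, per-subtype reports (each
#' malignant subtype against all benign), stage-stratified reports, the
#' serum tumor-marker panel comparison (McNemar) when marker values are
#' present, and pre/post-operative monitoring when paired samples exist.
#'
#' @param trained A `breath_pipeline` from [run_train()].
#' @return List of class `breath_evaluation`.
#' @export
run_evaluate <- function(trained) {
  model <- trained$model
  sheet <- trained$sheet
  X <- trained$normalized
  test_ids <- trained$split$test_ids
  level <- trained$config$ci_level
  X_test <- X[test_ids, , drop = FALSE]
  test_sheet <- sheet[match(test_ids, sheet$sample_id), , drop = FALSE]
  scores <- predict(model, X_test)
  y <- test_sheet$class

  test_report <- performance_report(scores, y, model$threshold,
                                    level = level, subgroup = "testing")

  subtype_reports <- list()
  for (st in c("LC", "thymoma", "EC")) {
    mask <- test_sheet$subtype == st | y == "benign"
    subtype_reports[[st]] <-
      performance_report(scores, y, model$threshold, subgroup_mask = mask,
                         level = level,
                         subgroup = paste0(st, " vs benign"))
  }
  stage_reports <- list()
  stage_groups <- list(`early (0+I+II)` = c("0", "I", "II"),
                       `late (III+IV)` = c("III", "IV"))
  for (g in names(stage_groups)) {
    mask <- (y == "malignant" & test_sheet$stage %in% stage_groups[[g]]) |
      y == "benign"
    stage_reports[[g]] <-
      performance_report(scores, y, model$threshold, subgroup_mask = mask,
                         level = level, subgroup = g)
  }

  # Serum panel comparison on malignant test samples with >= 1 marker.
  serum <- NULL
  panel <- serum_panel_classify(test_sheet)
  mal <- y == "malignant" & !is.na(panel$panel_positive)
  if (any(mal)) {
    model_correct <- scores[mal] >= model$threshold
    panel_correct <- panel$panel_positive[mal]
    marker_sens <- colMeans(
      panel[mal, paste0(names(SERUM_MARKERS), "_pos")], na.rm = TRUE)
    serum <- list(n = sum(mal),
                  model_sensitivity = mean(model_correct),
                  panel_sensitivity = mean(panel_correct),
                  marker_sensitivity = marker_sens,
                  mcnemar = mcnemar_test(model_correct, panel_correct))
  }

  # Pre/post monitoring over all QC-surviving pairs (train + test subjects).
  prepost <- NULL
  pre <- sheet[sheet$timepoint == "preop", c("sample_id", "pair_id", "class")]
  post <- sheet[sheet$timepoint == "postop", c("sample_id", "pair_id")]
  pairs <- merge(pre, post, by = "pair_id",
                 suffixes = c("_pre", "_post"))
  if (nrow(pairs) >= 2) {
    pairs <- data.frame(pre_id = pairs$sample_id_pre,
                        post_id = pairs$sample_id_post,
                        class = pairs$class, stringsAsFactors = FALSE)
    prepost <- list(pairs = pairs)
    for (grp in c("malignant", "benign")) {
      mask <- pairs$class == grp
      prepost[[grp]] <- if (sum(mask) >= 2) {
        prepost_comparison(model, X, X, pairs, group_mask = mask)
      } else NULL
    }
  }

  structure(list(test_report = test_report,
                 subtype_reports = subtype_reports,
                 stage_reports = stage_reports,
                 serum = serum, prepost = prepost,
                 predictions = data.frame(sample_id = test_ids,
                                          score = scores, class = y,
                                          stringsAsFactors = FALSE)),
            class = "breath_evaluation")
}
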