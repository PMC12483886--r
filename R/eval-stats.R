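# Evaluation statistics: ROC AUC with DeLong variance, Wilson score
# intervals, confusion-based performance reports, the DeLong test for
# paired AUC comparison, McNemar's test, serum tumor-marker panel rules,
# and paired pre/post-operative monitoring.

#' ROC AUC by pairwise comparison (rank statistic)
#'
#' AUC is the fraction of positive-negative pairs in which the positive
#' scores higher, counting ties as one half — computed via midranks.
#'
#' @param scores Numeric prediction scores (higher = more malignant).
#' @param labels Class labels (malignant = positive).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  y <- .class01(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("roc_auc: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`, clipped to [0, 1].
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm((1 + level) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  pmin(1, pmax(0, c(lower = centre - half, upper = centre + half)))
}

#' Clopper-Pearson (exact) binomial interval
#'
#' Provided as an alternative to [wilson_ci()].
#'
#' @inheritParams wilson_ci
#' @return Numeric vector `c(lower, upper)`.
#' @export
clopper_pearson_ci <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  a <- (1 - level) / 2
  lower <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lower = lower, upper = upper)
}

# DeLong placement values: for each positive, the fraction of negatives it
# beats (ties half); for each negative, the fraction of positives it loses
# to. Returns list(v10, v01, auc).
.delong_placements <- function(scores, y) {
  sp <- scores[y == 1]; sn <- scores[y == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
}

# DeLong variance of a single AUC; NA when either class has < 2 samples.
.delong_var <- function(scores, y) {
  pl <- .delong_placements(scores, y)
  n1 <- length(pl$v10); n0 <- length(pl$v01)
  if (n1 < 2 || n0 < 2) return(NA_real_)
  stats::var(pl$v10) / n1 + stats::var(pl$v01) / n0
}

#' DeLong test for two correlated AUCs
#'
#' Both models score the same samples (paired design). The difference in
#' AUCs is tested with the DeLong placement-value covariance estimator and a
#' two-sided normal reference.
#'
#' @param scores_a,scores_b Paired score vectors from the two models.
#' @param labels Shared class labels.
#' @return List: `auc_a`, `auc_b`, `z`, `p_value`, `var_diff`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop("delong_test: score vectors must be paired (same samples)",
         call. = FALSE)
  }
  y <- .class01(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 < 2 || n0 < 2) {
    stop("delong_test: need at least two samples per class", call. = FALSE)
  }
  pa <- .delong_placements(scores_a, y)
  pb <- .delong_placements(scores_b, y)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (abs(d) < 1e-12) {
      return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p_value = 1,
                  var_diff = 0))
    }
    stop("delong_test: zero variance with unequal AUCs (degenerate pairing)",
         call. = FALSE)
  }
  z <- d / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), var_diff = var_diff)
}

#' McNemar's test on paired correctness indicators
#'
#' `b` counts samples only model A got right, `c` samples only model B got
#' right. Exact two-sided binomial p-value when `b + c <= 25`, otherwise the
#' chi-square approximation with continuity correction.
#'
#' @param correct_a,correct_b Paired logical vectors of per-sample
#'   correctness.
#' @return List: `b`, `c`, `p_value`, `method`.
#' @export
mcnemar_test <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  ok <- !is.na(correct_a) & !is.na(correct_b)
  a <- correct_a[ok]; b_ <- correct_b[ok]
  b <- sum(a & !b_)
  c_ <- sum(!a & b_)
  n <- b + c_
  if (n == 0) {
    return(list(b = b, c = c_, p_value = 1, method = "exact"))
  }
  if (n <= 25) {
    p <- min(1, 2 * stats::pbinom(min(b, c_), n, 0.5))
    method <- "exact"
  } else {
    stat <- (abs(b - c_) - 1)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-square"
  }
  list(b = b, c = c_, p_value = p, method = method)
}

#' Performance report at a decision threshold
#'
#' Confusion counts under the rule `score >= threshold` implies malignant,
#' with binomial confidence intervals (Wilson score by default) on
#' sensitivity, specificity, accuracy and F1, and a DeLong normal-theory
#' interval on the AUC. F1 is treated as the proportion `2TP / (2TP+FP+FN)`
#' for its interval.
#'
#' @param scores Prediction scores.
#' @param labels Class labels (malignant = positive).
#' @param threshold Decision threshold from the training set.
#' @param subgroup_mask Optional logical vector restricting the report to a
#'   subgroup (e.g. lung cancer vs all benign).
#' @param level Confidence level.
#' @param ci_method `"wilson"` (default) or `"clopper-pearson"` for the
#'   proportion intervals.
#' @param subgroup Optional label recorded in the report.
#' @return List of class `perf_report`: `counts` (TP/FP/TN/FN), `metrics`
#'   (data.frame metric/estimate/lower/upper/k/n), `n`, `threshold`,
#'   `subgroup`. A zero-member subgroup yields an empty report (`n = 0`)
#'   rather than an error.
#' @export
performance_report <- function(scores, labels, threshold,
                               subgroup_mask = NULL, level = 0.95,
                               ci_method = c("wilson", "clopper-pearson"),
                               subgroup = NA_character_) {
  ci_method <- match.arg(ci_method)
  ci_fun <- if (ci_method == "wilson") wilson_ci else clopper_pearson_ci
  if (!is.null(subgroup_mask)) {
    scores <- scores[subgroup_mask]
    labels <- labels[subgroup_mask]
  }
  n <- length(scores)
  empty <- data.frame(metric = c("auc", "sensitivity", "specificity",
                                 "accuracy", "f1"),
                      estimate = NA_real_, lower = NA_real_,
                      upper = NA_real_, k = NA_real_, n = NA_real_,
                      stringsAsFactors = FALSE)
  if (n == 0) {
    return(structure(list(counts = c(TP = 0, FP = 0, TN = 0, FN = 0),
                          metrics = empty, n = 0L, threshold = threshold,
                          subgroup = subgroup), class = "perf_report"))
  }
  y <- .class01(labels)
  pred <- scores >= threshold
  tp <- sum(pred & y == 1); fn <- sum(!pred & y == 1)
  fp <- sum(pred & y == 0); tn <- sum(!pred & y == 0)
  prop_row <- function(metric, k, nn) {
    if (nn == 0) return(data.frame(metric = metric, estimate = NA_real_,
                                   lower = NA_real_, upper = NA_real_,
                                   k = NA_real_, n = 0))
    ci <- ci_fun(k, nn, level)
    data.frame(metric = metric, estimate = k / nn, lower = ci[[1]],
               upper = ci[[2]], k = k, n = nn, stringsAsFactors = FALSE)
  }
  auc_row <- if (tp + fn > 0 && fp + tn > 0) {
    auc <- roc_auc(scores, y)
    v <- .delong_var(scores, y)
    z <- stats::qnorm((1 + level) / 2)
    ci <- if (is.na(v)) c(NA_real_, NA_real_) else {
      pmin(1, pmax(0, auc + c(-1, 1) * z * sqrt(v)))
    }
    data.frame(metric = "auc", estimate = auc, lower = ci[1], upper = ci[2],
               k = NA_real_, n = n, stringsAsFactors = FALSE)
  } else {
    data.frame(metric = "auc", estimate = NA_real_, lower = NA_real_,
               upper = NA_real_, k = NA_real_, n = n)
  }
  metrics <- rbind(
    auc_row,
    prop_row("sensitivity", tp, tp + fn),
    prop_row("specificity", tn, tn + fp),
    prop_row("accuracy", tp + tn, n),
    prop_row("f1", 2 * tp, 2 * tp + fp + fn)
  )
  rownames(metrics) <- NULL
  structure(list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 metrics = metrics, n = as.integer(n), threshold = threshold,
                 subgroup = subgroup),
            class = "perf_report")
}

#' @export
print.perf_report <- function(x, ...) {
  cat("Performance report",
      if (!is.na(x$subgroup)) paste0(" [", x$subgroup, "]"), "\n", sep = "")
  cat(sprintf("n = %d, threshold = %.4g\n", x$n, x$threshold))
  cat(sprintf("counts: TP=%d FP=%d TN=%d FN=%d\n",
              x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"]))
  print(x$metrics, digits = 3)
  invisible(x)
}

#' Serum tumor-marker panel classification
#'
#' A subject is panel-positive when any available serum marker lies strictly
#' above its normal range upper limit (CA125 0-35 KU/L, ProGRP 0-46 ng/L,
#' CEA 0-5 ug/L, CYFRA21-1 0-3 ng/L). Samples with all markers missing are
#' excluded (`panel_positive = NA`) rather than called negative.
#'
#' @param sheet A [sample_sheet()] (or data.frame with the marker columns).
#' @return A `data.frame`: `sample_id`, per-marker positivity
#'   (`ca125_pos`, ...), `n_markers_available`, `panel_positive`.
#' @export
serum_panel_classify <- function(sheet) {
  vals <- as.matrix(sheet[, names(SERUM_MARKERS)])
  pos <- sweep(vals, 2, SERUM_MARKERS, ">")
  available <- rowSums(!is.na(vals))
  panel <- apply(pos, 1, function(r) {
    if (all(is.na(r))) NA else any(r, na.rm = TRUE)
  })
  out <- data.frame(sample_id = sheet$sample_id, stringsAsFactors = FALSE)
  colnames(pos) <- paste0(names(SERUM_MARKERS), "_pos")
  out <- cbind(out, as.data.frame(pos))
  out$n_markers_available <- available
  out$panel_positive <- panel
  rownames(out) <- NULL
  out
}

#' Paired pre/post-operative score comparison
#'
#' Scores each subject's pre-operative and post-operative samples with the
#' fitted classifier and tests the per-pair change (post minus pre) against
#' zero, by default with a paired two-sided t-test (Wilcoxon signed-rank
#' available as an alternative since predicted probabilities are bounded).
#'
#' @param model A fitted classifier with a `predict` method returning
#'   probabilities (see [fit_final()]).
#' @param X_pre,X_post Normalized matrices whose rows are matched via
#'   `pairs`.
#' @param pairs A `data.frame` with columns `pre_id`, `post_id` naming rows
#'   of `X_pre` / `X_post`.
#' @param group_mask Optional logical vector (one per pair) selecting a
#'   diagnosis subgroup.
#' @param method `"t"` (paired t-test, default) or `"wilcoxon"` (signed
#'   rank).
#' @return List: `mean_change`, `statistic`, `p_value`, `n_pairs`, `method`.
#' @export
prepost_comparison <- function(model, X_pre, X_post, pairs,
                               group_mask = NULL,
                               method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  if (!is.null(group_mask)) pairs <- pairs[group_mask, , drop = FALSE]
  if (nrow(pairs) < 2) {
    stop("prepost_comparison: need at least 2 pre/post pairs", call. = FALSE)
  }
  pre <- predict(model, X_pre[pairs$pre_id, , drop = FALSE])
  post <- predict(model, X_post[pairs$post_id, , drop = FALSE])
  d <- post - pre
  if (all(d == 0)) {
    return(list(mean_change = 0, statistic = 0, p_value = 1,
                n_pairs = nrow(pairs), method = method))
  }
  res <- if (method == "t") {
    stats::t.test(d)
  } else {
    suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE))
  }
  list(mean_change = mean(d), statistic = unname(res$statistic),
       p_value = res$p.value, n_pairs = nrow(pairs), method = method)
}
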