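# Dataset partitioning, AUC-ranked progressive feature selection with
# stratified cross-validation, grid-searched regularized logistic
# regression, and Youden-index thresholding.

#' Stratified train/test split
#'
#' Randomly partitions the pre-operative samples into a discovery (training)
#' and a testing set, stratified on the class label. The training set size
#' is `floor(train_fraction * n)`; per-class allocations use
#' largest-remainder rounding, so each class's proportion is within one
#' sample of the stratified ideal.
#'
#' @param sheet A [sample_sheet()]; only `timepoint == "preop"` rows are
#'   eligible (post-operative samples are reserved for monitoring).
#' @param train_fraction Fraction assigned to the discovery set (default
#'   0.60).
#' @param seed Integer seed making the split deterministic.
#' @return List of class `split_spec`: `train_ids`, `test_ids`,
#'   `train_fraction`, `seed`.
#' @export
stratified_split <- function(sheet, train_fraction = 0.6, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  eligible <- sheet[sheet$timepoint == "preop", , drop = FALSE]
  cls <- eligible$class
  counts <- table(cls)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("stratified_split: need at least 2 pre-op samples per class",
         call. = FALSE)
  }
  n <- nrow(eligible)
  n_train <- floor(train_fraction * n)
  alloc <- .largest_remainder(n_train, counts / n)
  train_ids <- character(0)
  .with_seed(seed, {
    for (k in names(alloc)) {
      ids_k <- eligible$sample_id[cls == k]
      train_ids <- c(train_ids, sample(ids_k, alloc[[k]]))
    }
  })
  train_ids <- sort(train_ids)
  test_ids <- sort(setdiff(eligible$sample_id, train_ids))
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Rank candidate features by univariate training AUC
#'
#' Features are ordered by descending discriminative AUC, treating AUC `a`
#' and `1 - a` symmetrically via `max(a, 1 - a)`. Ties are broken by smaller
#' screening p-value, then by compound id.
#'
#' @param X Training matrix (samples x compounds).
#' @param y Training class labels.
#' @param candidates Compound ids to rank (typically screened candidates).
#' @param p_values Optional named p-values used for tie-breaking.
#' @return A `data.frame` with columns `feature`, `auc`, `sym_auc`, ordered
#'   best first.
#' @export
rank_features <- function(X, y, candidates, p_values = NULL) {
  stopifnot(length(candidates) > 0, all(candidates %in% colnames(X)))
  y01 <- .class01(y)
  auc <- vapply(candidates, function(j) roc_auc(X[, j], y01), numeric(1))
  sym <- pmax(auc, 1 - auc)
  pv <- if (is.null(p_values)) rep(NA_real_, length(candidates)) else {
    as.numeric(p_values[candidates])
  }
  ord <- order(-sym, pv, candidates, na.last = TRUE)
  data.frame(feature = candidates[ord], auc = auc[ord], sym_auc = sym[ord],
             p_value = pv[ord], stringsAsFactors = FALSE, row.names = NULL)
}

#' Stratified cross-validation fold assignment
#'
#' @param y Class labels.
#' @param k Requested number of folds; reduced (with a warning) when the
#'   smaller class has fewer members than folds.
#' @param seed Integer seed.
#' @return Integer vector of fold memberships in `1..k_effective`.
#' @export
make_stratified_folds <- function(y, k = 5, seed = 1L) {
  y01 <- .class01(y)
  min_class <- min(table(y01))
  if (min_class < 2) {
    stop("make_stratified_folds: each class needs at least 2 samples",
         call. = FALSE)
  }
  if (min_class < k) {
    warning("make_stratified_folds: reducing folds from ", k, " to ",
            min_class, " (smallest stratum size)")
    k <- min_class
  }
  folds <- integer(length(y01))
  .with_seed(seed, {
    for (cls in unique(y01)) {
      idx <- sample(which(y01 == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Default hyperparameters used during forward selection (mild L2 shrinkage).
default_selection_hyper <- function() {
  list(penalty = "l2", strength = 0.01, class_weights = "uniform",
       maxit = 1000L)
}

#' Regularized logistic regression fit
#'
#' Thin wrapper around an elastic-net binomial fit at a single fixed
#' penalty. Features are used as given (no internal standardization; the
#' normalization pipeline already z-scales compounds).
#'
#' @param X Numeric matrix (samples x features).
#' @param y Class labels (malignant = 1).
#' @param penalty `"l1"` (lasso) or `"l2"` (ridge).
#' @param strength Penalty strength lambda (>= 0).
#' @param class_weights `"uniform"` or `"balanced"` (inverse class
#'   frequency).
#' @param maxit Iteration cap.
#' @return List of class `logistic_fit`: `coefficients` (named), `intercept`
#'   and the hyperparameters.
#' @export
fit_logistic <- function(X, y, penalty = c("l2", "l1"), strength = 0.01,
                         class_weights = c("uniform", "balanced"),
                         maxit = 1000L) {
  penalty <- match.arg(penalty)
  class_weights <- match.arg(class_weights)
  X <- as.matrix(X)
  y01 <- .class01(y)
  if (length(unique(y01)) < 2) {
    stop("fit_logistic: both classes required", call. = FALSE)
  }
  w <- if (class_weights == "balanced") {
    tab <- table(y01)
    n <- length(y01)
    as.numeric(n / (2 * tab[as.character(y01)]))
  } else rep(1, length(y01))
  padded <- ncol(X) == 1L
  Xf <- if (padded) cbind(X, `.pad.` = 0) else X
  # Routine glmnet chatter is muffled: small CV folds trip its small-class
  # advisory, and a low iteration cap is a deliberate hyperparameter here.
  fit <- withCallingHandlers(
    glmnet::glmnet(Xf, y01, family = "binomial",
                   alpha = if (penalty == "l1") 1 else 0,
                   lambda = strength, weights = w,
                   standardize = FALSE, maxit = maxit, thresh = 1e-10),
    warning = function(cnd) {
      if (grepl("fewer than 8|Convergence for 1th lambda|empty model",
                conditionMessage(cnd))) {
        invokeRestart("muffleWarning")
      }
    })
  beta <- as.numeric(fit$beta)
  names(beta) <- rownames(fit$beta)
  if (padded) beta <- beta[colnames(X)]
  structure(list(coefficients = beta, intercept = as.numeric(fit$a0),
                 penalty = penalty, strength = strength,
                 class_weights = class_weights, maxit = maxit),
            class = "logistic_fit")
}

#' @export
predict.logistic_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, names(object$coefficients), drop = FALSE]
  stats::plogis(object$intercept + drop(X %*% object$coefficients))
}

# Mean out-of-fold AUC of a logistic model on a fixed feature set.
.cv_mean_auc <- function(X, y01, features, folds, hyper) {
  vals <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- fit_logistic(X[tr, features, drop = FALSE], y01[tr],
                        penalty = hyper$penalty, strength = hyper$strength,
                        class_weights = hyper$class_weights,
                        maxit = hyper$maxit)
    scores <- predict(fit, X[!tr, features, drop = FALSE])
    roc_auc(scores, y01[!tr])
  }, numeric(1))
  mean(vals)
}

#' Forward feature selection by cross-validated AUC
#'
#' Starting from the top-ranked feature, adds one feature at a time in rank
#' order, recording the mean out-of-fold AUC of the logistic model after
#' each addition. Stops once the improvement over the running best is at
#' most `delta` for `patience` consecutive additions; the chosen size `k` is
#' the argmax of mean CV AUC among the evaluated steps (smallest `k` on
#' ties).
#'
#' @param X Training matrix.
#' @param y Training class labels.
#' @param ranked Feature ids in rank order (from [rank_features()]).
#' @param folds Number of stratified CV folds (default 5).
#' @param delta Minimum mean-CV-AUC improvement counted as progress
#'   (default 0.005).
#' @param patience Number of consecutive non-improving additions tolerated
#'   before stopping (default 2).
#' @param seed Seed for the fold assignment.
#' @param hyper Hyperparameters used during selection (default: ridge,
#'   strength 0.01, uniform weights).
#' @return List of class `selection_trace`: `trace` (data.frame `k`,
#'   `feature`, `mean_cv_auc`), `chosen_k`, `features` (the chosen set),
#'   `delta`, `patience`, `folds`, `seed`.
#' @export
forward_select <- function(X, y, ranked, folds = 5, delta = 0.005,
                           patience = 2, seed = 1L,
                           hyper = default_selection_hyper()) {
  stopifnot(length(ranked) > 0, all(ranked %in% colnames(X)))
  y01 <- .class01(y)
  fold_id <- make_stratified_folds(y01, folds, seed)
  trace <- data.frame(k = integer(0), feature = character(0),
                      mean_cv_auc = numeric(0), stringsAsFactors = FALSE)
  best <- -Inf
  streak <- 0L
  for (k in seq_along(ranked)) {
    cvauc <- .cv_mean_auc(X, y01, ranked[seq_len(k)], fold_id, hyper)
    trace <- rbind(trace, data.frame(k = k, feature = ranked[k],
                                     mean_cv_auc = cvauc,
                                     stringsAsFactors = FALSE))
    if (k > 1 && cvauc - best <= delta) {
      streak <- streak + 1L
    } else {
      streak <- 0L
    }
    best <- max(best, cvauc)
    if (streak >= patience) break
  }
  chosen_k <- trace$k[which.max(trace$mean_cv_auc)]  # smallest k on ties
  structure(list(trace = trace, chosen_k = chosen_k,
                 features = ranked[seq_len(chosen_k)],
                 delta = delta, patience = patience,
                 folds = length(unique(fold_id)), seed = as.integer(seed)),
            class = "selection_trace")
}

#' Default hyperparameter grid
#'
#' Penalty in \{L1, L2\}, strength in \{0.01, 0.1, 1, 10\}, class weights in
#' \{uniform, balanced\}, iteration cap in \{100, 1000\}. Row order defines
#' the deterministic tie-break.
#'
#' @return A `data.frame`, one row per hyperparameter combination.
#' @export
default_grid <- function() {
  expand.grid(penalty = c("l1", "l2"), strength = c(0.01, 0.1, 1, 10),
              class_weights = c("uniform", "balanced"),
              maxit = c(100L, 1000L),
              stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

#' Grid search over logistic hyperparameters by stratified CV AUC
#'
#' Exhaustively evaluates every grid row with the same stratified folds and
#' returns the combination with the highest mean out-of-fold AUC; ties are
#' broken by grid order (first row wins).
#'
#' @param X Training matrix.
#' @param y Training class labels.
#' @param features Fixed feature set (from [forward_select()]).
#' @param grid Hyperparameter grid (default [default_grid()]).
#' @param folds Number of stratified folds.
#' @param seed Seed for the fold assignment.
#' @return List: `best` (hyperparameter list), `results` (grid with a
#'   `mean_cv_auc` column).
#' @export
grid_search_cv <- function(X, y, features, grid = default_grid(),
                           folds = 5, seed = 1L) {
  stopifnot(nrow(grid) >= 1, all(features %in% colnames(X)))
  y01 <- .class01(y)
  fold_id <- make_stratified_folds(y01, folds, seed)
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    hyper <- as.list(grid[i, , drop = FALSE])
    .cv_mean_auc(X, y01, features, fold_id, hyper)
  }, numeric(1))
  best_i <- which.max(scores)  # which.max returns the first maximum
  results <- cbind(grid, mean_cv_auc = scores)
  best <- as.list(grid[best_i, , drop = FALSE])
  best$maxit <- as.integer(best$maxit)
  list(best = best, results = results)
}

#' Youden-index decision threshold
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' sorted scores plus -Inf/+Inf sentinels; the returned threshold maximizes
#' J = sensitivity + specificity - 1 under the rule `score >= threshold`
#' implies malignant. Ties are broken toward higher specificity, then lower
#' threshold. When every cutoff gives J = 0 (e.g. all scores equal) the
#' sentinel is returned with a warning.
#'
#' @param scores Prediction scores.
#' @param labels Class labels (malignant = positive; both classes required).
#' @return The threshold, with attributes `youden` (J), `sensitivity` and
#'   `specificity` at the threshold.
#' @export
youden_threshold <- function(scores, labels) {
  y <- .class01(labels)
  if (length(unique(y)) < 2) {
    stop("youden_threshold: both classes required", call. = FALSE)
  }
  us <- sort(unique(scores))
  cand <- c(-Inf, if (length(us) > 1) (us[-1] + us[-length(us)]) / 2, Inf)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  sens <- vapply(cand, function(t) sum(scores >= t & y == 1) / n1, numeric(1))
  spec <- vapply(cand, function(t) sum(scores < t & y == 0) / n0, numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[spec[best] == max(spec[best])]
  best <- best[which.min(cand[best])]
  thr <- cand[best]
  if (max(j) <= 0) {
    warning("youden_threshold: no cutoff separates the classes (J = 0); ",
            "sentinel threshold returned")
  }
  structure(thr, youden = j[best], sensitivity = sens[best],
            specificity = spec[best])
}

#' Fit the final classifier and attach its decision threshold
#'
#' Fits the regularized logistic model on the selected features and attaches
#' the Youden-index threshold computed on the training predictions. A
#' degenerate (infinite) threshold falls back to 0.5 with a warning.
#'
#' @param X Training matrix.
#' @param y Training class labels.
#' @param features Selected feature ids.
#' @param hyper Hyperparameter list (`penalty`, `strength`, `class_weights`,
#'   `maxit`), e.g. `grid_search_cv(...)$best`.
#' @return List of class `breath_classifier`: `features`, `coefficients`,
#'   `intercept`, `hyper`, `threshold`, `train_scores`.
#' @export
fit_final <- function(X, y, features, hyper = default_selection_hyper()) {
  stopifnot(all(features %in% colnames(X)))
  y01 <- .class01(y)
  fit <- fit_logistic(X[, features, drop = FALSE], y01,
                      penalty = hyper$penalty, strength = hyper$strength,
                      class_weights = hyper$class_weights,
                      maxit = hyper$maxit)
  scores <- predict(fit, X[, features, drop = FALSE])
  thr <- youden_threshold(scores, y01)
  if (!is.finite(thr)) {
    warning("fit_final: degenerate Youden threshold; falling back to 0.5")
    thr <- 0.5
  }
  structure(list(features = features,
                 coefficients = fit$coefficients,
                 intercept = fit$intercept,
                 hyper = hyper,
                 threshold = as.numeric(thr),
                 train_scores = scores),
            class = "breath_classifier")
}

#' @export
predict.breath_classifier <- function(object, newdata,
                                      type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  prob <- stats::plogis(object$intercept + drop(X %*% object$coefficients))
  if (type == "prob") return(prob)
  ifelse(prob >= object$threshold, "malignant", "benign")
}

#' @export
print.breath_classifier <- function(x, ...) {
  cat("Regularized logistic breath-VOC classifier\n")
  cat(sprintf("  %d features; penalty %s, strength %g, weights %s\n",
              length(x$features), x$hyper$penalty, x$hyper$strength,
              x$hyper$class_weights))
  cat(sprintf("  decision threshold (Youden): %.4f\n", x$threshold))
  invisible(x)
}
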