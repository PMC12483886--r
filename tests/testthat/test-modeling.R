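make_sheet <- function(n_mal, n_ben) {
  n <- n_mal + n_ben
  sample_sheet(sample_id = sprintf("s%03d", 1:n),
               class = rep(c("malignant", "benign"), c(n_mal, n_ben)),
               subtype = rep(c("LC", "benign_nodule"), c(n_mal, n_ben)),
               stage = "unknown", timepoint = "preop",
               pair_id = sprintf("p%03d", 1:n))
}

test_that("stratified split hits the floor(0.6 n) discovery size", {
  sheet <- make_sheet(97, 35)
  sp <- stratified_split(sheet, seed = 4)
  expect_length(sp$train_ids, 79)
  expect_length(sp$test_ids, 53)
  expect_setequal(c(sp$train_ids, sp$test_ids), sheet$sample_id)
  # class allocation within one sample of the stratified ideal
  tr_cls <- sheet$class[match(sp$train_ids, sheet$sample_id)]
  expect_lt(abs(sum(tr_cls == "malignant") - 79 * 97 / 132), 1)

  sheet2 <- make_sheet(5, 5)
  sp2 <- stratified_split(sheet2, seed = 1)
  tr2 <- sheet2$class[match(sp2$train_ids, sheet2$sample_id)]
  expect_equal(unname(table(tr2)["malignant"]), 3)
  expect_equal(unname(table(tr2)["benign"]), 3)

  expect_identical(stratified_split(sheet, seed = 99),
                   stratified_split(sheet, seed = 99))
  # post-operative samples are never eligible
  sheet3 <- make_sheet(10, 10)
  sheet3$timepoint[1:2] <- "postop"
  sp3 <- stratified_split(sheet3, seed = 2)
  expect_false(any(sheet3$sample_id[1:2] %in%
                     c(sp3$train_ids, sp3$test_ids)))
})

test_that("feature ranking uses symmetric AUC with documented tie-breaks", {
  set.seed(8)
  n <- 12
  y <- rep(c("malignant", "benign"), each = 6)
  X <- cbind(perfect = ifelse(y == "malignant", 1, 0) + rnorm(n, 0, 0.01),
             inverse = ifelse(y == "malignant", -2, 2) + rnorm(n, 0, 0.05),
             noise = rnorm(n))
  rownames(X) <- paste0("s", 1:n)
  rk <- rank_features(X, y, colnames(X))
  expect_identical(rk$feature[1:2] %in% c("perfect", "inverse"),
                   c(TRUE, TRUE))  # inverse direction treated symmetrically
  expect_identical(rk$feature[3], "noise")
  # brute-force pairwise oracle agrees with the ranking AUCs
  y01 <- as.integer(y == "malignant")
  for (j in colnames(X)) {
    expect_equal(rk$auc[rk$feature == j], pairwise_auc(X[, j], y01),
                 tolerance = 1e-12)
  }
  # ties broken by smaller p-value, then id
  Xt <- cbind(b_feat = X[, "perfect"], a_feat = X[, "perfect"])
  rk2 <- rank_features(Xt, y, colnames(Xt),
                       p_values = c(b_feat = 0.001, a_feat = 0.01))
  expect_identical(rk2$feature, c("b_feat", "a_feat"))
  rk3 <- rank_features(Xt, y, colnames(Xt),
                       p_values = c(b_feat = 0.01, a_feat = 0.01))
  expect_identical(rk3$feature, c("a_feat", "b_feat"))
})

test_that("forward selection finds a planted single informative feature", {
  ks <- integer(10)
  included <- logical(10)
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 60
    y <- rep(c("malignant", "benign"), each = n / 2)
    X <- matrix(rnorm(n * 51), n, 51,
                dimnames = list(paste0("s", 1:n),
                                c("signal", paste0("noise", 1:50))))
    X[, "signal"] <- X[, "signal"] + ifelse(y == "malignant", 2.5, 0)
    rk <- rank_features(X, y, colnames(X))
    tr <- forward_select(X, y, rk$feature, seed = s)
    ks[s] <- tr$chosen_k
    included[s] <- "signal" %in% tr$features
    # the trace has no gaps up to the stop point
    expect_identical(tr$trace$k, seq_len(nrow(tr$trace)))
  }
  expect_true(all(included))
  expect_lte(median(ks), 3)
})

test_that("grid search is exhaustive with grid-order tie-breaking", {
  set.seed(21)
  n <- 40
  y <- rep(c("malignant", "benign"), each = n / 2)
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  X[, "f1"] <- ifelse(y == "malignant", 3, -3) + rnorm(n, 0, 0.1)
  rownames(X) <- paste0("s", 1:n)

  g1 <- data.frame(penalty = "l2", strength = 0.1,
                   class_weights = "uniform", maxit = 1000L,
                   stringsAsFactors = FALSE)
  expect_identical(grid_search_cv(X, y, "f1", grid = g1, seed = 3)$best,
                   as.list(g1))

  # separable data: every mild penalty reaches CV AUC 1 -> first row wins
  g2 <- expand.grid(penalty = c("l1", "l2"), strength = c(0.01, 0.1),
                    class_weights = "uniform", maxit = 1000L,
                    stringsAsFactors = FALSE)
  res <- grid_search_cv(X, y, "f1", grid = g2, seed = 3)
  expect_true(all(res$results$mean_cv_auc == 1))
  expect_identical(res$best, as.list(g2[1, , drop = FALSE]))

  # exhaustive oracle: independently recompute each cell with the same folds
  y01 <- as.integer(y == "malignant")
  folds <- make_stratified_folds(y01, 5, seed = 3)
  g3 <- default_grid()[c(1, 8, 17, 26), ]
  res3 <- grid_search_cv(X, y, c("f1", "f2"), grid = g3, seed = 3)
  oracle <- sapply(seq_len(nrow(g3)), function(i) {
    mean(sapply(1:5, function(f) {
      fit <- fit_logistic(X[folds != f, c("f1", "f2")], y01[folds != f],
                          penalty = g3$penalty[i], strength = g3$strength[i],
                          class_weights = g3$class_weights[i],
                          maxit = g3$maxit[i])
      roc_auc(predict(fit, X[folds == f, c("f1", "f2")]), y01[folds == f])
    }))
  })
  expect_equal(res3$results$mean_cv_auc, oracle, tolerance = 1e-12)
  best_i <- which.max(oracle)
  expect_equal(res3$best$penalty, g3$penalty[best_i])
  expect_equal(res3$best$strength, g3$strength[best_i])
  expect_equal(res3$best$class_weights, g3$class_weights[best_i])
})

test_that("the ridge logistic fit matches an independent IRLS oracle", {
  set.seed(55)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y01 <- rbinom(n, 1, plogis(X[, 1] - 0.5 * X[, 2]))
  lambda <- 0.05
  fit <- fit_logistic(X, y01, penalty = "l2", strength = lambda)

  # penalized IRLS for the objective -(1/n) loglik + (lambda/2)||beta||^2
  Xi <- cbind(1, X)
  beta <- rep(0, 4)
  pen <- diag(c(0, 1, 1, 1)) * lambda
  for (it in 1:200) {
    eta <- drop(Xi %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y01 - mu) / w
    A <- crossprod(Xi, Xi * w) / n + pen
    beta_new <- solve(A, crossprod(Xi, w * z) / n)
    if (max(abs(beta_new - beta)) < 1e-12) { beta <- beta_new; break }
    beta <- beta_new
  }
  expect_equal(unname(fit$intercept), unname(beta[1]), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients), unname(beta[-1]), tolerance = 1e-6)

  # flipping the labels flips the linear model
  flip <- fit_logistic(X, 1 - y01, penalty = "l2", strength = lambda)
  expect_equal(flip$coefficients, -fit$coefficients, tolerance = 1e-6)
  expect_equal(flip$intercept, -fit$intercept, tolerance = 1e-6)
})

test_that("the final model separates a trivially separable feature", {
  y <- rep(c("malignant", "benign"), each = 10)
  X <- matrix(c(rnorm(10, 3), rnorm(10, -3)), 20, 1,
              dimnames = list(paste0("s", 1:20), "f"))
  m <- fit_final(X, y, "f", list(penalty = "l2", strength = 1,
                                 class_weights = "uniform", maxit = 1000L))
  scores <- predict(m, X)
  expect_equal(roc_auc(scores, y), 1)
  expect_true(all(diff(scores[order(X[, "f"])]) >= 0))  # monotone in feature
  expect_gt(m$threshold, 0)
  expect_lt(m$threshold, 1)
  expect_identical(unname(predict(m, X, type = "class")[1]), "malignant")
})

test_that("the Youden threshold maximizes J with documented tie-breaks", {
  thr <- youden_threshold(c(0.8, 0.7, 0.5, 0.2),
                          c("malignant", "malignant", "benign", "benign"))
  expect_equal(as.numeric(thr), 0.6)
  expect_equal(attr(thr, "youden"), 1)

  expect_warning(t2 <- youden_threshold(rep(0.4, 6), rep(c(1, 0), 3)),
                 "sentinel")
  expect_false(is.finite(t2))

  # exhaustive oracle over random instances
  set.seed(66)
  for (i in 1:30) {
    n <- 30
    y01 <- rbinom(n, 1, 0.5)
    if (length(unique(y01)) < 2) y01[1:2] <- c(0, 1)
    scores <- round(rnorm(n), 2)  # rounding forces ties
    thr <- suppressWarnings(youden_threshold(scores, y01))
    jmax <- max(sapply(c(-Inf, sort(unique(scores)), Inf), function(t) {
      mean(scores[y01 == 1] >= t) + mean(scores[y01 == 0] < t) - 1
    }))
    j_at <- mean(scores[y01 == 1] >= thr) + mean(scores[y01 == 0] < thr) - 1
    expect_equal(j_at, jmax, tolerance = 1e-12)
  }
})

test_that("the training path never reads evaluation samples", {
  co <- generate_cohort(synthetic_config(n_malignant = 40, n_benign = 20,
                                         n_compounds = 60, effect_size = 1,
                                         postop_fraction = 0, seed = 12))
  qc <- apply_qc(co$peaks, co$snr)
  sheet <- co$sheet[co$sheet$sample_id %in% qc$report$retained_samples, ]
  split <- stratified_split(sheet, seed = 5)
  nm <- normalize_peaks(qc$peaks, reference_samples = split$train_ids)
  cfg <- pipeline_config(seed = 5)
  fit1 <- train_classifier(nm, sheet, split, config = cfg)

  poisoned <- nm
  poisoned[split$test_ids, ] <- matrix(
    rnorm(length(split$test_ids) * ncol(nm)), length(split$test_ids))
  fit2 <- train_classifier(poisoned, sheet, split, config = cfg)
  expect_identical(fit1$model$coefficients, fit2$model$coefficients)
  expect_identical(fit1$model$threshold, fit2$model$threshold)
  expect_identical(fit1$screening$candidate, fit2$screening$candidate)
})
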