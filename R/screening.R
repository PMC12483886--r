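# Dual-criteria differential-VOC screening: per-compound Wilcoxon rank-sum
# p-values combined with OPLS-DA variable importance in projection (VIP),
# then exclusion-list filtering of known contaminants/drug metabolites.

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value by enumeration when the smaller group has at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with tie-corrected variance and continuity correction. Two samples with
#' all values identical carry no evidence and return p = 1.
#'
#' @param x,y Numeric vectors for the two groups (both non-empty).
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("rank_sum_test: both groups must be non-empty", call. = FALSE)
  }
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(1)
  has_ties <- anyDuplicated(pooled) > 0
  exact <- min(length(x), length(y)) <= 8 && !has_ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  min(1, res$p.value)
}

#' Fit an OPLS-DA model with a single predictive component
#'
#' Orthogonal projections to latent structures discriminant analysis for a
#' binary outcome: `n_orthogonal` components capturing systematic variation
#' orthogonal to the class are removed from `X` before the final
#' one-component PLS fit, concentrating the class-predictive variation in a
#' single predictive component. With `n_orthogonal = 0` the model is exactly
#' one-component PLS-DA.
#'
#' @param X Numeric matrix (samples x compounds); columns are centered
#'   internally.
#' @param y Class labels (`malignant`/`benign`, logical, or 0/1); encoded
#'   as a centered +/-1 response.
#' @param n_orthogonal Number of orthogonal components to strip (>= 0).
#' @return List of class `opls_model`: predictive weights `w` (unit norm),
#'   loadings `p_load`, scores `t_pred`, regression scalar `q`, orthogonal
#'   `w_ortho`/`p_ortho`/`t_ortho` matrices, `explained_y_variance` (R2Y of
#'   the predictive component on the deflated data), column `means`, and the
#'   number of compounds `p`.
#' @export
fit_oplsda <- function(X, y, n_orthogonal = 1) {
  X <- as.matrix(X)
  y01 <- .class01(y)
  if (length(unique(y01)) < 2L) {
    stop("fit_oplsda: y must contain both classes", call. = FALSE)
  }
  if (n_orthogonal < 0) stop("fit_oplsda: n_orthogonal must be >= 0",
                             call. = FALSE)
  if (n_orthogonal + 1 > qr(scale(X, scale = FALSE))$rank) {
    stop("fit_oplsda: more components requested than the rank of X supports",
         call. = FALSE)
  }
  means <- colMeans(X)
  Xc <- sweep(X, 2, means)
  yc <- ifelse(y01 == 1, 1, -1)
  yc <- yc - mean(yc)

  p <- ncol(X)
  W_o <- P_o <- matrix(0, p, 0)
  T_o <- matrix(0, nrow(X), 0)
  Xd <- Xc
  weight_vec <- function(M) {
    w <- drop(crossprod(M, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("fit_oplsda: degenerate weight vector", call. = FALSE)
    w / nw
  }
  for (k in seq_len(n_orthogonal)) {
    w <- weight_vec(Xd)
    t_pred <- drop(Xd %*% w)
    p_load <- drop(crossprod(Xd, t_pred)) / sum(t_pred^2)
    w_o <- p_load - drop(crossprod(w, p_load)) * w
    nw_o <- sqrt(sum(w_o^2))
    if (nw_o < 1e-10) {
      stop("fit_oplsda: no orthogonal variation left for component ", k,
           call. = FALSE)
    }
    w_o <- w_o / nw_o
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
  }
  w <- weight_vec(Xd)
  t_pred <- drop(Xd %*% w)
  p_load <- drop(crossprod(Xd, t_pred)) / sum(t_pred^2)
  q <- sum(yc * t_pred) / sum(t_pred^2)
  r2y <- 1 - sum((yc - q * t_pred)^2) / sum(yc^2)
  structure(list(w = stats::setNames(w, colnames(X)),
                 p_load = p_load, t_pred = t_pred, q = q,
                 w_ortho = W_o, p_ortho = P_o, t_ortho = T_o,
                 explained_y_variance = r2y,
                 n_orthogonal = n_orthogonal, means = means, p = p),
            class = "opls_model")
}

#' VIP scores of an OPLS-DA model
#'
#' Variable importance in projection over the predictive component only (the
#' standard OPLS-DA convention: orthogonal variation has already been
#' filtered out). With a single predictive component this reduces to
#' `sqrt(p) * |w_j| / ||w||`, so the squared scores always sum to the number
#' of compounds.
#'
#' @param model A fitted [fit_oplsda()] model.
#' @return Named non-negative vector of VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  w <- model$w
  sqrt(model$p) * abs(w) / sqrt(sum(w^2))
}

#' Screen compounds for candidate biomarkers
#'
#' Computes, per compound, the two-sided rank-sum p-value, the OPLS-DA VIP
#' score, and the univariate AUC against the class. A compound is flagged
#' `candidate` iff `p_value < alpha` (strict) and `vip > vip_cutoff`
#' (strict) and it is not on the exclusion list.
#'
#' @param X Normalized matrix (training samples only), samples x compounds.
#' @param y Class labels (malignant = positive).
#' @param exclusion Character vector of compound ids to exclude (drug
#'   metabolites, environmental contaminants, ...).
#' @param alpha Significance cutoff (default 0.05).
#' @param vip_cutoff VIP cutoff (default 1).
#' @param n_orthogonal Orthogonal components for the OPLS-DA fit (default 1).
#' @param retention_times Optional named per-compound retention times carried
#'   into the output.
#' @return A `data.frame` of class `screening_table` with columns
#'   `compound_id`, `retention_time`, `p_value`, `vip`, `auc`, `candidate`,
#'   `excluded`, one row per compound in column order of `X`.
#' @export
screen_compounds <- function(X, y, exclusion = character(),
                             alpha = 0.05, vip_cutoff = 1, n_orthogonal = 1,
                             retention_times = NULL) {
  X <- as.matrix(X)
  y01 <- .class01(y)
  if (length(unique(y01)) < 2L) {
    stop("screen_compounds: both classes required", call. = FALSE)
  }
  ids <- colnames(X)
  pvals <- vapply(seq_len(ncol(X)), function(j) {
    rank_sum_test(X[y01 == 1, j], X[y01 == 0, j])
  }, numeric(1))
  model <- fit_oplsda(X, y01, n_orthogonal = n_orthogonal)
  vip <- vip_scores(model)
  auc <- vapply(seq_len(ncol(X)), function(j) roc_auc(X[, j], y01), numeric(1))
  excluded <- ids %in% exclusion
  candidate <- pvals < alpha & vip > vip_cutoff & !excluded
  rt <- rep(NA_real_, length(ids))
  if (!is.null(retention_times)) {
    rt <- as.numeric(retention_times[ids])
  }
  out <- data.frame(compound_id = ids, retention_time = rt,
                    p_value = pvals, vip = as.numeric(vip), auc = auc,
                    candidate = candidate, excluded = excluded,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("screening_table", "data.frame")
  out
}
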