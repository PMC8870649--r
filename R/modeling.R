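# Discriminant-analysis classification with stratified k-fold
# cross-validation, ROC construction, AUC, and Youden cut-off.

#' Cross-validation configuration
#'
#' @param k Number of folds (default 5; disjoint validation sets, so
#'   leave-one-out is deliberately not offered as a default).
#' @param seed Integer seed controlling fold assignment.
#' @param stratified Preserve per-class proportions within each fold?
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(k = 5, seed = 1, stratified = TRUE) {
  if (!is_count(k) || k < 2) stopf("k must be an integer >= 2")
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "cv_config")
}

#' Stratified k-fold assignment
#'
#' @param n Number of rows.
#' @param labels 0/1 vector of length `n`.
#' @param cv A [cv_config()].
#' @return Integer vector of fold ids in `1..k`; reproducible for a fixed
#'   seed, per-class proportions preserved within one row when stratified.
#' @export
kfold_split <- function(n, labels, cv = cv_config()) {
  if (n < cv$k) stopf("need at least k = %d rows, got %d", cv$k, n)
  if (length(labels) != n) stopf("labels must have length n")
  folds <- integer(n)
  with_seed(cv$seed, {
    if (cv$stratified) {
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        folds[idx] <- rep_len(seq_len(cv$k), length(idx))
      }
    } else {
      folds[sample.int(n)] <- rep_len(seq_len(cv$k), n)
    }
  })
  for (f in seq_len(cv$k))
    if (length(unique(labels[folds != f])) < 2)
      stopf("fold %d leaves a single-class training set", f)
  folds
}

# Pooled-covariance Gaussian (linear) discriminant fit.
lda_fit <- function(x, labels, reg = 1e-8) {
  x <- as.matrix(x)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stopf("discriminant fit needs exactly two classes")
  means <- lapply(classes, function(cl) colMeans(x[labels == cl, , drop = FALSE]))
  n <- nrow(x); p <- ncol(x)
  sw <- matrix(0, p, p)
  for (cl in classes) {
    xc <- scale(x[labels == cl, , drop = FALSE], center = TRUE, scale = FALSE)
    sw <- sw + crossprod(xc)
  }
  sigma <- sw / (n - 2)
  prior <- vapply(classes, function(cl) mean(labels == cl), 0)
  inv <- tryCatch(solve(sigma), error = function(e) NULL)
  if (is.null(inv)) {
    warning("singular pooled covariance; regularizing with scaled identity",
            call. = FALSE)
    sigma <- sigma + diag(reg * max(mean(diag(sigma)), 1), p)
    inv <- solve(sigma)   # still singular -> hard error
  }
  list(classes = classes, means = means, prior = prior, sigma_inv = inv)
}

# Posterior probability of the FIRST class (classes are sorted, so with
# 0/1 labels this is P(class 0 | x)).
lda_posterior <- function(fit, x) {
  x <- as.matrix(x)
  disc <- vapply(seq_along(fit$classes), function(k) {
    m <- fit$means[[k]]
    drop(x %*% (fit$sigma_inv %*% m)) -
      0.5 * drop(t(m) %*% fit$sigma_inv %*% m) + log(fit$prior[k])
  }, numeric(nrow(x)))
  disc <- matrix(disc, nrow = nrow(x))
  w <- exp(disc - apply(disc, 1, max))
  w[, 1] / rowSums(w)
}

#' Out-of-fold discriminant scores
#'
#' For each fold, a linear discriminant model (class-conditional Gaussians
#' with pooled covariance) is fitted on the training rows; validation rows
#' receive the posterior probability of class 0 (non-responder). Every row
#' is scored exactly once.
#'
#' @param table Data frame containing the feature columns.
#' @param features Character vector of retained feature names.
#' @param labels 0/1 vector (0 = non-responder).
#' @param cv A [cv_config()].
#' @return Numeric vector of out-of-fold scores, one per row (higher =
#'   more non-responder-like). Attribute `folds` records the assignment.
#' @export
cross_validated_scores <- function(table, features, labels, cv = cv_config()) {
  x <- as.matrix(table[, features, drop = FALSE])
  if (anyNA(x)) stopf("missing values in the selected features")
  n <- nrow(x)
  folds <- kfold_split(n, labels, cv)
  scores <- numeric(n)
  for (f in seq_len(cv$k)) {
    tr <- folds != f
    fit <- lda_fit(x[tr, , drop = FALSE], labels[tr])
    scores[!tr] <- lda_posterior(fit, x[!tr, , drop = FALSE])
  }
  attr(scores, "folds") <- folds
  scores
}

#' Empirical ROC curve, AUC and Youden cut-off
#'
#' The curve is evaluated at every distinct score (rule: predict positive
#' when `score >= threshold`), plus sentinels. AUC uses the trapezoidal
#' rule, which equals the Mann-Whitney U statistic normalized by
#' `n1 * n0`. The Youden cut-off maximizes `J = sens + spec - 1`, ties
#' broken toward the lower threshold (higher sensitivity).
#'
#' @param scores Numeric scores, higher = more positive-class-like.
#' @param labels Binary labels.
#' @param positive The label value treated as positive for sensitivity
#'   (default `0`, the non-responder class).
#' @return An object of class `roc_result`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `auc`, `youden_cutoff`,
#'   `sens_at_cutoff`, `spec_at_cutoff`, `j_at_cutoff`.
#' @export
roc_curve <- function(scores, labels, positive = 0) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), 0)
  # rank-based AUC (trapezoid over the empirical curve, ties -> 1/2)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.min(thr[best])]
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, youden_cutoff = thr[best],
                 sens_at_cutoff = sens[best], spec_at_cutoff = spec[best],
                 j_at_cutoff = j[best], positive = positive),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f; Youden cut-off %.4g (sens %.1f%%, spec %.1f%%)\n",
    x$auc, x$youden_cutoff, 100 * x$sens_at_cutoff, 100 * x$spec_at_cutoff))
  invisible(x)
}

#' Youden-index optimal cut-off
#'
#' @param roc A [roc_curve()] result.
#' @return List with `cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
youden_cutoff <- function(roc) {
  list(cutoff = roc$youden_cutoff, sensitivity = roc$sens_at_cutoff,
       specificity = roc$spec_at_cutoff, j = roc$j_at_cutoff)
}

#' Single-feature ROC analysis
#'
#' Uses the raw feature as the score, oriented so that a higher score
#' indicates the positive (non-responder) class: the feature is negated
#' when its point-biserial correlation with the positive-class indicator
#' is negative.
#'
#' @param feature Numeric feature values.
#' @param labels Binary labels.
#' @param positive Positive-class label value (default 0, non-responder).
#' @return A [roc_curve()] result; attribute `flipped` records whether the
#'   orientation was inverted.
#' @export
single_feature_roc <- function(feature, labels, positive = 0) {
  r <- suppressWarnings(point_biserial(feature, as.numeric(labels == positive)))
  flipped <- !is.na(r) && r < 0
  roc <- roc_curve(if (flipped) -feature else feature, labels, positive)
  if (flipped) roc$youden_cutoff <- -roc$youden_cutoff
  attr(roc, "flipped") <- flipped
  roc
}
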