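# Mixed descriptive-inferential feature reduction: point-biserial ranking
# followed by one-at-a-time forward logistic regression with a p-value
# stopping rule.

#' Point-biserial correlation
#'
#' The Pearson correlation between a continuous feature and a 0/1 outcome.
#'
#' @param feature Numeric vector.
#' @param labels 0/1 vector of the same length.
#' @return Correlation in `[-1, 1]`; `NA` (with a warning) when the feature
#'   is constant or only one class is present.
#' @export
point_biserial <- function(feature, labels) {
  if (length(feature) != length(labels)) stopf("length mismatch")
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  if (length(unique(labels)) < 2 || stats::sd(feature) == 0) {
    warning("point-biserial undefined (constant feature or single class)",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(feature, as.numeric(labels))
}

#' Rank features by point-biserial correlation with the outcome
#'
#' Features are sorted by `|pbc|` descending (signed descending via
#' `sort_mode`), with lexicographic name order breaking ties for
#' determinism. Features with undefined pbc (constant, or missing values)
#' are dropped with a logged reason.
#'
#' @param table Data frame of candidate feature columns (numeric).
#' @param labels 0/1 outcome vector, one per row.
#' @param sort_mode `"abs"` (default) or `"signed"`.
#' @return Data frame `feature`, `pbc` in rank order; dropped features in
#'   attribute `dropped`.
#' @export
rank_features <- function(table, labels, sort_mode = c("abs", "signed")) {
  sort_mode <- match.arg(sort_mode)
  nm <- colnames(table)
  pbc <- vapply(nm, function(f) {
    x <- table[[f]]
    if (anyNA(x) || !is.numeric(x) || stats::sd(x) == 0) return(NA_real_)
    suppressWarnings(point_biserial(x, labels))
  }, 0)
  dropped <- nm[is.na(pbc)]
  keep <- !is.na(pbc)
  nm <- nm[keep]; pbc <- pbc[keep]
  key <- if (sort_mode == "abs") -abs(pbc) else -pbc
  ord <- order(key, nm)
  out <- data.frame(feature = nm[ord], pbc = pbc[ord])
  attr(out, "dropped") <- dropped
  out
}

fit_logistic <- function(table, labels, feats) {
  d <- data.frame(.y = labels, table[, feats, drop = FALSE], check.names = FALSE)
  ok <- TRUE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = d, family = stats::binomial()),
    warning = function(w) {
      ok <<- FALSE
      invokeRestart("muffleWarning")
    })
  list(fit = fit, converged = ok && fit$converged)
}

#' Forward logistic feature selection with a growing-p stopping rule
#'
#' Step `k` fits a maximum-likelihood logistic model on the top-`k` ranked
#' features and records a p-value; iteration stops the first time the
#' p-value exceeds the previous step's, and the retained set is the prefix
#' of the previous (best) step. By default the monitored p-value is the
#' model-vs-intercept likelihood-ratio p (`p_mode = "lrt"`), the only
#' p-value defined for every multi-feature step; alternatives are the
#' incremental model-vs-previous 1-df LRT (`"inc"`) and the newest
#' coefficient's Wald p (`"wald"`). A non-convergent or separated fit is
#' treated as a growing p-value (stop, with a warning).
#'
#' @param table Data frame of candidate features.
#' @param labels 0/1 outcome vector.
#' @param sort_mode Passed to [rank_features()].
#' @param p_mode Which p-value sequence to monitor.
#' @return A `selection_result`: list with `ranking` (from
#'   [rank_features()]), `retained` (character vector, a prefix of the
#'   ranking), `p_trace` (p-value per attempted step), `stop_step`, and
#'   `wald_p` (per-coefficient Wald p-values of the retained model).
#' @export
forward_select <- function(table, labels, sort_mode = c("abs", "signed"),
                           p_mode = c("lrt", "inc", "wald")) {
  sort_mode <- match.arg(sort_mode)
  p_mode <- match.arg(p_mode)
  ranking <- rank_features(table, labels, sort_mode)
  feats <- ranking$feature
  if (length(feats) == 0) stopf("no usable features to select from")
  p_trace <- numeric(0)
  prev_p <- Inf
  prev_dev <- NULL
  stop_step <- 0L
  best_fit <- NULL
  for (k in seq_along(feats)) {
    res <- fit_logistic(table, labels, feats[seq_len(k)])
    if (!res$converged) {
      warning(sprintf(
        "logistic fit did not converge cleanly at step %d (possible separation); stopping", k),
        call. = FALSE)
      p_trace <- c(p_trace, NA_real_)
      break
    } else {
      fit <- res$fit
      p <- switch(p_mode,
        lrt = stats::pchisq(fit$null.deviance - fit$deviance, df = k,
                            lower.tail = FALSE),
        inc = {
          d0 <- if (k == 1) fit$null.deviance else prev_dev
          stats::pchisq(d0 - fit$deviance, df = 1, lower.tail = FALSE)
        },
        wald = stats::coef(summary(fit))[k + 1L, "Pr(>|z|)"])
      prev_dev <- fit$deviance
    }
    p_trace <- c(p_trace, p)
    if (p > prev_p) break
    prev_p <- p
    stop_step <- k
    best_fit <- res$fit
  }
  if (stop_step == 0L) {
    # step 1 already failed to converge (e.g. perfect separation): retain
    # the top-ranked feature, which needs no model to be defined
    stop_step <- 1L
    best_fit <- NULL
  }
  retained <- feats[seq_len(stop_step)]
  wald_p <- if (!is.null(best_fit))
    stats::coef(summary(best_fit))[-1, "Pr(>|z|)", drop = TRUE] else NULL
  structure(list(ranking = ranking, retained = retained, p_trace = p_trace,
                 stop_step = stop_step, p_mode = p_mode, wald_p = wald_p),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> retained %d feature(s): %s\n",
              length(x$retained), paste(x$retained, collapse = ", ")))
  cat(sprintf("  p-trace (%s): %s\n", x$p_mode,
              paste(signif(x$p_trace, 3), collapse = " -> ")))
  invisible(x)
}

#' Prepare clinical covariates for selection
#'
#' Grading enters as an ordinal numeric (1/2/3); chromogranin A values are
#' log-transformed (`log(1 + x)`) because they are strongly right-skewed.
#' `CgA_post` post-dates therapy and is excluded from the default predictor
#' set; set `include_cga_post = TRUE` to restore it.
#'
#' @param clinical Data frame with any of `Grading`, `PRRT_cycles`,
#'   `cumulative_activity_GBq`, `CgA_pre`, `CgA_post`.
#' @param include_cga_post Keep the post-therapy CgA column?
#' @return Transformed data frame.
#' @export
prepare_clinical <- function(clinical, include_cga_post = FALSE) {
  out <- clinical
  if ("Grading" %in% names(out)) out$Grading <- as.numeric(out$Grading)
  for (col in c("CgA_pre", "CgA_post"))
    if (col %in% names(out)) out[[col]] <- log1p(out[[col]])
  if (!include_cga_post) out$CgA_post <- NULL
  out
}
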