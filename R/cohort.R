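# Group-difference testing, per-site sub-analyses, delta-radiomics
# summaries, and report tables.

#' Mann-Whitney U test
#'
#' `U` counts pairs where a value of `a` exceeds a value of `b` (ties
#' count one half), so `U = 0` when every `a` lies below every `b` and
#' `U = n1*n2/2` for identical samples. The two-sided p-value uses the
#' exact U distribution when there are no ties and `min(n1, n2) <= 8`
#' (configurable), and a tie-corrected normal approximation with
#' continuity correction otherwise.
#'
#' @param a,b Numeric samples (both non-empty).
#' @param exact_max Largest `min(n1, n2)` for which the exact distribution
#'   is used (ties always force the approximation).
#' @return List with `U`, `p`, `n1`, `n2`, `method`.
#' @export
mann_whitney <- function(a, b, exact_max = 8) {
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0 || n2 == 0) stopf("both groups must be non-empty")
  all_v <- c(a, b)
  r <- rank(all_v)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(all_v)
  has_ties <- any(ties > 1)
  if (!has_ties && min(n1, n2) <= exact_max) {
    method <- "exact"
    p <- min(1, 2 * min(stats::pwilcox(u, n1, n2),
                        stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)))
  } else {
    method <- "normal-approx"
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
    if (sigma == 0) return(list(U = u, p = 1, n1 = n1, n2 = n2, method = method))
    z <- (abs(u - mu) - 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  list(U = u, p = p, n1 = n1, n2 = n2, method = method)
}

#' Compare features between responders and non-responders
#'
#' Per feature: group location/dispersion summaries and a two-sided
#' Mann-Whitney p-value.
#'
#' @param table Data frame of feature columns.
#' @param labels 0/1 vector (1 = responder).
#' @param features Feature names (default: all numeric columns).
#' @return Data frame, one row per feature: group sizes, mean/sd/median
#'   per group, `U`, `p`.
#' @export
group_comparison <- function(table, labels, features = NULL) {
  if (is.null(features))
    features <- names(table)[vapply(table, is.numeric, TRUE)]
  rows <- lapply(features, function(f) {
    x <- table[[f]]
    keep <- !is.na(x)
    resp <- x[keep & labels == 1]; nonr <- x[keep & labels == 0]
    if (length(resp) == 0 || length(nonr) == 0) return(NULL)
    mw <- mann_whitney(nonr, resp)
    data.frame(feature = f, n_responder = length(resp),
               n_nonresponder = length(nonr),
               mean_responder = mean(resp), sd_responder = stats::sd(resp),
               median_responder = stats::median(resp),
               mean_nonresponder = mean(nonr), sd_nonresponder = stats::sd(nonr),
               median_nonresponder = stats::median(nonr),
               U = mw$U, p = mw$p)
  })
  do.call(rbind, rows)
}

#' Per-site (district) sub-analysis
#'
#' Restricts the cohort to one anatomical district, tests every feature
#' responder vs non-responder (Mann-Whitney), and attaches a
#' single-feature ROC/Youden analysis for each feature significant at
#' `alpha`. Following the reporting convention of the source workflow, a
#' ROC with AUC < 0.5 is flagged `not_informative`; the flipped-orientation
#' AUC (`1 - AUC`) is reported alongside, since AUC below chance usually
#' signals an inverted score direction.
#'
#' @param table Data frame with feature columns and a `district` column.
#' @param labels 0/1 vector (1 = responder).
#' @param district District to analyze.
#' @param features Feature names (default: all numeric columns except
#'   identifiers).
#' @param alpha Significance level gating the ROC analyses (default 0.05).
#' @return List with `district`, `comparisons` (data frame) and `roc`
#'   (named list of [roc_curve()] results with `not_informative` flags).
#' @export
per_site_analysis <- function(table, labels, district, features = NULL,
                              alpha = 0.05) {
  if (!"district" %in% names(table)) stopf("table must have a district column")
  sel <- table$district == district
  if (!any(sel)) stopf("district %s absent from the table", district)
  sub <- table[sel, , drop = FALSE]
  lab <- labels[sel]
  if (length(unique(lab)) < 2)
    stopf("district %s has a single response class", district)
  if (is.null(features)) {
    features <- names(sub)[vapply(sub, is.numeric, TRUE)]
    features <- setdiff(features, c("label", "dichotomous"))
  }
  cmp <- group_comparison(sub, lab, features)
  rocs <- list()
  for (f in cmp$feature[cmp$p < alpha]) {
    roc <- single_feature_roc(sub[[f]], lab, positive = 0)
    roc$not_informative <- roc$auc < 0.5
    roc$auc_flipped <- 1 - roc$auc
    rocs[[f]] <- roc
  }
  list(district = district, comparisons = cmp, roc = rocs)
}

#' Delta-radiomics group summary
#'
#' Per feature: mean, SD, median and range of the percent change per
#' response group, plus a two-sided Mann-Whitney p. Lesions with missing
#' deltas (zero baseline, or CR lesions without follow-up features) are
#' excluded pairwise.
#'
#' @param deltas Data frame with columns `lesion_id`, `feature`,
#'   `delta_percent`.
#' @param labels Data frame with columns `lesion_id`, `dichotomous`.
#' @return Data frame, one row per feature and group.
#' @export
delta_group_summary <- function(deltas, labels) {
  d <- merge(deltas, labels[, c("lesion_id", "dichotomous")], by = "lesion_id")
  d <- d[!is.na(d$delta_percent), ]
  rows <- lapply(unique(d$feature), function(f) {
    sub <- d[d$feature == f, ]
    resp <- sub$delta_percent[sub$dichotomous == 1]
    nonr <- sub$delta_percent[sub$dichotomous == 0]
    if (length(resp) == 0 && length(nonr) == 0) return(NULL)
    p <- if (length(resp) > 0 && length(nonr) > 0) mann_whitney(nonr, resp)$p
         else NA_real_
    grp <- function(g, v) if (length(v) == 0) NULL else
      data.frame(feature = f, group = g, n = length(v), mean = mean(v),
                 sd = stats::sd(v), median = stats::median(v),
                 min = min(v), max = max(v), p = p)
    rbind(grp("responder", resp), grp("non_responder", nonr))
  })
  do.call(rbind, rows)
}

#' Assemble the analysis report bundle
#'
#' Collects cohort composition (district and response-category counts),
#' per-district group comparisons, delta summaries and ROC summaries into
#' one bundle whose numbers are all traceable to the inputs.
#'
#' @param table Feature table with `district` column.
#' @param labels Data frame `lesion_id`, `category`, `dichotomous`
#'   (row-aligned with `table`).
#' @param deltas Optional delta data frame (see [delta_group_summary()]).
#' @param rocs Optional named list of [roc_curve()] results.
#' @param n_tests Number of hypothesis tests performed upstream (footnoted;
#'   no multiplicity correction is applied).
#' @return An object of class `petrad_report`.
#' @export
build_report <- function(table, labels, deltas = NULL, rocs = NULL,
                         n_tests = NA_integer_) {
  if (nrow(table) == 0) stopf("empty cohort: nothing to report")
  if (nrow(table) != nrow(labels)) stopf("table and labels are misaligned")
  cohort <- as.data.frame(table(district = table$district,
                                category = labels$category))
  district_totals <- stats::aggregate(Freq ~ district, cohort, sum)
  per_district <- lapply(unique(as.character(table$district)), function(d) {
    sel <- table$district == d
    if (length(unique(labels$dichotomous[sel])) < 2) return(NULL)
    cmp <- group_comparison(table[sel, , drop = FALSE],
                            labels$dichotomous[sel])
    cbind(district = d, cmp)
  })
  per_district <- do.call(rbind, per_district)
  delta_tab <- if (!is.null(deltas)) delta_group_summary(deltas, labels)
  roc_tab <- if (!is.null(rocs)) do.call(rbind, lapply(names(rocs), function(nm) {
    r <- rocs[[nm]]
    data.frame(model = nm, auc = r$auc, cutoff = r$youden_cutoff,
               sensitivity = r$sens_at_cutoff, specificity = r$spec_at_cutoff)
  }))
  structure(list(cohort = cohort, district_totals = district_totals,
                 per_district = per_district, deltas = delta_tab,
                 roc = roc_tab, n_lesions = nrow(table), n_tests = n_tests),
            class = "petrad_report")
}

#' Write a report bundle to CSV/JSON files
#'
#' @param report A [build_report()] bundle.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    if (is.null(df)) return()
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  emit(report$cohort, "cohort_composition.csv")
  emit(report$per_district, "per_district_comparisons.csv")
  emit(report$deltas, "delta_summary.csv")
  emit(report$roc, "roc_summary.csv")
  jsonlite::write_json(list(n_lesions = report$n_lesions,
                            n_tests = report$n_tests),
                       file.path(dir, "report_meta.json"), auto_unbox = TRUE)
  invisible(c(files, file.path(dir, "report_meta.json")))
}
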