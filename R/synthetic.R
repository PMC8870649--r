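# Synthetic-data generators: voxel-level lesions with controlled intensity
# moments, per-district feature cohorts with the published location/scale
# structure, paired T0/T1 cohorts, and machine-readable copies of the
# published summary tables used for calibration and testing.

#' Published per-district summary parameters
#'
#' Location ("median +/- DS" read as location/scale) and scale of
#' HISTO_Skewness, HISTO_Kurtosis and SUV_max for responder and
#' non-responder lesions in the three main districts, with the published
#' group sizes (lymph node 50/41, liver 108/61, bone 18/24
#' responder/non-responder).
#'
#' @return Data frame with columns `district`, `feature`, `group`, `mean`,
#'   `sd`, `n`.
#' @export
table2_params <- function() {
  row <- function(district, feature, group, mean, sd, n)
    data.frame(district = district, feature = feature, group = group,
               mean = mean, sd = sd, n = n)
  rbind(
    row("lymph_node", "HISTO_Skewness", "responder",     2.01,  2.12, 50),
    row("lymph_node", "HISTO_Skewness", "non_responder", 3.02,  1.44, 41),
    row("lymph_node", "HISTO_Kurtosis", "responder",    11.03, 11.79, 50),
    row("lymph_node", "HISTO_Kurtosis", "non_responder",13.72,  8.85, 41),
    row("lymph_node", "SUV_max",        "responder",    18.67, 12.14, 50),
    row("lymph_node", "SUV_max",        "non_responder",18.16, 13.86, 41),
    row("liver",      "HISTO_Skewness", "responder",     1.35,  2.25, 108),
    row("liver",      "HISTO_Skewness", "non_responder", 3.63,  1.90, 61),
    row("liver",      "HISTO_Kurtosis", "responder",     9.04, 11.90, 108),
    row("liver",      "HISTO_Kurtosis", "non_responder",19.34, 13.86, 61),
    row("liver",      "SUV_max",        "responder",    19.39, 10.17, 108),
    row("liver",      "SUV_max",        "non_responder",20.87, 10.14, 61),
    row("bone",       "HISTO_Skewness", "responder",     2.40,  1.89, 18),
    row("bone",       "HISTO_Skewness", "non_responder", 4.03,  1.87, 24),
    row("bone",       "HISTO_Kurtosis", "responder",    11.57, 12.83, 18),
    row("bone",       "HISTO_Kurtosis", "non_responder",23.13, 15.46, 24),
    row("bone",       "SUV_max",        "responder",    10.31,  9.41, 18),
    row("bone",       "SUV_max",        "non_responder",28.42, 28.61, 24))
}

#' Embedded published-cohort fixtures
#'
#' Machine-readable copies of the published cohort composition, response
#' distribution, grading, per-district summaries, delta summaries, and
#' headline ROC operating points, for tests and report validation.
#'
#' @return Named list: `districts`, `response`, `grading`,
#'   `grading_response` (responsive/total per grade), `table2`, `table3`,
#'   `roc` (per-analysis AUC/cut-off/sens/spec).
#' @export
paper_fixtures <- function() {
  delta_row <- function(district, feature, group, mean, sd, min, max)
    data.frame(district = district, feature = feature, group = group,
               mean = mean, sd = sd, min = min, max = max)
  list(
    n_patients = 38L,
    districts = c(liver = 169L, lymph_node = 91L, bone = 42L,
                  parenchymal_other = 22L),
    response = c(PD = 133L, SD = 79L, PR = 92L, CR = 20L),
    grading = c(G1 = 9L, G2 = 27L, G3 = 2L),
    grading_response = data.frame(
      grade = c("G1", "G2", "G3"),
      responsive = c(28L, 157L, 6L),
      total = c(82L, 232L, 10L)),
    table2 = table2_params(),
    table3 = rbind(
      delta_row("lymph_node", "HISTO_Skewness", "responder",      21.18, 265.75,  -880.0, 1533.3),
      delta_row("lymph_node", "HISTO_Skewness", "non_responder", 176.83, 469.34,   -96.3, 2550.0),
      delta_row("lymph_node", "HISTO_Kurtosis", "responder",      13.97,  83.08,   -82.9,  340.5),
      delta_row("lymph_node", "HISTO_Kurtosis", "non_responder",  -4.48,  40.84,   -85.2,   96.2),
      delta_row("liver",      "HISTO_Skewness", "responder",     -17.72, 865.36, -6300.0, 4800.0),
      delta_row("liver",      "HISTO_Skewness", "non_responder", 134.23, 324.32,  -180.0, 1203.82),
      delta_row("liver",      "HISTO_Kurtosis", "responder",       9.76,  52.45,   -94.83, 193.68),
      delta_row("liver",      "HISTO_Kurtosis", "non_responder",  14.64,  60.64,   -94.07, 175.68),
      delta_row("bone",       "HISTO_Skewness", "responder",       6.84,  70.95,  -125.0,  134.53),
      delta_row("bone",       "HISTO_Skewness", "non_responder", -24.54,  71.06,  -240.8,   56.6),
      delta_row("bone",       "HISTO_Kurtosis", "responder",      66.15, 113.10,   -28.1,  338.5),
      delta_row("bone",       "HISTO_Kurtosis", "non_responder",  -0.33,  41.43,   -55.7,  103.7)),
    roc = data.frame(
      analysis = c("all_skewness", "all_kurtosis", "all_combined", "all_suvmax",
                   "lymph_node_skewness", "lymph_node_kurtosis",
                   "liver_skewness", "liver_kurtosis",
                   "bone_skewness", "bone_kurtosis"),
      auc = c(0.745, 0.722, 0.744, 0.523, 0.67, 0.64, 0.76, 0.75, 0.73, 0.72),
      cutoff = c(2.45, 6.94, NA, NA, 2.45, 8.10, 1.94, 6.55, 3.33, 15.33),
      sensitivity = c(80.6, 61.2, 66.4, 36.7, 76, 76, 87, 87, 79, 79),
      specificity = c(67.2, 75.9, 70.3, 63.3, 60, 58, 67, 68, 78, 78)))
}

#' Cohort simulation specification
#'
#' @param districts Character vector of districts to draw (default: the
#'   three districts with published parameters).
#' @param params Data frame in the format of [table2_params()].
#' @param features Informative features to include (default skewness and
#'   kurtosis; `SUV_max` available).
#' @param n_noise Number of uninformative standard-normal noise features.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(districts = c("lymph_node", "liver", "bone"),
                        params = table2_params(),
                        features = c("HISTO_Skewness", "HISTO_Kurtosis"),
                        n_noise = 0, seed = 1) {
  if (any(params$sd <= 0)) stopf("all scale parameters must be positive")
  if (any(params$n < 2)) stopf("group sizes must be >= 2")
  missing <- setdiff(districts, unique(params$district))
  if (length(missing)) stopf("no parameters for district(s): %s",
                             paste(missing, collapse = ", "))
  structure(list(districts = districts, params = params, features = features,
                 n_noise = as.integer(n_noise), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Sample a per-district feature cohort
#'
#' Informative features are drawn from per-group normal distributions with
#' the configured location/scale; noise features are standard normal,
#' independent of the labels. Labels code 1 = responder.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with `lesion_id`, `district`, `label`, the
#'   informative features, and `noise_01..` columns.
#' @export
sample_feature_cohort <- function(spec) {
  with_seed(spec$seed, {
    blocks <- list()
    for (d in spec$districts) {
      for (g in c("responder", "non_responder")) {
        pd <- spec$params[spec$params$district == d & spec$params$group == g, ]
        pd <- pd[pd$feature %in% spec$features, , drop = FALSE]
        if (nrow(pd) == 0)
          stopf("no parameters for district %s group %s", d, g)
        n <- unique(pd$n)
        if (length(n) != 1)
          stopf("inconsistent group sizes for district %s group %s", d, g)
        cols <- lapply(seq_len(nrow(pd)), function(i)
          stats::rnorm(n, pd$mean[i], pd$sd[i]))
        names(cols) <- pd$feature
        blocks[[length(blocks) + 1L]] <- data.frame(
          district = d, label = if (g == "responder") 1L else 0L, cols,
          check.names = FALSE)
      }
    }
    out <- do.call(rbind, blocks)
    if (spec$n_noise > 0) {
      noise <- matrix(stats::rnorm(nrow(out) * spec$n_noise), nrow(out))
      colnames(noise) <- sprintf("noise_%02d", seq_len(spec$n_noise))
      out <- cbind(out, noise)
    }
    out <- cbind(lesion_id = sprintf("L%04d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out
  })
}

#' Lesion phantom specification
#'
#' @param n_voxels ROI size in voxels (>= 1).
#' @param mean_suv Target mean SUV of the raw intensities.
#' @param skewness Target raw-intensity skewness.
#' @param kurtosis Optional target kurtosis, only checked for feasibility
#'   (`kurtosis >= skewness^2 + 1`); the moment-matched generator's
#'   kurtosis follows from its skewness.
#' @param sd_suv Target SUV standard deviation (default `mean_suv / 4`).
#' @param semi_axes Ellipsoid semi-axes in voxels (default near-spherical,
#'   scaled to fit `n_voxels`).
#' @param spacing Voxel spacing in mm.
#' @param seed Integer seed.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(n_voxels = 500, mean_suv = 10, skewness = 1,
                        kurtosis = NULL, sd_suv = mean_suv / 4,
                        semi_axes = NULL, spacing = c(3, 3, 3), seed = 1) {
  if (!is_count(n_voxels) || n_voxels < 1) stopf("n_voxels must be >= 1")
  if (mean_suv <= 0 || sd_suv < 0) stopf("mean_suv must be > 0, sd_suv >= 0")
  if (!is.null(kurtosis) && kurtosis < skewness^2 + 1)
    stopf("infeasible moment targets: kurtosis < skewness^2 + 1")
  structure(list(n_voxels = as.integer(n_voxels), mean_suv = mean_suv,
                 skewness = skewness, kurtosis = kurtosis, sd_suv = sd_suv,
                 semi_axes = semi_axes, spacing = spacing,
                 seed = as.integer(seed)),
            class = "lesion_spec")
}

# Lognormal sigma^2 solving skew = (w + 2) sqrt(w - 1), w = exp(sigma^2).
lognormal_shape <- function(skew) {
  s <- abs(skew)
  f <- function(w) (w + 2) * sqrt(w - 1) - s
  w <- stats::uniroot(f, c(1 + 1e-12, 1e6))$root
  sqrt(log(w))
}

# Draw n values with the requested mean, sd and skewness via a
# moment-matched shifted (possibly mirrored) lognormal; skew ~ 0 falls
# back to a normal.
draw_moment_matched <- function(n, mean, sd, skew) {
  if (sd == 0) return(rep(mean, n))
  if (abs(skew) < 1e-3) return(stats::rnorm(n, mean, sd))
  sigma <- lognormal_shape(skew)
  w <- exp(sigma^2)
  # standard lognormal LN(0, sigma): mean m0, sd s0
  m0 <- exp(sigma^2 / 2)
  s0 <- sqrt((w - 1) * w)
  z <- (stats::rlnorm(n, 0, sigma) - m0) / s0   # zero-mean, unit-sd, skew s
  if (skew < 0) z <- -z
  mean + sd * z
}

#' Generate a synthetic lesion phantom
#'
#' Builds an ellipsoidal mask with exactly `n_voxels` voxels inside a
#' zero-background volume and fills it with intensities drawn from a
#' moment-matched shifted lognormal (normal when the target skewness is
#' ~0), clipped to the discretization window `[0, 60)`.
#'
#' @param spec A [lesion_spec()].
#' @return List with `volume` (a [pet_volume()]) and `roi` (a
#'   [lesion_roi()]).
#' @export
synth_lesion_volume <- function(spec) {
  n <- spec$n_voxels
  # bounding box with margin; rank voxels by normalized ellipsoid radius
  # and keep the n innermost, so the mask has exactly n voxels
  r0 <- max(2, ceiling((3 * n / (4 * pi))^(1 / 3)) + 2)
  axes <- spec$semi_axes
  if (is.null(axes)) axes <- c(1, 1, 1)
  axes <- axes / max(axes)
  dims <- pmax(2 * ceiling(r0 * 2 * axes) + 3, 5)
  cx <- (dims + 1) / 2
  gx <- ((seq_len(dims[1]) - cx[1]) / axes[1])^2
  gy <- ((seq_len(dims[2]) - cx[2]) / axes[2])^2
  gz <- ((seq_len(dims[3]) - cx[3]) / axes[3])^2
  rad <- outer(outer(gx, gy, "+"), gz, "+")
  ord <- order(rad, seq_along(rad))   # deterministic tie-break
  mask <- array(FALSE, dims)
  mask[ord[seq_len(n)]] <- TRUE
  vals <- with_seed(spec$seed, {
    v <- draw_moment_matched(n, spec$mean_suv, spec$sd_suv, spec$skewness)
    pmin(pmax(v, 0), 60 - 1e-9)
  })
  vox <- array(0, dims)
  vox[mask] <- vals
  list(volume = pet_volume(vox, spacing = spec$spacing),
       roi = lesion_roi(mask, lesion_id = "synthetic_lesion",
                        district = "liver", timepoint = "T0"))
}

#' Sample a paired T0/T1 cohort for delta-radiomics
#'
#' Draws a baseline cohort from `spec`, then sets
#' `T1 = T0 * (1 + Delta/100)` with per-lesion `Delta` drawn from
#' per-group normal distributions given by `delta_shift`.
#'
#' @param spec A [cohort_spec()].
#' @param delta_shift Data frame `district`, `feature`, `group`, `mean`,
#'   `sd` of the percent-change distribution (e.g. the published delta
#'   summaries from `paper_fixtures()$table3`).
#' @return List with `t0`, `t1` (feature tables), and `deltas` (long data
#'   frame `lesion_id`, `feature`, `delta_percent` of the drawn changes).
#' @export
sample_paired_cohort <- function(spec, delta_shift) {
  t0 <- sample_feature_cohort(spec)
  t1 <- t0
  deltas <- list()
  with_seed(child_seed(spec$seed, 7), {
    for (f in spec$features) {
      dv <- numeric(nrow(t0))
      for (d in spec$districts) {
        for (g in c("responder", "non_responder")) {
          sel <- t0$district == d & t0$label == (g == "responder")
          ds <- delta_shift[delta_shift$district == d &
                              delta_shift$feature == f &
                              delta_shift$group == g, ]
          if (nrow(ds) != 1)
            stopf("need one delta row for %s/%s/%s", d, f, g)
          dv[sel] <- stats::rnorm(sum(sel), ds$mean, ds$sd)
        }
      }
      t1[[f]] <- t0[[f]] * (1 + dv / 100)
      deltas[[f]] <- data.frame(lesion_id = t0$lesion_id, feature = f,
                                delta_percent = dv)
    }
  })
  list(t0 = t0, t1 = t1, deltas = do.call(rbind, deltas))
}
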