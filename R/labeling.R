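# Per-lesion response labeling from paired baseline (T0) / follow-up (T1)
# measurements, dichotomization, and delta-radiomics.

#' Construct a lesion measurement
#'
#' @param lesion_id Lesion identifier.
#' @param timepoint `"T0"` or `"T1"`.
#' @param size Longest diameter in mm (required when `present`).
#' @param suv_max Maximum SUV (required when `present`).
#' @param present `FALSE` when the lesion has disappeared at this timepoint.
#' @return An object of class `lesion_measurement`.
#' @export
lesion_measurement <- function(lesion_id, timepoint = c("T0", "T1"),
                               size = NA_real_, suv_max = NA_real_,
                               present = TRUE) {
  timepoint <- match.arg(timepoint)
  if (present) {
    if (!is.finite(size) || size <= 0) stopf("size must be > 0 for a present lesion")
    if (!is.finite(suv_max) || suv_max <= 0) stopf("suv_max must be > 0 for a present lesion")
  }
  structure(list(lesion_id = as.character(lesion_id), timepoint = timepoint,
                 size = size, suv_max = suv_max, present = isTRUE(present)),
            class = "lesion_measurement")
}

#' Classify per-lesion response to therapy
#'
#' Categories follow the per-lesion +/-25 percent rule on size or SUVmax:
#' disappearance is CR; an increase of at least `threshold` percent in
#' either size or SUVmax is PD; otherwise a decrease of at least
#' `threshold` percent in either is PR; otherwise SD. Either criterion
#' suffices (OR rule) and PD takes precedence over PR when they conflict.
#'
#' @param t0,t1 [lesion_measurement()] objects for the same lesion; `t0`
#'   must be present.
#' @param threshold Percent change defining PD/PR (default 25).
#' @return A `response_label`: list with `lesion_id`, `category`
#'   (`"PD"`, `"SD"`, `"PR"`, `"CR"`) and `dichotomous` (0 = PD,
#'   1 = responsive).
#' @export
classify_response <- function(t0, t1, threshold = 25) {
  if (!identical(t0$lesion_id, t1$lesion_id))
    stopf("mismatched lesion ids: %s vs %s", t0$lesion_id, t1$lesion_id)
  if (!t0$present) stopf("baseline (T0) measurement must be present")
  if (!t1$present) {
    category <- "CR"
  } else {
    ch_size <- 100 * (t1$size - t0$size) / t0$size
    ch_suv <- 100 * (t1$suv_max - t0$suv_max) / t0$suv_max
    category <- if (ch_size >= threshold || ch_suv >= threshold) "PD"
    else if (ch_size <= -threshold || ch_suv <= -threshold) "PR"
    else "SD"
  }
  structure(list(lesion_id = t0$lesion_id, category = category,
                 dichotomous = dichotomize(category)),
            class = "response_label")
}

#' Dichotomize a response category
#'
#' Progression (PD) codes 0; any responsive outcome (SD, PR, CR) codes 1.
#'
#' @param category `"PD"`, `"SD"`, `"PR"` or `"CR"` (or a `response_label`).
#' @return Integer 0 or 1.
#' @export
dichotomize <- function(category) {
  if (inherits(category, "response_label")) category <- category$category
  category <- match.arg(category, c("PD", "SD", "PR", "CR"))
  if (category == "PD") 0L else 1L
}

#' Delta-radiomics percent change
#'
#' `Delta = 100 * (f_t1 - f_t0) / f_t0`. Undefined (NA) when the baseline
#' value is 0, rather than infinite.
#'
#' @param f_t0,f_t1 Baseline and follow-up feature values (vectorized).
#' @return Percent change, `NA` where `f_t0 == 0`.
#' @export
delta_feature <- function(f_t0, f_t1) {
  out <- 100 * (f_t1 - f_t0) / f_t0
  out[f_t0 == 0] <- NA_real_
  out
}

#' Label a cohort of paired measurements
#'
#' @param measurements Data frame with columns `lesion_id`, `timepoint`
#'   (`"T0"`/`"T1"`), `size`, `suv_max`, `present` (logical; missing column
#'   means all present).
#' @param threshold Percent change rule passed to [classify_response()].
#' @return Data frame `lesion_id`, `category`, `dichotomous`.
#' @export
label_cohort <- function(measurements, threshold = 25) {
  if (!"present" %in% names(measurements)) measurements$present <- TRUE
  ids <- unique(measurements$lesion_id)
  rows <- lapply(ids, function(id) {
    sub <- measurements[measurements$lesion_id == id, ]
    r0 <- sub[sub$timepoint == "T0", ]
    r1 <- sub[sub$timepoint == "T1", ]
    if (nrow(r0) != 1 || nrow(r1) != 1)
      stopf("lesion %s needs exactly one T0 and one T1 row", id)
    lab <- classify_response(
      lesion_measurement(id, "T0", r0$size, r0$suv_max, r0$present),
      lesion_measurement(id, "T1", r1$size, r1$suv_max, r1$present),
      threshold)
    data.frame(lesion_id = id, category = lab$category,
               dichotomous = lab$dichotomous)
  })
  do.call(rbind, rows)
}
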