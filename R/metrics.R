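#' Accurate-prediction rate
#'
#' Percentage of subjects whose predicted REE lies within 90-110% of their
#' measured REE (an "accurate prediction" in the validation literature).
#' The band is closed at both ends by default: a prediction at exactly 90%
#' or 110% of measured counts as accurate.
#'
#' @param predicted,measured paired REE values in kcal/d; `measured` must
#'   be positive.
#' @param lower,upper the accuracy band as fractions of measured REE.
#' @param inclusive whether the band boundaries count as accurate.
#' @return percentage in \[0, 100\].
#' @export
accurate_prediction_rate <- function(predicted, measured,
                                     lower = 0.90, upper = 1.10,
                                     inclusive = TRUE) {
  check_pairs(predicted, measured)
  ratio <- predicted / measured
  inside <- if (inclusive) ratio >= lower & ratio <= upper
            else ratio > lower & ratio < upper
  100 * mean(inside)
}

#' Bias percent
#'
#' Mean over subjects of the per-subject percentage difference
#' `100 * (predicted - measured) / measured`. The denominator is the
#' measured (reference) REE.
#'
#' @inheritParams accurate_prediction_rate
#' @return mean percentage difference.
#' @export
bias_percent <- function(predicted, measured) {
  check_pairs(predicted, measured)
  mean(100 * (predicted - measured) / measured)
}

#' Root mean squared error
#'
#' `sqrt(mean((predicted - measured)^2))` with the plain 1/n denominator.
#'
#' @inheritParams accurate_prediction_rate
#' @return RMSE in kcal/d.
#' @export
ree_rmse <- function(predicted, measured) {
  check_pairs(predicted, measured, positive_measured = FALSE)
  sqrt(mean((predicted - measured)^2))
}

check_pairs <- function(predicted, measured, positive_measured = TRUE) {
  if (length(predicted) == 0L || length(predicted) != length(measured)) {
    stop("predicted and measured must be non-empty and the same length",
         call. = FALSE)
  }
  if (anyNA(predicted) || anyNA(measured)) {
    stop("predicted and measured must not contain NA", call. = FALSE)
  }
  if (positive_measured && any(measured <= 0)) {
    stop("measured REE must be positive", call. = FALSE)
  }
  invisible(TRUE)
}

#' Bland-Altman agreement analysis
#'
#' Per-subject agreement between a prediction method and the reference
#' measurement: each subject contributes a point (mean of the two values,
#' difference predicted - measured); the limits of agreement are drawn at
#' the mean difference plus and minus `multiplier` times the SD of the
#' differences (sample SD, n-1 denominator). The multiplier defaults to 2,
#' not 1.96.
#'
#' @inheritParams accurate_prediction_rate
#' @param id optional subject identifiers carried into the point table.
#' @param multiplier half-width of the limits of agreement in SDs.
#' @return object of class `"bland_altman"`: list with `points` (data frame
#'   `id`, `mean_kcal_d`, `diff_kcal_d`), `mean_diff`, `sd_diff`,
#'   `lower_loa`, `upper_loa`, `multiplier`, `outlier_count`.
#' @export
bland_altman <- function(predicted, measured, id = NULL, multiplier = 2) {
  check_pairs(predicted, measured, positive_measured = FALSE)
  if (length(predicted) < 2L) {
    stop("Bland-Altman analysis needs at least 2 pairs (SD undefined)",
         call. = FALSE)
  }
  diffs <- predicted - measured
  mean_diff <- mean(diffs)
  sd_diff <- stats::sd(diffs)
  structure(list(
    points = data.frame(
      id = if (is.null(id)) as.character(seq_along(diffs)) else as.character(id),
      mean_kcal_d = (predicted + measured) / 2,
      diff_kcal_d = diffs,
      stringsAsFactors = FALSE),
    mean_diff = mean_diff,
    sd_diff = sd_diff,
    lower_loa = mean_diff - multiplier * sd_diff,
    upper_loa = mean_diff + multiplier * sd_diff,
    multiplier = multiplier,
    outlier_count = sum(abs(diffs - mean_diff) > multiplier * sd_diff)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<Bland-Altman> n = %d, mean diff = %.1f, SD = %.1f, LoA = [%.1f, %.1f], %d outlier(s)\n",
    nrow(x$points), x$mean_diff, x$sd_diff, x$lower_loa, x$upper_loa,
    x$outlier_count))
  invisible(x)
}

#' Stratified validation summaries
#'
#' The validation-table machinery: for every equation and every stratum
#' (BMI group x sex, plus the `overall`/`both` margins) it recomputes, from
#' the raw per-subject pairs, the mean predicted - measured difference,
#' the accurate-prediction percentage, the bias percent and the RMSE.
#' Inapplicable predictions are excluded from the statistics and counted in
#' `n_inapplicable`; empty strata are emitted with `NA` statistics, never
#' dropped.
#'
#' @param cohort a `ree_cohort` with `measured_ree` and `bmi_group` set for
#'   every subject.
#' @param predictions output of [predict_all()] for the same cohort.
#' @param bmi_groups BMI strata to report in addition to `"overall"`.
#' @inheritParams accurate_prediction_rate
#' @return data frame with one row per (equation x BMI stratum x sex
#'   stratum): `equation_id`, `bmi_group`, `sex`, `n`, `n_inapplicable`,
#'   `mean_difference`, `accurate_pct`, `bias_pct`, `rmse`.
#' @export
stratified_validation <- function(cohort, predictions,
                                  bmi_groups = c("normal", "overweight", "obese"),
                                  lower = 0.90, upper = 1.10,
                                  inclusive = TRUE) {
  if (anyNA(cohort$measured_ree)) {
    stop("every subject needs a measured_ree for validation", call. = FALSE)
  }
  if (anyNA(cohort$bmi_group)) {
    stop("every subject needs a bmi_group for stratified validation",
         call. = FALSE)
  }
  merged <- merge(predictions,
                  cohort[, c("id", "sex", "bmi_group", "measured_ree")],
                  by = "id", sort = FALSE)
  equation_ids <- unique(predictions$equation_id)
  rows <- list()
  for (eq in equation_ids) {
    sub_eq <- merged[merged$equation_id == eq, , drop = FALSE]
    for (grp in c("overall", bmi_groups)) {
      sub_g <- if (grp == "overall") sub_eq
               else sub_eq[sub_eq$bmi_group == grp, , drop = FALSE]
      for (sx in c("both", "male", "female")) {
        sub <- if (sx == "both") sub_g else sub_g[sub_g$sex == sx, , drop = FALSE]
        ok <- !is.na(sub$predicted_ree_kcal_d)
        n <- sum(ok)
        rows[[length(rows) + 1L]] <- data.frame(
          equation_id = eq, bmi_group = grp, sex = sx,
          n = n, n_inapplicable = sum(!ok),
          mean_difference = if (n > 0)
            mean(sub$predicted_ree_kcal_d[ok] - sub$measured_ree[ok]) else NA_real_,
          accurate_pct = if (n > 0)
            accurate_prediction_rate(sub$predicted_ree_kcal_d[ok],
                                     sub$measured_ree[ok],
                                     lower, upper, inclusive) else NA_real_,
          bias_pct = if (n > 0)
            bias_percent(sub$predicted_ree_kcal_d[ok], sub$measured_ree[ok])
            else NA_real_,
          rmse = if (n > 0)
            ree_rmse(sub$predicted_ree_kcal_d[ok], sub$measured_ree[ok])
            else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
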