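#' Energy unit conversion
#'
#' Converts between kcal/d, kJ/d and MJ/d using the thermochemical calorie
#' (1 kcal = 4.184 kJ by definition, so 1 MJ = 1000/4.184 kcal). The factor
#' is exposed as an argument so sensitivity to the conversion convention can
#' be probed; round trips are exact to machine precision.
#'
#' @param value numeric energy amount(s).
#' @param from,to one of `"kcal_per_day"`, `"kJ_per_day"`, `"MJ_per_day"`.
#' @param kj_per_kcal kilojoules per kilocalorie (default thermochemical
#'   4.184).
#' @return `value` expressed in `to`.
#' @export
convert_energy <- function(value, from, to, kj_per_kcal = 4.184) {
  units <- c(kcal_per_day = NA_real_, kJ_per_day = 1, MJ_per_day = 1000)
  if (!from %in% names(units) || !to %in% names(units)) {
    stop("unknown energy unit: ", setdiff(c(from, to), names(units))[1],
         call. = FALSE)
  }
  # express in kJ/d, then in the target unit
  in_kj <- switch(from,
                  kcal_per_day = value * kj_per_kcal,
                  kJ_per_day = value,
                  MJ_per_day = value * 1000)
  switch(to,
         kcal_per_day = in_kj / kj_per_kcal,
         kJ_per_day = in_kj,
         MJ_per_day = in_kj / 1000)
}

# One dispatch variant of an equation: a sex filter, an age interval in
# years, and the printed coefficients keyed by predictor. Recognised
# predictor keys: intercept, weight (kg), height_cm, height_m, age (years),
# sex (the equation's own 0/1 coding), fat_mass (kg), fat_free_mass (kg).
ree_variant <- function(sex, age_lo, age_hi, coef) {
  list(sex = sex, age_lo = age_lo, age_hi = age_hi, coef = coef)
}

ree_equation_spec <- function(equation_id, label, native_unit, sex_code,
                              stated_age_range, variants) {
  keys <- unique(unlist(lapply(variants, function(v) names(v$coef))))
  known <- c("intercept", "weight", "height_cm", "height_m", "age", "sex",
             "fat_mass", "fat_free_mass")
  if (!all(keys %in% known)) {
    stop("unknown coefficient key(s): ",
         paste(setdiff(keys, known), collapse = ", "), call. = FALSE)
  }
  field_of <- c(weight = "weight", height_cm = "height", height_m = "height",
                age = "age", sex = "sex", fat_mass = "fat_mass",
                fat_free_mass = "fat_free_mass")
  required <- unname(unique(field_of[setdiff(keys, "intercept")]))
  structure(
    list(equation_id = equation_id, label = label,
         native_unit = native_unit, sex_code = sex_code,
         stated_age_range = stated_age_range, variants = variants,
         required_fields = required),
    class = "ree_equation_spec")
}

#' @export
print.ree_equation_spec <- function(x, ...) {
  cat(sprintf("<ree equation '%s'> %s\n", x$equation_id, x$label))
  cat(sprintf("  native unit: %s; stated ages %g-%g years; requires: %s\n",
              x$native_unit, x$stated_age_range[1], x$stated_age_range[2],
              paste(x$required_fields, collapse = ", ")))
  invisible(x)
}

#' Registry of pediatric REE prediction equations
#'
#' Returns the 14 prediction equations handled by the package: 13 published
#' literature equations (WHO, Schofield, IOM, Kim, Henry, Molnar, two
#' Mueller forms, Derumeaux-Burel, Schmelzle, Tverskaya, two Lazzer forms)
#' plus the fat-free-mass equation `new_ffm` (REE = 505.412 + 24.383 FFM,
#' kcal/d). Coefficients are stored exactly as published, in each equation's
#' native energy unit; the Lazzer weight/height form takes height in metres.
#' Sex codings are per equation (Molnar and Mueller code male = 0, Tverskaya
#' and Lazzer male = 1) and never leak outside the registry.
#'
#' Each call returns a fresh copy, so callers cannot mutate the registry.
#'
#' @return named list of equation specifications, length 14.
#' @export
ree_equations <- function() {
  male0 <- c(male = 0, female = 1)
  male1 <- c(male = 1, female = 0)
  list(
    who = ree_equation_spec(
      "who", "WHO/FAO/UNU (1985)", "kcal_per_day", male1, c(3, 18),
      list(
        ree_variant("male", 3, 10, c(intercept = 495, weight = 22.7)),
        ree_variant("female", 3, 10, c(intercept = 499, weight = 22.5)),
        ree_variant("male", 10, 18, c(intercept = 651, weight = 18.4)),
        ree_variant("female", 10, 18, c(intercept = 746, weight = 12.5)))),
    schofield = ree_equation_spec(
      "schofield", "Schofield (1985)", "kcal_per_day", male1, c(3, 18),
      list(
        ree_variant("male", 3, 10,
                    c(intercept = 414.7, weight = 19.589, height_cm = 1.302)),
        ree_variant("female", 3, 10,
                    c(intercept = 371.0, weight = 16.961, height_cm = 1.617)),
        ree_variant("male", 10, 18,
                    c(intercept = 515.3, weight = 16.245, height_cm = 1.371)),
        ree_variant("female", 10, 18,
                    c(intercept = 200.0, weight = 8.361, height_cm = 4.654)))),
    iom = ree_equation_spec(
      "iom", "Institute of Medicine (2004)", "kcal_per_day", male1, c(3, 18),
      list(
        ree_variant("male", 3, 18,
                    c(intercept = 68, age = -43.3, height_cm = 7.12,
                      weight = 19.2)),
        ree_variant("female", 3, 18,
                    c(intercept = 189, age = -17.6, height_cm = 6.25,
                      weight = 7.9)))),
    kim = ree_equation_spec(
      "kim", "Kim (2009)", "kcal_per_day", male1, c(4, 11),
      list(
        ree_variant("all", 4, 11,
                    c(intercept = 632.4, age = 15.66, weight = 9.53)))),
    henry = ree_equation_spec(
      "henry", "Henry (2005)", "kcal_per_day", male1, c(3, 18),
      list(
        ree_variant("male", 3, 10,
                    c(intercept = 306, weight = 15.1, height_cm = 0.742)),
        ree_variant("female", 3, 10,
                    c(intercept = 349, weight = 15.9, height_cm = 2.1)),
        ree_variant("male", 10, 18,
                    c(intercept = 299, weight = 15.6, height_cm = 2.66)),
        ree_variant("female", 10, 18,
                    c(intercept = 462, weight = 9.40, height_cm = 2.49)))),
    molnar = ree_equation_spec(
      "molnar", "Molnar (1995)", "kJ_per_day", male0, c(10, 16),
      list(
        ree_variant("all", 10, 16,
                    c(intercept = 594.3, weight = 50.2, height_cm = 29.6,
                      age = -144.5, sex = -550)))),
    muller_a = ree_equation_spec(
      "muller_a", "Mueller weight/height (2004)", "MJ_per_day", male0, c(5, 17),
      list(
        ree_variant("all", 5, 17,
                    c(intercept = -0.808, weight = 0.02606,
                      height_cm = 0.04129, sex = 0.311, age = -0.08369)))),
    muller_b = ree_equation_spec(
      "muller_b", "Mueller FFM (2004)", "MJ_per_day", male0, c(5, 17),
      list(
        ree_variant("all", 5, 17,
                    c(intercept = 2.694, fat_free_mass = 0.07885,
                      fat_mass = 0.02132, sex = 0.327)))),
    derumeaux_burel = ree_equation_spec(
      "derumeaux_burel", "Derumeaux-Burel (2004)", "MJ_per_day", male1, c(3, 18),
      list(
        ree_variant("all", 3, 18,
                    c(intercept = 3.3647, fat_free_mass = 0.1371,
                      age = -0.1644)))),
    schmelzle = ree_equation_spec(
      "schmelzle", "Schmelzle (2004)", "kcal_per_day", male1, c(4, 15),
      list(
        ree_variant("male", 4, 15,
                    c(intercept = -794, weight = 6.6, height_cm = 13.1)),
        ree_variant("female", 4, 15,
                    c(intercept = 579, weight = 11.9, height_cm = 0.84)))),
    tverskaya = ree_equation_spec(
      "tverskaya", "Tverskaya (1998)", "kcal_per_day", male1, c(6, 18),
      list(
        ree_variant("all", 6, 18,
                    c(intercept = 775, fat_free_mass = 28.4, age = -37,
                      fat_mass = 3.3, sex = 82)))),
    lazzer_a = ree_equation_spec(
      "lazzer_a", "Lazzer weight/height (2006)", "kJ_per_day", male1, c(6, 18),
      list(
        ree_variant("all", 6, 18,
                    c(intercept = 1454.50, sex = 892.68, age = -115.93,
                      weight = 54.96, height_m = 1816.23)))),
    lazzer_b = ree_equation_spec(
      "lazzer_b", "Lazzer FFM (2006)", "kJ_per_day", male1, c(6, 18),
      list(
        ree_variant("all", 6, 18,
                    c(intercept = 3631.23, sex = 909.12, age = -107.48,
                      fat_free_mass = 68.39, fat_mass = 55.19)))),
    new_ffm = ree_equation_spec(
      "new_ffm", "Fat-free mass equation", "kcal_per_day", male1, c(6, 18),
      list(
        ree_variant("all", 6, 18,
                    c(intercept = 505.412, fat_free_mass = 24.383))))
  )
}

# Resolve which variant applies to a sex/age. Age brackets partition at
# their boundary: the child bracket is [lo, hi), the oldest bracket for a
# sex is closed above. If no bracket contains the age (subject outside the
# equation's stated range), the nearest bracket is used; strict mode makes
# that an error instead.
match_variant <- function(spec, sex, age, strict_age_range = FALSE) {
  cands <- Filter(function(v) v$sex == "all" || v$sex == sex, spec$variants)
  if (length(cands) == 0L) {
    stop(sprintf("equation '%s' has no variant for sex '%s'",
                 spec$equation_id, sex), call. = FALSE)
  }
  hi_max <- max(vapply(cands, function(v) v$age_hi, numeric(1)))
  inside <- vapply(cands, function(v) {
    age >= v$age_lo && (age < v$age_hi || (v$age_hi == hi_max && age <= v$age_hi))
  }, logical(1))
  if (any(inside)) return(cands[[which(inside)[1]]])
  if (strict_age_range) {
    stop(sprintf("age %.2f is outside the stated range %g-%g of equation '%s'",
                 age, spec$stated_age_range[1], spec$stated_age_range[2],
                 spec$equation_id), call. = FALSE)
  }
  dist <- vapply(cands, function(v) {
    if (age < v$age_lo) v$age_lo - age else age - v$age_hi
  }, numeric(1))
  cands[[which.min(dist)]]
}

#' Predict REE for one subject with one equation
#'
#' Evaluates the equation's printed linear form with the subject's values,
#' substituting the equation's own 0/1 sex coding, then converts the result
#' to kcal/d. Subjects whose age falls outside the equation's stated age
#' range are still evaluated (the validation tables cover all equations for
#' the whole cohort) but flagged; `strict_age_range = TRUE` refuses them.
#'
#' @param spec an equation specification from [ree_equations()].
#' @param subject a list or one-row data frame with the fields the equation
#'   requires (`sex`, `age`, and a subset of `weight`, `height`,
#'   `fat_mass`, `fat_free_mass`).
#' @param strict_age_range error instead of flagging out-of-range ages.
#' @param kj_per_kcal energy conversion factor, see [convert_energy()].
#' @return list with `subject_id`, `equation_id`, `predicted_ree` (kcal/d),
#'   `native_value`, `native_unit`, `out_of_stated_range`.
#' @export
predict_ree <- function(spec, subject, strict_age_range = FALSE,
                        kj_per_kcal = 4.184) {
  stopifnot(inherits(spec, "ree_equation_spec"))
  subject <- as.list(subject)
  for (field in c("sex", "age", spec$required_fields)) {
    val <- subject[[field]]
    if (is.null(val) || (length(val) == 1L && is.na(val))) {
      stop(sprintf("equation '%s' is inapplicable: subject field '%s' is missing",
                   spec$equation_id, field), call. = FALSE)
    }
  }
  variant <- match_variant(spec, subject$sex, subject$age, strict_age_range)
  supplied <- c(intercept = 1,
                weight = subject$weight %||% NA_real_,
                height_cm = subject$height %||% NA_real_,
                height_m = (subject$height %||% NA_real_) / 100,
                age = subject$age,
                sex = unname(spec$sex_code[subject$sex]),
                fat_mass = subject$fat_mass %||% NA_real_,
                fat_free_mass = subject$fat_free_mass %||% NA_real_)
  native <- sum(variant$coef * supplied[names(variant$coef)])
  list(subject_id = subject$id %||% NA_character_,
       equation_id = spec$equation_id,
       predicted_ree = convert_energy(native, spec$native_unit,
                                      "kcal_per_day", kj_per_kcal),
       native_value = native,
       native_unit = spec$native_unit,
       out_of_stated_range = subject$age < spec$stated_age_range[1] ||
         subject$age > spec$stated_age_range[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict REE for a whole cohort
#'
#' Applies each selected equation to each subject. Pairs an equation cannot
#' score (a required field is absent) are recorded with the reason rather
#' than dropped, so downstream accounting of who contributed to which
#' stratum stays exact.
#'
#' @param cohort a `ree_cohort` (or compatible data frame).
#' @param equation_ids equations to apply; default all 14.
#' @inheritParams predict_ree
#' @return data frame with one row per (subject, equation):
#'   `id`, `equation_id`, `predicted_ree_kcal_d`, `native_value`,
#'   `native_unit`, `out_of_stated_range`, `inapplicable_reason`.
#' @export
predict_all <- function(cohort, equation_ids = NULL,
                        strict_age_range = FALSE, kj_per_kcal = 4.184) {
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  registry <- ree_equations()
  if (is.null(equation_ids)) equation_ids <- names(registry)
  unknown <- setdiff(equation_ids, names(registry))
  if (length(unknown) > 0L) {
    stop("unknown equation id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- vector("list", nrow(cohort) * length(equation_ids))
  k <- 0L
  for (i in seq_len(nrow(cohort))) {
    subject <- as.list(cohort[i, , drop = FALSE])
    for (eq in equation_ids) {
      k <- k + 1L
      res <- tryCatch(
        predict_ree(registry[[eq]], subject, strict_age_range, kj_per_kcal),
        error = function(e) conditionMessage(e))
      if (is.character(res)) {
        rows[[k]] <- data.frame(
          id = subject$id, equation_id = eq,
          predicted_ree_kcal_d = NA_real_, native_value = NA_real_,
          native_unit = registry[[eq]]$native_unit,
          out_of_stated_range = NA, inapplicable_reason = res,
          stringsAsFactors = FALSE)
      } else {
        rows[[k]] <- data.frame(
          id = subject$id, equation_id = eq,
          predicted_ree_kcal_d = res$predicted_ree,
          native_value = res$native_value, native_unit = res$native_unit,
          out_of_stated_range = res$out_of_stated_range,
          inapplicable_reason = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
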