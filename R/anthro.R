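#' Body mass index
#'
#' @param weight body weight in kg (> 0).
#' @param height standing height in cm (> 0).
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0)) {
    stop("weight and height must be positive", call. = FALSE)
  }
  weight / (height / 100)^2
}

# unguarded BMI for synthetic cohorts, where untruncated gaussian draws can
# stray outside physical ranges by design
bmi_raw <- function(weight, height) weight / (height / 100)^2

#' Read an LMS reference table
#'
#' An LMS table gives, per sex and age, the Box-Cox power `L`, median `M`
#' and coefficient of variation `S` of a growth reference (here BMI-for-age).
#' Expected columns: `sex` (`male`/`female`), `age_unit` (`months` or
#' `years`), `age`, `L`, `M`, `S`. Ages are normalised to decimal years and
#' rows sorted by age within sex.
#'
#' The package ships a deliberately synthetic fixture table
#' (`synthetic_lms_bmi.csv` under `extdata`) with smooth made-up curves so
#' the classification pipeline is exercisable without any reference
#' download; for real work supply the WHO 2007 BMI-for-age table in this
#' layout.
#'
#' @param path CSV path.
#' @return data frame with columns `sex`, `age` (years), `L`, `M`, `S`,
#'   class `"lms_table"`.
#' @export
read_lms_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sex", "age_unit", "age", "L", "M", "S")
  if (!all(needed %in% names(raw))) {
    stop("LMS table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (!all(raw$sex %in% c("male", "female"))) {
    stop("LMS sex must be 'male' or 'female'", call. = FALSE)
  }
  if (!all(raw$age_unit %in% c("months", "years"))) {
    stop("LMS age_unit must be 'months' or 'years'", call. = FALSE)
  }
  if (any(raw$M <= 0) || any(raw$S <= 0)) {
    stop("LMS M and S must be positive", call. = FALSE)
  }
  raw$age <- ifelse(raw$age_unit == "months", raw$age / 12, raw$age)
  out <- raw[order(raw$sex, raw$age), c("sex", "age", "L", "M", "S")]
  rownames(out) <- NULL
  class(out) <- c("lms_table", class(out))
  out
}

# L, M and S at an exact age, linearly interpolated between the bracketing
# table rows; no extrapolation outside the table's coverage.
lms_lookup <- function(table, sex, age) {
  rows <- table[table$sex == sex, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("LMS table has no rows for sex '", sex, "'", call. = FALSE)
  }
  if (age < min(rows$age) || age > max(rows$age)) {
    stop(sprintf("age %.2f years is outside LMS table coverage [%.2f, %.2f]",
                 age, min(rows$age), max(rows$age)), call. = FALSE)
  }
  list(L = stats::approx(rows$age, rows$L, xout = age)$y,
       M = stats::approx(rows$age, rows$M, xout = age)$y,
       S = stats::approx(rows$age, rows$S, xout = age)$y)
}

#' LMS z-score
#'
#' The Box-Cox (LMS) transform of a measurement against a growth reference:
#' `z = ((x/M)^L - 1) / (L * S)` for `L != 0`, and the limit
#' `z = log(x/M) / S` at `L = 0`.
#'
#' @param x positive measurement (e.g. BMI in kg/m^2).
#' @param L Box-Cox power.
#' @param M reference median (> 0).
#' @param S reference coefficient of variation (> 0).
#' @return z-score in SD units.
#' @export
lms_zscore <- function(x, L, M, S) {
  if (any(x <= 0) || any(M <= 0) || any(S <= 0)) {
    stop("x, M and S must be positive", call. = FALSE)
  }
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  z <- numeric(n)
  log_case <- abs(L) < 1e-12
  z[log_case] <- log(x[log_case] / M[log_case]) / S[log_case]
  z[!log_case] <- ((x[!log_case] / M[!log_case])^L[!log_case] - 1) /
    (L[!log_case] * S[!log_case])
  z
}

#' BMI-for-age z-score from an LMS table
#'
#' @param weight kg.
#' @param height cm.
#' @param sex `"male"` or `"female"`.
#' @param age decimal years; must lie inside the table's coverage.
#' @param table an `lms_table` from [read_lms_table()].
#' @return BMI-for-age z-score.
#' @export
bmi_for_age_z <- function(weight, height, sex, age, table) {
  n <- max(length(weight), length(height), length(sex), length(age))
  weight <- rep_len(weight, n); height <- rep_len(height, n)
  sex <- rep_len(sex, n); age <- rep_len(age, n)
  vapply(seq_len(n), function(i) {
    ref <- lms_lookup(table, sex[i], age[i])
    lms_zscore(bmi(weight[i], height[i]), ref$L, ref$M, ref$S)
  }, numeric(1))
}

#' Weight-status classification from a BMI-for-age z-score
#'
#' WHO 2007 school-age convention: obesity above +2 SD, overweight above
#' +1 SD, thinness below -2 SD. Boundaries go to the lower category
#' (z = 1 is `normal`, z = 2 is `overweight`).
#'
#' @param z finite BMI-for-age z-score(s).
#' @return character vector over `{thin, normal, overweight, obese}`.
#' @export
classify_bmi_group <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  ifelse(z > 2, "obese",
         ifelse(z > 1, "overweight",
                ifelse(z >= -2, "normal", "thin")))
}
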