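#' Cohort construction and validation
#'
#' A cohort is a data frame with one row per subject and a fixed column
#' contract: `id` (unique, character), `sex` (`"male"`/`"female"`), `age`
#' (decimal years), `weight` (kg), `height` (cm), and optionally `fat_mass`
#' (kg), `fat_free_mass` (kg), `measured_ree` (kcal/d), `bmi_z` (SD score)
#' and `bmi_group` (`"thin"`, `"normal"`, `"overweight"`, `"obese"`). Missing
#' optional values are `NA`.
#'
#' When weight, fat mass and fat-free mass are all present, their
#' consistency is checked: `|weight - (fat_mass + fat_free_mass)|` must not
#' exceed `mass_tolerance` (bioimpedance devices report the decomposition
#' exactly, so the default 1 kg is generous).
#'
#' @param data data frame with at least `id`, `sex`, `age`, `weight`,
#'   `height`.
#' @param provenance optional character note recording where the cohort
#'   came from (file path or generator configuration).
#' @param mass_tolerance maximum allowed absolute discrepancy (kg) between
#'   weight and fat mass + fat-free mass.
#' @param check_physical enforce physical ranges (positive weight, height,
#'   REE, ...). The untruncated gaussian generator mode disables this: its
#'   rare out-of-range draws are a documented property of the calibration,
#'   not data errors.
#' @return the validated data frame with class `"ree_cohort"` prepended and
#'   a `provenance` attribute.
#' @export
ree_cohort <- function(data, provenance = NULL, mass_tolerance = 1.0,
                       check_physical = TRUE) {
  stopifnot(is.data.frame(data))
  required <- c("id", "sex", "age", "weight", "height")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$id <- as.character(data$id)
  if (anyDuplicated(data$id)) {
    stop("subject ids must be unique", call. = FALSE)
  }
  if (!all(data$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  for (col in c("fat_mass", "fat_free_mass", "measured_ree", "bmi_z")) {
    if (!col %in% names(data)) data[[col]] <- NA_real_
  }
  if (!"bmi_group" %in% names(data)) data$bmi_group <- NA_character_
  bad_group <- !is.na(data$bmi_group) &
    !data$bmi_group %in% c("thin", "normal", "overweight", "obese")
  if (any(bad_group)) {
    stop("unknown bmi_group value(s): ",
         paste(unique(data$bmi_group[bad_group]), collapse = ", "),
         call. = FALSE)
  }
  if (check_physical) {
    if (any(data$age < 0, na.rm = TRUE)) stop("age must be >= 0", call. = FALSE)
    if (any(data$weight <= 0, na.rm = TRUE)) stop("weight must be > 0", call. = FALSE)
    if (any(data$height <= 0, na.rm = TRUE)) stop("height must be > 0", call. = FALSE)
    if (any(data$fat_mass < 0, na.rm = TRUE)) stop("fat_mass must be >= 0", call. = FALSE)
    if (any(data$fat_free_mass <= 0, na.rm = TRUE)) stop("fat_free_mass must be > 0", call. = FALSE)
    if (any(data$measured_ree <= 0, na.rm = TRUE)) stop("measured_ree must be > 0", call. = FALSE)
  }

  complete <- !is.na(data$fat_mass) & !is.na(data$fat_free_mass)
  if (any(complete)) {
    gap <- abs(data$weight[complete] -
                 (data$fat_mass[complete] + data$fat_free_mass[complete]))
    if (any(gap > mass_tolerance)) {
      stop(sprintf(
        "weight and fat_mass + fat_free_mass disagree by more than %.2f kg for subject(s): %s",
        mass_tolerance,
        paste(utils::head(data$id[complete][gap > mass_tolerance], 5), collapse = ", ")),
        call. = FALSE)
    }
  }
  attr(data, "provenance") <- provenance
  class(data) <- c("ree_cohort", class(data))
  data
}

#' Read a cohort CSV
#'
#' Expects the column layout `id,sex,age_years,weight_kg,height_cm,
#' fat_mass_kg,fat_free_mass_kg,measured_ree_kcal_d,bmi_z,bmi_group` with a
#' header, `.` decimal point and empty cells for absent values. Lines
#' starting with `#` (the generator's provenance header) are skipped.
#'
#' Physical-range checks default to off here (unlike [ree_cohort()]):
#' cohort files written by the untruncated gaussian generator may contain
#' rare out-of-range draws by design, and must round-trip.
#'
#' @param path path to the CSV file.
#' @inheritParams ree_cohort
#' @return a `ree_cohort` data frame.
#' @export
read_cohort_csv <- function(path, mass_tolerance = 1.0,
                            check_physical = FALSE) {
  raw <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  rename <- c(age_years = "age", weight_kg = "weight", height_cm = "height",
              fat_mass_kg = "fat_mass", fat_free_mass_kg = "fat_free_mass",
              measured_ree_kcal_d = "measured_ree")
  for (old in names(rename)) {
    if (old %in% names(raw)) names(raw)[names(raw) == old] <- rename[[old]]
  }
  if ("bmi_group" %in% names(raw)) {
    raw$bmi_group[!is.na(raw$bmi_group) & raw$bmi_group == ""] <- NA_character_
  }
  ree_cohort(raw, provenance = path, mass_tolerance = mass_tolerance,
             check_physical = check_physical)
}

#' Write a cohort CSV
#'
#' Emits the standard cohort column layout (see [read_cohort_csv()]).
#' The cohort's provenance attribute, if any, is written as a `#`-prefixed
#' header comment so reruns can be traced to their configuration.
#'
#' @param cohort a `ree_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- data.frame(
    id = cohort$id,
    sex = cohort$sex,
    age_years = cohort$age,
    weight_kg = cohort$weight,
    height_cm = cohort$height,
    fat_mass_kg = cohort$fat_mass,
    fat_free_mass_kg = cohort$fat_free_mass,
    measured_ree_kcal_d = cohort$measured_ree,
    bmi_z = cohort$bmi_z,
    bmi_group = cohort$bmi_group,
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  prov <- attr(cohort, "provenance")
  if (!is.null(prov)) {
    writeLines(paste0("# provenance: ", gsub("[\r\n]+", " ", prov)), con)
  }
  utils::write.csv(out, con, row.names = FALSE, na = "")
  invisible(path)
}
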