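#' Path to a packaged example data file
#'
#' @param file File name within `inst/extdata`; with no argument, lists the
#'   available files.
#' @return A file path (or a character vector of file names).
#' @export
dtpet_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "dtpet"))
  } else {
    system.file("extdata", file, package = "dtpet", mustWork = TRUE)
  }
}

TABLE1_COLS <- c("patient", "gender", "age", "veeg", "mri", "pet", "mdt_ez")

#' Load a TLE clinical-demographics table
#'
#' Reads and validates a seven-column patient table (patient number, gender,
#' age, video-EEG lateralization, MRI finding, PET finding, multidisciplinary
#' EZ localization). The packaged default is the 52-patient cohort table
#' shipped with the package, transcribed verbatim; finding strings are kept
#' exactly as printed (`Negative`, or `side/region[/etiology]`).
#'
#' @param path CSV path; defaults to the packaged 52-patient fixture.
#' @return A validated tibble with columns
#'   `patient`, `gender`, `age`, `veeg`, `mri`, `pet`, `mdt_ez`.
#' @examples
#' tab <- load_table1()
#' nrow(tab)
#' @export
load_table1 <- function(path = dtpet_example("table1_tle52.csv")) {
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) stop_dtpet(paste0("Cannot parse '", path, "': ",
                                          conditionMessage(e)),
                                   "dtpet_parse_error")
  )
  if (nrow(raw) == 0) {
    stop_dtpet("Patient table is empty (no data rows).", "dtpet_parse_error")
  }
  if (!identical(sort(names(raw)), sort(TABLE1_COLS))) {
    stop_dtpet(paste0("Expected columns {", paste(TABLE1_COLS, collapse = ", "),
                      "}, found {", paste(names(raw), collapse = ", "), "}."),
               "dtpet_parse_error")
  }
  raw <- raw[, TABLE1_COLS]
  age_num <- suppressWarnings(as.numeric(raw$age))
  bad_age <- which(is.na(age_num) | age_num != floor(age_num))
  if (length(bad_age)) {
    stop_dtpet(sprintf("Row %d: age '%s' is not an integer.",
                       bad_age[1], raw$age[bad_age[1]]), "dtpet_parse_error")
  }
  bad_gender <- which(!raw$gender %in% c("M", "F"))
  if (length(bad_gender)) {
    stop_dtpet(sprintf("Row %d: gender '%s' is not M or F.",
                       bad_gender[1], raw$gender[bad_gender[1]]),
               "dtpet_parse_error")
  }
  out_of_range <- which(age_num < 10 | age_num > 65)
  if (length(out_of_range)) {
    stop_dtpet(sprintf("Row %d: age %s outside the cohort range [10, 65].",
                       out_of_range[1], raw$age[out_of_range[1]]),
               "dtpet_parse_error")
  }
  dplyr::mutate(raw,
                patient = as.integer(.data$patient),
                age = as.integer(age_num))
}

finding_side <- function(x) {
  ifelse(x == "Negative", NA_character_, substr(x, 1, 1))
}

#' Demographic summary of a patient table
#'
#' Counts, percentages (rounded to 2 decimals) and age statistics computed
#' directly from the rows — including left/right lateralization counts per
#' modality and negative-finding counts. With a single row the age SD is
#' returned as `NA` (flagged unavailable). Percentages are always recomputed
#' from counts, never transcribed.
#'
#' @param rows A patient table from [load_table1()].
#' @return A one-row tibble of demographic statistics.
#' @examples
#' demographics(load_table1())
#' @export
demographics <- function(rows) {
  if (nrow(rows) < 1) stop_dtpet("Need at least one patient row.", "dtpet_domain_error")
  n <- nrow(rows)
  tibble(
    n = n,
    n_male = sum(rows$gender == "M"),
    pct_male = round(100 * sum(rows$gender == "M") / n, 2),
    age_mean = mean(rows$age),
    age_sd = if (n > 1) sd(rows$age) else NA_real_,
    age_min = min(rows$age),
    age_max = max(rows$age),
    n_veeg_negative = sum(rows$veeg == "Negative"),
    n_mri_negative = sum(rows$mri == "Negative"),
    n_pet_negative = sum(rows$pet == "Negative"),
    veeg_left = sum(finding_side(rows$veeg) == "L", na.rm = TRUE),
    veeg_right = sum(finding_side(rows$veeg) == "R", na.rm = TRUE),
    mri_left = sum(finding_side(rows$mri) == "L", na.rm = TRUE),
    mri_right = sum(finding_side(rows$mri) == "R", na.rm = TRUE),
    pet_left = sum(finding_side(rows$pet) == "L", na.rm = TRUE),
    pet_right = sum(finding_side(rows$pet) == "R", na.rm = TRUE),
    mdt_left = sum(finding_side(rows$mdt_ez) == "L", na.rm = TRUE),
    mdt_right = sum(finding_side(rows$mdt_ez) == "R", na.rm = TRUE)
  )
}
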