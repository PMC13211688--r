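#' Cohort dataset of animals and tissue measurements
#'
#' Bundles one animal table, one long measurement table and an optional
#' tissue-moisture map into a validated container used by every analysis
#' stage. Censored (below decision threshold) measurements store the
#' reporting threshold in `value` with `censored = TRUE`; downstream
#' statistics decide how to treat them.
#'
#' @param animals data.frame with columns `animal_id`, `sampling_date`
#'   (`Date` or ISO-8601 string), `latitude`, `longitude`, `region`
#'   (North/Central/South), `age_years`, `sex` (female/male), `body_mass_kg`,
#'   `body_length_cm`. Biometrics may be `NA`. An optional `bci` column is
#'   carried through untouched.
#' @param measurements data.frame with columns `animal_id`, `tissue` (one of
#'   [tissue_vocabulary()]), `analyte`, `value` (non-negative), `unit`
#'   (e.g. `"Bq/kg"`, `"ug/kg"`, `"mg/kg"`), `basis` (`"dry"` or `"wet"`),
#'   `censored` (logical). Optional `rel_uncertainty` (fraction).
#' @param tissue_moisture optional named numeric vector of moisture fractions
#'   per tissue, in `[0, 1)`.
#'
#' @return An object of class `cohort_dataset`.
#' @export
#' @examples
#' a <- data.frame(animal_id = "W1", sampling_date = "2015-06-01",
#'                 latitude = 44.8, longitude = 15.6, region = "Central",
#'                 age_years = 2, sex = "female",
#'                 body_mass_kg = 30, body_length_cm = 120)
#' m <- data.frame(animal_id = "W1", tissue = "muscle", analyte = "Cs137",
#'                 value = 6.5, unit = "Bq/kg", basis = "dry", censored = FALSE)
#' cohort_dataset(a, m)
cohort_dataset <- function(animals, measurements, tissue_moisture = NULL) {
  animals <- as.data.frame(animals)
  measurements <- as.data.frame(measurements)
  if (!inherits(animals$sampling_date, "Date"))
    animals$sampling_date <- as.Date(animals$sampling_date)
  if (nrow(measurements) > 0)
    measurements$censored <- as.logical(measurements$censored)
  obj <- structure(list(animals = animals,
                        measurements = measurements,
                        tissue_moisture = tissue_moisture),
                   class = "cohort_dataset")
  validate_cohort(obj)
  obj
}

ANIMAL_COLUMNS <- c("animal_id", "sampling_date", "latitude", "longitude",
                    "region", "age_years", "sex", "body_mass_kg",
                    "body_length_cm")
MEASUREMENT_COLUMNS <- c("animal_id", "tissue", "analyte", "value", "unit",
                         "basis", "censored")

#' Validate a cohort dataset
#'
#' Enforces the container invariants: schema completeness, coordinate and age
#' ranges, unique animal ids, the seven-tissue vocabulary, non-negative
#' values, referential integrity between measurements and animals, and
#' per-analyte unit/basis consistency.
#'
#' @param x a `cohort_dataset`.
#' @return `x`, invisibly; errors with a classed condition otherwise.
#' @export
validate_cohort <- function(x) {
  a <- x$animals; m <- x$measurements
  miss <- setdiff(ANIMAL_COLUMNS, names(a))
  if (length(miss))
    stop_radecol(paste0("animal table missing column: ", miss[1]), "radecol_schema_error")
  miss <- setdiff(MEASUREMENT_COLUMNS, names(m))
  if (length(miss))
    stop_radecol(paste0("measurement table missing column: ", miss[1]), "radecol_schema_error")
  if (anyDuplicated(a$animal_id))
    stop_radecol("duplicate animal_id in animal table", "radecol_validation_error")
  if (any(is.na(a$sampling_date)))
    stop_radecol("unparseable sampling_date", "radecol_validation_error")
  if (any(a$latitude < -90 | a$latitude > 90, na.rm = TRUE))
    stop_radecol("latitude outside [-90, 90]", "radecol_validation_error")
  if (any(a$longitude < -180 | a$longitude > 180, na.rm = TRUE))
    stop_radecol("longitude outside [-180, 180]", "radecol_validation_error")
  if (any(a$age_years < 0, na.rm = TRUE))
    stop_radecol("negative age_years", "radecol_validation_error")
  if (!all(a$region %in% c("North", "Central", "South")))
    stop_radecol("region must be North, Central or South", "radecol_validation_error")
  if (!all(a$sex %in% c("female", "male")))
    stop_radecol("sex must be female or male", "radecol_validation_error")
  if (nrow(m) > 0) {
    if (!all(m$tissue %in% tissue_vocabulary()))
      stop_radecol(paste0("tissue outside the 7-tissue vocabulary: ",
                          setdiff(m$tissue, tissue_vocabulary())[1]),
                   "radecol_validation_error")
    if (any(is.na(m$value)) || any(m$value < 0))
      stop_radecol("measurement value must be a non-negative number",
                   "radecol_validation_error")
    if (!all(m$basis %in% c("dry", "wet")))
      stop_radecol("basis must be dry or wet", "radecol_validation_error")
    orphan <- setdiff(m$animal_id, a$animal_id)
    if (length(orphan))
      stop_radecol(paste0("measurement references unknown animal_id: ", orphan[1]),
                   "radecol_referential_error")
    for (an in unique(m$analyte)) {
      sub <- m[m$analyte == an, ]
      if (length(unique(sub$unit)) > 1)
        stop_radecol(paste0("inconsistent units for analyte ", an),
                     "radecol_validation_error")
      if (length(unique(sub$basis)) > 1)
        stop_radecol(paste0("inconsistent basis for analyte ", an),
                     "radecol_validation_error")
    }
  }
  invisible(x)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("cohort_dataset:", nrow(x$animals), "animals,",
      nrow(x$measurements), "measurements,",
      length(unique(x$measurements$analyte)), "analytes\n")
  invisible(x)
}

#' Read a cohort from CSV files
#'
#' Reads the animal and measurement tables (comma-separated, UTF-8, ISO-8601
#' dates, "." decimal mark) and returns a validated [cohort_dataset]. Row
#' order is preserved. Non-numeric biometric tokens (e.g. "/" for a missing
#' body mass) are read as `NA`.
#'
#' @param animal_csv_path,measurement_csv_path paths to the two CSV files.
#' @return A [cohort_dataset].
#' @export
read_cohort <- function(animal_csv_path, measurement_csv_path) {
  for (p in c(animal_csv_path, measurement_csv_path))
    if (!file.exists(p)) stop_radecol(paste0("file not found: ", p), "radecol_io_error")
  a <- utils::read.csv(animal_csv_path, stringsAsFactors = FALSE,
                       colClasses = "character")
  m <- utils::read.csv(measurement_csv_path, stringsAsFactors = FALSE,
                       colClasses = "character")
  miss <- setdiff(ANIMAL_COLUMNS, names(a))
  if (length(miss))
    stop_radecol(paste0("animal table missing column: ", miss[1]), "radecol_schema_error")
  miss <- setdiff(MEASUREMENT_COLUMNS, names(m))
  if (length(miss))
    stop_radecol(paste0("measurement table missing column: ", miss[1]), "radecol_schema_error")
  num <- function(v) suppressWarnings(as.numeric(v))
  a$sampling_date <- as.Date(a$sampling_date)
  for (col in c("latitude", "longitude", "age_years", "body_mass_kg", "body_length_cm"))
    a[[col]] <- num(a[[col]])
  if ("bci" %in% names(a)) a$bci <- num(a$bci)
  m$value <- num(m$value)
  m$censored <- as.logical(toupper(m$censored))
  if ("rel_uncertainty" %in% names(m)) m$rel_uncertainty <- num(m$rel_uncertainty)
  cohort_dataset(a, m)
}

#' Write a cohort to CSV files
#'
#' Inverse of [read_cohort()]: writes the two tables so that re-reading them
#' yields a field-for-field equal dataset. Dates are written ISO-8601; the
#' censored flag is written verbatim as TRUE/FALSE.
#'
#' @param dataset a [cohort_dataset].
#' @param animal_csv_path,measurement_csv_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(dataset, animal_csv_path, measurement_csv_path) {
  validate_cohort(dataset)
  a <- dataset$animals
  a$sampling_date <- format(a$sampling_date, "%Y-%m-%d")
  utils::write.csv(a, animal_csv_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$measurements, measurement_csv_path,
                   row.names = FALSE, quote = FALSE)
  invisible(c(animal_csv_path, measurement_csv_path))
}
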