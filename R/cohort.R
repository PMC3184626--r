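#' @importFrom rlang .data
#' @importFrom stats median quantile qnorm qt pnorm plogis qlogis rbinom rnorm
#'   rlnorm rbeta runif complete.cases model.matrix setNames sd var qbinom
#' @importFrom utils head
NULL

# Canonical sex / employment-status codings -----------------------------------

SEX_LEVELS <- c("male", "female")

EMPLOYMENT_LEVELS <- c(
  "currently_employed",
  "temporarily_discontinued",
  "indefinitely_discontinued",
  "other"
)

AGE_BAND_TABLE <- tibble::tibble(
  age_band = c("18-21", "22-29", "30-39", "40-49", "50-59", "60-64"),
  lower    = c(18L, 22L, 30L, 40L, 50L, 60L),
  upper    = c(21L, 29L, 39L, 49L, 59L, 64L)
)

#' Age bands used for sex-and-age stratification
#'
#' The six bands (18-21, 22-29, 30-39, 40-49, 50-59, 60-64) partition the
#' eligible working-age range 18-64 exactly. The top band is 60-64 because
#' eligibility is capped at 64 years.
#'
#' @return Character vector of band labels in ascending order.
#' @export
age_band_levels <- function() AGE_BAND_TABLE$age_band

#' Midpoint of each age band, in years
#'
#' Used when age enters a regression as a linear per-decade term: the band
#' midpoint divided by 10 gives the "10-year age group" covariate.
#'
#' @param age_band Character vector of band labels.
#' @return Numeric vector of band midpoints.
#' @export
age_band_midpoint <- function(age_band) {
  idx <- match(as.character(age_band), AGE_BAND_TABLE$age_band)
  if (anyNA(idx[!is.na(age_band)])) {
    bad <- unique(setdiff(as.character(age_band), AGE_BAND_TABLE$age_band))
    stop("unknown age band(s): ", paste(bad, collapse = ", "))
  }
  (AGE_BAND_TABLE$lower[idx] + AGE_BAND_TABLE$upper[idx]) / 2
}

#' Assign an age in years to its stratification band
#'
#' Band edges are inclusive; every integer age from 18 to 64 maps to exactly
#' one band.
#'
#' @param age Integer vector of ages in whole years.
#' @return Factor with levels `age_band_levels()`.
#' @export
#' @examples
#' assign_age_band(c(21, 22, 64))
assign_age_band <- function(age) {
  age <- as.numeric(age)
  out_of_range <- !is.na(age) & (age < 18 | age > 64)
  if (any(out_of_range)) {
    stop(
      "age outside the eligible range 18-64: ",
      paste(head(unique(age[out_of_range]), 5), collapse = ", ")
    )
  }
  cut(
    age,
    breaks = c(AGE_BAND_TABLE$lower - 0.5, 64.5),
    labels = AGE_BAND_TABLE$age_band
  )
}

#' Partition patient records into sex-by-age-band strata
#'
#' Adds an `age_band` column and splits the records into the 12 strata
#' (2 sexes x 6 bands). Empty strata are retained so the partition is always
#' exhaustive; cell sizes sum to the number of input records.
#'
#' @param records Tibble of patient records with `age` and `sex` columns.
#' @return Named list of tibbles, one per stratum, named `"<sex>.<band>"`.
#' @export
stratify <- function(records) {
  records <- dplyr::mutate(
    records,
    age_band = assign_age_band(.data$age),
    sex = factor(.data$sex, levels = SEX_LEVELS)
  )
  idx <- interaction(records$sex, records$age_band, sep = ".")
  split(records, idx, drop = FALSE)
}

#' Per-stratum record counts
#'
#' @param records Tibble with `age` and `sex`.
#' @return Tibble with `sex`, `age_band`, `n` (all 12 cells, zeros kept).
#' @export
stratum_counts <- function(records) {
  cells <- stratify(records)
  parts <- strsplit(names(cells), ".", fixed = TRUE)
  tibble::tibble(
    sex = factor(vapply(parts, `[`, "", 1), levels = SEX_LEVELS),
    age_band = factor(vapply(parts, `[`, "", 2), levels = age_band_levels()),
    n = unname(vapply(cells, nrow, 0L))
  ) |>
    dplyr::arrange(.data$sex, .data$age_band)
}

# Patient-table I/O ------------------------------------------------------------

#' Item-response column names for the four inventories
#'
#' @return Named list of column-name vectors.
#' @export
item_columns <- function() {
  list(
    chalder = sprintf("chalder_%02d", 1:11),
    sf36pf  = sprintf("sf36pf_%02d", 1:10),
    hadsA   = sprintf("hadsA_%d", 1:7),
    hadsD   = sprintf("hadsD_%d", 1:7)
  )
}

patient_table_columns <- function() {
  c(
    "patient_id", "centre", "assessment_year", "age", "sex",
    "duration_illness", "employment_status",
    unlist(item_columns(), use.names = FALSE), "vas"
  )
}

#' Read a patient assessment table from delimited text
#'
#' Expects a comma-separated file with a header row naming the schema columns:
#' demographics, illness duration in months, 4-category employment status and
#' item-level inventory responses. Empty fields become explicit missing values.
#' Records outside the 18-64 year eligibility window are excluded (with a
#' message) when `eligibility_filter = TRUE`.
#'
#' @param path Path to the CSV file.
#' @param eligibility_filter Drop records with age outside 18-64?
#' @return Tibble of patient records, one row per retained input row.
#' @export
load_patient_table <- function(path, eligibility_filter = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("patient_id", "centre", "assessment_year", "age", "sex",
                "duration_illness", "employment_status")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop("patient table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tbl) == 0) {
    return(empty_patient_table())
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  bad_age <- which(!is.na(tbl$age) & is.na(num(tbl$age)))
  if (length(bad_age) > 0) {
    stop("non-numeric age in row(s): ", paste(head(bad_age, 10), collapse = ", "))
  }

  status <- tbl$employment_status
  unknown <- !is.na(status) & !(status %in% EMPLOYMENT_LEVELS)
  if (any(unknown)) {
    warning(sum(unknown), " unrecognised employment_status value(s) set to missing")
    status[unknown] <- NA_character_
  }

  item_cols <- intersect(unlist(item_columns(), use.names = FALSE), names(tbl))
  out <- tibble::tibble(
    patient_id = tbl$patient_id,
    centre = tbl$centre,
    assessment_year = as.integer(num(tbl$assessment_year)),
    age = as.integer(num(tbl$age)),
    sex = factor(tbl$sex, levels = SEX_LEVELS),
    duration_illness = num(tbl$duration_illness),
    employment_status = factor(status, levels = EMPLOYMENT_LEVELS)
  )
  for (cl in item_cols) out[[cl]] <- num(tbl[[cl]])
  if ("vas" %in% names(tbl)) out$vas <- num(tbl$vas)

  if (any(!is.na(out$duration_illness) & out$duration_illness < 0)) {
    stop("negative duration_illness is not allowed")
  }

  if (eligibility_filter) {
    ineligible <- !is.na(out$age) & (out$age < 18 | out$age > 64)
    if (any(ineligible)) {
      message(sum(ineligible), " record(s) outside the 18-64 eligibility window excluded")
      out <- out[!ineligible, , drop = FALSE]
    }
  }
  out
}

empty_patient_table <- function() {
  out <- tibble::tibble(
    patient_id = character(), centre = character(),
    assessment_year = integer(), age = integer(),
    sex = factor(character(), levels = SEX_LEVELS),
    duration_illness = numeric(),
    employment_status = factor(character(), levels = EMPLOYMENT_LEVELS)
  )
  for (cl in unlist(item_columns(), use.names = FALSE)) out[[cl]] <- numeric()
  out$vas <- numeric()
  out
}

#' Write a patient table as comma-separated text
#'
#' Missing values are written as empty fields so `load_patient_table()`
#' round-trips them.
#'
#' @param records Patient-record tibble.
#' @param path Output path.
#' @export
write_patient_table <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}

# Economics and external-sample tables -----------------------------------------

#' Read the per-stratum economics table
#'
#' Columns: `sex`, `age_band`, `mean_annual_income` (currency per year),
#' `pct_population` (catchment population of the contributing services'
#' primary care trusts; may be blank where bands are pooled) and
#' `uk_population_thousands`.
#'
#' @param path Path to the CSV file.
#' @return Tibble keyed by sex and age band.
#' @export
load_economics_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("sex", "age_band", "mean_annual_income",
                "pct_population", "uk_population_thousands")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop("economics table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(tbl$mean_annual_income <= 0, na.rm = TRUE)) stop("mean_annual_income must be > 0")
  if (any(tbl$pct_population <= 0, na.rm = TRUE)) stop("pct_population must be > 0 where present")
  if (any(tbl$uk_population_thousands <= 0, na.rm = TRUE)) {
    stop("uk_population_thousands must be > 0 where present")
  }
  dplyr::mutate(
    tbl,
    sex = factor(.data$sex, levels = SEX_LEVELS),
    age_band = factor(.data$age_band, levels = age_band_levels())
  )
}

#' Read an external duration-of-unemployment sample
#'
#' Columns: `sex`, `duration_illness_months` (> 0) and
#' `duration_unemployment_months` (>= 0). Unemployment longer than illness is
#' not rejected here; the fraction estimator reports such records.
#'
#' @param path Path to the CSV file.
#' @return Tibble of external-sample records.
#' @export
load_external_sample <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("sex", "duration_illness_months", "duration_unemployment_months")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop("external sample is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(tbl$duration_illness_months) || anyNA(tbl$duration_unemployment_months)) {
    stop("external-sample durations must be present in every row")
  }
  if (any(tbl$duration_unemployment_months < 0)) {
    stop("duration_unemployment_months must be >= 0")
  }
  dplyr::mutate(tbl, sex = factor(.data$sex, levels = SEX_LEVELS))
}

# Packaged reference inputs -----------------------------------------------------

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "cfsmecosts")
  if (p == "") stop("packaged data file not found: ", file)
  p
}

#' Per-stratum summary of the assessed referral cohort
#'
#' The published per-stratum inputs of the cost model for the 2,170 adults
#' assessed by the five contributing NHS specialist services over 2006-2010:
#' patient count, percentage who had discontinued employment, and median
#' duration of illness in months, by sex and age band.
#'
#' @return Tibble with `sex`, `age_band`, `n_patients`, `frac_discontinued`,
#'   `median_illness_months`.
#' @export
reference_stratum_summary <- function() {
  tbl <- readr::read_csv(extdata_path("cohort_stratum_summary.csv"),
                         show_col_types = FALSE)
  dplyr::mutate(
    tbl,
    sex = factor(.data$sex, levels = SEX_LEVELS),
    age_band = factor(.data$age_band, levels = age_band_levels()),
    frac_discontinued = .data$pct_discontinued / 100
  ) |>
    dplyr::select("sex", "age_band", "n_patients", "frac_discontinued",
                  "median_illness_months")
}

#' Reference economics table (2009 incomes, mid-study populations)
#'
#' Office for National Statistics mean annual incomes by sex and age band,
#' the catchment (primary care trust) populations of the five contributing
#' services, and UK population estimates in thousands. Catchment and UK
#' population cells for the 18-21 band are blank: that band is pooled into
#' 22-29 for access rates and projection.
#'
#' @return Tibble as from [load_economics_table()].
#' @export
reference_economics <- function() {
  load_economics_table(extdata_path("uk_income_population.csv"))
}

#' Reference unemployment-fraction estimates by sex
#'
#' The mean fraction (duration of unemployment)/(duration of illness) with
#' 95% confidence bounds, estimated from an external sample of 60 patients
#' (22 men, 38 women) assessed mid-2010.
#'
#' @return Tibble with `sex`, `n`, `mean_fraction`, `ci_low`, `ci_high`.
#' @export
reference_unemployment_fractions <- function() {
  tbl <- readr::read_csv(extdata_path("unemployment_fractions.csv"),
                         show_col_types = FALSE)
  dplyr::mutate(tbl, sex = factor(.data$sex, levels = SEX_LEVELS))
}
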