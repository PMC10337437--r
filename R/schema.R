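#' Survey microdata schema
#'
#' The analysis operates on a tibble with one row per participant. Categorical
#' columns are factors with the fixed level sets below; biomarkers may be `NA`;
#' all self-report flags are logical. `microdata_schema()` returns the column
#' specification, `validate_microdata()` checks a tibble against it.
#'
#' @return A named list with one entry per column: either a character vector of
#'   factor levels, or one of `"character"`, `"integer"`, `"double"`,
#'   `"logical"`.
#' @export
microdata_schema <- function() {
  c(
    list(
      participant_id = "character",
      household_id = "character",
      setting = setting_levels(),
      age_years = "integer",
      age_group = age_group_levels(),
      sex = c("male", "female"),
      education = c("none_or_less_than_primary", "primary",
                    "secondary_or_higher"),
      marital = c("married_or_with_spouse", "widowed_or_not_with_spouse",
                  "never")
    ),
    stats::setNames(rep(list("integer"), 20L), asset_columns()),
    list(
      fbg_mg_dl = "double",
      hba1c_pct = "double",
      takes_t2d_drugs = "logical",
      takes_insulin = "logical",
      ever_tested_3y = "logical",
      ever_told_t2d = "logical",
      care_past_12m = "logical",
      advice_diet = "logical",
      advice_weight = "logical",
      advice_smoking = "logical",
      advice_exercise = "logical",
      provider_of_diagnosis = c("public", "private", "other", "none")
    )
  )
}

#' @rdname microdata_schema
#' @export
setting_levels <- function() {
  c("hospital_based", "health_center_based", "health_center_with_context",
    "community_based", "coexistence")
}

#' @rdname microdata_schema
#' @export
age_group_levels <- function() c("40-49", "50-59", "60+")

#' @rdname microdata_schema
#' @export
asset_columns <- function() {
  paste0("asset_", c(
    "electricity", "radio", "tv", "mobile_phone", "landline_phone",
    "refrigerator", "wardrobe", "sewing_machine", "bed", "sofa",
    "fan", "bicycle", "motorcycle", "car_truck", "boat_motor",
    "water_pump", "plough", "oxcart", "bank_account", "agricultural_land"
  ))
}

advice_columns <- function() {
  c("advice_diet", "advice_weight", "advice_smoking", "advice_exercise")
}

age_to_group <- function(age_years) {
  lv <- age_group_levels()
  factor(ifelse(age_years < 50, lv[1L], ifelse(age_years < 60, lv[2L], lv[3L])),
         levels = lv)
}

#' Validate survey microdata against the schema
#'
#' Checks column presence, types, factor domains and record-level invariants
#' (age at least 40 and consistent with `age_group`, biomarker plausibility
#' ranges, and that a diagnosing provider is recorded if and only if the
#' participant reports having been told they have T2D).
#'
#' @param data A tibble of survey microdata.
#' @return `data`, invisibly, if valid; otherwise an error naming the column
#'   and (where applicable) the first offending row.
#' @export
validate_microdata <- function(data) {
  schema <- microdata_schema()
  missing_cols <- setdiff(names(schema), names(data))
  if (length(missing_cols) > 0L) {
    stop("microdata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(data), names(schema))
  if (length(unknown) > 0L) {
    stop("microdata has unknown column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (col in names(schema)) {
    spec <- schema[[col]]
    x <- data[[col]]
    if (length(spec) > 1L) {          # factor with fixed levels
      vals <- as.character(x)
      bad <- which(!is.na(vals) & !(vals %in% spec))
      if (length(bad) > 0L) {
        stop(sprintf("column '%s': value '%s' at row %d is not one of {%s}",
                     col, vals[bad[1L]], bad[1L], paste(spec, collapse = ", ")),
             call. = FALSE)
      }
      if (anyNA(vals)) {
        bad <- which(is.na(vals))
        stop(sprintf("column '%s': missing value at row %d", col, bad[1L]),
             call. = FALSE)
      }
    } else {
      ok <- switch(spec,
        character = is.character(x),
        integer   = is.numeric(x) && all(is.na(x) | x == round(x)),
        double    = is.numeric(x),
        logical   = is.logical(x)
      )
      if (!ok) {
        stop(sprintf("column '%s': expected %s", col, spec), call. = FALSE)
      }
      if (spec != "double" && spec != "integer" && anyNA(x)) {
        stop(sprintf("column '%s': missing value at row %d", col,
                     which(is.na(x))[1L]), call. = FALSE)
      }
    }
  }
  bad <- which(data$age_years < 40L)
  if (length(bad) > 0L) {
    stop(sprintf("column 'age_years': value below 40 at row %d", bad[1L]),
         call. = FALSE)
  }
  grp <- as.character(age_to_group(data$age_years))
  bad <- which(grp != as.character(data$age_group))
  if (length(bad) > 0L) {
    stop(sprintf("column 'age_group': inconsistent with age_years at row %d",
                 bad[1L]), call. = FALSE)
  }
  bad <- which(!is.na(data$fbg_mg_dl) &
                 (data$fbg_mg_dl <= 30 | data$fbg_mg_dl >= 600))
  if (length(bad) > 0L) {
    stop(sprintf("column 'fbg_mg_dl': value outside (30, 600) at row %d",
                 bad[1L]), call. = FALSE)
  }
  bad <- which(!is.na(data$hba1c_pct) &
                 (data$hba1c_pct <= 3 | data$hba1c_pct >= 20))
  if (length(bad) > 0L) {
    stop(sprintf("column 'hba1c_pct': value outside (3, 20) at row %d",
                 bad[1L]), call. = FALSE)
  }
  has_provider <- as.character(data$provider_of_diagnosis) != "none"
  bad <- which(has_provider != data$ever_told_t2d)
  if (length(bad) > 0L) {
    stop(sprintf(paste0("column 'provider_of_diagnosis': provider recorded ",
                        "iff ever_told_t2d violated at row %d"), bad[1L]),
         call. = FALSE)
  }
  invisible(data)
}

# Coerce character columns read from CSV to schema factors.
as_microdata <- function(data) {
  schema <- microdata_schema()
  for (col in names(schema)) {
    spec <- schema[[col]]
    if (length(spec) > 1L && col %in% names(data)) {
      data[[col]] <- factor(as.character(data[[col]]), levels = spec)
    } else if (identical(spec, "integer") && col %in% names(data)) {
      data[[col]] <- as.integer(data[[col]])
    }
  }
  tibble::as_tibble(data)
}

#' Read and write survey microdata CSV
#'
#' UTF-8 CSV with a header row, one row per participant, columns exactly as in
#' [microdata_schema()], and `NA` as the missingness marker. The round trip
#' `read_microdata(write_microdata(x, path))` reproduces `x` field for field.
#'
#' @param data Microdata tibble (validated before writing).
#' @param path File path.
#' @return `read_microdata()` returns a validated microdata tibble;
#'   `write_microdata()` returns `path` invisibly.
#' @export
write_microdata <- function(data, path) {
  validate_microdata(data)
  out <- data
  for (col in names(out)) {
    if (is.factor(out[[col]])) out[[col]] <- as.character(out[[col]])
  }
  readr::write_csv(out, path, na = "NA")
  invisible(path)
}

#' @rdname write_microdata
#' @export
read_microdata <- function(path) {
  schema <- microdata_schema()
  type_of <- function(spec) {
    if (length(spec) > 1L) return(readr::col_character())
    switch(spec,
      character = readr::col_character(),
      integer   = readr::col_integer(),
      double    = readr::col_double(),
      logical   = readr::col_logical()
    )
  }
  cols <- lapply(schema, type_of)
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing_cols <- setdiff(names(schema), header)
  if (length(missing_cols) > 0L) {
    stop("file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(header, names(schema))
  if (length(unknown) > 0L) {
    stop("file has unknown column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  data <- readr::read_csv(path, col_types = do.call(readr::cols, cols),
                          na = "NA", show_col_types = FALSE)
  prob <- readr::problems(data)
  if (nrow(prob) > 0L) {
    stop(sprintf("malformed value in column %s at file row %d",
                 prob$col[1L], prob$row[1L]), call. = FALSE)
  }
  data <- as_microdata(data)
  validate_microdata(data)
  data
}

#' Round half away from zero
#'
#' The rounding convention used for displayed percentages (so 10.75 displays
#' as 10.8, not banker's 10.7 via [round()]).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
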