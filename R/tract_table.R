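#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Canonical column layout of a tract table. Exposure columns carry the unit in
# the name so files are self-describing.
tract_table_columns <- c(
  "tract_id", "bc_ugm3", "no2_ppb", "pop_total", "pop_nonwhite",
  "pop_poverty", "poverty_moe", "ej_flag", "ej_criterion"
)

ej_criterion_levels <- c("race", "poverty", "race_and_poverty", "none")

# Map from pollutant name used throughout the package to its exposure column.
pollutant_column <- function(pollutant) {
  cols <- c(bc = "bc_ugm3", no2 = "no2_ppb")
  if (!pollutant %in% names(cols)) {
    stop("unknown pollutant '", pollutant, "'; expected one of: ",
      paste(names(cols), collapse = ", "),
      call. = FALSE
    )
  }
  cols[[pollutant]]
}

#' Validate a tract table
#'
#' Checks the schema and the row-level invariants of a tract table:
#' demographic counts cannot exceed the total population, counts and
#' exposures are non-negative, and the EJ flag is consistent with the EJ
#' criterion (`ej_flag` is `TRUE` exactly when `ej_criterion != "none"`).
#'
#' @param tracts A data frame with the tract-table columns (see
#'   [read_tract_table()]).
#' @return The validated table, invisibly coerced to a tibble.
#' @export
validate_tract_table <- function(tracts) {
  missing <- setdiff(tract_table_columns, names(tracts))
  if (length(missing) > 0) {
    stop("tract table is missing required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  tracts <- as_tibble(tracts)
  if (anyDuplicated(tracts$tract_id)) {
    stop("duplicated tract_id values in tract table", call. = FALSE)
  }
  bad <- function(cond) tracts$tract_id[which(cond)]

  for (col in c("pop_total", "pop_nonwhite", "pop_poverty", "poverty_moe")) {
    neg <- bad(tracts[[col]] < 0)
    if (length(neg) > 0) {
      stop("negative ", col, " for tract(s): ",
        paste(utils::head(neg, 5), collapse = ", "),
        call. = FALSE
      )
    }
  }
  for (col in c("bc_ugm3", "no2_ppb")) {
    neg <- bad(!is.na(tracts[[col]]) & tracts[[col]] < 0)
    if (length(neg) > 0) {
      stop("negative exposure in ", col, " for tract(s): ",
        paste(utils::head(neg, 5), collapse = ", "),
        call. = FALSE
      )
    }
  }
  over <- bad(tracts$pop_nonwhite > tracts$pop_total |
    tracts$pop_poverty > tracts$pop_total)
  if (length(over) > 0) {
    stop("demographic count exceeds total population for tract(s): ",
      paste(utils::head(over, 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(tracts$ej_criterion %in% ej_criterion_levels)) {
    stop("ej_criterion must be one of: ",
      paste(ej_criterion_levels, collapse = ", "),
      call. = FALSE
    )
  }
  inconsistent <- bad(tracts$ej_flag != (tracts$ej_criterion != "none"))
  if (length(inconsistent) > 0) {
    stop("ej_flag inconsistent with ej_criterion for tract(s): ",
      paste(utils::head(inconsistent, 5), collapse = ", "),
      call. = FALSE
    )
  }
  tracts
}

#' Read a census-tract table from CSV
#'
#' The tract table is the central input: one row per census tract with the
#' modelled long-term exposure for each pollutant (black carbon in ug/m3,
#' NO2 in ppb), population counts, the published margin of error on the
#' poverty count, and the environmental-justice designation.
#'
#' @param path Path to a comma-separated, UTF-8, headered CSV with columns
#'   `tract_id, bc_ugm3, no2_ppb, pop_total, pop_nonwhite, pop_poverty,
#'   poverty_moe, ej_flag, ej_criterion`.
#' @return A tibble, one row per tract, validated against the table
#'   invariants.
#' @seealso [write_tract_table()], [validate_tract_table()]
#' @export
read_tract_table <- function(path) {
  tracts <- readr::read_csv(
    path,
    col_types = readr::cols(
      tract_id = readr::col_character(),
      bc_ugm3 = readr::col_double(),
      no2_ppb = readr::col_double(),
      pop_total = readr::col_double(),
      pop_nonwhite = readr::col_double(),
      pop_poverty = readr::col_double(),
      poverty_moe = readr::col_double(),
      ej_flag = readr::col_logical(),
      ej_criterion = readr::col_character()
    )
  )
  validate_tract_table(tracts)
}

#' Write a tract table to CSV
#'
#' @param tracts A valid tract table (see [read_tract_table()] for the
#'   schema).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tract_table <- function(tracts, path) {
  tracts <- validate_tract_table(tracts)
  readr::write_csv(tracts, path)
  invisible(path)
}
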