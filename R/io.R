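cohort_csv_columns <- c(
  "patient_id", "fmc_min", "ecg_min", "txf_min", "twt_min",
  "FMC", "ECG", "TXF", "TWT", "EF", "LOS"
)

#' Read and write cohort CSV files
#'
#' The cohort interchange format has the fixed header
#' `patient_id,fmc_min,ecg_min,txf_min,twt_min,FMC,ECG,TXF,TWT,EF,LOS`:
#' durations as decimal minutes, delay flags and outcomes as 0/1. Reading
#' validates the header (naming any missing column) and rejects non-binary
#' flag values; write/read round-trips are lossless at full double
#' precision.
#'
#' @param cohort Cohort tibble (see [generate_cohort()]).
#' @param path File path.
#' @return `read_cohort_csv()` returns the cohort tibble;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  missing <- setdiff(cohort_csv_columns, names(cohort))
  if (length(missing) > 0) {
    rlang::abort(paste0("cohort missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  out <- dplyr::select(cohort, dplyr::all_of(cohort_csv_columns)) |>
    # 17 significant digits guarantee a bit-exact double round-trip
    dplyr::mutate(dplyr::across(
      dplyr::ends_with("_min"),
      function(x) formatC(x, digits = 17, format = "g")
    ))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  # durations come in as text and through strtod so the 17-digit
  # representation round-trips bit-exactly
  cohort <- readr::read_csv(path, col_types = readr::cols(
    fmc_min = readr::col_character(), ecg_min = readr::col_character(),
    txf_min = readr::col_character(), twt_min = readr::col_character(),
    .default = readr::col_double()
  ))
  missing <- setdiff(cohort_csv_columns, names(cohort))
  if (length(missing) > 0) {
    rlang::abort(paste0("cohort file header missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  for (col in c("fmc_min", "ecg_min", "txf_min", "twt_min")) {
    parsed <- as.numeric(cohort[[col]])
    if (anyNA(parsed) && !anyNA(cohort[[col]])) {
      rlang::abort(paste0("column '", col, "' contains non-numeric values"))
    }
    cohort[[col]] <- parsed
  }
  for (col in c("FMC", "ECG", "TXF", "TWT", "EF", "LOS")) {
    if (!all(cohort[[col]] %in% c(0, 1))) {
      rlang::abort(paste0("column '", col, "' contains non-binary values"))
    }
    cohort[[col]] <- as.integer(cohort[[col]])
  }
  cohort$patient_id <- as.integer(cohort$patient_id)
  dplyr::select(cohort, dplyr::all_of(cohort_csv_columns))
}

#' Read and write truth-table CSV files
#'
#' Columns are the condition names followed by `OUT` (one of 1/0/C/R), `n`
#' and `incl`.
#'
#' @param truth_table A `qca_truth_table`.
#' @param path File path.
#' @param conditions Condition names expected when reading; default the four
#'   care stages.
#' @param outcome Outcome label to attach when reading.
#' @return The truth table (reading) or `path`, invisibly (writing).
#' @export
write_truth_table_csv <- function(truth_table, path) {
  conditions <- attr(truth_table, "conditions")
  out <- tibble::as_tibble(truth_table) |>
    dplyr::select(dplyr::all_of(c(conditions, "OUT", "n", "incl")))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_truth_table_csv
#' @export
read_truth_table_csv <- function(path, conditions = stemi_stages,
                                 outcome = NA_character_) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  tt <- readr::read_csv(path, col_types = readr::cols(
    OUT = readr::col_character(), .default = readr::col_double()
  ))
  missing <- setdiff(c(conditions, "OUT", "n", "incl"), names(tt))
  if (length(missing) > 0) {
    rlang::abort(paste0("truth-table file missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  for (cond in conditions) {
    if (!all(tt[[cond]] %in% c(0, 1))) {
      rlang::abort(paste0("condition '", cond, "' contains non-binary values"))
    }
    tt[[cond]] <- as.integer(tt[[cond]])
  }
  tt$n <- as.integer(tt$n)
  structure(tt,
            conditions = conditions, outcome = outcome,
            n_cases = sum(tt$n),
            class = c("qca_truth_table", class(tibble::tibble())))
}

#' Write a simulated trajectory to CSV
#'
#' @param trajectory An `sd_trajectory`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "sd_trajectory"))
  readr::write_csv(tibble::as_tibble(trajectory), path)
  invisible(path)
}

#' Write sensitivity bands to CSV
#'
#' @param bands A `sensitivity_bands` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_bands_csv <- function(bands, path) {
  stopifnot(inherits(bands, "sensitivity_bands"))
  readr::write_csv(tibble::as_tibble(bands), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file extension selects the parser (`.yaml`/`.yml` or `.json`); the
#' result is validated with [validate_pipeline_config()] before being
#' returned, so an invalid configuration never reaches the pipeline.
#'
#' @param path File path.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  config <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    rlang::abort("config must be a .yaml, .yml or .json file")
  }
  validate_pipeline_config(config)
}
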