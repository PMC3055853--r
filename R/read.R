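#' Define a closed observation window
#'
#' The window over which claims are ascertained, inclusive at both ends
#' (a stated calendar year such as "Jan 1 to Dec 31" is a closed interval).
#'
#' @param start,end Window bounds, coercible to `Date` (ISO-8601 strings work).
#'
#' @return A list of class `observation_window` with `Date` elements
#'   `start` and `end`.
#' @export
#' @examples
#' observation_window("2008-01-01", "2008-12-31")
observation_window <- function(start, end) {
  start <- parse_iso_date(start, "start")
  end <- parse_iso_date(end, "end")
  if (start > end) {
    abort("Window `start` must not be after `end`.")
  }
  structure(list(start = start, end = end), class = "observation_window")
}

#' @export
print.observation_window <- function(x, ...) {
  cat("<observation_window> ", format(x$start), " .. ", format(x$end),
    " (inclusive)\n",
    sep = ""
  )
  invisible(x)
}

in_window <- function(dates, window) {
  dates >= window$start & dates <= window$end
}

parse_iso_date <- function(x, what) {
  if (inherits(x, "Date")) {
    return(x)
  }
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(out)) {
    abort(paste0("`", what, "` is not a valid ISO-8601 (YYYY-MM-DD) date."))
  }
  out
}

# Strict ISO date parsing for file columns: returns Dates, aborting with the
# offending data line numbers (header = line 1) when any value fails to parse.
parse_date_column <- function(x, column, path) {
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(out) | is.na(x) | !grepl("^\\d{4}-\\d{2}-\\d{2}$", x))
  if (length(bad) > 0) {
    abort(paste0(
      "Unparseable `", column, "` in '", path, "' at line",
      if (length(bad) > 1) "s " else " ",
      paste(head(bad, 5) + 1L, collapse = ", "),
      if (length(bad) > 5) " ..." else "",
      " (expected YYYY-MM-DD)."
    ))
  }
  out
}

check_columns <- function(found, required, path) {
  missing <- setdiff(required, found)
  extra <- setdiff(found, required)
  if (length(missing) > 0 || length(extra) > 0) {
    msg <- paste0("'", path, "' does not have the expected column layout.")
    if (length(missing) > 0) {
      msg <- c(msg, paste0("Missing column(s): ", paste(missing, collapse = ", ")))
    }
    if (length(extra) > 0) {
      msg <- c(msg, paste0("Unexpected column(s): ", paste(extra, collapse = ", ")))
    }
    abort(paste(msg, collapse = " "))
  }
  invisible(TRUE)
}

read_delimited <- function(path, col_names) {
  if (!file.exists(path)) {
    abort(paste0("File not found: '", path, "'"))
  }
  df <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  check_columns(names(df), col_names, path)
  df
}

#' Read outpatient dialysis claims
#'
#' Reads a claims file (`patient_id,service_date,procedure_code,setting`),
#' keeps only outpatient claims whose procedure code belongs to `code_set`
#' and whose service date falls inside the closed observation window, and
#' collapses claims identical in (patient, date, code) to a single record.
#' Inpatient dialysis claims are discarded with a logged count: the case
#' definitions are exclusively outpatient.
#'
#' @param path Path to a UTF-8 CSV file with header
#'   `patient_id,service_date,procedure_code,setting`.
#' @param window An [observation_window()].
#' @param code_set A [code_set()]; defaults to the CCP outpatient dialysis
#'   codes of [ccp_dialysis_codes()].
#'
#' @return A tibble with columns `patient_id`, `service_date` (`Date`),
#'   `procedure_code`, `setting` (all retained rows have
#'   `setting == "outpatient"`), one row per distinct
#'   (patient, date, code) triple, sorted by patient then date then code.
#' @export
read_claims <- function(path, window, code_set = ccp_dialysis_codes()) {
  stopifnot(inherits(window, "observation_window"))
  df <- read_delimited(
    path,
    c("patient_id", "service_date", "procedure_code", "setting")
  )
  if (nrow(df) == 0) {
    return(tibble(
      patient_id = character(), service_date = as.Date(character()),
      procedure_code = character(), setting = character()
    ))
  }
  bad_setting <- which(!df$setting %in% c("outpatient", "inpatient"))
  if (length(bad_setting) > 0) {
    abort(paste0(
      "Invalid `setting` (must be 'outpatient' or 'inpatient') in '", path,
      "' at line", if (length(bad_setting) > 1) "s " else " ",
      paste(head(bad_setting, 5) + 1L, collapse = ", "),
      if (length(bad_setting) > 5) " ..." else "", "."
    ))
  }
  df$service_date <- parse_date_column(df$service_date, "service_date", path)

  n_inpatient <- sum(df$setting == "inpatient")
  if (n_inpatient > 0) {
    inform(paste0(
      "read_claims: discarded ", n_inpatient,
      " inpatient claim(s); definitions use outpatient claims only."
    ))
  }
  out <- df |>
    dplyr::filter(
      .data$setting == "outpatient",
      .data$procedure_code %in% code_set$code,
      in_window(.data$service_date, window)
    ) |>
    dplyr::distinct(
      .data$patient_id, .data$service_date, .data$procedure_code,
      .keep_all = TRUE
    ) |>
    dplyr::arrange(.data$patient_id, .data$service_date, .data$procedure_code)
  as_tibble(out)
}

#' Read the registry reference standard
#'
#' Reads a registry extract (`patient_id,start_date`): one chronic dialysis
#' patient per row with the date of first dialysis for end-stage renal
#' disease (or the date a nephrologist deemed dialysis chronic). Duplicate
#' patient entries are resolved to the earliest start date with a warning.
#'
#' @param path Path to a UTF-8 CSV file with header `patient_id,start_date`.
#'
#' @return A tibble with columns `patient_id` and `start_date` (`Date`),
#'   at most one row per patient, sorted by `patient_id`.
#' @export
read_registry <- function(path) {
  df <- read_delimited(path, c("patient_id", "start_date"))
  if (nrow(df) == 0) {
    return(tibble(patient_id = character(), start_date = as.Date(character())))
  }
  df$start_date <- parse_date_column(df$start_date, "start_date", path)
  dup <- unique(df$patient_id[duplicated(df$patient_id)])
  if (length(dup) > 0) {
    warn(paste0(
      "read_registry: ", length(dup),
      " patient(s) appear more than once; keeping the earliest start_date ",
      "for: ", paste(head(dup, 5), collapse = ", "),
      if (length(dup) > 5) " ..." else "", "."
    ))
  }
  df |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(start_date = min(.data$start_date), .groups = "drop") |>
    dplyr::arrange(.data$patient_id)
}

#' Read optional patient attributes
#'
#' Attributes (`patient_id,birth_year,sex`) support cohort summaries only;
#' they play no role in classification. `birth_year` may be blank; `sex`
#' must be one of `male`, `female`, `unknown`, or blank (read as `unknown`).
#'
#' @param path Path to a UTF-8 CSV file with header
#'   `patient_id,birth_year,sex`.
#'
#' @return A tibble with columns `patient_id`, `birth_year` (integer, may be
#'   `NA`) and `sex` (factor male/female/unknown).
#' @export
read_attributes <- function(path) {
  df <- read_delimited(path, c("patient_id", "birth_year", "sex"))
  if (nrow(df) == 0) {
    return(tibble(
      patient_id = character(), birth_year = integer(),
      sex = factor(character(), levels = c("male", "female", "unknown"))
    ))
  }
  birth_year <- suppressWarnings(as.integer(df$birth_year))
  bad <- which(!is.na(df$birth_year) & nzchar(df$birth_year) & is.na(birth_year))
  if (length(bad) > 0) {
    abort(paste0(
      "Unparseable `birth_year` in '", path, "' at line",
      if (length(bad) > 1) "s " else " ",
      paste(head(bad, 5) + 1L, collapse = ", "), "."
    ))
  }
  sex <- df$sex
  sex[is.na(sex) | !nzchar(sex)] <- "unknown"
  bad_sex <- which(!sex %in% c("male", "female", "unknown"))
  if (length(bad_sex) > 0) {
    abort(paste0(
      "Invalid `sex` in '", path, "' at line",
      if (length(bad_sex) > 1) "s " else " ",
      paste(head(bad_sex, 5) + 1L, collapse = ", "),
      " (expected male/female/unknown)."
    ))
  }
  tibble(
    patient_id = df$patient_id,
    birth_year = birth_year,
    sex = factor(sex, levels = c("male", "female", "unknown"))
  )
}

#' Read an explicit study-population file
#'
#' One patient id per line (or a single-column CSV with header `patient_id`).
#' Supplying the population pins the denominator `N` of the agreement
#' statistics, which otherwise defaults to the union of patients seen in the
#' input files.
#'
#' @param path Path to the population file.
#' @return Character vector of unique patient ids.
#' @export
read_population <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: '", path, "'"))
  }
  ids <- readr::read_lines(path)
  ids <- ids[nzchar(ids)]
  if (length(ids) > 0 && identical(ids[[1]], "patient_id")) {
    ids <- ids[-1]
  }
  unique(ids)
}
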