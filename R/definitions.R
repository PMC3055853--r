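#' The four claims-based chronic dialysis case definitions
#'
#' Identifiers for the four temporal case definitions, from least to most
#' restrictive:
#'
#' * `d1`: at least 1 outpatient claim,
#' * `d2`: at least 2 outpatient claims (on distinct days),
#' * `d3`: at least 2 outpatient claims at least 90 days apart,
#' * `d4`: continuous outpatient claims spanning at least 90 days with no
#'   gap between successive claims greater than 21 days.
#'
#' The definitions are nested: every `d4` positive is `d3` positive, every
#' `d3` positive is `d2` positive, and every `d2` positive is `d1` positive.
#'
#' @return Named character vector mapping definition id to a human-readable
#'   label.
#' @export
dialysis_definitions <- function() {
  c(
    d1 = "At least 1 outpatient claim",
    d2 = "At least 2 outpatient claims",
    d3 = "At least 2 outpatient claims at least 90 days apart",
    d4 = "Continuous outpatient claims at least 90 days apart with no gap in claims greater than 21 days"
  )
}

match_definition <- function(definition) {
  match.arg(definition, names(dialysis_definitions()))
}

#' Collapse claims to per-patient claim-day series
#'
#' The canonical input to every case definition: for each patient, the
#' strictly increasing sequence of distinct calendar days carrying at least
#' one qualifying outpatient dialysis claim. Several claims on one day
#' (distinct codes, or billing resubmissions) collapse to a single claim day,
#' so same-day duplicates cannot manufacture chronicity.
#'
#' @param claims A claims tibble as returned by [read_claims()] (already
#'   filtered to outpatient dialysis codes within the window).
#' @param window Optional [observation_window()]; if given, dates outside the
#'   window raise an error (claims are expected to be pre-filtered).
#'
#' @return A tibble with columns `patient_id`, `dates` (list-column of sorted
#'   distinct `Date` vectors) and `n_days`, one row per patient with at least
#'   one claim.
#' @export
to_day_series <- function(claims, window = NULL) {
  if (nrow(claims) == 0) {
    return(tibble(
      patient_id = character(), dates = list(), n_days = integer()
    ))
  }
  if (!is.null(window) && !all(in_window(claims$service_date, window))) {
    abort("Claims contain service dates outside the observation window.")
  }
  claims |>
    dplyr::distinct(.data$patient_id, .data$service_date) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      dates = list(sort(.data$service_date)), .groups = "drop"
    ) |>
    dplyr::mutate(n_days = lengths(.data$dates)) |>
    dplyr::arrange(.data$patient_id)
}

as_claim_days <- function(dates) {
  dates <- sort(unique(parse_iso_date(dates, "dates")))
  dates
}

#' Case-definition predicates on a claim-day series
#'
#' Each predicate takes one patient's claim days (a `Date` vector; duplicates
#' and ordering are normalised internally) and returns `TRUE` if the patient
#' satisfies the definition:
#'
#' * `classify_d1()`: at least one claim day.
#' * `classify_d2()`: at least two distinct claim days.
#' * `classify_d3()`: two claim days at least `min_span` (90) days apart —
#'   equivalently, last minus first claim day is at least 90 days.
#' * `classify_d4()`: some consecutive run of claim days in which every
#'   successive gap is at most `max_gap` (21) days spans at least `min_span`
#'   (90) days. A gap of exactly 21 days does not break a run ("greater than
#'   21 days" is strict); a span of exactly 90 days qualifies ("at least 90
#'   days" is inclusive). All day differences are calendar-day counts.
#'
#' @param dates `Date` vector (or ISO-8601 strings) of one patient's claim
#'   days.
#' @param min_span Minimum span in days for `d3`/`d4` (default 90).
#' @param max_gap Maximum within-run gap in days for `d4` (default 21).
#'
#' @return Logical scalar.
#' @name classify
#' @examples
#' days <- as.Date("2008-01-01") + c(0, 20, 40, 60, 80, 100)
#' classify_d4(days) # TRUE: all gaps 20 <= 21, span 100 >= 90
#' classify_d4(as.Date("2008-01-01") + c(0, 30, 60, 90)) # FALSE: gaps 30 > 21
NULL

#' @rdname classify
#' @export
classify_d1 <- function(dates) {
  length(as_claim_days(dates)) >= 1L
}

#' @rdname classify
#' @export
classify_d2 <- function(dates) {
  length(as_claim_days(dates)) >= 2L
}

#' @rdname classify
#' @export
classify_d3 <- function(dates, min_span = 90L) {
  d <- as_claim_days(dates)
  # span of the extreme dates equals the maximum over all pairs
  length(d) >= 2L && as.integer(d[length(d)] - d[1L]) >= min_span
}

#' @rdname classify
#' @export
classify_d4 <- function(dates, min_span = 90L, max_gap = 21L) {
  d <- as_claim_days(dates)
  if (length(d) < 2L) {
    return(FALSE)
  }
  gaps <- as.integer(diff(d))
  # Maximal runs delimited by gaps > max_gap: any qualifying contiguous
  # sub-run lies inside one maximal run, whose span is the largest there.
  run_id <- cumsum(c(0L, gaps > max_gap))
  day <- as.integer(d)
  spans <- vapply(
    split(day, run_id), function(x) x[length(x)] - x[1L], integer(1)
  )
  any(spans >= min_span)
}

classifier_for <- function(definition) {
  switch(match_definition(definition),
    d1 = classify_d1,
    d2 = classify_d2,
    d3 = classify_d3,
    d4 = classify_d4
  )
}

#' Assign the cohort-entry index date
#'
#' Cohort entry for a claims-identified patient is the date of the second
#' outpatient claim day. Definition `d1` admits patients with a single claim
#' day; for those the first (only) claim day is used, since no second exists.
#'
#' @param dates One patient's claim days (`Date` vector).
#' @param definition Definition id (`"d1"`..`"d4"`); the patient must be
#'   positive under it, otherwise an error is raised.
#'
#' @return A `Date` scalar.
#' @export
assign_index_date <- function(dates, definition = "d1") {
  definition <- match_definition(definition)
  d <- as_claim_days(dates)
  if (length(d) == 0) {
    abort("Cannot assign an index date to an empty claim-day series.")
  }
  if (!classifier_for(definition)(d)) {
    abort(paste0(
      "Patient is not positive under definition '", definition,
      "'; index dates are defined for positives only."
    ))
  }
  if (length(d) >= 2L) d[2L] else d[1L]
}

#' Classify a cohort under one case definition
#'
#' Applies a case-definition predicate to every patient's claim-day series
#' and assigns each positive patient an index date.
#'
#' @param series Claim-day series tibble from [to_day_series()].
#' @param definition Definition id (`"d1"`..`"d4"`).
#' @param window Optional [observation_window()]; if given, assigned index
#'   dates are checked to lie inside it.
#'
#' @return A tibble with columns `patient_id`, `definition`, `index_date`,
#'   one row per positive patient.
#' @export
#' @examples
#' claims <- tibble::tibble(
#'   patient_id = c("a", "a", "b"),
#'   service_date = as.Date(c("2008-01-01", "2008-01-08", "2008-06-01")),
#'   procedure_code = "13.99B", setting = "outpatient"
#' )
#' classify_cohort(to_day_series(claims), "d2")
classify_cohort <- function(series, definition, window = NULL) {
  definition <- match_definition(definition)
  pred <- classifier_for(definition)
  empty <- tibble(
    patient_id = character(), definition = character(),
    index_date = as.Date(character())
  )
  if (nrow(series) == 0) {
    return(empty)
  }
  keep <- vapply(series$dates, pred, logical(1))
  if (!any(keep)) {
    return(empty)
  }
  pos <- series[keep, ]
  idx <- as.Date(
    vapply(
      pos$dates, function(d) as.numeric(assign_index_date(d, definition)),
      numeric(1)
    ),
    origin = "1970-01-01"
  )
  out <- tibble(
    patient_id = pos$patient_id,
    definition = definition,
    index_date = idx
  )
  if (!is.null(window) && !all(in_window(out$index_date, window))) {
    abort("Assigned index dates fall outside the observation window.")
  }
  out
}
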