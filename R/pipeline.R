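#' Run the full claims-vs-registry validation
#'
#' End-to-end pipeline: read the claims and registry files, apply each
#' requested case definition over the observation window, build the 2x2
#' table per definition against the registry reference standard, and return
#' the agreement reports plus cohort summaries.
#'
#' The study population (the denominator `N`) is the union of every patient
#' id seen in the claims, registry, attributes, and population inputs. The
#' original validation drew its population from a laboratory cohort that is
#' not reconstructible from claims alone, so when comparability of `N`
#' matters supply `population` explicitly (a character vector of ids or a
#' path readable by [read_population()]).
#'
#' @param claims_path Path to a claims CSV ([read_claims()] layout).
#' @param registry_path Path to a registry CSV ([read_registry()] layout).
#' @param window An [observation_window()].
#' @param attributes_path Optional path to an attributes CSV
#'   ([read_attributes()] layout) for cohort summaries.
#' @param population Optional explicit study population: a character vector
#'   of patient ids, or a single path to a population file.
#' @param definitions Definition ids to evaluate (default all four, see
#'   [dialysis_definitions()]).
#' @param code_set Dialysis procedure [code_set()] (default
#'   [ccp_dialysis_codes()]).
#' @param output_dir Optional directory; when given, `agreement_report.csv`,
#'   `cohort_summary.csv`, `classification.csv` and a fixed-width
#'   `agreement_report.txt` are written there.
#' @param include_negative Also report specificity, NPV, negative agreement
#'   (suppressed by default: with a rare outcome they are insensitive to the
#'   definition).
#' @param verbose Log record counts at each filtering step (to stderr).
#'
#' @return A list of class `validation_result` with elements `reports`
#'   (tibble, one [agreement_report()] row per definition), `summaries`
#'   (tibble, one [summarize_cohort()] row per definition), `classification`
#'   (tibble of positives with index dates across definitions), and
#'   `population_size`.
#' @export
run_validation <- function(claims_path, registry_path, window,
                           attributes_path = NULL, population = NULL,
                           definitions = names(dialysis_definitions()),
                           code_set = ccp_dialysis_codes(),
                           output_dir = NULL, include_negative = FALSE,
                           verbose = TRUE) {
  definitions <- vapply(definitions, match_definition, character(1))
  if (length(definitions) == 0) {
    abort("At least one definition must be requested.")
  }
  say <- function(...) if (verbose) inform(paste0(...))

  claims <- read_claims(claims_path, window, code_set)
  registry <- read_registry(registry_path)
  say(
    "Retained ", nrow(claims), " outpatient dialysis claim(s) for ",
    dplyr::n_distinct(claims$patient_id), " patient(s); registry has ",
    nrow(registry), " patient(s)."
  )
  attributes <- NULL
  if (!is.null(attributes_path)) {
    attributes <- read_attributes(attributes_path)
  }

  pop <- unique(c(
    claims$patient_id, registry$patient_id,
    if (!is.null(attributes)) attributes$patient_id,
    if (is.null(population)) {
      character()
    } else if (length(population) == 1 && file.exists(population)) {
      read_population(population)
    } else {
      as.character(population)
    }
  ))
  if (length(pop) == 0) {
    abort("Empty study population: no patients in any input.")
  }
  say("Study population N = ", length(pop), ".")

  series <- to_day_series(claims, window)

  reports <- list()
  summaries <- list()
  classifications <- list()
  for (def in definitions) {
    cls <- classify_cohort(series, def, window)
    t <- build_two_by_two(cls$patient_id, registry$patient_id, pop)
    reports[[def]] <- agreement_report(
      t, def, include_negative = include_negative
    )
    summaries[[def]] <- summarize_cohort(
      cls$patient_id, series, attributes, def,
      reference_year = as.integer(format(window$start, "%Y"))
    )
    classifications[[def]] <- cls
    say(
      "Definition ", def, ": ", nrow(cls), " claims-positive patient(s)."
    )
  }

  out <- structure(
    list(
      reports = dplyr::bind_rows(reports),
      summaries = dplyr::bind_rows(summaries),
      classification = dplyr::bind_rows(classifications),
      population_size = length(pop)
    ),
    class = "validation_result"
  )
  if (!is.null(output_dir)) {
    write_validation(out, output_dir)
  }
  out
}

#' @export
print.validation_result <- function(x, ...) {
  cat("<validation_result> N =", format(x$population_size, big.mark = ","), "\n\n")
  print(as.data.frame(x$reports), row.names = FALSE)
  invisible(x)
}

write_validation <- function(result, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      abort(paste0("Cannot create output directory '", dir, "'."))
    }
  }
  readr::write_csv(
    result$reports, file.path(dir, "agreement_report.csv"),
    progress = FALSE
  )
  readr::write_csv(
    result$summaries, file.path(dir, "cohort_summary.csv"),
    progress = FALSE
  )
  readr::write_csv(
    result$classification, file.path(dir, "classification.csv"),
    progress = FALSE
  )
  txt <- utils::capture.output(
    print(as.data.frame(result$reports), row.names = FALSE)
  )
  writeLines(txt, file.path(dir, "agreement_report.txt"))
  invisible(dir)
}

#' Summarize a claims-identified cohort
#'
#' Descriptive statistics for the patients positive under one definition:
#' cohort size, mean age and standard deviation, percent male (when
#' attributes are supplied), and the median and interquartile range of the
#' number of claim days in the window. Patients missing an attribute are
#' excluded from that statistic only.
#'
#' @param positives Character vector of positive patient ids.
#' @param series Claim-day series tibble from [to_day_series()].
#' @param attributes Optional attributes tibble from [read_attributes()].
#' @param definition Label for the summary row.
#' @param reference_year Year used to convert birth year to age (typically
#'   the window start year).
#'
#' @return A one-row tibble: `definition`, `n`, `mean_age`, `sd_age`,
#'   `pct_male`, `median_claim_days`, `iqr_claim_days_low`,
#'   `iqr_claim_days_high`.
#' @export
summarize_cohort <- function(positives, series, attributes = NULL,
                             definition = NA_character_,
                             reference_year = NULL) {
  positives <- unique(as.character(positives))
  n <- length(positives)
  mean_age <- sd_age <- pct_male <- NA_real_
  if (!is.null(attributes) && n > 0) {
    att <- attributes[attributes$patient_id %in% positives, ]
    ages <- att$birth_year[!is.na(att$birth_year)]
    if (length(ages) > 0 && !is.null(reference_year)) {
      age <- reference_year - ages
      mean_age <- mean(age)
      sd_age <- if (length(age) > 1) sd(age) else NA_real_
    }
    known_sex <- att$sex[att$sex != "unknown"]
    if (length(known_sex) > 0) {
      pct_male <- 100 * mean(known_sex == "male")
    }
  }
  median_cd <- iqr_lo <- iqr_hi <- NA_real_
  if (n > 0) {
    cd <- series$n_days[series$patient_id %in% positives]
    if (length(cd) > 0) {
      median_cd <- median(cd)
      q <- quantile(cd, c(0.25, 0.75), names = FALSE)
      iqr_lo <- q[1]
      iqr_hi <- q[2]
    }
  }
  tibble(
    definition = as.character(definition), n = n,
    mean_age = mean_age, sd_age = sd_age, pct_male = pct_male,
    median_claim_days = median_cd,
    iqr_claim_days_low = iqr_lo, iqr_claim_days_high = iqr_hi
  )
}
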