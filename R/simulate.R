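#' Scenario parameters for the synthetic claims generator
#'
#' Bundles and validates the generative parameters of [simulate_claims()].
#' Defaults emulate the setting the case definitions were designed for: a
#' population of one million adults with an outpatient creatinine measure, a
#' registry prevalence of chronic dialysis of 0.2%, hemodialysis billed with
#' per-week management codes and peritoneal dialysis with monthly management
#' codes, imperfect claim capture (missed billings, shadow billing), sporadic
#' temporary-dialysis bursts for acute kidney injury (AKI) among non-registry
#' patients, and an early-death hazard after dialysis initiation.
#'
#' @param n_population Number of individuals in the study population.
#' @param window [observation_window()] of claim ascertainment; defaults to
#'   calendar year 2008.
#' @param registry_prevalence Probability an individual is a registry chronic
#'   dialysis patient.
#' @param prevalent_fraction Fraction of registry patients already on
#'   dialysis at window start (the rest initiate during the window).
#' @param modality_mix Probability a registry patient is on hemodialysis
#'   rather than peritoneal dialysis.
#' @param hd_claim_period_days Days between successive hemodialysis claims
#'   (7 = per-week management billing).
#' @param pd_claim_period_days Days between successive peritoneal dialysis
#'   management claims.
#' @param hd_billing `"per_week"` bills hemodialysis with the weekly
#'   management code 13.99OA; `"per_session"` bills each contact with the
#'   treatment code 13.99B (set `hd_claim_period_days` accordingly, e.g. 2-3).
#' @param claim_capture_prob Probability a due claim is actually present in
#'   the claims file (captures missed billings, billing errors, shadow
#'   billing by salaried physicians).
#' @param aki_rate Probability a non-registry individual has a temporary
#'   dialysis episode during the window.
#' @param aki_duration_mean,aki_duration_sd Mean and standard deviation (in
#'   days) of the gamma-distributed AKI episode duration.
#' @param aki_duration_max Upper truncation of AKI episode duration, in days.
#'   Kept below 90 by default so temporary dialysis cannot satisfy the
#'   90-day-span definitions by construction; raise it to study boundary
#'   leakage.
#' @param aki_claim_period_days Days between claims within an AKI episode.
#' @param early_death_hazard Per-day probability of death after dialysis
#'   start (for prevalent patients, after window start). Death halts claim
#'   emission the same day.
#' @param seed Integer seed; the full output is reproducible given the seed.
#'
#' @return A validated list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_population = 1e6,
                         window = observation_window("2008-01-01", "2008-12-31"),
                         registry_prevalence = 0.002,
                         prevalent_fraction = 0.75,
                         modality_mix = 0.8,
                         hd_claim_period_days = 7L,
                         pd_claim_period_days = 30L,
                         hd_billing = c("per_week", "per_session"),
                         claim_capture_prob = 0.9,
                         aki_rate = 5e-4,
                         aki_duration_mean = 21,
                         aki_duration_sd = 14,
                         aki_duration_max = 89L,
                         aki_claim_period_days = 7L,
                         early_death_hazard = 0.001,
                         seed = NULL) {
  hd_billing <- match.arg(hd_billing)
  stopifnot(inherits(window, "observation_window"))
  check_prob <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      abort(paste0("`", name, "` must be a single probability in [0, 1]."))
    }
  }
  check_count <- function(x, name, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != round(x)) {
      abort(paste0("`", name, "` must be a single integer >= ", min, "."))
    }
  }
  check_count(n_population, "n_population")
  check_prob(registry_prevalence, "registry_prevalence")
  check_prob(prevalent_fraction, "prevalent_fraction")
  check_prob(modality_mix, "modality_mix")
  check_prob(claim_capture_prob, "claim_capture_prob")
  check_prob(aki_rate, "aki_rate")
  check_prob(early_death_hazard, "early_death_hazard")
  check_count(hd_claim_period_days, "hd_claim_period_days")
  check_count(pd_claim_period_days, "pd_claim_period_days")
  check_count(aki_claim_period_days, "aki_claim_period_days")
  check_count(aki_duration_max, "aki_duration_max")
  if (!is.numeric(aki_duration_mean) || aki_duration_mean <= 0 ||
    !is.numeric(aki_duration_sd) || aki_duration_sd <= 0) {
    abort("`aki_duration_mean` and `aki_duration_sd` must be positive.")
  }
  if (!is.null(seed)) {
    check_count(seed, "seed", min = 0)
  }
  structure(
    list(
      n_population = as.integer(n_population), window = window,
      registry_prevalence = registry_prevalence,
      prevalent_fraction = prevalent_fraction,
      modality_mix = modality_mix,
      hd_claim_period_days = as.integer(hd_claim_period_days),
      pd_claim_period_days = as.integer(pd_claim_period_days),
      hd_billing = hd_billing,
      claim_capture_prob = claim_capture_prob,
      aki_rate = aki_rate,
      aki_duration_mean = aki_duration_mean,
      aki_duration_sd = aki_duration_sd,
      aki_duration_max = as.integer(aki_duration_max),
      aki_claim_period_days = as.integer(aki_claim_period_days),
      early_death_hazard = early_death_hazard,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_scenario"
  )
}

# Gamma duration matched to mean/sd, rounded to whole days, truncated to
# [1, max]; max < 90 guarantees temporary dialysis stays below the 90-day span.
sample_aki_duration <- function(n, mean, sd, max) {
  shape <- (mean / sd)^2
  rate <- shape / mean
  d <- round(rgamma(n, shape = shape, rate = rate))
  pmin(pmax(d, 1L), max)
}

# Claim days anchored at `anchor`, emitted every `period` days over the
# closed day range [from, to], each retained with probability `capture`.
emit_schedule <- function(anchor, from, to, period, capture) {
  if (to < from) {
    return(as.Date(character()))
  }
  off0 <- ceiling(as.numeric(from - anchor) / period) * period
  off_max <- as.numeric(to - anchor)
  if (off0 > off_max) {
    return(as.Date(character()))
  }
  offsets <- seq(off0, off_max, by = period)
  due <- anchor + offsets
  if (capture < 1) {
    due <- due[runif(length(due)) < capture]
  }
  due
}

#' Simulate a claims file, registry, and ground truth
#'
#' Generates a synthetic study population under a [sim_scenario()]:
#'
#' * *Chronic dialysis patients* (registry members) emit outpatient dialysis
#'   claims at their modality's billing period from their dialysis start (or
#'   from window start, if already prevalent) until death or window end; each
#'   due claim survives with `claim_capture_prob`, so some registry patients
#'   are missed or under-billed in the claims stream (false negatives).
#' * *Temporary dialysis patients* (AKI) are non-registry individuals who
#'   emit a burst of claims over a sampled episode duration shorter than 90
#'   days (false positives for the lenient definitions; the 90-day-span
#'   definitions exclude them by construction). A one-day episode reduces to
#'   a single stray claim, the shape of an isolated billing error.
#' * *Unexposed individuals* emit no dialysis claims.
#'
#' @param scenario A [sim_scenario()].
#'
#' @return A list of class `dialysis_sim` with elements `claims` (tibble in
#'   [read_claims()] layout), `registry` (tibble in [read_registry()]
#'   layout), `truth` (tibble: `patient_id`, `label` in
#'   chronic_dialysis/temporary_dialysis/unexposed, `dialysis_start`,
#'   `death_date`), and the `scenario`.
#' @export
#' @examples
#' sim <- simulate_claims(sim_scenario(n_population = 2000, seed = 1))
#' table(sim$truth$label)
simulate_claims <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(scenario$seed)) {
    return(withr::with_seed(scenario$seed, simulate_claims_impl(scenario)))
  }
  simulate_claims_impl(scenario)
}

simulate_claims_impl <- function(s) {
  n <- s$n_population
  win <- s$window
  win_len <- as.integer(win$end - win$start) + 1L
  ids <- sprintf("P%07d", seq_len(n))

  is_registry <- runif(n) < s$registry_prevalence
  reg_ids <- ids[is_registry]
  k <- length(reg_ids)

  hd_code <- if (s$hd_billing == "per_week") "13.99OA" else "13.99B"

  registry <- tibble(
    patient_id = character(), start_date = as.Date(character())
  )
  claim_rows <- list()
  dialysis_start <- rep(as.Date(NA), n)
  death_date <- rep(as.Date(NA), n)

  if (k > 0) {
    prevalent <- runif(k) < s$prevalent_fraction
    # prevalent patients started up to ~9 years before the window (registry
    # accrual horizon); incident patients start inside the window
    start <- as.Date(ifelse(
      prevalent,
      win$start - sample.int(9L * 365L, k, replace = TRUE),
      win$start + sample.int(win_len, k, replace = TRUE) - 1L
    ), origin = "1970-01-01")
    is_hd <- runif(k) < s$modality_mix
    emission_start <- pmax(start, win$start)
    if (s$early_death_hazard > 0) {
      death <- emission_start + rgeom(k, s$early_death_hazard)
    } else {
      death <- rep(as.Date(NA), k)
    }
    period <- ifelse(is_hd, s$hd_claim_period_days, s$pd_claim_period_days)
    code <- ifelse(is_hd, hd_code, "13.99D")

    for (i in seq_len(k)) {
      horizon <- min(win$end, death[i], na.rm = TRUE)
      days <- emit_schedule(
        start[i], emission_start[i], horizon, period[i], s$claim_capture_prob
      )
      if (length(days) > 0) {
        claim_rows[[length(claim_rows) + 1L]] <- tibble(
          patient_id = reg_ids[i], service_date = days,
          procedure_code = code[i], setting = "outpatient"
        )
      }
    }
    registry <- tibble(patient_id = reg_ids, start_date = start)
    dialysis_start[is_registry] <- start
    death_date[is_registry] <- death
  }

  non_reg <- which(!is_registry)
  is_aki <- logical(n)
  if (length(non_reg) > 0 && s$aki_rate > 0) {
    aki_sel <- non_reg[runif(length(non_reg)) < s$aki_rate]
    is_aki[aki_sel] <- TRUE
    m <- length(aki_sel)
    if (m > 0) {
      burst_start <- win$start + sample.int(win_len, m, replace = TRUE) - 1L
      duration <- sample_aki_duration(
        m, s$aki_duration_mean, s$aki_duration_sd, s$aki_duration_max
      )
      for (j in seq_len(m)) {
        horizon <- min(win$end, burst_start[j] + duration[j] - 1L)
        days <- emit_schedule(
          burst_start[j], burst_start[j], horizon, s$aki_claim_period_days,
          s$claim_capture_prob
        )
        if (length(days) > 0) {
          claim_rows[[length(claim_rows) + 1L]] <- tibble(
            patient_id = ids[aki_sel[j]], service_date = days,
            procedure_code = "13.99A", setting = "outpatient"
          )
        }
      }
      dialysis_start[aki_sel] <- burst_start
    }
  }

  claims <- if (length(claim_rows) > 0) {
    dplyr::arrange(
      dplyr::bind_rows(claim_rows),
      .data$patient_id, .data$service_date, .data$procedure_code
    )
  } else {
    tibble(
      patient_id = character(), service_date = as.Date(character()),
      procedure_code = character(), setting = character()
    )
  }

  truth <- tibble(
    patient_id = ids,
    label = dplyr::case_when(
      is_registry ~ "chronic_dialysis",
      is_aki ~ "temporary_dialysis",
      .default = "unexposed"
    ),
    dialysis_start = dialysis_start,
    death_date = death_date
  )

  structure(
    list(claims = claims, registry = registry, truth = truth, scenario = s),
    class = "dialysis_sim"
  )
}

#' @export
print.dialysis_sim <- function(x, ...) {
  cat(
    "<dialysis_sim> population ", x$scenario$n_population,
    ": ", nrow(x$registry), " registry patient(s), ",
    sum(x$truth$label == "temporary_dialysis"), " temporary-dialysis, ",
    nrow(x$claims), " claims\n",
    sep = ""
  )
  invisible(x)
}

#' Write a simulated dataset as plain-text fixtures
#'
#' Emits `claims.csv`, `registry.csv`, and `truth.csv` (plus a
#' `scenario.txt` echo of the generating parameters for provenance) in the
#' layouts read by [read_claims()], [read_registry()]. Output bytes are a
#' pure function of the simulation, so a fixed seed gives identical files.
#'
#' @param sim A `dialysis_sim` from [simulate_claims()].
#' @param dir Output directory, created if needed.
#'
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "dialysis_sim"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      abort(paste0("Cannot create output directory '", dir, "'."))
    }
  }
  paths <- c(
    claims = file.path(dir, "claims.csv"),
    registry = file.path(dir, "registry.csv"),
    truth = file.path(dir, "truth.csv"),
    scenario = file.path(dir, "scenario.txt")
  )
  readr::write_csv(sim$claims, paths[["claims"]], progress = FALSE)
  readr::write_csv(sim$registry, paths[["registry"]], progress = FALSE)
  readr::write_csv(sim$truth, paths[["truth"]], progress = FALSE)
  writeLines(format_scenario(sim$scenario), paths[["scenario"]])
  invisible(paths)
}

format_scenario <- function(s) {
  kv <- c(
    n_population = s$n_population,
    window_start = format(s$window$start),
    window_end = format(s$window$end),
    registry_prevalence = s$registry_prevalence,
    prevalent_fraction = s$prevalent_fraction,
    modality_mix = s$modality_mix,
    hd_claim_period_days = s$hd_claim_period_days,
    pd_claim_period_days = s$pd_claim_period_days,
    hd_billing = s$hd_billing,
    claim_capture_prob = s$claim_capture_prob,
    aki_rate = s$aki_rate,
    aki_duration_mean = s$aki_duration_mean,
    aki_duration_sd = s$aki_duration_sd,
    aki_duration_max = s$aki_duration_max,
    aki_claim_period_days = s$aki_claim_period_days,
    early_death_hazard = s$early_death_hazard,
    seed = if (is.null(s$seed)) "" else s$seed
  )
  paste(names(kv), unname(kv), sep = " = ")
}

#' Read a scenario file
#'
#' Parses a flat `key = value` text file (the format written by
#' [write_fixture()]'s scenario echo) into a [sim_scenario()]. Unknown keys
#' raise an error; `window_start`/`window_end` assemble the observation
#' window.
#'
#' @param path Path to the scenario file.
#' @return A `sim_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: '", path, "'"))
  }
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(parts) != 2
  if (any(bad)) {
    abort(paste0(
      "Malformed scenario line(s): ",
      paste(head(lines[bad], 3), collapse = "; ")
    ))
  }
  vals <- setNames(
    vapply(parts, `[`, character(1), 2), vapply(parts, `[`, character(1), 1)
  )
  known_num <- c(
    "n_population", "registry_prevalence", "prevalent_fraction",
    "modality_mix", "hd_claim_period_days", "pd_claim_period_days",
    "claim_capture_prob", "aki_rate", "aki_duration_mean", "aki_duration_sd",
    "aki_duration_max", "aki_claim_period_days", "early_death_hazard", "seed"
  )
  unknown <- setdiff(
    names(vals), c(known_num, "window_start", "window_end", "hd_billing")
  )
  if (length(unknown) > 0) {
    abort(paste0(
      "Unknown scenario key(s): ", paste(unknown, collapse = ", ")
    ))
  }
  args <- list()
  for (key in intersect(names(vals), known_num)) {
    if (nzchar(vals[[key]])) {
      args[[key]] <- as.numeric(vals[[key]])
    }
  }
  if ("hd_billing" %in% names(vals)) {
    args$hd_billing <- vals[["hd_billing"]]
  }
  if (all(c("window_start", "window_end") %in% names(vals))) {
    args$window <- observation_window(
      vals[["window_start"]], vals[["window_end"]]
    )
  }
  do.call(sim_scenario, args)
}
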