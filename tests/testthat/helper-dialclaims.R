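# Brute-force reference for the continuous-claims definition: enumerate every
# contiguous sub-run of the sorted claim days and test it directly against the
# gap and span rules. Independent of the run-decomposition used by
# classify_d4().
d4_brute_force <- function(dates, min_span = 90L, max_gap = 21L) {
  d <- sort(unique(as.integer(as.Date(dates))))
  n <- length(d)
  if (n < 2) {
    return(FALSE)
  }
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      run <- d[i:j]
      if (all(diff(run) <= max_gap) && run[length(run)] - run[1] >= min_span) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Random claim-day series within calendar year 2008 (<= n_max distinct days).
random_claim_days <- function(n_max = 12, origin = as.Date("2008-01-01")) {
  n <- sample.int(n_max, 1)
  origin + sort(sample.int(366, n)) - 1L
}

write_csv_lines <- function(lines, file = withr::local_tempfile(
                              fileext = ".csv",
                              .local_envir = parent.frame()
                            )) {
  writeLines(lines, file)
  file
}

window_2008 <- function() observation_window("2008-01-01", "2008-12-31")
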