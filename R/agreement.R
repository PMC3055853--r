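#' Construct a 2x2 agreement table
#'
#' The analytic framework for validating a claims definition against the
#' registry reference standard is the 2x2 table
#'
#' |                | registry + | registry - |
#' |----------------|-----------|-----------|
#' | claims +       | a         | b         |
#' | claims -       | c         | d         |
#'
#' with `N = a + b + c + d` the study population.
#'
#' @param a,b,c,d Non-negative integer counts; `a` = positive under both,
#'   `b` = claims-only, `c` = registry-only, `d` = negative under both.
#'
#' @return An object of class `two_by_two`.
#' @seealso [build_two_by_two()] to derive the counts from patient-id sets.
#' @export
#' @examples
#' two_by_two(1805, 519, 422, 1115351)
two_by_two <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("All four counts must be non-negative integers.")
  }
  if (sum(counts) <= 0) {
    abort("The table total N = a + b + c + d must be positive.")
  }
  # doubles: products such as (c + d)(b + d) overflow 32-bit integers at
  # population scale (N ~ 10^6)
  structure(
    list(
      a = as.numeric(counts[["a"]]), b = as.numeric(counts[["b"]]),
      c = as.numeric(counts[["c"]]), d = as.numeric(counts[["d"]])
    ),
    class = "two_by_two"
  )
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
    dimnames = list(
      claims = c("positive", "negative"),
      registry = c("positive", "negative")
    )
  )
  cat("<two_by_two> N =", format(x$a + x$b + x$c + x$d, big.mark = ","), "\n")
  print(m)
  invisible(x)
}

#' Build the 2x2 table from patient-id sets
#'
#' @param admin_positives Character vector of patients positive under the
#'   claims definition.
#' @param registry_positives Character vector of patients in the registry
#'   reference standard.
#' @param population Character vector of all patients in the study
#'   population; both positive sets must be subsets of it.
#'
#' @return A [two_by_two()] object.
#' @export
build_two_by_two <- function(admin_positives, registry_positives, population) {
  admin_positives <- unique(as.character(admin_positives))
  registry_positives <- unique(as.character(registry_positives))
  population <- unique(as.character(population))
  stray <- setdiff(union(admin_positives, registry_positives), population)
  if (length(stray) > 0) {
    abort(paste0(
      "Positive patients outside the study population: ",
      paste(head(stray, 10), collapse = ", "),
      if (length(stray) > 10) " ..." else "", "."
    ))
  }
  a <- length(intersect(admin_positives, registry_positives))
  b <- length(setdiff(admin_positives, registry_positives))
  c <- length(setdiff(registry_positives, admin_positives))
  d <- length(population) - a - b - c
  two_by_two(a, b, c, d)
}

check_2x2 <- function(t) {
  if (!inherits(t, "two_by_two")) {
    abort("Expected a `two_by_two` object; see two_by_two().")
  }
  invisible(t)
}

#' Agreement statistics on a 2x2 table
#'
#' The validation statistics reported for each case definition against the
#' registry reference standard:
#'
#' * `sensitivity()`: `a / (a + c)`, the proportion of registry patients the
#'   claims definition captures.
#' * `ppv()`: `a / (a + b)`, the probability a claims-positive patient is in
#'   the registry.
#' * `positive_agreement()`: the Cicchetti-Feinstein proportion of specific
#'   positive agreement, `2a / (2a + b + c)` — agreement restricted to
#'   positive classifications, uncorrected for chance.
#' * `cohen_kappa()`: chance-corrected overall agreement,
#'   `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o = (a + d) / N`
#'   and chance agreement
#'   `p_e = ((a + b)(a + c) + (c + d)(b + d)) / N^2`.
#' * `prevalence_pct()`: `100 (a + b) / N`, the claims-positive prevalence as
#'   a percentage.
#' * `specificity()`, `npv()`, `negative_agreement()`: computable but, with a
#'   very large non-diseased population and a rare outcome, insensitive to
#'   the choice of definition; excluded from default reports (see
#'   [agreement_report()]).
#'
#' When the outcome is rare (`d` much larger than `a`, `b`, `c`), kappa
#' converges to the positive agreement, which is why the two can print
#' identically for rare conditions such as chronic dialysis.
#'
#' All functions return full-precision values; rounding (half-up, 3 decimals
#' for proportions and kappa, 2 for prevalence percent) happens only in
#' [agreement_report()] serialization.
#'
#' @param t A [two_by_two()] table.
#' @return A numeric scalar.
#' @name agreement_statistics
#' @examples
#' t <- two_by_two(1805, 519, 422, 1115351)
#' sensitivity(t)
#' cohen_kappa(t)
NULL

#' @rdname agreement_statistics
#' @export
sensitivity <- function(t) {
  check_2x2(t)
  if (t$a + t$c == 0) {
    abort("sensitivity is undefined: no registry-positive patients (a + c = 0).")
  }
  t$a / (t$a + t$c)
}

#' @rdname agreement_statistics
#' @export
ppv <- function(t) {
  check_2x2(t)
  if (t$a + t$b == 0) {
    abort("PPV is undefined: no claims-positive patients (a + b = 0).")
  }
  t$a / (t$a + t$b)
}

#' @rdname agreement_statistics
#' @export
positive_agreement <- function(t) {
  check_2x2(t)
  if (2 * t$a + t$b + t$c == 0) {
    abort("positive agreement is undefined: 2a + b + c = 0.")
  }
  2 * t$a / (2 * t$a + t$b + t$c)
}

#' @rdname agreement_statistics
#' @export
cohen_kappa <- function(t) {
  check_2x2(t)
  n <- t$a + t$b + t$c + t$d
  p_o <- (t$a + t$d) / n
  p_e <- ((t$a + t$b) * (t$a + t$c) + (t$c + t$d) * (t$b + t$d)) / n^2
  if (p_e >= 1) {
    abort("kappa is undefined: chance agreement p_e = 1.")
  }
  (p_o - p_e) / (1 - p_e)
}

#' @rdname agreement_statistics
#' @export
prevalence_pct <- function(t) {
  check_2x2(t)
  100 * (t$a + t$b) / (t$a + t$b + t$c + t$d)
}

#' @rdname agreement_statistics
#' @export
specificity <- function(t) {
  check_2x2(t)
  if (t$b + t$d == 0) {
    abort("specificity is undefined: b + d = 0.")
  }
  t$d / (t$b + t$d)
}

#' @rdname agreement_statistics
#' @export
npv <- function(t) {
  check_2x2(t)
  if (t$c + t$d == 0) {
    abort("NPV is undefined: c + d = 0.")
  }
  t$d / (t$c + t$d)
}

#' @rdname agreement_statistics
#' @export
negative_agreement <- function(t) {
  check_2x2(t)
  if (2 * t$d + t$b + t$c == 0) {
    abort("negative agreement is undefined: 2d + b + c = 0.")
  }
  2 * t$d / (2 * t$d + t$b + t$c)
}

#' Landis-Koch category for a kappa value
#'
#' The conventional qualitative bands: kappa of at most 0.20 is `poor`,
#' (0.20, 0.40] `fair`, (0.40, 0.60] `moderate`, (0.60, 0.80] `substantial`,
#' and above 0.80 `near_perfect`. Bands are half-open with the upper bound
#' included, so 0.80 is `substantial` and 0.801 is `near_perfect`.
#'
#' @param k Numeric kappa value(s), each at most 1.
#' @return Factor with levels poor < fair < moderate < substantial <
#'   near_perfect.
#' @export
#' @examples
#' kappa_category(c(0.15, 0.793, 0.81))
kappa_category <- function(k) {
  if (any(k > 1 + 1e-12, na.rm = TRUE)) {
    abort("kappa cannot exceed 1.")
  }
  # snap to band edges: a kappa that is mathematically exactly 0.60 must not
  # jump bands on a 1-ulp floating-point excess
  k <- round(k, 9)
  cut(k,
    breaks = c(-Inf, 0.20, 0.40, 0.60, 0.80, 1),
    labels = c("poor", "fair", "moderate", "substantial", "near_perfect"),
    right = TRUE, ordered_result = TRUE
  )
}

#' Round half away from zero
#'
#' Reporting rounds half-up (0.5 rounds away from zero) at a fixed number of
#' decimals, rather than R's default round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Assemble a one-row agreement report for a definition
#'
#' Computes every reported validation statistic for one case definition's
#' 2x2 table. Specificity, NPV and negative agreement are suppressed by
#' default — with a rare outcome and over a million true negatives they sit
#' at essentially 1.0 regardless of definition — but are available with
#' `include_negative = TRUE`.
#'
#' @param t A [two_by_two()] table.
#' @param definition Definition id or label for the report row.
#' @param include_negative Also report specificity, NPV, and negative
#'   agreement.
#' @param rounded Round for reporting (half-up; 3 decimals for proportions
#'   and kappa, 2 for prevalence percent). `FALSE` returns full precision.
#'
#' @return A one-row tibble with columns `definition`, `n_admin_positive`,
#'   `prevalence_pct`, `a`, `b`, `c`, `d`, `positive_agreement`,
#'   `sensitivity`, `ppv`, `kappa`, `kappa_category` (and the negative-side
#'   columns when requested).
#' @export
#' @examples
#' agreement_report(two_by_two(1805, 519, 422, 1115351), "d1")
agreement_report <- function(t, definition = NA_character_,
                             include_negative = FALSE, rounded = TRUE) {
  check_2x2(t)
  k <- cohen_kappa(t)
  r3 <- if (rounded) function(x) round_half_up(x, 3) else identity
  r2 <- if (rounded) function(x) round_half_up(x, 2) else identity
  out <- tibble(
    definition = as.character(definition),
    n_admin_positive = t$a + t$b,
    prevalence_pct = r2(prevalence_pct(t)),
    a = t$a, b = t$b, c = t$c, d = t$d,
    positive_agreement = r3(positive_agreement(t)),
    sensitivity = r3(sensitivity(t)),
    ppv = r3(ppv(t)),
    kappa = r3(k),
    kappa_category = as.character(kappa_category(k))
  )
  if (include_negative) {
    out$specificity <- r3(specificity(t))
    out$npv <- r3(npv(t))
    out$negative_agreement <- r3(negative_agreement(t))
  }
  out
}

#' Published validation counts for the four definitions
#'
#' The 2x2 counts reported by the Alberta outpatient-claims validation study
#' that compared the four case definitions against the NARP/SARP end-stage
#' renal disease registry over calendar year 2008 (study population
#' N = 1,118,097; 2,227 registry patients). Shipped as a plain-text table so
#' the reported statistics can be recomputed without any real administrative
#' data.
#'
#' @return A tibble with columns `definition`, `a`, `b`, `c`, `d`.
#' @export
#' @examples
#' counts <- published_counts()
#' agreement_report(with(counts[1, ], two_by_two(a, b, c, d)), "d1")
published_counts <- function() {
  path <- system.file("extdata", "published_counts.csv",
    package = "dialclaims", mustWork = TRUE
  )
  readr::read_csv(
    path,
    col_types = readr::cols(
      definition = readr::col_character(),
      a = readr::col_integer(), b = readr::col_integer(),
      c = readr::col_integer(), d = readr::col_integer()
    ),
    progress = FALSE
  )
}
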