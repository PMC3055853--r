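#' Construct a dialysis procedure-code set
#'
#' A code set is the list of procedure codes whose outpatient claims count as
#' dialysis care. Codes must be unique and non-empty.
#'
#' @param codes Character vector of procedure codes.
#' @param descriptions Optional character vector of per-code descriptions,
#'   recycled against `codes` if length 1.
#'
#' @return A tibble of class `code_set` with columns `code` and `description`.
#' @seealso [ccp_dialysis_codes()] for the default outpatient dialysis set.
#' @export
#' @examples
#' code_set(c("13.99A", "13.99B"))
code_set <- function(codes, descriptions = NA_character_) {
  if (length(codes) == 0) {
    abort("`codes` must contain at least one procedure code.")
  }
  codes <- as.character(codes)
  if (anyNA(codes) || any(!nzchar(codes))) {
    abort("Procedure codes must be non-empty strings.")
  }
  if (anyDuplicated(codes)) {
    abort(paste0(
      "Duplicate procedure codes: ",
      paste(unique(codes[duplicated(codes)]), collapse = ", ")
    ))
  }
  descriptions <- rep_len(as.character(descriptions), length(codes))
  out <- tibble(code = codes, description = descriptions)
  class(out) <- c("code_set", class(out))
  out
}

#' Canadian CCP outpatient chronic dialysis billing codes
#'
#' The six Canadian Classification of Diagnostic, Therapeutic and Surgical
#' Procedures (CCP) physician billing codes that capture outpatient dialysis
#' care: per-treatment hemodialysis codes, peritoneal dialysis management
#' codes, and the two per-week management codes used for home/remote dialysis.
#' This is the default code set for [read_claims()].
#'
#' @return A `code_set` tibble with six rows.
#' @export
ccp_dialysis_codes <- function() {
  code_set(
    codes = c("13.99A", "13.99B", "13.99C", "13.99D", "13.99O", "13.99OA"),
    descriptions = c(
      "Hemodialysis treatment, unstable patient",
      "Hemodialysis treatment, stable patient",
      paste(
        "Assessment and management of an unstable patient with acute/chronic",
        "renal failure treated by peritoneal dialysis"
      ),
      paste(
        "Assessment and management of a stable patient with chronic renal",
        "failure treated by peritoneal dialysis"
      ),
      paste(
        "Management of dialysis patients on home dialysis or receiving",
        "treatment in a remote hemodialysis unit (per week)"
      ),
      "Management of patient on hemodialysis or peritoneal dialysis (per week)"
    )
  )
}
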