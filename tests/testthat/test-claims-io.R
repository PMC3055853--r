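test_that("read_claims keeps only in-window outpatient dialysis claims", {
  f <- write_csv_lines(c(
    "patient_id,service_date,procedure_code,setting",
    "p1,2008-03-01,13.99B,outpatient",
    "p2,2008-03-01,13.99B,inpatient",
    "p3,2009-03-01,13.99B,outpatient"
  ))
  expect_message(
    claims <- read_claims(f, window_2008()),
    "discarded 1 inpatient"
  )
  expect_equal(nrow(claims), 1)
  expect_equal(claims$patient_id, "p1")
  expect_s3_class(claims$service_date, "Date")
})

test_that("read_claims drops codes outside the code set and exact duplicates", {
  f <- write_csv_lines(c(
    "patient_id,service_date,procedure_code,setting",
    "p1,2008-03-01,13.99B,outpatient",
    "p1,2008-03-01,13.99B,outpatient",
    "p1,2008-03-01,13.99D,outpatient",
    "p1,2008-03-01,99.99X,outpatient"
  ))
  claims <- read_claims(f, window_2008())
  # byte-identical rows collapse; distinct codes on one day both survive
  expect_equal(nrow(claims), 2)
  expect_setequal(claims$procedure_code, c("13.99B", "13.99D"))
})

test_that("read_claims handles an empty file and reports format problems", {
  empty <- write_csv_lines("patient_id,service_date,procedure_code,setting")
  expect_equal(nrow(read_claims(empty, window_2008())), 0)

  missing_col <- write_csv_lines(c(
    "patient_id,service_date,procedure_code",
    "p1,2008-03-01,13.99B"
  ))
  expect_error(
    read_claims(missing_col, window_2008()),
    "Missing column.*setting"
  )

  bad_date <- write_csv_lines(c(
    "patient_id,service_date,procedure_code,setting",
    "p1,2008-03-01,13.99B,outpatient",
    "p2,03/05/2008,13.99B,outpatient"
  ))
  expect_error(read_claims(bad_date, window_2008()), "line 3")

  bad_setting <- write_csv_lines(c(
    "patient_id,service_date,procedure_code,setting",
    "p1,2008-03-01,13.99B,clinic"
  ))
  expect_error(read_claims(bad_setting, window_2008()), "setting")
})

test_that("read_claims output is a fixed point of write/read and row order", {
  rows <- c(
    "p3,2008-05-02,13.99OA,outpatient",
    "p1,2008-03-01,13.99B,outpatient",
    "p1,2008-02-01,13.99B,outpatient",
    "p2,2008-03-01,13.99D,inpatient",
    "p1,2008-03-01,13.99A,outpatient"
  )
  header <- "patient_id,service_date,procedure_code,setting"
  f1 <- write_csv_lines(c(header, rows))
  claims <- suppressMessages(read_claims(f1, window_2008()))

  withr::with_seed(11, {
    for (i in 1:5) {
      fp <- write_csv_lines(c(header, sample(rows)))
      expect_identical(
        suppressMessages(read_claims(fp, window_2008())), claims
      )
    }
  })

  out <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(claims, out)
  expect_identical(read_claims(out, window_2008()), claims)
})

test_that("read_registry resolves duplicate patients to the earliest start", {
  f <- write_csv_lines(c(
    "patient_id,start_date",
    "p1,2008-03-01",
    "p1,2008-01-15",
    "p2,2007-06-30"
  ))
  expect_warning(reg <- read_registry(f), "earliest")
  expect_equal(nrow(reg), 2)
  expect_equal(reg$start_date[reg$patient_id == "p1"], as.Date("2008-01-15"))

  empty <- write_csv_lines("patient_id,start_date")
  expect_equal(nrow(read_registry(empty)), 0)

  bad <- write_csv_lines(c("patient_id,start_date", "p1,15-01-2008"))
  expect_error(read_registry(bad), "start_date")
})

test_that("attributes and population files read with validation", {
  f <- write_csv_lines(c(
    "patient_id,birth_year,sex",
    "p1,1950,male",
    "p2,,female",
    "p3,1980,"
  ))
  att <- read_attributes(f)
  expect_equal(att$birth_year, c(1950L, NA, 1980L))
  expect_equal(as.character(att$sex), c("male", "female", "unknown"))

  bad <- write_csv_lines(c("patient_id,birth_year,sex", "p1,1950,M"))
  expect_error(read_attributes(bad), "sex")

  popf <- write_csv_lines(c("patient_id", "p1", "p2", "p2"))
  expect_equal(read_population(popf), c("p1", "p2"))
})

test_that("code sets validate their invariants", {
  expect_error(code_set(character()), "at least one")
  expect_error(code_set(c("13.99A", "13.99A")), "Duplicate")
  expect_error(code_set(c("13.99A", "")), "non-empty")
  ccp <- ccp_dialysis_codes()
  expect_equal(nrow(ccp), 6)
  expect_true(all(c("13.99A", "13.99OA") %in% ccp$code))
})

test_that("observation windows are validated closed intervals", {
  w <- observation_window("2008-01-01", "2008-12-31")
  expect_s3_class(w$start, "Date")
  expect_error(observation_window("2008-12-31", "2008-01-01"), "after")
  expect_error(observation_window("2008-13-01", "2008-12-31"), "ISO-8601")
})
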