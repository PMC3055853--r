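test_that("scenario validation names the offending field", {
  expect_error(sim_scenario(registry_prevalence = 1.5), "registry_prevalence")
  expect_error(sim_scenario(claim_capture_prob = -0.1), "claim_capture_prob")
  expect_error(sim_scenario(hd_claim_period_days = 0), "hd_claim_period_days")
  expect_error(sim_scenario(n_population = 0), "n_population")
  expect_error(sim_scenario(aki_duration_mean = -2), "aki_duration_mean")
})

test_that("simulation is reproducible by seed and varies across seeds", {
  sc <- function(seed) sim_scenario(n_population = 5000, seed = seed)
  sim_a <- simulate_claims(sc(101))
  sim_b <- simulate_claims(sc(101))
  expect_identical(sim_a$claims, sim_b$claims)
  expect_identical(sim_a$registry, sim_b$registry)
  expect_identical(sim_a$truth, sim_b$truth)

  sim_c <- simulate_claims(sc(102))
  expect_false(identical(sim_a$claims, sim_c$claims))
})

test_that("registry size follows the binomial sampling of prevalence", {
  sim <- simulate_claims(sim_scenario(n_population = 50000, seed = 5))
  bounds <- qbinom(c(0.005, 0.995), 50000, 0.002)
  expect_gte(nrow(sim$registry), bounds[1])
  expect_lte(nrow(sim$registry), bounds[2])
  expect_true(all(
    sim$truth$patient_id[sim$truth$label == "chronic_dialysis"] %in%
      sim$registry$patient_id
  ))
  expect_equal(sum(sim$truth$label == "chronic_dialysis"), nrow(sim$registry))
})

test_that("a noise-free scenario recovers the registry exactly under d1", {
  sim <- simulate_claims(sim_scenario(
    n_population = 5000, claim_capture_prob = 1, aki_rate = 0,
    early_death_hazard = 0, prevalent_fraction = 1, seed = 21
  ))
  series <- to_day_series(sim$claims)
  pos <- classify_cohort(series, "d1")$patient_id
  t <- build_two_by_two(pos, sim$registry$patient_id, sim$truth$patient_id)
  expect_equal(sensitivity(t), 1)
  expect_equal(ppv(t), 1)
})

test_that("temporary-dialysis episodes stay below the 90-day span", {
  sim <- simulate_claims(sim_scenario(
    n_population = 5000, aki_rate = 0.05, claim_capture_prob = 1,
    early_death_hazard = 0, seed = 33
  ))
  aki_ids <- sim$truth$patient_id[sim$truth$label == "temporary_dialysis"]
  expect_gt(length(aki_ids), 50)
  series <- to_day_series(sim$claims)
  aki_series <- series[series$patient_id %in% aki_ids, ]
  # with full capture every AKI patient has at least one claim...
  expect_setequal(aki_series$patient_id, aki_ids)
  expect_true(all(vapply(aki_series$dates, classify_d1, logical(1))))
  # ...but none can satisfy a 90-day-span definition by construction
  expect_false(any(vapply(aki_series$dates, classify_d3, logical(1))))
  expect_false(any(vapply(aki_series$dates, classify_d4, logical(1))))
})

test_that("no claims are emitted after death", {
  sim <- simulate_claims(sim_scenario(
    n_population = 20000, early_death_hazard = 0.01, seed = 8
  ))
  joined <- dplyr::inner_join(
    sim$claims, sim$truth[!is.na(sim$truth$death_date), ],
    by = "patient_id"
  )
  expect_gt(nrow(joined), 0)
  expect_true(all(joined$service_date <= joined$death_date))
})

test_that("definition nesting holds on simulated cohorts", {
  for (seed in 1:5) {
    sim <- simulate_claims(sim_scenario(
      n_population = 3000, aki_rate = 0.01, seed = seed
    ))
    series <- to_day_series(sim$claims)
    pos <- lapply(
      c(d1 = "d1", d2 = "d2", d3 = "d3", d4 = "d4"),
      function(d) classify_cohort(series, d)$patient_id
    )
    expect_true(all(pos$d4 %in% pos$d3))
    expect_true(all(pos$d3 %in% pos$d2))
    expect_true(all(pos$d2 %in% pos$d1))
  }
})

test_that("lower claim capture does not raise one-claim sensitivity", {
  sens_d1 <- function(capture, seed) {
    sim <- simulate_claims(sim_scenario(
      n_population = 10000, claim_capture_prob = capture, aki_rate = 0,
      seed = seed
    ))
    series <- to_day_series(sim$claims)
    pos <- classify_cohort(series, "d1")$patient_id
    t <- build_two_by_two(pos, sim$registry$patient_id, sim$truth$patient_id)
    sensitivity(t)
  }
  seeds <- 1:10
  hi <- vapply(seeds, function(s) sens_d1(0.95, s), numeric(1))
  lo <- vapply(seeds, function(s) sens_d1(0.30, s), numeric(1))
  expect_lte(mean(lo), mean(hi))
})

test_that("fixtures round-trip through the readers with identical bytes per seed", {
  sim <- simulate_claims(sim_scenario(
    n_population = 4000, aki_rate = 0.005, seed = 55
  ))
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  paths1 <- write_fixture(sim, dir1)
  paths2 <- write_fixture(simulate_claims(sim$scenario), dir2)
  for (nm in c("claims", "registry", "truth", "scenario")) {
    expect_identical(
      readLines(paths1[[nm]]), readLines(paths2[[nm]])
    )
  }
  reread <- read_claims(paths1[["claims"]], sim$scenario$window)
  expect_identical(reread, sim$claims)
  expect_identical(read_registry(paths1[["registry"]]), sim$registry)

  empty <- simulate_claims(sim_scenario(
    n_population = 5, registry_prevalence = 0, aki_rate = 0, seed = 1
  ))
  pe <- write_fixture(empty, withr::local_tempdir())
  expect_equal(length(readLines(pe[["claims"]])), 1) # header only
})

test_that("scenario files round-trip through read_scenario", {
  sc <- sim_scenario(
    n_population = 1234, claim_capture_prob = 0.8, aki_rate = 0.001,
    hd_billing = "per_session", hd_claim_period_days = 3, seed = 9
  )
  dir <- withr::local_tempdir()
  paths <- write_fixture(simulate_claims(sc), dir)
  sc2 <- read_scenario(paths[["scenario"]])
  expect_equal(sc2$n_population, sc$n_population)
  expect_equal(sc2$claim_capture_prob, sc$claim_capture_prob)
  expect_equal(sc2$hd_billing, "per_session")
  expect_equal(sc2$window$start, sc$window$start)
  expect_identical(simulate_claims(sc2)$claims, simulate_claims(sc)$claims)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("n_population = 10", "nonsense_key = 1"), bad)
  expect_error(read_scenario(bad), "nonsense_key")
})
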