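test_that("simulation is seeded-deterministic and returns n valid rows", {
  cfg <- sim_config(n = 10, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 10)
  expect_silent(validate_cohort(a))
  expect_true(all(a$lean_body_mass_kg <= a$body_weight_kg))
  expect_true(all(a$time_days[a$event == "censored"] == cfg$censor_day))
})

test_that("invalid configs fail naming the offending field", {
  expect_error(sim_config(n = 1), "n")
  expect_error(sim_config(dose_lognormal_sigma = 0), "dose_lognormal_sigma")
  expect_error(sim_config(adult_fraction = 1.2), "adult_fraction")
  expect_error(sim_config(censor_day = 0), "censor_day")
})

test_that("threshold scenario yields zero recoveries below the threshold", {
  d0 <- qlnorm(0.4, 0.773, 0.78)
  coh <- simulate_cohort(sim_config(
    n = 619, seed = 3,
    scenario = scenario_curve("threshold", d0 = d0, high_level = 1.5),
    dose_metric_for_scenario = "per_bw"))
  per_bw <- coh$cd34_total / coh$body_weight_kg / 1e5
  expect_true(all(coh$event[per_bw < d0] != "recovered"))
  expect_true(any(per_bw < d0))   # the threshold is exercised
})

test_that("a threshold below the dose minimum raises a warning", {
  expect_warning(
    simulate_cohort(sim_config(
      n = 100, seed = 1,
      scenario = scenario_curve("threshold", d0 = 1e-6))),
    "unexercised")
})

test_that("flat scenario carries no dose signal", {
  coh <- simulate_cohort(sim_config(n = 10000, seed = 11,
                                    scenario = scenario_curve("flat")))
  rec <- coh$event == "recovered"
  dose <- coh$cd34_total / coh$body_weight_kg / 1e5
  tau <- cor(dose[rec], coh$time_days[rec], method = "kendall")
  expect_lt(abs(tau), 0.05)
  # Harrell C of the per-kg dose against recovery time is ~0.5
  C <- harrell_c(coh$time_days, coh$event, dose)
  expect_lt(abs(C$value - 0.5), 0.03)
})

test_that("doubling the death hazard increases deaths before recovery", {
  for (s in 1:5) {
    base <- sim_config(n = 10000, seed = s)
    dbl <- sim_config(n = 10000, seed = s, death_rate = 2 * base$death_rate)
    n1 <- sum(simulate_cohort(base)$event == "died_before_recovery")
    n2 <- sum(simulate_cohort(dbl)$event == "died_before_recovery")
    expect_gt(n2, n1)
  }
})

test_that("default calibration gives ~10 deaths before recovery per 619", {
  deaths <- vapply(1:10, function(s)
    sum(simulate_cohort(sim_config(n = 619, seed = s))$event ==
          "died_before_recovery"), numeric(1))
  expect_true(abs(mean(deaths) - 10) <= 8)
})

test_that("cohort CSV round trip is lossless and schema is enforced", {
  coh <- simulate_cohort(sim_config(n = 3, seed = 5))
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back, coh, tolerance = 1e-12)

  bad <- coh
  bad$lean_body_mass_kg <- bad$body_weight_kg + 1
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_cohort(path2), "lean_body_mass_kg")

  bad2 <- coh
  bad2$event[1] <- "vanished"
  path3 <- tempfile(fileext = ".csv")
  utils::write.csv(bad2, path3, row.names = FALSE)
  expect_error(read_cohort(path3), "unknown event")

  bad3 <- coh
  names(bad3)[2] <- "gender"
  path4 <- tempfile(fileext = ".csv")
  utils::write.csv(bad3, path4, row.names = FALSE)
  expect_error(read_cohort(path4), "sex")
})
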