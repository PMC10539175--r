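test_that("harrell_c matches the exhaustive pair-enumeration oracle", {
  for (s in 1:30) {
    d <- random_censored_cohort(sample(10:50, 1), seed = s)
    got <- harrell_c(d$time, d$status, d$score)
    oracle <- brute_force_c(d$time, d$status, d$score)
    expect_equal(got$value, oracle$value, tolerance = 1e-12)
    expect_equal(unname(got$n_pairs), oracle$n_pairs)
    expect_equal(unname(got$n_tied), oracle$n_tied)
  }
})

test_that("harrell_c handles the textbook extremes and the worked toy", {
  t <- c(3, 9, 14, 20)
  # higher score, shorter time: perfect concordance
  expect_equal(harrell_c(t, rep(1, 4), -t)$value, 1.0)
  expect_equal(harrell_c(t, rep(1, 4), t)$value, 0.0)

  # toy cohort enumerated by hand: 5 permissible pairs, 3 concordant
  toy <- harrell_c(c(5, 7, 7, 10),
                   c("recovered", "recovered", "censored", "recovered"),
                   c(4, 3, 5, 1))
  expect_equal(toy$value, 3 / 5)
  expect_equal(unname(toy$n_pairs), 5)
})

test_that("concordance is rank-invariant and anti-symmetric", {
  for (s in 1:10) {
    d <- random_cox_cohort(40, seed = 40 + s)  # continuous scores, no ties
    c1 <- harrell_c(d$time, d$status, d$x)$value
    c2 <- harrell_c(d$time, d$status, -d$x)$value
    expect_equal(c1 + c2, 1, tolerance = 1e-12)
    c3 <- harrell_c(d$time, d$status, exp(3 * d$x))$value
    expect_equal(c1, c3, tolerance = 1e-12)
  }
})

test_that("day-21 labels use an inclusive boundary and mask deaths", {
  coh <- manual_cohort(dose_per_bv = runif(5, 0.5, 2),
                       time_days = c(21, 22, 10, 30, 60),
                       event = c("recovered", "recovered",
                                 "died_before_recovery", "recovered",
                                 "censored"))
  lab <- day21_labels(coh)
  expect_equal(lab$label, c(1L, 0L, NA_integer_, 0L, 0L))
  expect_equal(lab$mask, c(TRUE, TRUE, FALSE, TRUE, TRUE))
})

test_that("simulated 619-cohort leaves ~609 rows for the day-21 endpoint", {
  kept <- vapply(1:5, function(s)
    sum(day21_labels(simulate_cohort(sim_config(n = 619, seed = s)))$mask),
    numeric(1))
  expect_true(abs(mean(kept) - 609) <= 8)
})

test_that("logistic concordance equals the rank AUROC of the dose", {
  for (s in 1:20) {
    set.seed(60 + s)
    n <- 200
    dose <- rlnorm(n)
    lab <- rbinom(n, 1, plogis(-0.5 + 0.8 * log2(dose)))
    if (length(unique(lab)) < 2) next
    est <- logistic_concordance(lab, dose)
    r <- rank(dose)
    n1 <- sum(lab == 1)
    auc_rank <- (sum(r[lab == 1]) - n1 * (n1 + 1) / 2) /
      (n1 * (n - n1))
    expect_equal(est$value, auc_rank, tolerance = 1e-12)
  }
  # perfectly ordered labels
  dose <- 1:10
  expect_equal(logistic_concordance(c(rep(0, 5), rep(1, 5)), dose)$value, 1)
  expect_error(logistic_concordance(rep(1, 10), dose), "both classes")
})

test_that("label-independent dose gives AUROC 0.5 at large n", {
  set.seed(99)
  n <- 10000
  dose <- rlnorm(n)
  lab <- rbinom(n, 1, 0.6)
  expect_lt(abs(logistic_concordance(lab, dose)$value - 0.5), 0.02)
})

test_that("concordance table partitions strata and mirrors the dose
           ordering", {
  coh <- add_dose_metrics(simulate_cohort(sim_config(n = 619, seed = 4)))
  tab <- concordance_table(coh)
  expect_equal(nrow(tab), 18)
  for (ep in c("interval", "day21")) {
    sub <- tab[tab$endpoint == ep & tab$metric == "per_bw", ]
    expect_equal(sub$n[sub$stratum == "all"],
                 sum(sub$n[sub$stratum != "all"]))
  }
  # signal rides on the per-kg dose: normalised doses out-discriminate the
  # absolute count, as in the clinical table
  iv <- tab[tab$endpoint == "interval" & tab$stratum == "all", ]
  expect_gt(iv$concordance[iv$metric == "per_bw"],
            iv$concordance[iv$metric == "abs"])
  expect_true(all(iv$concordance > 0.5))
})
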