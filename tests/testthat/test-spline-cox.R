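cohort_619 <- add_dose_metrics(simulate_cohort(sim_config(n = 619, seed = 2)))

test_that("unpenalised linear fit matches independent partial-likelihood
           maximisers", {
  # 1-parameter: optimize() over a naive double-loop Efron log likelihood
  for (s in 1:5) {
    d <- random_cox_cohort(30, seed = 100 + s)
    str <- cd34dose:::cox_structure(d$time, d$status,
                                    matrix(d$x, ncol = 1))
    fit <- cd34dose:::cox_newton(str, matrix(0, 1, 1))
    oracle <- optimize(function(b)
      naive_efron_loglik(d$time, d$status, b * d$x),
      interval = c(-5, 5), maximum = TRUE, tol = 1e-12)
    expect_equal(fit$beta, oracle$maximum, tolerance = 1e-6)
  }
  # multi-covariate: survival::coxph as an independent Newton solver
  for (s in 1:10) {
    set.seed(200 + s)
    n <- sample(20:40, 1)
    x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
    time <- rexp(n, exp(0.4 * x1 - 0.3 * x2))
    status <- rbinom(n, 1, 0.8)
    if (sum(status) < 3) next
    str <- cd34dose:::cox_structure(time, status, cbind(x1, x2))
    fit <- cd34dose:::cox_newton(str, matrix(0, 2, 2))
    cph <- survival::coxph(survival::Surv(time, status) ~ x1 + x2,
                           ties = "efron",
                           control = survival::coxph.control(eps = 1e-12,
                                                             iter.max = 50))
    expect_equal(unname(fit$beta), unname(coef(cph)), tolerance = 1e-8)
  }
})

test_that("two-group cohort without ties matches the closed Newton solve", {
  set.seed(31)
  n <- 30
  g <- rep(0:1, each = n / 2)
  time <- sort(runif(n, 1, 100))          # distinct times
  time <- time[order(runif(n))]
  status <- rep(1L, n)
  str <- cd34dose:::cox_structure(time, status, matrix(g, ncol = 1))
  fit <- cd34dose:::cox_newton(str, matrix(0, 1, 1))
  cph <- survival::coxph(survival::Surv(time, status) ~ g,
                         control = survival::coxph.control(eps = 1e-12))
  expect_equal(fit$beta, unname(coef(cph)), tolerance = 1e-8)
})

test_that("an extreme roughness penalty drives the fit to the linear model", {
  spec <- default_knots(cohort_619$dose_per_bv_1e7)
  fit <- penalized_pl_map(cohort_619, "per_bv", spec,
                          penalty_spec(1e8, spec))
  expect_true(all(abs(fit$beta_hat[-1]) < 1e-4))

  lin <- penalized_pl_map(cohort_619, "per_bv", spec = NULL)
  x <- log2(cohort_619$dose_per_bv_1e7)
  g_spline <- drop(rcs_basis(x, spec) %*% fit$beta_hat)
  r_spline <- normalize_to_population_mean(g_spline, g_spline)
  r_lin <- normalize_to_population_mean(lin$beta_hat * x, lin$beta_hat * x)
  expect_lt(max(abs(log(r_spline) - log(r_lin))), 0.01)
})

test_that("a randomly permuted dose has no detectable effect", {
  set.seed(77)
  coh <- cohort_619
  coh$dose_per_bv_1e7 <- sample(coh$dose_per_bv_1e7)
  coh$log2_per_bv <- log2(coh$dose_per_bv_1e7)
  fit <- penalized_pl_map(coh, "per_bv", spec = NULL)
  se <- sqrt(diag(solve(-fit$hessian)))
  expect_true(all(abs(fit$beta_hat) < 3 * se))
})

test_that("population-mean normalisation is exact and shift-invariant", {
  set.seed(5)
  g_grid <- matrix(rnorm(50 * 20), 50, 20)
  g_obs <- matrix(rnorm(50 * 100), 50, 100)
  r <- normalize_to_population_mean(g_grid, g_obs)
  r_obs <- normalize_to_population_mean(g_obs, g_obs)
  expect_true(all(abs(rowMeans(r_obs) - 1) < 1e-12))
  expect_true(all(r >= 0))
  # adding an intercept to every draw changes nothing
  r_shift <- normalize_to_population_mean(g_grid + 3.2, g_obs + 3.2)
  expect_equal(r, r_shift, tolerance = 1e-12)
  # constant log hazard gives r identically 1
  expect_equal(normalize_to_population_mean(rep(2, 5), rep(2, 7)),
               rep(1, 5))
})

test_that("MCMC is seed-deterministic and centred on the mode", {
  spec <- default_knots(cohort_619$dose_per_bv_1e7)
  pen <- penalty_spec(10, spec)
  p1 <- suppressWarnings(
    mcmc_curve_posterior(cohort_619, "per_bv", spec, pen, n_draws = 400,
                         burn = 200, chains = 2, seed = 42))
  p2 <- suppressWarnings(
    mcmc_curve_posterior(cohort_619, "per_bv", spec, pen, n_draws = 400,
                         burn = 200, chains = 2, seed = 42))
  expect_identical(p1$draws, p2$draws)

  # mode ~ median for the log-concave posterior, on the 10-90% dose range
  rng <- quantile(cohort_619$dose_per_bv_1e7, c(0.1, 0.9))
  on_range <- p1$dose_grid >= rng[1] & p1$dose_grid <= rng[2]
  expect_lt(max(abs(p1$summary$r_median[on_range] -
                      p1$map_curve[on_range])), 0.1)
})

test_that("flat-scenario credible band covers hazard 1 on most of the
           grid", {
  coh <- add_dose_metrics(simulate_cohort(
    sim_config(n = 619, seed = 8, scenario = scenario_curve("flat"))))
  post <- suppressWarnings(
    mcmc_curve_posterior(coh, "per_bw", n_draws = 800, burn = 400,
                         chains = 2, seed = 8))
  covered <- post$summary$r_lo2.5 <= 1 & post$summary$r_hi97.5 >= 1
  expect_gte(mean(covered), 0.9)
  expect_equal(threshold_diagnostic(post)$verdict, "no_threshold")
})

test_that("credible bands cover the generative plateau curve", {
  hits <- total <- 0
  for (s in 1:12) {
    cfg <- sim_config(n = 200, seed = 300 + s)
    coh <- add_dose_metrics(simulate_cohort(cfg))
    post <- suppressWarnings(
      mcmc_curve_posterior(coh, "per_bw", penalty = NULL, n_draws = 600,
                           burn = 300, chains = 1, seed = s))
    r_gen <- scenario_relative_hazard(cfg$scenario, post$dose_grid)
    r_obs <- scenario_relative_hazard(cfg$scenario,
                                      coh$dose_per_kg_1e5)
    r_true <- r_gen / mean(r_obs)
    covered <- post$summary$r_lo2.5 <= r_true &
      post$summary$r_hi97.5 >= r_true
    hits <- hits + sum(covered)
    total <- total + length(covered)
  }
  expect_gte(hits / total, 0.85)
})

test_that("threshold diagnostic separates threshold from plateau cohorts", {
  d0 <- qlnorm(0.4, 0.773, 0.78)
  for (s in 1:2) {
    thr_coh <- add_dose_metrics(simulate_cohort(sim_config(
      n = 619, seed = s,
      scenario = scenario_curve("threshold", d0 = d0, high_level = 1.5))))
    post <- suppressWarnings(
      mcmc_curve_posterior(thr_coh, "per_bw", n_draws = 800, burn = 400,
                           chains = 2, seed = s))
    v <- threshold_diagnostic(post)
    expect_equal(v$verdict, "threshold_consistent")
    # a smooth penalised fit localises the edge to well under a doubling
    expect_lt(abs(log2(v$zero_region[2]) - log2(d0)), 0.75)
    # eps = 0 can never flag a zero region
    expect_equal(threshold_diagnostic(post, eps = 0)$verdict,
                 "no_threshold")

    pla_coh <- add_dose_metrics(simulate_cohort(sim_config(n = 619,
                                                           seed = s)))
    post2 <- suppressWarnings(
      mcmc_curve_posterior(pla_coh, "per_bw", n_draws = 800, burn = 400,
                           chains = 2, seed = s))
    expect_equal(threshold_diagnostic(post2)$verdict, "no_threshold")
  }
})

test_that("linear Cox HR behaves at the null and recovers a known slope", {
  set.seed(13)
  coh <- cohort_619
  coh$dose_per_bv_1e7 <- sample(coh$dose_per_bv_1e7)
  hr0 <- linear_cox_hr(coh, "per_bv")
  expect_true(hr0$ci_95[1] < 1 && hr0$ci_95[2] > 1)

  slope <- 0.25                       # log2-hazard per doubling
  b_true <- slope * log(2)            # log HR per unit of log2 dose
  hit <- 0
  for (s in 1:20) {
    coh_lin <- simulate_cohort(sim_config(
      n = 619, seed = 500 + s,
      scenario = scenario_curve("linear", slope = slope)))
    hr <- linear_cox_hr(coh_lin, "per_bw", scale = "log2")
    if (abs(hr$log_hr - b_true) < 2 * hr$se) hit <- hit + 1
  }
  expect_gte(hit, 18)
})
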