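# cd34dose

Dose–response analysis of CD34+ graft cell dose versus time to granulocyte
recovery after haematopoietic cell transplant.

After a transplant, the granulocyte recovery hazard rises with the CD34+
cell dose — but how? Is there a **threshold** dose below which recovery
fails, or a **plateau** above which more cells stop helping? And should
dose be normalised to the recipient's **body weight** (cells/kg, the
clinical convention) or to their **blood volume** (cells/L, which tracks
marrow space)? `cd34dose` provides:

* a calibrated **competing-risk cohort simulator** with configurable
  threshold / plateau / linear / flat dose–hazard scenarios
  (`sim_config()`, `simulate_cohort()`, `scenario_curve()`);
* three **dose normalisations** and lean-body-mass strata
  (`add_dose_metrics()`, `dose_calculator()`, `estimate_blood_volume()`);
* a Bayesian **penalised restricted-cubic-spline Cox model** of the
  relative recovery hazard `r(d) = exp(g(log2 d)) / mean_i exp(g(log2 d_i))`,
  with an own Efron-tie partial-likelihood engine, analytic roughness
  penalty, adaptive-Metropolis credible bands that integrate out the
  smoothing weight, and a threshold-dose verdict
  (`penalized_pl_map()`, `mcmc_curve_posterior()`, `threshold_diagnostic()`);
* **concordance** analyses: Harrell's C on the recovery interval and
  day-21 logistic AUROC, in an 18-cell metric x stratum x endpoint table
  (`harrell_c()`, `logistic_concordance()`, `concordance_table()`);
* a **quintile** analysis converting the interval-vs-dose slope into the
  effective doubling time of engrafting granulocyte precursors
  (`quintile_summary()`, `doubling_time()`);
* a YAML-configurable **pipeline** (`run_full_analysis()`).

See the methods vignette (`vignettes/dose-response-methods.Rmd`) for the
model, calibration and design rationale.

## Worked example

Simulate a 619-recipient cohort under the default plateau scenario and run
each analysis stage:

```r
library(cd34dose)

# one recipient's dose normalisations
dose_calculator("M", body_weight_kg = 70, cd34_total = 40e5,
                lean_body_mass_kg = 50)
#> $blood_volume_l
#> [1] 4
#> $dose_per_kg   # 10^5 cells / kg
#> [1] 0.5714286
#> $dose_per_bv   # 10^7 cells / L
#> [1] 0.1

coh <- add_dose_metrics(simulate_cohort(sim_config(n = 619, seed = 1)))

# which dose metric discriminates outcomes best?
tab <- concordance_table(coh)
subset(tab, stratum == "all")
#>  metric stratum endpoint   n concordance
#>     abs     all interval 619       0.574
#>  per_bw     all interval 619       0.593
#>  per_bv     all interval 619       0.592
#>     abs     all    day21 600       0.633
#>  per_bw     all    day21 600       0.651
#>  per_bv     all    day21 600       0.651

# spline Cox posterior of the relative hazard, and the threshold verdict
post <- mcmc_curve_posterior(coh, "per_bv", n_draws = 1000, burn = 400,
                             chains = 2, seed = 1)
post
#> <curve_posterior> per_bv dose metric; 1000 draws, 2 chains
#>   lambda = 3.625, acceptance = 0.31, R-hat = 1.028
#>   dose grid: [0.02711, 4.4] (200 points)
threshold_diagnostic(post)
#> <threshold_verdict> no_threshold
#>   eps = 0.05, prob_cut = 0.95

# quintile kinetics: days saved per dose doubling = precursor doubling time
quintile_summary(coh, "per_bv")
#> <quintile_summary> per_bv dose metric, 600 recovered patients
#>  quintile   n median_dose median_log2_dose median_interval_days
#>         1 120   0.1274187      -2.97235164                 22.0
#>         2 120   0.2392048      -2.06368702                 20.5
#>         3 120   0.3697448      -1.43539842                 18.5
#>         4 120   0.5578823      -0.84197507                 18.0
#>         5 120   1.0238112       0.03393645                 18.0
#>   Pearson r = -0.926, slope = -1.438 days/doubling, doubling time = 1.44 days

# conventional log-linear summary
linear_cox_hr(coh, "per_bv", scale = "log2")[c("hr_per_unit", "ci_95", "p")]
#> $hr_per_unit
#> [1] 1.271265
#> $ci_95
#> [1] 1.187077 1.361424
#> $p
#> [1] 4.297936e-12
```

Or run everything from a config file:

```r
cfg <- system.file("extdata", "example_config.yaml", package = "cd34dose")
report <- run_full_analysis(cfg)
report
#> <analysis_report> n = 619 (612 recovered, 7 died before recovery)
#> threshold verdicts:
#>    per_bw : no_threshold
#>    per_bv : no_threshold
#> linear HR per unit [per_bv]: 1.676 [1.411, 1.990]
```

## License

MIT (see `LICENSE`).
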