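#' Estimate recipient blood volume
#'
#' Two estimators are provided. The default, `"per_lbm"`, is proportional to
#' lean body mass (`litres = coefficient * LBM / 1000`, default 80 mL per kg
#' of lean body mass), reflecting that blood volume tracks lean body mass
#' rather than total body weight. The alternative `"nadler"` is the classical
#' Nadler sex-specific height-weight formula.
#'
#' @param sex `"M"` or `"F"` (vectorised).
#' @param lean_body_mass_kg lean body mass in kg (required for `per_lbm`).
#' @param body_weight_kg body weight in kg (required for `nadler`).
#' @param height_m height in metres (required for `nadler`).
#' @param method `"per_lbm"` or `"nadler"`.
#' @param coefficient mL of blood per kg of lean body mass (`per_lbm` only).
#' @return list with `litres` (numeric vector), `method`, `coefficient`.
#' @examples
#' estimate_blood_volume("M", lean_body_mass_kg = 50)$litres  # 4.0 L
#' @export
estimate_blood_volume <- function(sex, lean_body_mass_kg = NULL,
                                  body_weight_kg = NULL, height_m = NULL,
                                  method = c("per_lbm", "nadler"),
                                  coefficient = 80) {
  method <- match.arg(method)
  if (method == "per_lbm") {
    if (is.null(lean_body_mass_kg))
      stop("`lean_body_mass_kg` is required for method = 'per_lbm'",
           call. = FALSE)
    if (any(lean_body_mass_kg <= 0) || coefficient <= 0)
      stop("lean body mass and coefficient must be > 0", call. = FALSE)
    litres <- coefficient * lean_body_mass_kg / 1000
  } else {
    if (is.null(height_m) || is.null(body_weight_kg))
      stop("`height_m` and `body_weight_kg` are required for method = 'nadler'",
           call. = FALSE)
    if (any(height_m <= 0) || any(body_weight_kg <= 0))
      stop("height and body weight must be > 0", call. = FALSE)
    male <- sex == "M"
    litres <- ifelse(male,
                     0.3669 * height_m^3 + 0.03219 * body_weight_kg + 0.6041,
                     0.3561 * height_m^3 + 0.03308 * body_weight_kg + 0.1833)
  }
  list(litres = litres, method = method,
       coefficient = if (method == "per_lbm") coefficient else NA_real_)
}

#' Compute the three CD34-positive dose expressions
#'
#' From an absolute graft CD34-positive cell count, recipient body weight and
#' blood volume, computes the three dose normalisations in the clinical
#' reporting units -- absolute count (1e5 cells), per kg of body weight
#' (1e5 cells/kg) and per litre of blood volume (1e7 cells/L) -- together
#' with their base-2 logarithms.
#'
#' @param abs_cd34 absolute CD34-positive cell count, > 0 (vectorised).
#' @param body_weight_kg body weight in kg, > 0.
#' @param blood_volume_l blood volume in litres, > 0.
#' @return list with `abs_cd34`, `dose_per_kg`, `dose_per_bv`, `log2_abs`,
#'   `log2_per_kg`, `log2_per_bv`.
#' @examples
#' compute_dose_metrics(40e5, body_weight_kg = 20, blood_volume_l = 1.5)
#' @export
compute_dose_metrics <- function(abs_cd34, body_weight_kg, blood_volume_l) {
  if (any(abs_cd34 <= 0) || any(body_weight_kg <= 0) ||
      any(blood_volume_l <= 0))
    stop("all inputs to compute_dose_metrics must be > 0", call. = FALSE)
  dose_per_kg <- abs_cd34 / body_weight_kg / 1e5
  dose_per_bv <- abs_cd34 / blood_volume_l / 1e7
  list(abs_cd34 = abs_cd34,
       dose_per_kg = dose_per_kg, dose_per_bv = dose_per_bv,
       log2_abs = log2(abs_cd34 / 1e5),
       log2_per_kg = log2(dose_per_kg), log2_per_bv = log2(dose_per_bv))
}

#' Extend a cohort with blood volume, dose metrics and LBM/BW stratum
#'
#' Adds the derived analysis columns to a cohort: `blood_volume_l`,
#' `dose_abs_1e5`, `dose_per_kg_1e5`, `dose_per_bv_1e7`, their log2
#' counterparts, and `lbm_bw_stratum`.
#'
#' @param cohort a cohort `data.frame` (see [simulate_cohort()]).
#' @param bv_method,bv_coefficient passed to [estimate_blood_volume()].
#' @param low_pct,high_pct stratification percentiles, see [lbm_bw_strata()].
#' @return the cohort with derived columns appended.
#' @export
add_dose_metrics <- function(cohort, bv_method = "per_lbm",
                             bv_coefficient = 80,
                             low_pct = 15, high_pct = 85) {
  validate_cohort(cohort[, cohort_columns])
  bv <- estimate_blood_volume(cohort$sex, cohort$lean_body_mass_kg,
                              method = bv_method,
                              coefficient = bv_coefficient)
  dm <- compute_dose_metrics(cohort$cd34_total, cohort$body_weight_kg,
                             bv$litres)
  cohort$blood_volume_l <- bv$litres
  cohort$dose_abs_1e5 <- cohort$cd34_total / 1e5
  cohort$dose_per_kg_1e5 <- dm$dose_per_kg
  cohort$dose_per_bv_1e7 <- dm$dose_per_bv
  cohort$log2_abs <- dm$log2_abs
  cohort$log2_per_kg <- dm$log2_per_kg
  cohort$log2_per_bv <- dm$log2_per_bv
  cohort$lbm_bw_stratum <- lbm_bw_strata(cohort, low_pct, high_pct)$label
  cohort
}

dose_column <- function(metric = c("abs", "per_bw", "per_bv"),
                        log2 = FALSE) {
  metric <- match.arg(metric)
  col <- switch(metric, abs = "dose_abs_1e5", per_bw = "dose_per_kg_1e5",
                per_bv = "dose_per_bv_1e7")
  if (log2) {
    col <- switch(metric, abs = "log2_abs", per_bw = "log2_per_kg",
                  per_bv = "log2_per_bv")
  }
  col
}

#' Stratify by extreme vs normal lean-body-mass to body-weight ratio
#'
#' Labels each recipient `"extreme"` when the ratio LBM/BW is strictly below
#' the `low_pct`-th or strictly above the `high_pct`-th empirical percentile
#' of the supplied cohort, `"normal"` otherwise. These are the strata in
#' which the per-blood-volume dose is expected to outperform the per-kg dose
#' most clearly.
#'
#' @param cohort a cohort `data.frame` with `lean_body_mass_kg` and
#'   `body_weight_kg`.
#' @param low_pct,high_pct stratification percentiles (0 < low < high < 100).
#' @return list with `label` (character vector `"extreme"`/`"normal"`) and
#'   `counts` (named integer vector).
#' @export
lbm_bw_strata <- function(cohort, low_pct = 15, high_pct = 85) {
  stopifnot(nrow(cohort) > 0, low_pct > 0, high_pct < 100,
            low_pct < high_pct)
  ratio <- cohort$lean_body_mass_kg / cohort$body_weight_kg
  if (diff(range(ratio)) == 0) {
    warning("LBM/BW ratio is constant; all rows labelled 'normal'",
            call. = FALSE)
    label <- rep("normal", length(ratio))
  } else {
    qs <- stats::quantile(ratio, c(low_pct, high_pct) / 100, type = 7,
                          names = FALSE)
    label <- ifelse(ratio < qs[1] | ratio > qs[2], "extreme", "normal")
  }
  counts <- c(extreme = sum(label == "extreme"),
              normal = sum(label == "normal"))
  list(label = label, counts = counts)
}

#' Poisson sampling noise in the number of HSCs in a graft
#'
#' Haematopoietic stem cells are a small minority of CD34-positive cells, so
#' the HSC content of a graft with a given CD34 count is itself a Poisson
#' draw. For an expected HSC count lambda = cd34_count * hsc_per_cd34, the
#' relative fluctuation is 1/sqrt(lambda); the conventional "full width" of
#' the variation is taken as the three-standard-deviation relative
#' fluctuation 3/sqrt(lambda). A graft of 40 x 1e5 CD34-positive cells at
#' 1 HSC per 5000 CD34-positive cells has lambda = 800 and a ~10% three-sigma
#' fluctuation in HSC numbers.
#'
#' @param cd34_count CD34-positive cell count, > 0.
#' @param hsc_per_cd34 assumed HSC fraction among CD34-positive cells, in
#'   (0, 1].
#' @return list with `lambda` (expected HSC count), `cv_pct`
#'   (= 100/sqrt(lambda)) and `three_sigma_pct` (= 300/sqrt(lambda)).
#' @examples
#' hsc_poisson_variation(40e5, 1 / 5000)
#' @export
hsc_poisson_variation <- function(cd34_count, hsc_per_cd34) {
  if (any(cd34_count <= 0)) stop("`cd34_count` must be > 0", call. = FALSE)
  if (any(hsc_per_cd34 <= 0) || any(hsc_per_cd34 > 1))
    stop("`hsc_per_cd34` must be in (0, 1]", call. = FALSE)
  lambda <- cd34_count * hsc_per_cd34
  if (any(lambda == 0)) stop("expected HSC count is 0", call. = FALSE)
  list(lambda = lambda, cv_pct = 100 / sqrt(lambda),
       three_sigma_pct = 300 / sqrt(lambda))
}
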