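# Concordance of dose metrics with granulocyte recovery: Harrell's C for
# the interval endpoint and Mann-Whitney AUROC of a logistic model for the
# day-21 endpoint, overall and within LBM/BW strata.

#' Harrell's concordance of a score with time to recovery
#'
#' Orientation: a higher score should predict a shorter time to recovery,
#' so a pair is concordant when the patient with the higher score recovers
#' first. A pair is permissible when the shorter of the two times is an
#' observed recovery; deaths before recovery and administrative censoring
#' count as censored. Tied event times contribute no permissible pair;
#' tied scores receive half credit:
#' `C = (concordant + 0.5 * tied_score) / permissible`.
#'
#' @param time event/censoring times in days.
#' @param event character vector (`"recovered"` / `"died_before_recovery"` /
#'   `"censored"`) or 0/1 status with 1 = recovered.
#' @param score numeric predictor (higher = faster expected recovery).
#' @return object of class `concordance_estimate`: `value`, `n_pairs`,
#'   `n_tied`, `endpoint = "interval"`.
#' @export
harrell_c <- function(time, event, score) {
  stopifnot(length(time) == length(event), length(time) == length(score))
  status <- if (is.numeric(event)) as.integer(event) else
    as.integer(event == "recovered")
  if (sum(status) < 1) stop("need at least 1 recovery event", call. = FALSE)
  fit <- survival::concordance(survival::Surv(time, status) ~ score)
  cnt <- fit$count
  # survival::concordance orients "higher score ~ longer time"; recovery is
  # a favourable event, so our concordant pairs are its discordant ones
  permissible <- cnt["concordant"] + cnt["discordant"] + cnt["tied.x"]
  if (permissible <= 0) stop("no permissible pairs", call. = FALSE)
  value <- (cnt["discordant"] + 0.5 * cnt["tied.x"]) / permissible
  structure(list(value = unname(value), n_pairs = unname(permissible),
                 n_tied = unname(cnt["tied.x"]), endpoint = "interval"),
            class = "concordance_estimate")
}

#' @export
print.concordance_estimate <- function(x, ...) {
  cat(sprintf("<concordance_estimate> %s endpoint: C = %.4f (%d pairs)\n",
              x$endpoint, x$value, as.integer(x$n_pairs)))
  invisible(x)
}

#' Day-21 recovery labels
#'
#' Binary endpoint: recovered within 21 days of transplant (inclusive).
#' Patients who died before granulocyte recovery are excluded (masked);
#' patients censored alive without recovery are labelled 0.
#'
#' @param cohort cohort `data.frame`.
#' @param day horizon in days (default 21).
#' @return list with `label` (0/1, `NA` where masked) and `mask` (logical,
#'   `TRUE` = included).
#' @export
day21_labels <- function(cohort, day = 21) {
  mask <- cohort$event != "died_before_recovery"
  label <- as.integer(cohort$event == "recovered" & cohort$time_days <= day)
  label[!mask] <- NA_integer_
  list(label = label, mask = mask)
}

#' Logistic-model concordance (AUROC) of dose with a binary endpoint
#'
#' Fits `label ~ dose` by maximum-likelihood logistic regression and
#' reports the Mann-Whitney AUROC of the fitted probabilities. Because the
#' fitted probability is monotone in the single covariate, this equals the
#' rank AUROC of the dose itself; both are computed and compared as an
#' internal cross-check.
#'
#' @param labels binary 0/1 vector.
#' @param dose numeric dose vector.
#' @return object of class `concordance_estimate` with
#'   `endpoint = "day21"`.
#' @export
logistic_concordance <- function(labels, dose) {
  keep <- !is.na(labels)
  labels <- labels[keep]
  dose <- dose[keep]
  if (length(unique(labels)) < 2)
    stop("both classes must be present", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm(labels ~ dose, family = stats::binomial()))
  if (!fit$converged || any(abs(stats::coef(fit)) > 25))
    warning("possible separation in the logistic fit; ",
            "AUROC is still defined by ranks", call. = FALSE)
  score <- stats::fitted(fit)
  auc <- rank_auroc(labels, score)
  slope <- stats::coef(fit)["dose"]
  auc_dose <- rank_auroc(labels, if (!is.na(slope) && slope < 0) -dose
                         else dose)
  if (abs(auc - auc_dose) > 1e-10)
    warning("model AUROC differs from rank AUROC of the dose",
            call. = FALSE)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  sc1 <- score[labels == 1]
  sc0 <- score[labels == 0]
  shared <- intersect(unique(sc1), unique(sc0))
  tied <- sum(vapply(shared, function(v) sum(sc1 == v) * sum(sc0 == v),
                     numeric(1)))
  structure(list(value = auc, n_pairs = n1 * n0, n_tied = tied,
                 endpoint = "day21"),
            class = "concordance_estimate")
}

# Mann-Whitney AUROC via ranks (ties get half credit)
rank_auroc <- function(labels, score) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(score)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Concordance table across dose metrics, strata and endpoints
#'
#' The full concordance machinery: for each of the three dose metrics
#' (absolute, per body weight, per blood volume), within all cases and the
#' extreme / normal LBM-to-BW strata, the Harrell concordance with the
#' interval to recovery (all rows; deaths censored at death time) and the
#' logistic AUROC for recovery by day 21 (deaths before recovery
#' excluded).
#'
#' @param cohort cohort `data.frame`; derived columns are added when
#'   absent.
#' @return `data.frame` with columns `metric`, `stratum`, `endpoint`, `n`,
#'   `concordance` (18 rows; `NA` concordance marks an undefined cell).
#' @export
concordance_table <- function(cohort) {
  if (!"lbm_bw_stratum" %in% names(cohort)) cohort <- add_dose_metrics(cohort)
  metrics <- c("abs", "per_bw", "per_bv")
  strata <- c("all", "extreme", "normal")
  d21 <- day21_labels(cohort)
  out <- expand.grid(metric = metrics, stratum = strata,
                     endpoint = c("interval", "day21"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n <- NA_integer_
  out$concordance <- NA_real_
  for (i in seq_len(nrow(out))) {
    rows <- if (out$stratum[i] == "all") rep(TRUE, nrow(cohort)) else
      cohort$lbm_bw_stratum == out$stratum[i]
    dose <- cohort[[dose_column(out$metric[i])]]
    est <- tryCatch({
      if (out$endpoint[i] == "interval") {
        sub <- which(rows)
        out$n[i] <- length(sub)
        harrell_c(cohort$time_days[sub], cohort$event[sub], dose[sub])
      } else {
        sub <- which(rows & d21$mask)
        out$n[i] <- length(sub)
        logistic_concordance(d21$label[sub], dose[sub])
      }
    }, error = function(e) NULL)
    if (!is.null(est)) out$concordance[i] <- est$value
  }
  out
}
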