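#' Generative dose-response scenario curves
#'
#' A `scenario_curve` maps a CD34-positive cell dose to a generative relative
#' recovery hazard. Four shapes are supported:
#' \describe{
#'   \item{threshold}{hazard exactly 0 below the threshold dose `d0`, stepping
#'     to `high_level` at and above it -- the classical "threshold dose"
#'     hypothesis.}
#'   \item{plateau}{hazard rises (linearly in log2 dose) from `low_level` at
#'     `d0/4` to `high_level` at `d0` and stays flat above -- the shape the
#'     clinical hazard curves take, with a positive hazard however low the
#'     dose.}
#'   \item{linear}{log2 hazard changes by `slope` per doubling of dose.}
#'   \item{flat}{hazard 1 at every positive dose (null scenario).}
#' }
#' A dose of exactly zero returns hazard 0 for every kind: with no cells there
#' is no recovery.
#'
#' @param kind one of `"threshold"`, `"plateau"`, `"linear"`, `"flat"`.
#' @param d0 threshold/breakpoint dose, in the units of the dose metric the
#'   curve is applied to (e.g. 1e5 cells/kg for the per-body-weight metric).
#' @param low_level relative hazard at the low-dose end (plateau kind), >= 0.
#' @param high_level plateau / above-threshold relative hazard, > 0.
#' @param slope log2-hazard change per doubling of dose (linear kind).
#' @param d_ref reference dose at which the linear curve has hazard 1.
#' @return an object of class `scenario_curve`.
#' @examples
#' sc <- scenario_curve("plateau", d0 = 3, low_level = 0.5, high_level = 1.5)
#' scenario_relative_hazard(sc, c(0.1, 3, 10))
#' @export
scenario_curve <- function(kind = c("threshold", "plateau", "linear", "flat"),
                           d0 = 1, low_level = 0.5, high_level = 1.5,
                           slope = 0.25, d_ref = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(d0) || length(d0) != 1L || d0 <= 0)
    stop("`d0` must be a single positive number", call. = FALSE)
  if (low_level < 0) stop("`low_level` must be >= 0", call. = FALSE)
  if (high_level <= 0) stop("`high_level` must be > 0", call. = FALSE)
  if (kind == "plateau" && low_level <= 0)
    stop("`low_level` must be > 0 for the plateau kind", call. = FALSE)
  if (kind == "plateau" && high_level < low_level)
    stop("`high_level` must be >= `low_level`", call. = FALSE)
  structure(list(kind = kind, d0 = d0, low_level = low_level,
                 high_level = high_level, slope = slope, d_ref = d_ref),
            class = "scenario_curve")
}

#' Evaluate a scenario curve
#'
#' Deterministic evaluation of the generative dose -> relative-hazard mapping.
#' Continuous in dose for every kind except `threshold`.
#'
#' @param curve a [scenario_curve()].
#' @param dose numeric vector of doses, >= 0. Dose 0 returns hazard 0 for all
#'   kinds.
#' @return numeric vector of relative hazards, >= 0.
#' @export
scenario_relative_hazard <- function(curve, dose) {
  stopifnot(inherits(curve, "scenario_curve"))
  if (!is.numeric(dose) || any(!is.finite(dose)))
    stop("`dose` must be finite numeric", call. = FALSE)
  if (any(dose < 0)) stop("`dose` must be >= 0", call. = FALSE)
  r <- switch(curve$kind,
    flat = rep(1, length(dose)),
    threshold = ifelse(dose < curve$d0, 0, curve$high_level),
    linear = 2^(curve$slope * log2(pmax(dose, .Machine$double.xmin) /
                                     curve$d_ref)),
    plateau = {
      lo <- curve$d0 / 4
      f <- (log2(pmax(dose, .Machine$double.xmin)) - log2(lo)) /
        (log2(curve$d0) - log2(lo))
      curve$low_level +
        (curve$high_level - curve$low_level) * pmin(pmax(f, 0), 1)
    })
  r[dose == 0] <- 0
  r
}

#' @export
print.scenario_curve <- function(x, ...) {
  cat("<scenario_curve>", x$kind, "\n")
  switch(x$kind,
    threshold = cat("  d0 =", x$d0, " high_level =", x$high_level, "\n"),
    plateau = cat("  ramp", x$low_level, "->", x$high_level,
                  "over [", x$d0 / 4, ",", x$d0, "]\n"),
    linear = cat("  slope =", x$slope, "per doubling, d_ref =", x$d_ref, "\n"),
    flat = cat("  hazard 1 everywhere\n"))
  invisible(x)
}
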