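#' Restricted cubic spline specification
#'
#' Knots are on the log2-dose scale. The basis is the standard restricted
#' (natural) cubic truncated-power construction: piecewise cubic between the
#' boundary knots and exactly linear outside them.
#'
#' @param knots strictly increasing numeric vector of knot locations
#'   (log2 dose), length >= 3.
#' @param placement `"quantile"` or `"manual"` (provenance only).
#' @return object of class `spline_spec`.
#' @export
spline_spec <- function(knots, placement = c("manual", "quantile")) {
  placement <- match.arg(placement)
  knots <- as.numeric(knots)
  if (length(knots) < 3) stop("need at least 3 knots", call. = FALSE)
  if (any(diff(knots) <= 0))
    stop("knots must be strictly increasing (no duplicates)", call. = FALSE)
  structure(list(knots = knots, n_knots = length(knots),
                 placement = placement), class = "spline_spec")
}

# Harrell's conventional outer/inner quantile positions by knot count
harrell_positions <- function(k) {
  switch(as.character(k),
         "3" = c(10, 50, 90),
         "4" = c(5, 35, 65, 95),
         "5" = c(5, 27.5, 50, 72.5, 95),
         "6" = c(5, 23, 41, 59, 77, 95),
         "7" = c(2.5, 18.33, 34.17, 50, 65.83, 81.67, 97.5),
         seq(5, 95, length.out = k)) / 100
}

#' Default knot placement for a dose vector
#'
#' Places `n_knots` knots at Harrell's conventional empirical percentiles of
#' log2 dose (for 5 knots: the 5 / 27.5 / 50 / 72.5 / 95 percentiles).
#'
#' @param doses positive dose vector (reporting units).
#' @param n_knots number of knots (default 5).
#' @return a [spline_spec()] with `placement = "quantile"`.
#' @export
default_knots <- function(doses, n_knots = 5) {
  if (any(doses <= 0)) stop("doses must be > 0", call. = FALSE)
  x <- log2(doses)
  if (length(unique(x)) < n_knots)
    stop("fewer than ", n_knots, " distinct dose values; ",
         "use fewer knots", call. = FALSE)
  kn <- stats::quantile(x, harrell_positions(n_knots), type = 7,
                        names = FALSE)
  if (any(diff(kn) <= 0))
    stop("quantile knots are not distinct; use fewer knots", call. = FALSE)
  spline_spec(kn, placement = "quantile")
}

#' Restricted cubic spline design matrix
#'
#' Column 1 is `x` itself; columns 2..(K-1) are the truncated-power
#' restricted-cubic terms with the two boundary-knot corrections, scaled by
#' `(t_K - t_1)^2` so all columns share the scale of `x`. The fitted curve
#' is exactly linear for `x` outside the boundary knots.
#'
#' @param x numeric vector on the log2-dose scale.
#' @param spec a [spline_spec()].
#' @return matrix `[length(x), n_knots - 1]`.
#' @export
rcs_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"), all(is.finite(x)))
  t <- spec$knots
  K <- length(t)
  tau <- (t[K] - t[1])^2
  pp3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), K - 1)
  out[, 1] <- x
  for (j in seq_len(K - 2)) {
    cj <- (t[K] - t[j]) / (t[K] - t[K - 1])
    ej <- (t[K - 1] - t[j]) / (t[K] - t[K - 1])
    out[, j + 1] <- (pp3(x - t[j]) - cj * pp3(x - t[K - 1]) +
                       ej * pp3(x - t[K])) / tau
  }
  colnames(out) <- c("lin", paste0("nl", seq_len(K - 2)))
  out
}

#' Roughness matrix of the restricted cubic basis
#'
#' The matrix `S` with `S[j, k] = integral of B_j''(x) B_k''(x) dx` over the
#' knot span. Second derivatives of the restricted basis are piecewise
#' linear and vanish outside the boundary knots, so the integral is computed
#' exactly by Simpson's rule on each inter-knot interval. The linear column
#' has zero second derivative, hence `t(beta) %*% S %*% beta = 0` exactly
#' for any coefficient vector whose curve is linear in log2 dose.
#'
#' @param spec a [spline_spec()].
#' @return symmetric positive-semidefinite matrix `[K-1, K-1]`.
#' @export
roughness_matrix <- function(spec) {
  t <- spec$knots
  K <- length(t)
  tau <- (t[K] - t[1])^2
  d2 <- function(x) {
    # second derivative of each basis column at x (piecewise linear)
    out <- matrix(0, length(x), K - 1)
    for (j in seq_len(K - 2)) {
      cj <- (t[K] - t[j]) / (t[K] - t[K - 1])
      ej <- (t[K - 1] - t[j]) / (t[K] - t[K - 1])
      out[, j + 1] <- 6 * (pmax(x - t[j], 0) - cj * pmax(x - t[K - 1], 0) +
                             ej * pmax(x - t[K], 0)) / tau
    }
    out
  }
  S <- matrix(0, K - 1, K - 1)
  for (m in seq_len(K - 1)) {
    a <- t[m]; b <- t[m + 1]; h <- b - a
    fa <- d2(a); fm <- d2((a + b) / 2); fb <- d2(b)
    # product of two linear pieces is quadratic: Simpson is exact
    S <- S + (h / 6) * (crossprod(fa) + 4 * crossprod(fm) + crossprod(fb))
  }
  (S + t(S)) / 2
}

#' Penalty specification
#'
#' Bundles the smoothing weight with the roughness matrix of a spline
#' specification. The penalised log partial likelihood is
#' `lpl(beta) - lambda/2 * t(beta) S beta`; equivalently the penalty is a
#' (partially improper) Gaussian smoothing prior whose null space is the set
#' of curves linear in log2 dose.
#'
#' @param lambda smoothing weight, >= 0.
#' @param spec a [spline_spec()] (used to build the roughness matrix), or
#'   `NULL` if `matrix` is supplied directly.
#' @param matrix optional explicit roughness matrix.
#' @return object of class `penalty_spec` with fields `lambda`, `matrix`.
#' @export
penalty_spec <- function(lambda, spec = NULL, matrix = NULL) {
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  if (is.null(matrix)) {
    if (is.null(spec)) stop("supply `spec` or `matrix`", call. = FALSE)
    matrix <- roughness_matrix(spec)
  }
  structure(list(lambda = lambda, matrix = matrix), class = "penalty_spec")
}
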