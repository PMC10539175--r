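# Internal Cox partial-likelihood engine (Efron ties), shared by the MAP
# fit, the lambda selection and the MCMC sampler.

# Precompute the risk-set bookkeeping for fast repeated likelihood
# evaluation. Rows are sorted by time; for each distinct event time the
# risk set is a suffix of the sorted order, so suffix cumulative sums give
# the risk-set totals.
cox_structure <- function(time, status, X) {
  stopifnot(length(time) == length(status), nrow(X) == length(time))
  ord <- order(time)
  t_s <- time[ord]
  d_s <- as.integer(status[ord])
  X_s <- X[ord, , drop = FALSE]
  ev_rows <- which(d_s == 1L)
  if (length(ev_rows) < 2) stop("need at least 2 events", call. = FALSE)
  ut <- unique(t_s[ev_rows])
  first_idx <- match(ut, t_s)                      # risk-set suffix start
  ev_group <- match(t_s[ev_rows], ut)              # group of each event row
  d_k <- tabulate(ev_group, nbins = length(ut))
  gend <- cumsum(d_k)                              # event-row group ends
  term_g <- rep(seq_along(ut), d_k)                # one Efron term per event
  term_f <- unlist(lapply(d_k, function(d) (seq_len(d) - 1) / d))
  list(n = length(t_s), p = ncol(X_s), time = t_s, status = d_s, X = X_s,
       ev_rows = ev_rows, ut = ut, first_idx = first_idx,
       ev_group = ev_group, d_k = d_k, gend = gend,
       term_g = term_g, term_f = term_f)
}

revcumsum <- function(x) rev(cumsum(rev(x)))

# Efron log partial likelihood; fully vectorised (used inside the MCMC).
cox_loglik <- function(str, beta) {
  eta <- drop(str$X %*% beta)
  m <- max(eta)                      # guard exp overflow; lpl is shift-free
  s <- exp(eta - m)
  S_R <- revcumsum(s)[str$first_idx]
  cs <- cumsum(s[str$ev_rows])
  S_D <- cs[str$gend] - c(0, cs[str$gend[-length(str$gend)]])
  denom <- S_R[str$term_g] - str$term_f * S_D[str$term_g]
  sum(eta[str$ev_rows] - m) - sum(log(denom))
}

# Gradient and Hessian of the Efron log partial likelihood.
cox_grad_hess <- function(str, beta) {
  p <- str$p
  eta <- drop(str$X %*% beta)
  m <- max(eta)
  s <- exp(eta - m)
  sX <- str$X * s
  rc_s <- revcumsum(s)
  rc_sX <- apply(sX, 2, revcumsum)
  if (is.null(dim(rc_sX))) rc_sX <- matrix(rc_sX, ncol = ncol(sX))
  # suffix sums of s * x_j * x_k for the upper triangle
  ut_idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  sXX <- sX[, ut_idx[, 1], drop = FALSE] * str$X[, ut_idx[, 2], drop = FALSE]
  rc_sXX <- apply(sXX, 2, revcumsum)
  if (is.null(dim(rc_sXX))) rc_sXX <- matrix(rc_sXX, ncol = ncol(sXX))

  fi <- str$first_idx
  S_R <- rc_s[fi]
  A_R <- rc_sX[fi, , drop = FALSE]
  B_R <- rc_sXX[fi, , drop = FALSE]

  ev <- str$ev_rows
  grp_sum <- function(v) {
    cs <- apply(as.matrix(v), 2, cumsum)
    cs <- rbind(0, cs)
    cs[str$gend + 1, , drop = FALSE] -
      cs[c(1, str$gend[-length(str$gend)] + 1), , drop = FALSE]
  }
  S_D <- drop(grp_sum(s[ev]))
  A_D <- grp_sum(sX[ev, , drop = FALSE])
  B_D <- grp_sum(sXX[ev, , drop = FALSE])

  grad <- colSums(str$X[ev, , drop = FALSE])
  H <- matrix(0, p, p)
  expand <- function(v) {
    M <- matrix(0, p, p)
    M[upper.tri(M, diag = TRUE)] <- v
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    M
  }
  for (i in seq_along(str$term_g)) {
    g <- str$term_g[i]; f <- str$term_f[i]
    D <- S_R[g] - f * S_D[g]
    a <- (A_R[g, ] - f * A_D[g, ]) / D
    B <- expand(B_R[g, ] - f * B_D[g, ]) / D
    grad <- grad - a
    H <- H - (B - tcrossprod(a))
  }
  list(grad = grad, hessian = H)
}

# Newton maximisation of the penalised log partial likelihood
# lpl(beta) - 0.5 * t(beta) P beta, with step halving and a ridge fallback
# for separated (monotone-likelihood) fits.
cox_newton <- function(str, P, beta0 = NULL, tol = 1e-9, max_iter = 100) {
  p <- str$p
  beta <- if (is.null(beta0)) rep(0, p) else beta0
  obj <- function(b) cox_loglik(str, b) - 0.5 * sum(b * (P %*% b))
  f <- obj(beta)
  ridge_used <- FALSE
  for (it in seq_len(max_iter)) {
    gh <- cox_grad_hess(str, beta)
    gpen <- gh$grad - drop(P %*% beta)
    Hpen <- gh$hessian - P
    step <- tryCatch(solve(-Hpen, gpen), error = function(e) {
      solve(-Hpen + diag(1e-8, p), gpen)
    })
    # step halving on the penalised objective
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      fc <- obj(cand)
      if (is.finite(fc) && fc >= f - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) break
    }
    beta <- beta + alpha * step
    f <- obj(beta)
    if (max(abs(gpen)) < tol) break
    if (max(abs(beta)) > 30 && !ridge_used) {
      warning("possible separation (monotone partial likelihood); ",
              "adding a small ridge penalty", call. = FALSE)
      P <- P + diag(1e-3, p)
      ridge_used <- TRUE
      beta <- rep(0, p)
      f <- obj(beta)
    }
    if (it == max_iter) {
      gh <- cox_grad_hess(str, beta)
      gn <- max(abs(gh$grad - drop(P %*% beta)))
      if (gn > 1e-4)
        stop(sprintf(
          "Newton iterations did not converge (gradient norm %.3g)", gn),
          call. = FALSE)
    }
  }
  gh <- cox_grad_hess(str, beta)
  list(beta = beta, hessian = gh$hessian, hessian_pen = gh$hessian - P,
       log_pl = cox_loglik(str, beta),
       log_pl_pen = f, ridge_used = ridge_used)
}
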