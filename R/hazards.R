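# Survival engines.
#
# fit_aalen() implements Aalen's additive hazard model with time-varying
# cumulative coefficients: at each ordered event time the coefficient
# increment is the least-squares solve of the event indicator on the at-risk
# design, dB(t) = (X_r' X_r)^{-1} X_r' dN(t), with the optional-variation
# covariance estimator accumulated alongside. Tied events are handled in a
# single solve (dN carries multiplicities). The per-covariate test
# aggregates increments over the identifiable range with a configurable
# weight (constant by default).
#
# fit_coxph() is the standard Cox proportional-hazards fit (Breslow ties),
# used by the per-variant pleiotropy screen.

#' Aalen additive-hazard regression with time-varying coefficients
#'
#' @param design numeric matrix (samples x covariates) whose first column is
#'   the intercept; column names label the coefficients.
#' @param time positive follow-up times.
#' @param event 0/1 event indicators; at least one event required.
#' @param rcond_tol estimation stops (later events dropped, with a count)
#'   once the reciprocal condition number of the at-risk Gram matrix falls
#'   below this tolerance.
#' @return An object of class `aalen_fit`: `times` (ordered distinct event
#'   times within the identifiable range), `dB` / `B` (increments and
#'   cumulative coefficients, times x covariates), `dOmega_diag` /
#'   `Omega_diag` (optional-variation variance increments and cumulative
#'   diagonals), `n_dropped_events` and `identifiable_end`.
#' @export
fit_aalen <- function(design, time, event, rcond_tol = 1e-10) {
  X <- as.matrix(design)
  stopifnot(nrow(X) == length(time), length(time) == length(event))
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) < 1) stop("no events")
  if (any(time <= 0)) stop("times must be positive")
  if (max(abs(X[, 1] - 1)) > 1e-12)
    stop("design must include an intercept as its first column")
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1L)))[seq_len(p)]

  ev_times <- sort(unique(time[event == 1]))
  K <- length(ev_times)
  # Traverse event times in decreasing order, growing the at-risk Gram
  # matrix incrementally (risk set only gains members as t decreases).
  ord <- order(time, decreasing = TRUE)
  Xs <- X[ord, , drop = FALSE]
  ts <- time[ord]
  es <- event[ord]
  M <- matrix(0, p, p)
  ptr <- 0L
  n <- nrow(Xs)
  dB <- matrix(NA_real_, K, p, dimnames = list(NULL, colnames(X)))
  dOm <- matrix(NA_real_, K, p, dimnames = list(NULL, colnames(X)))
  ok <- logical(K)
  n_risk <- integer(K)
  for (k in rev(seq_len(K))) {      # largest event time first
    t_k <- ev_times[k]
    while (ptr < n && ts[ptr + 1L] >= t_k) {
      ptr <- ptr + 1L
      M <- M + tcrossprod(Xs[ptr, ])
    }
    n_risk[k] <- ptr
    if (rcond(M) < rcond_tol) next  # outside the identifiable range
    rows <- which(ts[seq_len(ptr)] == t_k & es[seq_len(ptr)] == 1)
    Minv <- solve(M)
    s <- colSums(Xs[rows, , drop = FALSE])
    dB[k, ] <- Minv %*% s
    # optional variation: Minv (sum_i x_i x_i') Minv over the tied events
    Xe <- Xs[rows, , drop = FALSE]
    A <- Minv %*% crossprod(Xe) %*% Minv
    dOm[k, ] <- diag(A)
    ok[k] <- TRUE
  }
  n_dropped <- sum(!ok)
  # Identifiable range: once the Gram matrix is full rank going backwards in
  # the traversal (forwards in time it stays full rank until the risk set
  # thins out), retained event times form a prefix of the timeline.
  keep <- which(ok)
  if (!length(keep)) stop("singular at-risk design at the first event")
  times <- ev_times[keep]
  dB <- dB[keep, , drop = FALSE]
  dOm <- dOm[keep, , drop = FALSE]
  structure(list(times = times,
                 dB = dB,
                 B = apply(dB, 2, cumsum),
                 dOmega_diag = dOm,
                 Omega_diag = apply(dOm, 2, cumsum),
                 n_risk = n_risk[keep],
                 covariates = colnames(X),
                 n_dropped_events = n_dropped,
                 identifiable_end = max(times)),
            class = "aalen_fit")
}

#' @export
print.aalen_fit <- function(x, ...) {
  cat(sprintf("aalen_fit: %d covariates, %d event times (identifiable to t = %.3g, %d dropped)\n",
              length(x$covariates), length(x$times), x$identifiable_end,
              x$n_dropped_events))
  invisible(x)
}

#' Test a covariate's cumulative effect in an Aalen fit
#'
#' Aggregated statistic `U = sum_t K(t) dB_j(t)` with variance
#' `sum_t K(t)^2 dOmega_jj(t)`; standard-normal reference, two-sided p.
#' The default weight is constant over the identifiable range; number-at-risk
#' weighting can be supplied through `weights`.
#'
#' @param fit an `aalen_fit`.
#' @param covariate column name or index.
#' @param weights `"n_risk"` (the default: weight each increment by the
#'   number at risk, Aalen's classical choice, so the late, poorly estimated
#'   increments do not dominate the variance), `"constant"` (unweighted
#'   aggregation), or a numeric weight per retained event time.
#' @return list with `U`, `var`, `z`, `p`, `direction` (sign of `z`).
#' @export
aalen_test <- function(fit, covariate, weights = "n_risk") {
  stopifnot(inherits(fit, "aalen_fit"))
  if (length(fit$times) < 2) stop("fit must cover at least 2 event times")
  j <- if (is.character(covariate)) match(covariate, fit$covariates) else covariate
  if (is.na(j) || j < 1 || j > length(fit$covariates)) stop("unknown covariate")
  w <- if (is.character(weights)) {
    switch(match.arg(weights, c("n_risk", "constant")),
           n_risk = fit$n_risk,
           constant = rep(1, length(fit$times)))
  } else weights
  stopifnot(length(w) == length(fit$times))
  U <- sum(w * fit$dB[, j])
  v <- sum(w^2 * fit$dOmega_diag[, j])
  if (v <= 0) stop("zero variance for covariate ", fit$covariates[j])
  z <- U / sqrt(v)
  list(U = U, var = v, z = z, p = 2 * stats::pnorm(-abs(z)),
       direction = sign(z))
}

#' Test every non-intercept covariate of an Aalen fit
#'
#' @param fit an `aalen_fit`.
#' @return data.frame with one row per covariate: `covariate`, `U`, `z`,
#'   `p`, `direction`.
#' @export
aalen_test_all <- function(fit) {
  covs <- setdiff(fit$covariates, fit$covariates[1])
  res <- lapply(covs, function(cv) {
    t <- aalen_test(fit, cv)
    data.frame(covariate = cv, U = t$U, z = t$z, p = t$p,
               direction = t$direction, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cox proportional-hazards fit (Breslow ties)
#'
#' Wald tests from the inverse observed information; non-convergence and
#' monotone likelihood (infinite coefficients) are flagged, not silently
#' reported.
#'
#' @param design numeric matrix (samples x covariates), no intercept column
#'   (the baseline hazard absorbs it); constant columns are an error.
#' @param time positive follow-up times.
#' @param event 0/1 indicators, at least one event.
#' @param iter_max Newton-Raphson iteration cap.
#' @return list of class `cox_fit`: `beta`, `se`, `wald_p`, `converged`,
#'   `n_events`.
#' @export
fit_coxph <- function(design, time, event, iter_max = 50) {
  X <- as.matrix(design)
  if (sum(event) < 1) stop("no events: cannot fit a Cox model")
  sds <- apply(X, 2, stats::sd)
  if (any(sds < 1e-12)) stop("constant covariate in Cox design")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ X, ties = "breslow",
                    control = survival::coxph.control(iter.max = iter_max,
                                                      eps = 1e-9)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(beta = NULL, se = NULL, wald_p = NULL,
                          converged = FALSE, n_events = sum(event)),
                     class = "cox_fit"))
  }
  beta <- unname(stats::coef(fit))
  se <- sqrt(diag(fit$var))
  # monotone likelihood shows up as huge |beta| relative to se
  converged <- all(is.finite(beta)) && all(is.finite(se)) &&
    fit$iter < iter_max && all(abs(beta) < 15)
  structure(list(beta = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 wald_p = stats::setNames(2 * stats::pnorm(-abs(beta / se)),
                                          colnames(X)),
                 converged = converged,
                 n_events = sum(event)),
            class = "cox_fit")
}
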