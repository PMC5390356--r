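#' Kaplan-Meier product-limit estimator
#'
#' Right-censored survival curve: at each distinct event time t with d events
#' out of n at risk, the survival estimate multiplies by (1 - d/n). Subjects
#' censored at t are still at risk at t (events before censorings at tied
#' times).
#'
#' @param times positive follow-up times.
#' @param events event indicators, 1 = event, 0 = censored.
#' @return An object of class `km_curve`: list(event_times, n_at_risk,
#'   n_events, survival, n).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty survival input", call. = FALSE)
  if (length(times) != length(events)) stop("times/events length mismatch", call. = FALSE)
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  et <- sort(unique(times[events == 1]))
  n_at_risk <- vapply(et, function(t) sum(times >= t), numeric(1))
  n_events <- vapply(et, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_events / n_at_risk)
  structure(list(event_times = et, n_at_risk = n_at_risk, n_events = n_events,
                 survival = surv, n = length(times)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Step-function evaluation; S(t) = 1 before the first event time and the
#' last value is carried forward beyond the last event time.
#'
#' @param curve a `km_curve`.
#' @param t times at which to evaluate.
#' @return Survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  idx <- findInterval(t, curve$event_times)
  c(1, curve$survival)[idx + 1]
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n, "subjects,", sum(x$n_events), "events,",
      length(x$event_times), "distinct event times\n")
  if (length(x$event_times) > 0)
    cat(sprintf("S(last event time %g) = %.4f\n",
                max(x$event_times), min(x$survival)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Time", ylab = "Survival probability",
                          ylim = c(0, 1), ...) {
  tt <- c(0, x$event_times)
  ss <- c(1, x$survival)
  graphics::plot(tt, ss, type = "s", xlab = xlab, ylab = ylab, ylim = ylim, ...)
  invisible(x)
}

#' Two-group log-rank (Mantel-Haenszel) test
#'
#' Accumulates observed minus expected events for one group over the pooled
#' distinct event times, with the hypergeometric variance at each time;
#' chi-squared statistic with 1 degree of freedom.
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators.
#' @param groups two-group labels.
#' @return An object of class `logrank_result`: list(observed, expected,
#'   variance, chi2, p_value, df, groups).
#' @export
logrank_test <- function(times, events, groups) {
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  g <- as.factor(groups)
  if (nlevels(g) != 2) stop("logrank_test needs exactly 2 non-empty groups", call. = FALSE)
  if (sum(events) == 0) stop("log-rank statistic undefined with zero events", call. = FALSE)
  in1 <- g == levels(g)[1]
  et <- sort(unique(times[events == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in et) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & in1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  O <- c(O1, sum(events) - O1)
  E <- c(E1, sum(events) - E1)
  chi2 <- if (V > 0) (O1 - E1)^2 / V else 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(observed = stats::setNames(O, levels(g)),
                 expected = stats::setNames(E, levels(g)),
                 variance = V, chi2 = chi2, p_value = p, df = 1L,
                 groups = levels(g)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Log-rank test\n")
  print(data.frame(group = x$groups, observed = x$observed,
                   expected = round(x$expected, 3), row.names = NULL))
  cat(sprintf("chi2 = %.4f on %d df, p = %.4g\n", x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value by the minimum-likelihood rule: the sum of hypergeometric
#' probabilities of every table with the observed margins whose probability
#' does not exceed that of the observed table (within relative tolerance
#' 1e-7).
#'
#' @param tab 2x2 matrix (or something coercible) of non-negative integer
#'   counts with positive margins.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(144, 260, 53, 31), 2))
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero margin", call. = FALSE)
  k <- tab[1, 1]
  K <- sum(tab[1, ])          # white balls: row-1 total
  N <- sum(tab)
  n <- sum(tab[, 1])          # draws: column-1 total
  support <- max(0, n - (N - K)):min(K, n)
  dens <- stats::dhyper(support, K, N - K, n)
  p_obs <- stats::dhyper(k, K, N - K, n)
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

#' Cox proportional-hazards regression (Breslow ties)
#'
#' Newton-Raphson maximization of the Breslow partial likelihood, with
#' step-halving whenever a step decreases the likelihood. Convergence is
#' declared when the largest score component is below `tol`; coefficients
#' drifting past |beta| = 15 flag a monotone-likelihood separation and the
#' fit is marked non-converged. An optional ridge penalty (L2, strength
#' `ridge`) stabilizes fits with many covariates.
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators (>= 1 event).
#' @param covariates numeric matrix, one row per subject; no constant column.
#' @param ridge L2 penalty strength (default 0, unpenalized).
#' @param tol score convergence tolerance (default 1e-8).
#' @param max_iter Newton iteration cap (default 50).
#' @return An object of class `cox_fit`: list(coefficients, se, z, p_value,
#'   loglik, n, n_events, n_iterations, converged, ridge).
#' @export
cox_fit <- function(times, events, covariates, ridge = 0, tol = 1e-8,
                    max_iter = 50) {
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  n <- length(times)
  if (nrow(X) != n || length(events) != n) stop("dimension mismatch", call. = FALSE)
  if (sum(events) < 1) stop("need at least one event", call. = FALSE)
  if (anyNA(X) || any(!is.finite(X))) stop("covariates must be finite", call. = FALSE)
  if (any(apply(X, 2, stats::sd) == 0))
    stop("constant covariate: coefficient not identifiable", call. = FALSE)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  ord <- order(times)
  tt <- times[ord]; ev <- events[ord]; X <- X[ord, , drop = FALSE]
  # risk-set group index: subjects sharing a time share a risk set
  ut <- unique(tt)
  grp <- match(tt, ut)                    # ascending
  n_grp <- length(ut)

  # Breslow partial log-likelihood, score and information at beta. Risk-set
  # sums S0, S1, S2 at each distinct time are reverse cumulative sums of the
  # per-time-group aggregates, so the whole evaluation is vectorized.
  dead <- ev == 1
  d_g <- as.vector(rowsum(as.numeric(dead), grp))          # events per time
  has_d <- d_g > 0
  sumX_dead <- colSums(X[dead, , drop = FALSE])
  pair_idx1 <- rep(seq_len(p), p)
  pair_idx2 <- rep(seq_len(p), each = p)
  Xpairs <- X[, pair_idx1, drop = FALSE] * X[, pair_idx2, drop = FALSE]
  revcumsum <- function(m) {
    m <- as.matrix(m)
    apply(m[n_grp:1, , drop = FALSE], 2, cumsum)[n_grp:1, , drop = FALSE]
  }
  plik <- function(beta) {
    eta <- drop(X %*% beta)
    eta <- eta - mean(eta)  # numerical stabilization; PL is shift-invariant
    w <- exp(eta)
    S0 <- drop(revcumsum(rowsum(w, grp)))                  # n_grp
    S1 <- revcumsum(rowsum(X * w, grp))                    # n_grp x p
    S2 <- revcumsum(rowsum(Xpairs * w, grp))               # n_grp x p^2
    xbar <- S1 / S0
    ll <- sum(eta[dead]) - sum(d_g[has_d] * log(S0[has_d]))
    U <- sumX_dead - colSums(d_g * xbar)
    I <- matrix(colSums(d_g * S2 / S0), p, p) -
      crossprod(xbar, d_g * xbar)
    if (ridge > 0) {
      ll <- ll - ridge / 2 * sum(beta^2)
      U <- U - ridge * beta
      I <- I + diag(ridge, p)
    }
    list(ll = ll, U = U, I = I)
  }

  beta <- numeric(p)
  cur <- plik(beta)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    if (max(abs(cur$U)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(cur$I, cur$U), error = function(e) NULL)
    if (is.null(step)) break
    new_beta <- beta + step
    new <- plik(new_beta)
    halves <- 0
    while (new$ll < cur$ll && halves < 20) {   # step-halving
      step <- step / 2
      new_beta <- beta + step
      new <- plik(new_beta)
      halves <- halves + 1
    }
    beta <- new_beta
    cur <- new
    if (any(abs(beta) > 15)) break  # monotone-likelihood guard
  }
  if (max(abs(cur$U)) < tol && all(abs(beta) <= 15)) converged <- TRUE

  cov_mat <- tryCatch(solve(cur$I), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(cov_mat))
  z <- beta / se
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)), z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 loglik = cur$ll, score = cur$U, information = cur$I,
                 n = n, n_events = sum(events), n_iterations = iter,
                 converged = converged, ridge = ridge),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Breslow ties)",
      if (x$ridge > 0) sprintf("[ridge %.3g]", x$ridge) else "", "\n")
  print(data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                   se = x$se, z = x$z, p = signif(x$p_value, 4),
                   check.names = FALSE))
  cat(sprintf("n = %d, events = %d, log partial likelihood = %.4f, %s in %d iterations\n",
              x$n, x$n_events, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iterations))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' Time-dependent ROC for a survival marker
#'
#' Cumulative-case / dynamic-control ROC at `eval_time` using the
#' Kaplan-Meier estimator: cases are subjects with event time at or before
#' `eval_time`, controls those surviving beyond it. For each marker cutoff c,
#' \deqn{sens(c) = \frac{(1 - S_c(t))\,P(M > c)}{1 - S(t)}, \quad
#'       spec(c) = 1 - \frac{S_c(t)\,P(M > c)}{S(t)}}
#' where S is the overall KM survival at t and S_c the KM survival among
#' subjects with marker above c. The AUC is the trapezoidal area under
#' (1 - specificity, sensitivity).
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators.
#' @param marker numeric risk marker (higher = higher risk).
#' @param eval_time evaluation horizon, in the units of `times`, within the
#'   observed time range.
#' @return An object of class `survival_roc`: list(eval_time, cutoffs,
#'   sensitivity, specificity, auc, surv_at_eval).
#' @export
survival_roc <- function(times, events, marker, eval_time) {
  if (anyNA(marker) || any(!is.finite(marker)))
    stop("marker must be finite", call. = FALSE)
  if (eval_time <= 0 || eval_time > max(times))
    stop("eval_time outside the observed time range", call. = FALSE)
  S_t <- km_survival_at(km_estimate(times, events), eval_time)
  if (!any(events == 1 & times <= eval_time))
    stop("no events before eval_time: ROC degenerate", call. = FALSE)
  if (S_t <= 0 || S_t >= 1)
    stop("degenerate survival at eval_time", call. = FALSE)

  cutoffs <- sort(unique(marker))
  sens <- numeric(length(cutoffs))
  spec <- numeric(length(cutoffs))
  for (i in seq_along(cutoffs)) {
    above <- marker > cutoffs[i]
    p_above <- mean(above)
    if (!any(above)) { sens[i] <- 0; spec[i] <- 1; next }
    S_c <- km_survival_at(km_estimate(times[above], events[above]), eval_time)
    sens[i] <- (1 - S_c) * p_above / (1 - S_t)
    spec[i] <- 1 - S_c * p_above / S_t
  }
  sens <- pmin(pmax(sens, 0), 1)
  spec <- pmin(pmax(spec, 0), 1)
  fpr <- c(1, 1 - spec, 0)
  tpr <- c(1, sens, 0)
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (tpr[ord][-1] + tpr[ord][-length(tpr)]) / 2)
  structure(list(eval_time = eval_time, cutoffs = cutoffs,
                 sensitivity = sens, specificity = spec, auc = auc,
                 surv_at_eval = S_t),
            class = "survival_roc")
}

#' @export
print.survival_roc <- function(x, ...) {
  cat(sprintf("Time-dependent ROC at t = %g: AUC = %.4f (KM cumulative/dynamic)\n",
              x$eval_time, x$auc))
  invisible(x)
}

#' @export
plot.survival_roc <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "l",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = sprintf("AUC = %.3f at t = %g", x$auc, x$eval_time), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}
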