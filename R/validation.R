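#' Validate a key gene set on an independent cohort
#'
#' Fits a multivariable Cox model on the standardized expression of the key
#' genes in an external cohort, splits the samples at the median Cox risk
#' score (linear predictor), compares the two risk groups with Kaplan-Meier /
#' log-rank, and computes the time-dependent ROC of the risk score at
#' `eval_time`. Key genes missing from the validation matrix are dropped
#' (count reported); at least half must be present, and at least 2 overall.
#' When the gene set is large relative to the cohort (more than
#' n_samples / 10 genes), a ridge penalty (L2, strength 0.1) stabilizes the
#' Cox fit and is flagged. A non-converged Cox fit is reported with a
#' warning; the downstream split and ROC still run on its score.
#'
#' @param expr validation genes x samples matrix (gene-symbol keyed).
#' @param clinical clinical table covering every sample.
#' @param key_genes character vector of key prognostic gene ids.
#' @param eval_time ROC evaluation horizon, in the units of `os_time`.
#' @param ridge ridge strength used when the high-dimensional guard fires
#'   (default 0.1).
#' @return An object of class `external_validation`: list(cox, risk_score,
#'   partition ("high"/"low"), logrank, curves, roc, genes_used, n_missing,
#'   ridged).
#' @export
validate_external <- function(expr, clinical, key_genes, eval_time,
                              ridge = 0.1) {
  check_expression_matrix(expr)
  clinical <- align_clinical(expr, clinical)
  present <- intersect(key_genes, rownames(expr))
  n_missing <- length(key_genes) - length(present)
  if (n_missing > 0)
    message("[validate] ", n_missing, " key gene(s) absent from the validation matrix")
  if (length(present) < 2)
    stop("fewer than 2 key genes present in the validation matrix", call. = FALSE)
  if (length(present) < length(key_genes) / 2)
    stop("fewer than 50% of key genes present in the validation matrix", call. = FALSE)

  X <- t(expr[present, , drop = FALSE])
  X <- scale(X)           # per-gene standardization: affine-invariant score
  ridged <- length(present) > nrow(X) / 10
  pen <- if (ridged) ridge else 0
  if (ridged)
    message("[validate] high-dimensional guard: ridge penalty ", pen, " applied")
  fit <- cox_fit(clinical$os_time, clinical$os_event, X, ridge = pen)
  if (!fit$converged)
    warning("Cox fit did not converge; downstream results use the unconverged score",
            call. = FALSE)
  score <- drop(X %*% fit$coefficients)
  grp <- ifelse(score > stats::median(score), "high", "low")
  lr <- logrank_test(clinical$os_time, clinical$os_event, grp)
  curves <- lapply(split(seq_along(grp), grp), function(idx)
    km_estimate(clinical$os_time[idx], clinical$os_event[idx]))
  roc <- survival_roc(clinical$os_time, clinical$os_event, score, eval_time)
  structure(list(cox = fit, risk_score = stats::setNames(score, colnames(expr)),
                 partition = stats::setNames(grp, colnames(expr)),
                 logrank = lr, curves = curves, roc = roc,
                 genes_used = present, n_missing = n_missing, ridged = ridged),
            class = "external_validation")
}

#' @export
print.external_validation <- function(x, ...) {
  cat("External validation of", length(x$genes_used), "key genes",
      if (x$n_missing > 0) sprintf("(%d missing)", x$n_missing) else "", "\n")
  cat(sprintf("Cox fit: %s; median risk-score split log-rank p = %.4g; AUC(t = %g) = %.4f\n",
              if (x$cox$converged) "converged" else "NOT converged",
              x$logrank$p_value, x$roc$eval_time, x$roc$auc))
  invisible(x)
}
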