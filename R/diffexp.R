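#' Per-gene two-group summary statistics
#'
#' For each gene: log2 fold change (mean of group 2 minus mean of group 1 on
#' log2 data) and the pooled within-group variance with n1 + n2 - 2 residual
#' degrees of freedom. Group order follows `sort(unique(labels))`.
#'
#' @param expr genes x samples matrix.
#' @param labels two-group labels over the columns (vector, named or
#'   positional).
#' @return data.frame(gene_id, log2fc, s2) with attributes `df_residual`,
#'   `n1`, `n2`.
#' @export
fit_group_stats <- function(expr, labels) {
  check_expression_matrix(expr)
  labels <- align_labels(expr, labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("labels must define exactly 2 groups", call. = FALSE)
  g1 <- labels == lev[1]
  g2 <- labels == lev[2]
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2)
    stop("each group needs >= 2 samples for a residual variance", call. = FALSE)
  m1 <- rowMeans(expr[, g1, drop = FALSE])
  m2 <- rowMeans(expr[, g2, drop = FALSE])
  ss1 <- rowSums((expr[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((expr[, g2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  structure(data.frame(gene_id = rownames(expr), log2fc = m2 - m1,
                       s2 = (ss1 + ss2) / df, stringsAsFactors = FALSE,
                       row.names = NULL),
            df_residual = df, n1 = n1, n2 = n2)
}

align_labels <- function(expr, labels) {
  if (!is.null(names(labels))) {
    idx <- match(colnames(expr), names(labels))
    if (anyNA(idx)) stop("labels do not cover all samples", call. = FALSE)
    labels <- labels[idx]
  } else if (length(labels) != ncol(expr)) {
    stop("labels length must match the number of samples", call. = FALSE)
  }
  labels
}

#' Empirical-Bayes shrinkage of gene-wise variances
#'
#' Fits a scaled inverse-chi-squared prior to the observed residual variances
#' by matching moments of the log variances: with
#' \eqn{e_g = \log s_g^2 - \psi(df/2) + \log(df/2)}, the prior degrees of
#' freedom d0 solve \eqn{\psi'(d_0/2) = \mathrm{var}(e_g) - \psi'(df/2)} and
#' the prior variance is \eqn{s_0^2 = \exp(\bar e + \psi(d_0/2) -
#' \log(d_0/2))}. Posterior variances are the precision-weighted blend
#' \eqn{s^2_{post} = (d_0 s_0^2 + df\, s_g^2) / (d_0 + df)}.
#'
#' Zero variances are floored at the smallest positive variance times 1e-8
#' before taking logs.
#'
#' When the moment
#' equation has no positive solution the prior degrees of freedom are
#' infinite and every posterior variance equals the mean observed variance.
#'
#' @param s2 per-gene residual variances (>= 10 positive values).
#' @param df residual degrees of freedom shared by all genes.
#' @return list(d0, s0_sq, s2_post).
#' @export
squeeze_variances <- function(s2, df) {
  if (sum(s2 > 0) < 10)
    stop("need >= 10 genes with positive variance", call. = FALSE)
  s2f <- s2
  floor_val <- min(s2[s2 > 0]) * 1e-8
  s2f[s2f <= 0] <- floor_val
  G <- length(s2f)
  e <- log(s2f) - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  target <- mean((e - ebar)^2) * G / (G - 1) - trigamma(df / 2)
  if (!is.finite(target) || target <= 0) {
    # zero/negative excess dispersion of the log variances: all genes share
    # one variance, estimated by the arithmetic mean (all-equal case gives
    # back the common value exactly)
    s0_sq <- mean(s2f)
    return(list(d0 = Inf, s0_sq = s0_sq, s2_post = rep(s0_sq, G)))
  }
  d0 <- 2 * trigamma_inverse(target)
  s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq,
       s2_post = (d0 * s0_sq + df * s2) / (d0 + df))
}

# Solve trigamma(y) = x by Newton iteration on 1/y (the scale on which
# trigamma is nearly linear); x > 0.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Moderated t-test for a two-group contrast
#'
#' Combines [fit_group_stats()] and [squeeze_variances()]:
#' \eqn{t = log2fc / \sqrt{s^2_{post}(1/n_1 + 1/n_2)}}, two-sided p-value from
#' Student's t with d0 + df degrees of freedom (standard normal when d0 is
#' infinite).
#'
#' @param expr genes x samples matrix.
#' @param labels two-group labels over the columns.
#' @return An object of class `diffexp_result`: a data.frame with columns
#'   gene_id, log2fc, s2, s2_post, t_mod, p_value and attributes `d0`,
#'   `s0_sq`, `df_residual`, `n1`, `n2`.
#' @export
moderated_t_test <- function(expr, labels) {
  st <- fit_group_stats(expr, labels)
  df <- attr(st, "df_residual"); n1 <- attr(st, "n1"); n2 <- attr(st, "n2")
  if (sum(st$s2 > 0) >= 10) {
    pr <- squeeze_variances(st$s2, df)
  } else {
    # too few genes to estimate the variance prior: ordinary pooled t
    pr <- list(d0 = 0, s0_sq = NA_real_, s2_post = st$s2)
  }
  se <- sqrt(pr$s2_post * (1 / n1 + 1 / n2))
  t_mod <- st$log2fc / se
  df_total <- pr$d0 + df
  p <- if (is.finite(df_total)) 2 * stats::pt(-abs(t_mod), df = df_total) else
    2 * stats::pnorm(-abs(t_mod))
  p[st$log2fc == 0] <- 1
  out <- data.frame(gene_id = st$gene_id, log2fc = st$log2fc, s2 = st$s2,
                    s2_post = pr$s2_post, t_mod = t_mod, p_value = p,
                    stringsAsFactors = FALSE)
  structure(out, d0 = pr$d0, s0_sq = pr$s0_sq, df_residual = df,
            n1 = n1, n2 = n2, class = c("diffexp_result", "data.frame"))
}

#' @export
print.diffexp_result <- function(x, ...) {
  cat("Moderated t-test:", nrow(x), "genes;",
      "prior df =", format(attr(x, "d0"), digits = 4),
      "; prior variance =", format(attr(x, "s0_sq"), digits = 4), "\n")
  cat("Genes with p < 0.001:", sum(x$p_value < 0.001), "\n")
  NextMethod()
}

#' Select feature genes from a differential-expression result
#'
#' Genes with p-value strictly below `p_cut` and |log2FC| strictly above
#' `fc_cut`, in ascending p-value order.
#'
#' @param result a `diffexp_result`.
#' @param p_cut p-value threshold (default 0.001).
#' @param fc_cut absolute log2 fold-change threshold (default 0).
#' @return Character vector of gene ids.
#' @export
select_feature_genes <- function(result, p_cut = 0.001, fc_cut = 0) {
  keep <- result$p_value < p_cut & abs(result$log2fc) > fc_cut
  result$gene_id[keep][order(result$p_value[keep])]
}

#' Write per-gene differential results as TSV
#'
#' @param result a `diffexp_result`.
#' @param path output file.
#' @export
write_diffexp_tsv <- function(result, path) {
  utils::write.table(result[, c("gene_id", "log2fc", "t_mod", "p_value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
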