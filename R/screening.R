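#' Prognostic seed-gene screening by mean-split survival tests
#'
#' For each candidate gene, samples are split into high/low groups at the
#' gene's across-sample mean expression and the two groups compared with a
#' log-rank test; genes with p strictly below `p_cut` are retained. Genes
#' whose split leaves one side empty (e.g. constant genes) are skipped and
#' counted.
#'
#' @param expr genes x samples matrix.
#' @param clinical clinical table covering every sample.
#' @param genes candidate gene ids (default: all rows of `expr`).
#' @param p_cut log-rank p threshold (default 0.01).
#' @return An object of class `seed_screen`: list(seed_genes, p_values
#'   (named, all tested genes), skipped, p_cut). An empty result is a
#'   warning, not an error.
#' @export
seed_gene_screen <- function(expr, clinical, genes = rownames(expr),
                             p_cut = 0.01) {
  check_expression_matrix(expr)
  clinical <- align_clinical(expr, clinical)
  genes <- intersect(genes, rownames(expr))
  if (length(genes) == 0) stop("no candidate genes present", call. = FALSE)
  p <- stats::setNames(rep(NA_real_, length(genes)), genes)
  skipped <- character(0)
  for (g in genes) {
    x <- expr[g, ]
    hi <- x > mean(x)
    if (!any(hi) || all(hi)) { skipped <- c(skipped, g); next }
    p[g] <- logrank_test(clinical$os_time, clinical$os_event,
                         ifelse(hi, "high", "low"))$p_value
  }
  seed <- names(p)[!is.na(p) & p < p_cut]
  seed <- seed[order(p[seed])]
  if (length(seed) == 0)
    warning("no gene passed the seed screen at p < ", p_cut, call. = FALSE)
  structure(list(seed_genes = seed, p_values = p, skipped = skipped,
                 p_cut = p_cut),
            class = "seed_screen")
}

#' @export
print.seed_screen <- function(x, ...) {
  cat("Seed-gene screen (mean-split log-rank, p <", x$p_cut, "):",
      length(x$seed_genes), "of", length(x$p_values), "genes retained")
  if (length(x$skipped)) cat(";", length(x$skipped), "degenerate splits skipped")
  cat("\n")
  invisible(x)
}

#' Euclidean-distance hierarchical clustering of samples
#'
#' Hierarchical agglomerative clustering on Euclidean distance between sample
#' expression profiles, Ward linkage (`ward.D2`), cut into k groups.
#'
#' @param expr genes x samples matrix (the gene subset to cluster on).
#' @param k number of groups (default 2).
#' @param linkage hclust linkage method (default "ward.D2").
#' @return Integer cluster labels named by sample.
#' @export
euclidean_cluster <- function(expr, k = 2, linkage = "ward.D2") {
  check_expression_matrix(expr)
  if (k > ncol(expr)) stop("k exceeds the number of samples", call. = FALSE)
  d <- stats::dist(t(expr), method = "euclidean")
  stats::cutree(stats::hclust(d, method = linkage), k = k)
}

#' Fold-change threshold scan over the prognostic seed genes
#'
#' Implements key-gene selection: the samples are first reclassified by
#' Euclidean clustering on the seed genes; differential expression of each
#' seed gene is computed on that partition (moderated t). Then for every
#' |log2FC| threshold on a grid, the gene set {p < `p_de`, |log2FC| > t} is
#' formed; when it has at least 2 genes the samples are re-clustered on it
#' and the two-group log-rank p recorded (empty or singleton sets score
#' p = 1). The chosen threshold minimizes the log-rank p, ties going to the
#' smallest threshold (largest gene set).
#'
#' @param expr genes x samples matrix containing the seed genes.
#' @param clinical clinical table covering every sample.
#' @param seed_genes character vector of prognostic seed gene ids.
#' @param grid |log2FC| thresholds to scan (default seq(0.1, 1.5, 0.05)).
#' @param p_de differential-expression p threshold (default 0.001).
#' @return An object of class `threshold_scan`: list(scan — data.frame
#'   (threshold, n_genes, logrank_p), chosen_threshold, chosen_genes,
#'   seed_partition, seed_diffexp).
#' @export
fc_threshold_scan <- function(expr, clinical, seed_genes,
                              grid = seq(0.1, 1.5, by = 0.05),
                              p_de = 0.001) {
  check_expression_matrix(expr)
  clinical <- align_clinical(expr, clinical)
  seed_genes <- intersect(seed_genes, rownames(expr))
  if (length(seed_genes) < 2) stop("need >= 2 seed genes", call. = FALSE)
  seed_expr <- expr[seed_genes, , drop = FALSE]
  part <- euclidean_cluster(seed_expr, k = 2)
  de <- moderated_t_test(seed_expr, part)

  grid <- sort(grid)
  n_genes <- integer(length(grid))
  logrank_p <- rep(1, length(grid))
  gene_sets <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    gs <- de$gene_id[de$p_value < p_de & abs(de$log2fc) > grid[i]]
    n_genes[i] <- length(gs)
    gene_sets[[i]] <- gs
    if (length(gs) >= 2) {
      lab <- euclidean_cluster(expr[gs, , drop = FALSE], k = 2)
      if (length(unique(lab)) == 2)
        logrank_p[i] <- logrank_test(clinical$os_time, clinical$os_event,
                                     lab)$p_value
    }
  }
  if (all(n_genes < 2))
    stop("no threshold on the grid yields >= 2 genes", call. = FALSE)
  best <- which(logrank_p == min(logrank_p))[1]  # grid sorted: smallest t wins ties
  structure(list(scan = data.frame(threshold = grid, n_genes = n_genes,
                                   logrank_p = logrank_p),
                 chosen_threshold = grid[best],
                 chosen_genes = gene_sets[[best]],
                 seed_partition = part, seed_diffexp = de),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("|log2FC| threshold scan over %d thresholds [%.2f, %.2f]\n",
              nrow(x$scan), min(x$scan$threshold), max(x$scan$threshold)))
  best <- x$scan[x$scan$threshold == x$chosen_threshold, ]
  cat(sprintf("Optimum: |log2FC| > %.2f -> %d key genes, log-rank p = %.4g\n",
              x$chosen_threshold, best$n_genes, best$logrank_p))
  invisible(x)
}

#' @export
plot.threshold_scan <- function(x, ...) {
  graphics::plot(x$scan$threshold, -log10(x$scan$logrank_p), type = "b",
                 xlab = "|log2FC| threshold", ylab = "-log10 log-rank p", ...)
  graphics::abline(v = x$chosen_threshold, lty = 2)
  invisible(x)
}

#' Multivariate survival split on a key gene set
#'
#' Clusters the samples (Euclidean, Ward, k = 2) on the key genes, estimates
#' a Kaplan-Meier curve per group and tests the survival difference with the
#' log-rank test. Heavily unbalanced splits (a singleton group) are allowed
#' but flagged.
#'
#' @param expr genes x samples matrix containing the key genes.
#' @param key_genes character vector (>= 2 present in `expr`).
#' @param clinical clinical table covering every sample.
#' @return An object of class `group_survival`: list(partition, logrank,
#'   curves (per-group `km_curve`), unbalanced).
#' @export
multivariate_group_survival <- function(expr, key_genes, clinical) {
  check_expression_matrix(expr)
  clinical <- align_clinical(expr, clinical)
  key_genes <- intersect(key_genes, rownames(expr))
  if (length(key_genes) < 2) stop("need >= 2 key genes", call. = FALSE)
  part <- euclidean_cluster(expr[key_genes, , drop = FALSE], k = 2)
  sizes <- table(part)
  unbalanced <- min(sizes) <= 1
  if (unbalanced)
    message("[multivariate] unbalanced split: group sizes ",
            paste(sizes, collapse = "/"))
  lr <- logrank_test(clinical$os_time, clinical$os_event, part)
  curves <- lapply(split(seq_along(part), part), function(idx)
    km_estimate(clinical$os_time[idx], clinical$os_event[idx]))
  structure(list(partition = part, logrank = lr, curves = curves,
                 unbalanced = unbalanced),
            class = "group_survival")
}

#' @export
print.group_survival <- function(x, ...) {
  cat("Key-gene group survival: group sizes",
      paste(table(x$partition), collapse = " / "), "\n")
  cat(sprintf("Log-rank chi2 = %.4f, p = %.4g\n",
              x$logrank$chi2, x$logrank$p_value))
  invisible(x)
}

#' @export
plot.group_survival <- function(x, ...) {
  cols <- c("#1b6ca8", "#c0392b")
  first <- TRUE
  for (i in seq_along(x$curves)) {
    cv <- x$curves[[i]]
    tt <- c(0, cv$event_times); ss <- c(1, cv$survival)
    if (first) {
      graphics::plot(tt, ss, type = "s", col = cols[i], ylim = c(0, 1),
                     xlab = "Time", ylab = "Survival probability", ...)
      first <- FALSE
    } else graphics::lines(tt, ss, type = "s", col = cols[i])
  }
  graphics::legend("topright", legend = names(x$curves), col = cols,
                   lty = 1, bty = "n",
                   title = sprintf("log-rank p = %.3g", x$logrank$p_value))
  invisible(x)
}
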