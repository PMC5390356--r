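#' Collapse a probe-level matrix to gene symbols
#'
#' Probes mapping to the same gene symbol are averaged (arithmetic mean per
#' sample); probes absent from the map are dropped.
#'
#' @param probe_expr numeric probes x samples matrix, probe ids as row names.
#' @param probe_map data.frame with columns `probe_id`, `gene_symbol`
#'   (many probes per symbol allowed).
#' @return A genes x samples matrix, one row per mapped symbol.
#' @export
collapse_probes <- function(probe_expr, probe_map) {
  check_expression_matrix(probe_expr, "probe_expr")
  if (!all(c("probe_id", "gene_symbol") %in% names(probe_map)))
    stop("probe_map needs columns probe_id, gene_symbol", call. = FALSE)
  keep <- probe_map$probe_id %in% rownames(probe_expr)
  probe_map <- probe_map[keep, , drop = FALSE]
  if (nrow(probe_map) == 0)
    stop("no probe in the map matches the matrix", call. = FALSE)
  m <- probe_expr[probe_map$probe_id, , drop = FALSE]
  sym <- factor(probe_map$gene_symbol, levels = unique(probe_map$gene_symbol))
  out <- rowsum(m, group = sym, reorder = FALSE) / as.vector(table(sym))
  rownames(out) <- levels(sym)
  out
}

#' Remove low-variance and low-median genes
#'
#' Two sequential quantile filters: first genes whose across-sample variance
#' falls strictly below the `var_q` empirical quantile of all per-gene
#' variances are removed, then genes whose median falls strictly below the
#' `med_q` quantile of the remaining per-gene medians. Quantiles use the
#' linear-interpolation convention (type 7); strict `<` comparison means ties
#' at the threshold survive. With `mode = "joint"` both quantiles are computed
#' on the original matrix and the filters applied simultaneously.
#'
#' @param expr genes x samples matrix (>= 2 samples).
#' @param var_q,med_q quantile cutoffs in \[0, 1\] (default 0.2: drop the
#'   bottom fifth).
#' @param mode `"sequential"` (default) or `"joint"`.
#' @return The filtered matrix, genes in original order.
#' @export
filter_low_information <- function(expr, var_q = 0.2, med_q = 0.2,
                                   mode = c("sequential", "joint")) {
  check_expression_matrix(expr)
  mode <- match.arg(mode)
  if (ncol(expr) < 2) stop("need >= 2 samples to compute variances", call. = FALSE)
  v <- apply(expr, 1, stats::var)
  m <- apply(expr, 1, stats::median)
  if (mode == "joint") {
    keep <- v >= stats::quantile(v, var_q) & m >= stats::quantile(m, med_q)
    return(expr[keep, , drop = FALSE])
  }
  keep1 <- v >= stats::quantile(v, var_q)
  expr <- expr[keep1, , drop = FALSE]
  m <- m[keep1]
  keep2 <- m >= stats::quantile(m, med_q)
  expr[keep2, , drop = FALSE]
}

#' Center each gene across samples
#'
#' Subtracts the per-gene median (default) or mean, so every gene row is
#' centered at zero before clustering.
#'
#' @param expr genes x samples matrix.
#' @param method `"median"` (default) or `"mean"`.
#' @return The centered matrix.
#' @export
center_genes <- function(expr, method = c("median", "mean")) {
  check_expression_matrix(expr)
  method <- match.arg(method)
  ctr <- if (method == "median") apply(expr, 1, stats::median) else rowMeans(expr)
  expr - ctr
}

#' Standard preprocessing chain
#'
#' Optional probe collapsing, low-information filtering (statistics computed
#' on the uncentered matrix), then per-gene centering.
#'
#' @inheritParams filter_low_information
#' @inheritParams center_genes
#' @param probe_map optional probe map; when given, `expr` is treated as
#'   probe-level and collapsed first.
#' @return list(expr = centered filtered matrix, n_input, n_filtered).
#' @export
preprocess_expression <- function(expr, probe_map = NULL, var_q = 0.2,
                                  med_q = 0.2, mode = "sequential",
                                  method = "median") {
  if (!is.null(probe_map)) expr <- collapse_probes(expr, probe_map)
  n_input <- nrow(expr)
  expr <- filter_low_information(expr, var_q, med_q, mode)
  list(expr = center_genes(expr, method), n_input = n_input,
       n_filtered = nrow(expr))
}

#' Read a probe map from two-column TSV
#'
#' @param path TSV with columns probe_id, gene_symbol (header optional if the
#'   columns are named).
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% names(df))) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df)[1:2] <- c("probe_id", "gene_symbol")
  }
  df[, c("probe_id", "gene_symbol")]
}
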