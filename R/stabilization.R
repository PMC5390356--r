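#' Are two partitions the same up to label permutation?
#'
#' True iff the two labelings induce the same equivalence classes over the
#' same sample universe.
#'
#' @param a,b label vectors named by sample (or positional over the same
#'   samples).
#' @return TRUE/FALSE.
#' @export
partitions_equal <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("partitions cover different sample sets", call. = FALSE)
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("partitions cover different sample sets", call. = FALSE)
  }
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

#' Iterate consensus clustering and differential testing to a fixed point
#'
#' The stabilization loop: iteration 1 consensus-clusters the samples on all
#' genes and derives feature genes (moderated t, p < `p_cut`); every later
#' iteration clusters on the previous iteration's feature genes only,
#' re-derives feature genes (the variance prior is re-estimated on the current
#' gene subset), and stops as soon as the sample partition matches the
#' previous one (up to relabeling), the feature-gene set repeats exactly, or
#' the iteration cap is hit.
#'
#' @param expr preprocessed (filtered, centered) genes x samples matrix.
#' @param k number of sample groups (default 2).
#' @param n_resamples consensus resamples per iteration (default 1000).
#' @param sample_frac consensus subsampling fraction (default 0.8).
#' @param p_cut feature-gene p threshold (default 0.001).
#' @param fc_cut feature-gene |log2FC| threshold (default 0).
#' @param max_iter iteration cap (default 20).
#' @param min_genes smallest usable feature set; below it the loop aborts
#'   (default 10, the minimum for estimating the variance prior).
#' @param seed integer seed; per-iteration child seeds are derived from it.
#' @param verbose log one line per iteration to stderr.
#' @return An object of class `stabilization_result`: list(history, converged,
#'   reason, stable_genes, final_labels, n_iterations). `reason` is one of
#'   "labels_consistent", "genes_consistent", "iteration_cap".
#' @export
iterate_to_stability <- function(expr, k = 2, n_resamples = 1000,
                                 sample_frac = 0.8, p_cut = 0.001,
                                 fc_cut = 0, max_iter = 20, min_genes = 10,
                                 seed = NULL, verbose = FALSE) {
  check_expression_matrix(expr)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  history <- list()
  genes_prev <- rownames(expr)
  labels_prev <- NULL
  converged <- FALSE
  reason <- "iteration_cap"

  for (it in seq_len(max_iter)) {
    cc <- consensus_cluster(expr[genes_prev, , drop = FALSE], k = k,
                            n_resamples = n_resamples,
                            sample_frac = sample_frac,
                            seed = stage_seed(seed, paste0("stabilize_iter_", it)))
    de <- moderated_t_test(expr[genes_prev, , drop = FALSE], cc$labels)
    genes_new <- select_feature_genes(de, p_cut = p_cut, fc_cut = fc_cut)
    history[[it]] <- list(labels = cc$labels, feature_genes = genes_new,
                          n_input_genes = length(genes_prev),
                          n_feature_genes = length(genes_new))
    if (verbose)
      message(sprintf("[stabilize] iter %d: %d -> %d feature genes", it,
                      length(genes_prev), length(genes_new)))
    if (length(genes_new) < min_genes)
      stop("feature-gene set became empty/degenerate at iteration ", it,
           call. = FALSE)
    if (!is.null(labels_prev) && partitions_equal(labels_prev, cc$labels)) {
      converged <- TRUE; reason <- "labels_consistent"
    } else if (setequal(genes_prev, genes_new) && it > 1) {
      converged <- TRUE; reason <- "genes_consistent"
    }
    labels_prev <- cc$labels
    genes_prev <- genes_new
    if (converged) break
  }
  structure(list(history = history, converged = converged, reason = reason,
                 stable_genes = genes_prev, final_labels = labels_prev,
                 n_iterations = length(history)),
            class = "stabilization_result")
}

#' @export
print.stabilization_result <- function(x, ...) {
  cat("Stabilization loop:", x$n_iterations, "iterations;",
      if (x$converged) paste0("converged (", x$reason, ")") else
        "NOT converged (iteration cap)", "\n")
  counts <- vapply(x$history, function(h) h$n_feature_genes, integer(1))
  cat("Feature-gene counts:", paste(counts, collapse = " -> "), "\n")
  cat("Stable genes:", length(x$stable_genes),
      "| final group sizes:", paste(table(x$final_labels), collapse = " / "), "\n")
  invisible(x)
}
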