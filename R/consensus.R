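#' Base clusterer for one resample
#'
#' Hierarchical agglomerative clustering of samples (columns) with distance
#' 1 - Pearson correlation of expression profiles, average linkage, tree cut
#' into k groups.
#'
#' @param expr genes x samples matrix.
#' @param k number of groups (<= number of samples).
#' @return Integer cluster labels named by sample.
#' @export
inner_cluster <- function(expr, k) {
  check_expression_matrix(expr)
  n <- ncol(expr)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  if (k == n) {
    labels <- seq_len(n)
    names(labels) <- colnames(expr)
    return(labels)
  }
  cc <- suppressWarnings(stats::cor(expr))
  cc[is.na(cc)] <- 0  # zero-variance profiles: treat as uncorrelated
  d <- stats::as.dist(1 - cc)
  stats::cutree(stats::hclust(d, method = "average"), k = k)
}

#' Consensus clustering by subsampling
#'
#' Resampling-based consensus clustering of samples into k groups. Each
#' resample draws `ceiling(sample_frac * n)` samples without replacement,
#' clusters them with [inner_cluster()], and tallies co-clustering; the
#' consensus matrix is the elementwise ratio of co-cluster to co-sample
#' counts. Final labels come from average-linkage hierarchical clustering of
#' the distance 1 - consensus, cut at k.
#'
#' @param expr genes x samples matrix.
#' @param k number of groups (default 2).
#' @param n_resamples number of subsampling iterations (default 1000).
#' @param sample_frac fraction of samples drawn per iteration (default 0.8).
#' @param seed integer seed; the run is fully reproducible from it.
#' @return An object of class `consensus_result`: list(consensus,
#'   cosample_counts, cocluster_counts, labels, k, n_resamples,
#'   never_cosampled).
#' @export
consensus_cluster <- function(expr, k = 2, n_resamples = 1000,
                              sample_frac = 0.8, seed = NULL) {
  check_expression_matrix(expr)
  n <- ncol(expr)
  if (n < max(k + 1, 4)) stop("too few samples for consensus clustering", call. = FALSE)
  if (sample_frac <= 0 || sample_frac > 1) stop("sample_frac must be in (0, 1]", call. = FALSE)
  if (n_resamples < 1) stop("n_resamples must be >= 1", call. = FALSE)

  m <- ceiling(sample_frac * n)
  cosample <- matrix(0L, n, n, dimnames = list(colnames(expr), colnames(expr)))
  cocluster <- cosample
  with_seed(seed, {
    for (r in seq_len(n_resamples)) {
      idx <- if (m == n) seq_len(n) else sort(sample.int(n, m))
      cosample[idx, idx] <- cosample[idx, idx] + 1L
      lab <- inner_cluster(expr[, idx, drop = FALSE], k = min(k, m))
      for (g in unique(lab)) {
        gi <- idx[lab == g]
        cocluster[gi, gi] <- cocluster[gi, gi] + 1L
      }
    }
  })
  consensus <- matrix(0, n, n, dimnames = dimnames(cosample))
  pos <- cosample > 0
  consensus[pos] <- cocluster[pos] / cosample[pos]
  diag(consensus) <- 1
  never <- which(!pos & upper.tri(pos), arr.ind = TRUE)

  labels <- stats::cutree(stats::hclust(stats::as.dist(1 - consensus),
                                        method = "average"), k = k)
  structure(list(consensus = consensus, cosample_counts = cosample,
                 cocluster_counts = cocluster, labels = labels, k = k,
                 n_resamples = n_resamples, never_cosampled = never),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering: ", length(x$labels), " samples, k = ", x$k,
      ", ", x$n_resamples, " resamples\n", sep = "")
  cat("Group sizes:", paste(table(x$labels), collapse = " / "), "\n")
  off <- x$consensus[upper.tri(x$consensus)]
  cat(sprintf("Consensus entries (off-diagonal): mean %.3f, %% in {<0.1, >0.9}: %.1f\n",
              mean(off), 100 * mean(off < 0.1 | off > 0.9)))
  if (nrow(x$never_cosampled) > 0)
    cat("Warning:", nrow(x$never_cosampled), "sample pairs never co-sampled\n")
  invisible(x)
}

#' @export
plot.consensus_result <- function(x, ...) {
  ord <- order(x$labels)
  graphics::image(x$consensus[ord, ord], main = "Consensus matrix",
                  xaxt = "n", yaxt = "n",
                  col = grDevices::grey.colors(64, 1, 0), ...)
  invisible(x)
}

#' Write consensus labels as two-column TSV
#'
#' @param x a `consensus_result` (or any named label vector).
#' @param path output file.
#' @export
write_labels_tsv <- function(x, path) {
  labels <- if (inherits(x, "consensus_result")) x$labels else x
  utils::write.table(data.frame(sample_id = names(labels), cluster = labels),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
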