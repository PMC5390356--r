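#' Read a gene-set annotation
#'
#' `read_gmt` parses the GMT dialect (term, description, gene ids,
#' tab-separated); `read_annotation_tsv` parses a two-column TSV
#' (gene_id, term_id — or term_id, description, gene_id with a header).
#'
#' @param path file path.
#' @return An annotation map: list(terms = named list of gene-id vectors,
#'   descriptions = named character, universe = all annotated genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(terms) <- vapply(parts, `[`, "", 1)
  desc <- stats::setNames(vapply(parts, `[`, "", 2), names(terms))
  annotation_map(terms, desc)
}

#' @rdname read_gmt
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(df))) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df)[1:2] <- c("gene_id", "term_id")
  }
  terms <- lapply(split(df$gene_id, df$term_id), unique)
  desc <- stats::setNames(names(terms), names(terms))
  if ("description" %in% names(df))
    desc <- vapply(split(df$description, df$term_id), `[`, "", 1)
  annotation_map(terms, desc)
}

#' Build an annotation map from a named list of gene sets
#'
#' @param terms named list, term id -> character vector of gene ids
#'   (non-empty).
#' @param descriptions optional named character vector of term descriptions.
#' @export
annotation_map <- function(terms, descriptions = NULL) {
  if (any(lengths(terms) == 0)) stop("term sets must be non-empty", call. = FALSE)
  if (is.null(descriptions))
    descriptions <- stats::setNames(names(terms), names(terms))
  list(terms = terms, descriptions = descriptions,
       universe = unique(unlist(terms, use.names = FALSE)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' FDR-adjusted p-values (q-values): q_(i) = min over j >= i of m p_(j) / j,
#' capped at 1, returned in the input order.
#'
#' @param p p-values in \[0, 1\].
#' @return q-values of the same length.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation term, the one-sided p-value P(X >= k) under
#' Hypergeometric(N, K, n), where N is the universe size, K the term size
#' within the universe, n the effective query size and k the overlap.
#' Query genes outside the universe are dropped (count reported). q-values
#' by [bh_adjust()].
#'
#' @param query character vector of gene ids.
#' @param annotation an annotation map (see [annotation_map()]).
#' @param universe optional universe restriction (e.g. the genes on the
#'   expression platform); intersected with the annotation universe.
#' @param q_cut significance cutoff used by the printer (default 0.05);
#'   all terms are returned.
#' @return An object of class `enrichment_result`: data.frame(term_id,
#'   description, k, K, n, N, p_value, q_value, genes) sorted by q then p,
#'   with attribute `n_dropped` (query genes outside the universe).
#' @export
hypergeom_enrich <- function(query, annotation, universe = NULL,
                             q_cut = 0.05) {
  uni <- annotation$universe
  if (!is.null(universe)) uni <- intersect(uni, universe)
  eff_query <- intersect(unique(query), uni)
  n_dropped <- length(unique(query)) - length(eff_query)
  if (n_dropped > 0)
    message("[enrich] ", n_dropped, " query gene(s) outside the universe dropped")
  if (length(eff_query) == 0)
    stop("no query gene in the annotation universe", call. = FALSE)
  N <- length(uni); n <- length(eff_query)
  rows <- lapply(names(annotation$terms), function(tid) {
    tg <- intersect(annotation$terms[[tid]], uni)
    K <- length(tg)
    if (K == 0) return(NULL)
    ov <- intersect(eff_query, tg)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid, description = annotation$descriptions[[tid]],
               k = k, K = K, n = n, N = N, p_value = p,
               genes = paste(ov, collapse = ","), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- bh_adjust(res$p_value)
  res <- res[order(res$q_value, res$p_value), c("term_id", "description",
              "k", "K", "n", "N", "p_value", "q_value", "genes")]
  rownames(res) <- NULL
  structure(res, n_dropped = n_dropped, q_cut = q_cut,
            class = c("enrichment_result", "data.frame"))
}

#' @export
print.enrichment_result <- function(x, ...) {
  q_cut <- attr(x, "q_cut")
  sig <- x[x$q_value < q_cut, , drop = FALSE]
  cat("Over-representation analysis:", nrow(x), "terms tested,",
      nrow(sig), "with q <", q_cut, "\n")
  if (nrow(sig) > 0)
    print.data.frame(utils::head(sig[, c("term_id", "description", "k", "K",
                                         "p_value", "q_value")], 20),
                     digits = 4)
  invisible(x)
}

#' Write enrichment results as TSV
#'
#' @param result an `enrichment_result`.
#' @param path output file.
#' @export
write_enrichment_tsv <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
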