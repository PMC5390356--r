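#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic child seed for a named pipeline stage: polynomial string hash
# folded into [0, 2^31 - 2] so every stage draws from an independent stream.
stage_seed <- function(seed, stage) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% m
  as.integer(h)
}

check_expression_matrix <- function(expr, arg = "expr") {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop(arg, " must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop(arg, " must have gene row names and sample column names", call. = FALSE)
  if (anyDuplicated(rownames(expr))) stop(arg, ": duplicated gene ids", call. = FALSE)
  if (anyDuplicated(colnames(expr))) stop(arg, ": duplicated sample ids", call. = FALSE)
  if (anyNA(expr)) stop(arg, " contains missing values", call. = FALSE)
  invisible(expr)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions (up to label permutation), 0 the expected
#' agreement of independent random partitions.
#'
#' @param a,b label vectors of equal length.
#' @return A number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must cover the same items")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_i * sum_j / n2
  mx <- (sum_i + sum_j) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

#' Read / write the expression matrix TSV dialect
#'
#' Tab-separated text, first column the gene identifier, header row of
#' sample identifiers, log2-scale values.
#'
#' @param path file path.
#' @param expr numeric genes x samples matrix with dimnames.
#' @return `read_expression_tsv` returns the matrix; the writer returns
#'   `path` invisibly.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  check_expression_matrix(m)
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(expr, path) {
  check_expression_matrix(expr)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the clinical table TSV dialect
#'
#' Columns: sample_id, os_time, os_event (0/1), and optionally stage, grade.
#'
#' @param path file path.
#' @param clinical a data frame with the columns above.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_clinical(df)
}

#' @rdname read_clinical_tsv
#' @export
write_clinical_tsv <- function(clinical, path) {
  check_clinical(clinical)
  utils::write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_clinical <- function(df) {
  need <- c("sample_id", "os_time", "os_event")
  if (!all(need %in% names(df)))
    stop("clinical table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in clinical table", call. = FALSE)
  if (any(df$os_time <= 0)) stop("os_time must be positive", call. = FALSE)
  if (!all(df$os_event %in% c(0, 1))) stop("os_event must be 0/1", call. = FALSE)
  df
}

# Align a clinical table to the columns of an expression matrix.
align_clinical <- function(expr, clinical) {
  clinical <- check_clinical(clinical)
  idx <- match(colnames(expr), clinical$sample_id)
  if (anyNA(idx))
    stop("clinical table does not cover all expression samples", call. = FALSE)
  clinical[idx, , drop = FALSE]
}
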