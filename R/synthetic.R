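#' Simulate a tumor expression cohort with planted prognostic structure
#'
#' Generates a log2-scale gene expression matrix, a clinical table with
#' right-censored overall survival, and the ground truth needed for recovery
#' tests. The cohort carries the statistical structure the screening pipeline
#' assumes: two latent sample subtypes (roughly 35/65) separated by a block of
#' differentially expressed genes, a subset of genes whose expression modulates
#' the individual hazard, stage/grade labels associated with subtype, and
#' independent exponential censoring.
#'
#' Each gene g has a baseline level \eqn{\mu_g \sim N(7, gene\_mean\_sd)} on
#' the log2 scale (genes differ in expression level, as on a real array) and
#' measurement noise N(0, 1) around it. The DE block is planted among genes
#' with baseline above the 40th percentile: differential signatures of
#' interest live in the detectably expressed fraction, so the low-median
#' filter is exercised by genuinely low-expressed background genes rather
#' than by the planted signal. Genes in
#' the DE block are shifted by `de_logfc` in subtype 1. Survival times are
#' exponential with log-hazard
#' \deqn{\log h_i = \log(\lambda_0) + \sum_{g \in prog} \beta \, z_{gi}}
#' where \eqn{z_{gi}} is the standardized expression of prognostic gene g in
#' sample i and \eqn{\beta} = `log_hr`. Censoring times are exponential with
#' rate `censor_rate`; the observed time is the minimum of the two.
#'
#' @param n_samples number of samples (>= 4).
#' @param n_genes number of genes.
#' @param n_de number of differentially expressed genes.
#' @param de_logfc true |log2 fold change| of the DE block (subtype 1 minus
#'   0). With `de_direction = "both"` (default) the first half of the block
#'   is up-regulated and the second half down-regulated in subtype 1,
#'   mirroring real differential blocks; `"up"` shifts every DE gene by
#'   +`de_logfc`.
#' @param de_direction `"both"` or `"up"`.
#' @param gene_mean_sd sd of per-gene baseline expression levels (default 1;
#'   0 gives a flat background at 7).
#' @param n_prog number of prognostic genes.
#' @param log_hr per-unit (standardized expression) log hazard ratio of each
#'   prognostic gene.
#' @param baseline_hazard baseline exponential event rate (> 0).
#' @param censor_rate exponential censoring rate (> 0).
#' @param stage_assoc probability of stage IV in subtype 1; subtype 0 uses
#'   `stage_assoc_low`.
#' @param stage_assoc_low stage IV probability in subtype 0.
#' @param subtype_prop proportion of samples in subtype 1 (default 0.35,
#'   mirroring a 195/369 two-group split).
#' @param prog_in_de if TRUE (default) the prognostic genes are a subset of the
#'   DE block (requires `n_prog <= n_de`); if FALSE they form a disjoint block
#'   (requires `n_de + n_prog <= n_genes`).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return A list with elements `expr` (genes x samples matrix), `clinical`
#'   (data.frame: sample_id, os_time, os_event, stage, grade) and `truth`
#'   (list: subtype_label, de_genes, de_logfc — named per-gene true signed
#'   log2FC, prognostic_genes, log_hr, censoring_fraction).
#' @examples
#' coh <- simulate_cohort(n_samples = 40, n_genes = 50, n_de = 10,
#'                        de_logfc = 1.5, n_prog = 4, seed = 1)
#' dim(coh$expr)
#' @export
simulate_cohort <- function(n_samples = 300, n_genes = 1000, n_de = 40,
                            de_logfc = 1.5, n_prog = 10, log_hr = 0.8,
                            baseline_hazard = 0.1, censor_rate = 0.05,
                            stage_assoc = 0.5, stage_assoc_low = 0.15,
                            subtype_prop = 0.35, prog_in_de = TRUE,
                            de_direction = c("both", "up"),
                            gene_mean_sd = 1, seed = NULL) {
  de_direction <- match.arg(de_direction)
  if (n_samples < 4) stop("n_samples must be >= 4", call. = FALSE)
  if (baseline_hazard <= 0 || censor_rate <= 0)
    stop("rates must be positive", call. = FALSE)
  if (n_de > n_genes) stop("n_de exceeds n_genes", call. = FALSE)
  if (prog_in_de) {
    if (n_prog > n_de) stop("n_prog must be <= n_de when prog_in_de", call. = FALSE)
  } else if (n_de + n_prog > n_genes) {
    stop("n_de + n_prog exceeds n_genes", call. = FALSE)
  }
  if (stage_assoc < 0 || stage_assoc > 1) stop("stage_assoc must be in [0,1]", call. = FALSE)

  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    samples <- sprintf("S%03d", seq_len(n_samples))
    n1 <- round(subtype_prop * n_samples)
    subtype <- c(rep(1L, n1), rep(0L, n_samples - n1))
    subtype <- sample(subtype)
    names(subtype) <- samples

    mu <- stats::rnorm(n_genes, mean = 7, sd = gene_mean_sd)
    expr <- mu + matrix(stats::rnorm(n_genes * n_samples, mean = 0, sd = 1),
                        n_genes, n_samples)
    dimnames(expr) <- list(genes, samples)
    expressed <- genes[mu >= stats::quantile(mu, 0.4)]
    if (n_de > length(expressed))
      stop("n_de exceeds the expressed gene fraction", call. = FALSE)
    de_genes <- expressed[seq_len(n_de)]
    sign_vec <- rep(1, n_de)
    if (de_direction == "both" && n_de > 1)
      sign_vec[(ceiling(n_de / 2) + 1):n_de] <- -1
    true_fc <- stats::setNames(sign_vec * de_logfc, de_genes)
    if (n_de > 0) expr[de_genes, subtype == 1L] <-
      expr[de_genes, subtype == 1L] + true_fc
    prog_genes <- if (prog_in_de) de_genes[seq_len(n_prog)] else {
      if (n_de + n_prog > length(expressed))
        stop("n_de + n_prog exceeds the expressed gene fraction", call. = FALSE)
      expressed[n_de + seq_len(n_prog)]
    }

    # individual hazard from standardized prognostic expression
    lp <- rep(0, n_samples)
    if (n_prog > 0) {
      z <- expr[prog_genes, , drop = FALSE]
      z <- (z - rowMeans(z)) / apply(z, 1, stats::sd)
      lp <- colSums(z) * log_hr
    }
    hazard <- baseline_hazard * exp(lp)
    t_event <- stats::rexp(n_samples, rate = hazard)
    t_cens <- stats::rexp(n_samples, rate = censor_rate)
    os_time <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)

    p_stage <- ifelse(subtype == 1L, stage_assoc, stage_assoc_low)
    stage <- ifelse(stats::runif(n_samples) < p_stage, "IV", "III")
    p_grade <- ifelse(subtype == 1L, 0.85, 0.6)
    grade <- ifelse(stats::runif(n_samples) < p_grade, "G3", "G2")

    clinical <- data.frame(sample_id = samples, os_time = os_time,
                           os_event = os_event, stage = stage, grade = grade,
                           stringsAsFactors = FALSE)
    truth <- list(subtype_label = subtype,
                  de_genes = de_genes, de_logfc = true_fc,
                  prognostic_genes = prog_genes, log_hr = log_hr,
                  censoring_fraction = mean(1 - os_event))
    list(expr = expr, clinical = clinical, truth = truth)
  })
}

#' Expand a gene-level matrix to a probe-level matrix
#'
#' Duplicates a fraction of genes into two probes with independent Gaussian
#' measurement noise, returning the probe matrix and the probe-to-symbol map
#' used to collapse it back. Supports testing of [collapse_probes()]; it makes
#' no attempt at probe-level chemistry.
#'
#' @param expr gene-level matrix.
#' @param dup_frac fraction of genes measured by two probes.
#' @param noise_sd per-probe measurement noise sd.
#' @param seed integer seed.
#' @return list(probe_expr, probe_map) where probe_map is a data.frame with
#'   columns probe_id, gene_symbol.
#' @export
simulate_probe_matrix <- function(expr, dup_frac = 0.3, noise_sd = 0.1,
                                  seed = NULL) {
  check_expression_matrix(expr)
  with_seed(seed, {
    genes <- rownames(expr)
    n_dup <- round(dup_frac * length(genes))
    dup <- sample(genes, n_dup)
    probe_gene <- c(genes, dup)
    probe_id <- sprintf("P%05d_at", seq_along(probe_gene))
    pm <- expr[probe_gene, , drop = FALSE] +
      matrix(stats::rnorm(length(probe_gene) * ncol(expr), sd = noise_sd),
             length(probe_gene), ncol(expr))
    rownames(pm) <- probe_id
    list(probe_expr = pm,
         probe_map = data.frame(probe_id = probe_id, gene_symbol = probe_gene,
                                stringsAsFactors = FALSE))
  })
}

#' Write the simulation ground truth as JSON
#'
#' @param truth the `truth` element of [simulate_cohort()].
#' @param path output file.
#' @export
write_ground_truth_json <- function(truth, path) {
  out <- truth
  out$subtype_label <- as.list(truth$subtype_label)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
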