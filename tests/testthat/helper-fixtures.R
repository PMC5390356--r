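# Shared fixtures, all generated in code.

# A small well-separated cohort for clustering/DE tests; the DE block
# scales with the gene count so tiny matrices stay valid.
small_cohort <- function(seed = 42, n_samples = 80, n_genes = 200,
                         n_de = max(4, round(0.12 * n_genes)),
                         de_logfc = 2, n_prog = min(6, n_de), log_hr = 0.8,
                         ...) {
  simulate_cohort(n_samples = n_samples, n_genes = n_genes, n_de = n_de,
                  de_logfc = de_logfc, n_prog = n_prog, log_hr = log_hr,
                  seed = seed, ...)
}

# Matrix with prescribed per-gene variances (two-point rows, median 0).
matrix_with_variances <- function(vars) {
  a <- sqrt(vars / 2)
  m <- cbind(-a, a)
  rownames(m) <- sprintf("g%02d", seq_along(vars))
  colnames(m) <- c("s1", "s2")
  m
}

as_expr <- function(m, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

# Exponential survival data with a known binary or continuous effect.
sim_surv <- function(n, beta = 0, x = NULL, baseline = 0.1, censor = 0.05,
                     seed = NULL) {
  progsig:::with_seed(seed, {
    if (is.null(x)) x <- stats::rnorm(n)
    t_ev <- stats::rexp(n, rate = baseline * exp(beta * x))
    t_cn <- stats::rexp(n, rate = censor)
    list(times = pmin(t_ev, t_cn), events = as.integer(t_ev <= t_cn), x = x)
  })
}
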