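#' Run the full prognostic-gene discovery pipeline
#'
#' Orchestrates preprocess -> stabilization loop -> seed-gene screen ->
#' |log2FC| threshold scan -> multivariate group survival, optionally
#' followed by GO-style over-representation of the key genes and validation
#' on an independent cohort. Every stage draws its randomness from a child
#' seed derived from the global seed by a stable hash of the stage name, so
#' stages are individually reproducible. When `out_dir` is given, each
#' stage's tabular outputs are written as TSV and a JSON manifest records
#' the seed, the thresholds, and the gene counts per stage (the
#' filtered -> feature -> stable -> seed -> key funnel).
#'
#' @param expr genes x samples log2 expression matrix, or a path to its TSV.
#' @param clinical clinical table (sample_id, os_time, os_event, ...), or a
#'   path to its TSV.
#' @param probe_map optional probe map (data.frame or TSV path); when given,
#'   `expr` is treated as probe-level.
#' @param annotation optional annotation map (or GMT path) for enrichment.
#' @param validation optional list(expr, clinical, eval_time) for external
#'   validation (matrix/data.frame or paths).
#' @param var_q,med_q low-information filter quantiles (default 0.2).
#' @param k number of sample groups (default 2).
#' @param n_resamples consensus resamples per clustering (default 1000).
#' @param sample_frac consensus subsampling fraction (default 0.8).
#' @param p_feature feature-gene p threshold (default 0.001).
#' @param p_seed seed-gene log-rank p threshold (default 0.01).
#' @param p_de threshold-scan differential p threshold (default 0.001).
#' @param fc_grid |log2FC| scan grid (default seq(0.1, 1.5, 0.05)).
#' @param q_cut enrichment q-value cutoff (default 0.05).
#' @param max_iter stabilization iteration cap (default 20).
#' @param seed global integer seed (required for a reproducible run).
#' @param out_dir optional artifact directory.
#' @param verbose log stage-tagged lines to stderr (default TRUE).
#' @return An object of class `progsig_run`: list(preprocess, stabilization,
#'   seed_screen, scan, key_genes, group_survival, enrichment, validation,
#'   manifest).
#' @export
run_pipeline <- function(expr, clinical, probe_map = NULL, annotation = NULL,
                         validation = NULL, var_q = 0.2, med_q = 0.2, k = 2,
                         n_resamples = 1000, sample_frac = 0.8,
                         p_feature = 0.001, p_seed = 0.01, p_de = 0.001,
                         fc_grid = seq(0.1, 1.5, by = 0.05), q_cut = 0.05,
                         max_iter = 20, seed = NULL, out_dir = NULL,
                         verbose = TRUE) {
  if (is.null(seed)) stop("a global seed is required", call. = FALSE)
  say <- function(stage, ...) if (verbose) message("[", stage, "] ", ...)
  if (is.character(expr)) expr <- read_expression_tsv(expr)
  if (is.character(clinical)) clinical <- read_clinical_tsv(clinical)
  if (is.character(probe_map)) probe_map <- read_probe_map(probe_map)
  if (is.character(annotation)) annotation <- read_gmt(annotation)
  clinical <- align_clinical(if (is.null(probe_map)) expr else
    collapse_probes(expr, probe_map), clinical)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_tsv <- function(obj, name, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, name))
  }

  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      if (!is.null(out_dir)) write_manifest(partial = TRUE, failed = stage)
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  state <- new.env(parent = emptyenv())
  write_manifest <- function(partial = FALSE, failed = NULL) {
    man <- list(
      package = "progsig", version = as.character(utils::packageVersion("progsig")),
      seed = seed,
      parameters = list(var_q = var_q, med_q = med_q, k = k,
                        n_resamples = n_resamples, sample_frac = sample_frac,
                        p_feature = p_feature, p_seed = p_seed, p_de = p_de,
                        fc_grid = range(fc_grid), q_cut = q_cut,
                        max_iter = max_iter),
      gene_funnel = state$funnel, partial = partial, failed_stage = failed,
      chosen_threshold = state$chosen_threshold,
      multivariate_logrank_p = state$mv_p)
    if (!is.null(out_dir))
      jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
  }

  # -- preprocess ------------------------------------------------------------
  pp <- run_stage("preprocess", function() {
    out <- preprocess_expression(expr, probe_map = probe_map,
                                 var_q = var_q, med_q = med_q)
    say("preprocess", out$n_input, " genes -> ", out$n_filtered,
        " after variance/median filter, centered")
    out
  })
  save_tsv(pp$expr, "expression_preprocessed.tsv", write_expression_tsv)
  state$funnel <- list(input_genes = pp$n_input, filtered_genes = pp$n_filtered)

  # -- stabilization loop ----------------------------------------------------
  stab <- run_stage("stabilize", function() {
    st <- iterate_to_stability(pp$expr, k = k, n_resamples = n_resamples,
                               sample_frac = sample_frac, p_cut = p_feature,
                               max_iter = max_iter,
                               seed = stage_seed(seed, "stabilize"),
                               verbose = verbose)
    say("stabilize", st$n_iterations, " iterations, ",
        if (st$converged) st$reason else "iteration cap", "; ",
        length(st$stable_genes), " stable feature genes")
    st
  })
  save_tsv(stab$final_labels, "stable_labels.tsv", write_labels_tsv)
  if (!is.null(out_dir))
    writeLines(stab$stable_genes, file.path(out_dir, "stable_genes.txt"))
  state$funnel$feature_genes <- stab$history[[1]]$n_feature_genes
  state$funnel$stable_genes <- length(stab$stable_genes)

  # -- seed-gene screen ------------------------------------------------------
  screen <- run_stage("screen", function() {
    sc <- seed_gene_screen(pp$expr, clinical, genes = stab$stable_genes,
                           p_cut = p_seed)
    say("screen", length(sc$seed_genes), " prognostic seed genes (p < ",
        p_seed, ")")
    sc
  })
  if (!is.null(out_dir))
    writeLines(screen$seed_genes, file.path(out_dir, "seed_genes.txt"))
  state$funnel$seed_genes <- length(screen$seed_genes)

  # -- threshold scan --------------------------------------------------------
  scan <- run_stage("scan", function() {
    ts <- fc_threshold_scan(pp$expr, clinical, screen$seed_genes,
                            grid = fc_grid, p_de = p_de)
    say("scan", "optimal |log2FC| > ", ts$chosen_threshold, " -> ",
        length(ts$chosen_genes), " key prognostic genes")
    ts
  })
  if (!is.null(out_dir)) {
    utils::write.table(scan$scan, file.path(out_dir, "threshold_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(scan$chosen_genes, file.path(out_dir, "key_genes.txt"))
  }
  state$funnel$key_genes <- length(scan$chosen_genes)
  state$chosen_threshold <- scan$chosen_threshold

  # -- multivariate survival -------------------------------------------------
  mv <- run_stage("survival", function() {
    gs <- multivariate_group_survival(pp$expr, scan$chosen_genes, clinical)
    say("survival", "key-gene split log-rank p = ",
        signif(gs$logrank$p_value, 4))
    gs
  })
  state$mv_p <- mv$logrank$p_value

  # -- enrichment (optional) -------------------------------------------------
  enr <- NULL
  if (!is.null(annotation)) {
    enr <- run_stage("enrich", function() {
      e <- hypergeom_enrich(scan$chosen_genes, annotation,
                            universe = rownames(pp$expr), q_cut = q_cut)
      say("enrich", sum(e$q_value < q_cut), " terms with q < ", q_cut)
      e
    })
    save_tsv(enr, "enrichment.tsv", write_enrichment_tsv)
  }

  # -- external validation (optional) ---------------------------------------
  val <- NULL
  if (!is.null(validation)) {
    val <- run_stage("validate", function() {
      vex <- validation$expr
      vcl <- validation$clinical
      if (is.character(vex)) vex <- read_expression_tsv(vex)
      if (is.character(vcl)) vcl <- read_clinical_tsv(vcl)
      v <- validate_external(vex, vcl, scan$chosen_genes,
                             eval_time = validation$eval_time)
      say("validate", "log-rank p = ", signif(v$logrank$p_value, 4),
          ", AUC = ", round(v$roc$auc, 4))
      v
    })
  }

  manifest <- write_manifest()
  structure(list(preprocess = pp, stabilization = stab, seed_screen = screen,
                 scan = scan, key_genes = scan$chosen_genes,
                 group_survival = mv, enrichment = enr, validation = val,
                 manifest = manifest),
            class = "progsig_run")
}

#' @export
print.progsig_run <- function(x, ...) {
  f <- x$manifest$gene_funnel
  cat("Prognostic-gene discovery run (seed ", x$manifest$seed, ")\n", sep = "")
  cat(sprintf("Gene funnel: %d input -> %d filtered -> %d feature -> %d stable -> %d seed -> %d key\n",
              f$input_genes, f$filtered_genes, f$feature_genes,
              f$stable_genes, f$seed_genes, f$key_genes))
  cat(sprintf("Chosen |log2FC| threshold: %.2f; multivariate log-rank p = %.4g\n",
              x$manifest$chosen_threshold, x$manifest$multivariate_logrank_p))
  if (!is.null(x$validation))
    cat(sprintf("External validation: log-rank p = %.4g, AUC = %.4f\n",
                x$validation$logrank$p_value, x$validation$roc$auc))
  invisible(x)
}
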