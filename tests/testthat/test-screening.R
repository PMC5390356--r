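test_that("constant genes are skipped by the seed screen", {
  coh <- small_cohort(n_samples = 40, n_genes = 30)
  expr <- rbind(coh$expr, g_const = 5)
  sc <- suppressWarnings(
    seed_gene_screen(expr, coh$clinical,
                     genes = c("g_const", rownames(coh$expr)[1:5])))
  expect_in("g_const", sc$skipped)
  expect_true(is.na(sc$p_values["g_const"]))
})

test_that("planted prognostic genes pass the seed screen", {
  hits <- 0
  for (s in 1:10) {
    coh <- simulate_cohort(n_samples = 300, n_genes = 60, n_de = 20,
                           n_prog = 1, log_hr = 1.0, seed = 1000 + s)
    sc <- seed_gene_screen(coh$expr, coh$clinical)
    hits <- hits + (coh$truth$prognostic_genes %in% sc$seed_genes)
  }
  expect_gte(hits, 9)  # ~95% power per the design
})

test_that("null genes are retained at roughly the nominal rate", {
  coh <- simulate_cohort(n_samples = 200, n_genes = 400, n_de = 0,
                         de_logfc = 0, n_prog = 0, log_hr = 0, seed = 991)
  sc <- seed_gene_screen(coh$expr, coh$clinical, p_cut = 0.01)
  frac <- length(sc$seed_genes) / 400
  bounds <- qbinom(c(0.005, 0.995), 400, 0.01) / 400
  expect_gte(frac, bounds[1]); expect_lte(frac, bounds[2])
})

test_that("euclidean_cluster recovers planted blobs and co-clusters duplicates", {
  set.seed(24)
  blob <- cbind(matrix(rnorm(20 * 6), 20, 6),
                matrix(rnorm(20 * 6, mean = 4), 20, 6))
  blob <- as_expr(blob)
  lab <- euclidean_cluster(blob, k = 2)
  expect_equal(adjusted_rand_index(lab, rep(1:2, each = 6)), 1)
  dup <- as_expr(cbind(blob, blob + 1e-9),
                 samples = sprintf("s%d", 1:24))
  lab2 <- euclidean_cluster(dup, k = 2)
  expect_equal(unname(lab2[1:12]), unname(lab2[13:24]))
  expect_error(euclidean_cluster(blob, k = 13), "k exceeds")
})

test_that("euclidean_cluster matches the exhaustive minimum-WSS 2-partition", {
  # 7 points in 2D with an unambiguous optimal split
  pts <- rbind(c(0, 0), c(0.4, 0.1), c(0.2, 0.5),
               c(5, 5), c(5.3, 4.8), c(4.9, 5.4), c(5.1, 5.1))
  m <- as_expr(t(pts))
  lab <- euclidean_cluster(m, k = 2)
  wss <- function(g) {
    sum(sapply(split(seq_len(7), g), function(ix) {
      ctr <- colMeans(pts[ix, , drop = FALSE])
      sum(sweep(pts[ix, , drop = FALSE], 2, ctr)^2)
    }))
  }
  best <- NULL; best_w <- Inf
  for (mask in 1:(2^6 - 1)) {
    g <- c(0, as.integer(intToBits(mask))[1:6])
    w <- wss(g)
    if (w < best_w) { best_w <- w; best <- g }
  }
  expect_equal(adjusted_rand_index(lab, best), 1)
  expect_equal(wss(lab), best_w)
})

test_that("threshold scan: gene counts are non-increasing and ties go low", {
  coh <- simulate_cohort(n_samples = 150, n_genes = 300, n_de = 40,
                         de_logfc = 1.2, n_prog = 10, seed = 332)
  sc <- seed_gene_screen(coh$expr, coh$clinical)
  ts <- fc_threshold_scan(coh$expr, coh$clinical, sc$seed_genes)
  expect_true(all(diff(ts$scan$n_genes) <= 0))
  min_p <- min(ts$scan$logrank_p)
  expect_equal(ts$chosen_threshold,
               min(ts$scan$threshold[ts$scan$logrank_p == min_p]))
})

test_that("a single-threshold grid is chosen trivially", {
  coh <- simulate_cohort(n_samples = 100, n_genes = 200, n_de = 30,
                         de_logfc = 1.5, n_prog = 8, seed = 333)
  sc <- seed_gene_screen(coh$expr, coh$clinical)
  ts <- fc_threshold_scan(coh$expr, coh$clinical, sc$seed_genes, grid = 0.3)
  expect_equal(ts$chosen_threshold, 0.3)
})

test_that("scan recovers strong-FC prognostic genes among weak-FC seeds", {
  # planted prognostic genes at |log2FC| ~ 1.2; the remaining DE seeds are
  # weak (0.3) so a threshold in between isolates the planted set
  coh <- simulate_cohort(n_samples = 200, n_genes = 400, n_de = 40,
                         de_logfc = 0.3, n_prog = 10, log_hr = 0.8,
                         seed = 334)
  strong <- coh$truth$prognostic_genes
  sub <- coh$truth$subtype_label
  coh$expr[strong, sub == 1] <- coh$expr[strong, sub == 1] + 0.9  # 0.3 + 0.9
  seeds <- union(strong, coh$truth$de_genes)
  ts <- fc_threshold_scan(coh$expr, coh$clinical, seeds)
  expect_gte(length(intersect(ts$chosen_genes, strong)), 8)
})

test_that("scan errors when no threshold yields two genes", {
  coh <- small_cohort(n_samples = 40, n_genes = 30, n_de = 0, de_logfc = 0,
                      n_prog = 0, log_hr = 0, seed = 335)
  expect_error(fc_threshold_scan(coh$expr, coh$clinical,
                                 rownames(coh$expr)[1:10],
                                 grid = c(3, 4)),
               "no threshold")
})

test_that("multivariate split separates survival on a strong cohort", {
  coh <- simulate_cohort(n_samples = 200, n_genes = 300, n_de = 30,
                         de_logfc = 1.5, n_prog = 10, log_hr = 1.0,
                         seed = 336)
  mv <- multivariate_group_survival(coh$expr, coh$truth$prognostic_genes,
                                    coh$clinical)
  expect_lt(mv$logrank$p_value, 0.01)
  expect_length(mv$curves, 2)
  for (cv in mv$curves) expect_true(all(diff(cv$survival) <= 0))
  expect_equal(sum(mv$logrank$observed), sum(mv$logrank$expected))
})

test_that("survival-independent genes give uniform-ish multivariate p", {
  set.seed(25)
  ps <- replicate(20, {
    coh <- simulate_cohort(n_samples = 80, n_genes = 60, n_de = 10,
                           de_logfc = 1.5, n_prog = 2, log_hr = 0,
                           seed = sample.int(1e6, 1))
    multivariate_group_survival(coh$expr, coh$truth$de_genes,
                                coh$clinical)$logrank$p_value
  })
  expect_gt(mean(ps > 0.05), 0.6)  # no systematic false signal
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
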