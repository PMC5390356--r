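test_that("km_estimate matches hand product-limit computations", {
  # no censoring: empirical survival function
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2/3, 1/3, 0))
  # all censored: flat at 1
  km2 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_length(km2$event_times, 0)
  expect_equal(km_survival_at(km2, 2.5), 1)
  # censoring inside: times (1,2,2,4), events (1,0,1,1)
  km3 <- km_estimate(c(1, 2, 2, 4), c(1, 0, 1, 1))
  expect_equal(km3$event_times, c(1, 2, 4))
  expect_equal(km3$n_at_risk, c(4, 3, 1))
  expect_equal(km3$survival, c(3/4, 1/2, 0))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("km with all events equals the empirical survival function", {
  set.seed(11)
  t <- rexp(50)
  km <- km_estimate(t, rep(1, 50))
  emp <- sapply(km$event_times, function(x) mean(t > x))
  expect_equal(km$survival, emp)
})

test_that("km_estimate agrees with survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(12)
  t <- round(rexp(80), 2) + 0.01
  e <- rbinom(80, 1, 0.7)
  km <- km_estimate(t, e)
  sf <- summary(survival::survfit(survival::Surv(t, e) ~ 1))
  expect_equal(km$event_times, sf$time)
  expect_equal(km$survival, sf$surv, tolerance = 1e-12)
  expect_equal(km$n_at_risk, sf$n.risk)
})

test_that("KM curves are monotone non-increasing in [0, 1]", {
  for (s in 1:5) {
    d <- sim_surv(40, beta = 0.5, seed = s)
    km <- km_estimate(d$times, d$events)
    expect_true(all(diff(km$survival) <= 0))
    expect_true(all(km$survival >= 0 & km$survival <= 1))
  }
})

test_that("logrank_test matches the hand-tallied 4-subject fixture", {
  # group A: times (1,2) events; group B: times (3,4) events
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(unname(lr$observed["A"]), 2)
  expect_equal(unname(lr$expected["A"]), 1/2 + 1/3, tolerance = 1e-12)
  expect_equal(sum(lr$observed), sum(lr$expected))
  # label swap leaves the statistic unchanged
  lr2 <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("B", "B", "A", "A"))
  expect_equal(lr2$chi2, lr$chi2)
  expect_equal(lr2$p_value, lr$p_value)
  expect_error(logrank_test(1:4, rep(0, 4), c(1, 1, 2, 2)), "zero events")
})

test_that("logrank_test agrees with survival::survdiff", {
  skip_if_not_installed("survival")
  set.seed(13)
  for (rep in 1:5) {
    d <- sim_surv(60, beta = 0.8, x = rep(0:1, 30))
    lr <- logrank_test(d$times, d$events, d$x)
    sd_ <- survival::survdiff(survival::Surv(d$times, d$events) ~ d$x)
    expect_equal(lr$chi2, unname(sd_$chisq), tolerance = 1e-10)
    expect_equal(unname(lr$observed), unname(sd_$obs))
    expect_equal(unname(lr$expected), unname(sd_$exp), tolerance = 1e-10)
  }
})

test_that("logrank p agrees with a permutation null within MC error", {
  d <- sim_surv(40, beta = 0, seed = 14)
  g <- rep(0:1, 20)
  lr <- logrank_test(d$times, d$events, g)
  set.seed(15)
  perm <- replicate(1000, {
    logrank_test(d$times, d$events, sample(g))$chi2
  })
  p_perm <- mean(perm >= lr$chi2 - 1e-12)
  expect_lt(abs(p_perm - lr$p_value), 3 * sqrt(0.25 / 1000) + 0.02)
})

test_that("fisher_exact reproduces published 2x2 stage/grade associations", {
  expect_equal(fisher_exact(rbind(c(144, 53), c(260, 31))), 4.699e-06,
               tolerance = 1e-4)
  expect_equal(fisher_exact(rbind(c(10, 196), c(59, 279))), 8.491e-06,
               tolerance = 1e-4)
})

test_that("fisher_exact handles the enumerable 3x3-margin case and degenerate input", {
  # margins (3,3)/(3,3): 4 tables, all equally or less likely -> p = 1
  expect_equal(fisher_exact(rbind(c(2, 1), c(1, 2))), 1.0)
  expect_error(fisher_exact(rbind(c(0, 0), c(1, 2))), "zero margin")
  expect_error(fisher_exact(rbind(c(1.5, 1), c(1, 2))), "integers")
})

test_that("fisher_exact matches fisher.test on random tables", {
  set.seed(16)
  for (rep in 1:50) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    expect_equal(fisher_exact(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("cox_fit score test at beta = 0 equals the log-rank chi2", {
  d <- sim_surv(60, beta = 0.7, x = rep(0:1, 30), seed = 17)  # untied times
  lr <- logrank_test(d$times, d$events, d$x)
  fit0 <- cox_fit(d$times, d$events, cbind(x = d$x), max_iter = 0)
  score_chi2 <- drop(fit0$score %*% solve(fit0$information, fit0$score))
  expect_equal(score_chi2, lr$chi2, tolerance = 1e-8)
})

test_that("cox_fit agrees with survival::coxph (Breslow)", {
  skip_if_not_installed("survival")
  set.seed(18)
  n <- 200
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  t_ev <- rexp(n, rate = 0.1 * exp(0.5 * x[, 1] - 0.7 * x[, 2]))
  t_cn <- rexp(n, rate = 0.05)
  times <- pmin(t_ev, t_cn); events <- as.integer(t_ev <= t_cn)
  fit <- cox_fit(times, events, x)
  ref <- survival::coxph(survival::Surv(times, events) ~ x,
                         ties = "breslow")
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
})

test_that("cox_fit handles ties, errors and separation", {
  skip_if_not_installed("survival")
  set.seed(19)
  times <- sample(1:8, 60, replace = TRUE)
  events <- rbinom(60, 1, 0.7)
  x <- cbind(z = rnorm(60))
  fit <- cox_fit(times, events, x)
  ref <- survival::coxph(survival::Surv(times, events) ~ x, ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_error(cox_fit(times, events, cbind(rep(1, 60))), "constant")
  # perfectly separating covariate: monotone likelihood must be flagged
  d <- list(times = c(1, 2, 3, 4, 5, 6), events = rep(1, 6),
            x = c(1, 1, 1, 0, 0, 0))
  fit_sep <- cox_fit(d$times, d$events, cbind(d$x))
  expect_false(fit_sep$converged)
})

test_that("cox_fit recovers a planted log hazard ratio", {
  set.seed(20)
  est <- replicate(20, {
    d <- sim_surv(400, beta = 0.7)
    cox_fit(d$times, d$events, cbind(x = d$x))$coefficients
  })
  expect_lt(abs(mean(est) - 0.7), 0.1)
})

test_that("survival_roc: perfect marker gives AUC 1, risk ordering respected", {
  set.seed(21)
  t <- sort(rexp(60)) + 0.001
  # marker = -event time: highest risk fails first
  roc <- survival_roc(t, rep(1, 60), marker = -t, eval_time = median(t))
  expect_equal(roc$auc, 1, tolerance = 1e-9)
})

test_that("without censoring survival_roc equals the binary ROC oracle", {
  set.seed(22)
  n <- 150
  t <- rexp(n); m <- -log(t) + rnorm(n, sd = 0.5)
  tau <- quantile(t, 0.5)
  roc <- survival_roc(t, rep(1, n), m, eval_time = tau)
  # brute-force binary ROC with cases = {t <= tau}
  case <- t <= tau
  cuts <- sort(unique(m))
  sens <- sapply(cuts, function(c) mean(m[case] > c))
  spec <- sapply(cuts, function(c) mean(m[!case] <= c))
  expect_equal(roc$sensitivity, sens, tolerance = 1e-9)
  expect_equal(roc$specificity, spec, tolerance = 1e-9)
  fpr <- c(1, 1 - spec, 0); tpr <- c(1, sens, 0)
  ord <- order(fpr, tpr)
  L <- length(fpr)
  auc_oracle <- sum(diff(fpr[ord]) * (tpr[ord][-1] + tpr[ord][-L]) / 2)
  expect_equal(roc$auc, auc_oracle, tolerance = 1e-9)
})

test_that("uninformative marker gives AUC near 0.5", {
  set.seed(23)
  n <- 2000
  t <- rexp(n)
  m <- rnorm(n)
  roc <- survival_roc(t, rep(1, n), m, eval_time = quantile(t, 0.4))
  expect_gt(roc$auc, 0.45); expect_lt(roc$auc, 0.55)
})

test_that("survival_roc rejects degenerate horizons", {
  t <- c(1, 2, 3, 4); e <- c(1, 1, 1, 1)
  expect_error(survival_roc(t, e, 1:4, eval_time = 10), "time range")
  expect_error(survival_roc(t, c(0, 0, 1, 1), 1:4, eval_time = 0.5),
               "no events")
})
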