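test_that("Kaplan-Meier estimates match hand-computed product-limit values", {
  rec <- toy_records()  # events at 1,2,4,6; censored at 3,5
  km <- km_estimate(rec)
  ev <- km[km$n_event > 0, ]
  # n=6, drops at 1 (5/6), 2 (x 4/5), 4 (x 2/3, after a censor), 6 (x 0)
  expect_equal(ev$estimate, c(5 / 6, 2 / 3, 4 / 9, 0),
               tolerance = 1e-10, ignore_attr = TRUE)
  # all censored: flat curve at 1
  flat <- km_estimate(tibble::tibble(time = 1:4, event = rep(0L, 4)))
  expect_true(all(flat$estimate == 1))
  # horizon restriction censors beyond the horizon
  km5 <- km_estimate(rec, horizon = 4.5)
  expect_lte(max(km5$time), 4.5)
  # empty group errors by name
  rec$group <- factor(rep("a", 6), levels = c("a", "b"))
  expect_error(km_estimate(rec, "group"), regexp = "b",
               class = "budquant_survival_error")
})

test_that("log-rank matches a hand-computed statistic and is null on
           duplicated groups", {
  rec <- tibble::tibble(time = c(1, 2, 3, 4), event = rep(1L, 4),
                        group = c("A", "A", "B", "B"))
  lr <- logrank_test(rec, "group")
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-10)  # hand-derived O-E/V
  dup <- tibble::tibble(time = rep(c(1, 2, 3), 2), event = rep(1L, 6),
                        group = rep(c("A", "B"), each = 3))
  lr0 <- logrank_test(dup, "group")
  expect_lt(lr0$statistic, 1e-10)
  expect_equal(lr0$p_value, 1, tolerance = 1e-8)
  one <- tibble::tibble(time = 1:3, event = rep(1L, 3), group = rep("A", 3))
  expect_error(logrank_test(one, "group"), class = "budquant_survival_error")
})

test_that("log-rank p-values are uniform under the null", {
  ps <- vapply(1:300, function(s) {
    set.seed(2000 + s)
    rec <- tibble::tibble(time = rexp(40, 0.1),
                          event = rbinom(40, 1, 0.8),
                          group = rep(c("A", "B"), 20))
    logrank_test(rec, "group")$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the cut-point scan equals brute-force enumeration over all valid
           splits", {
  for (s in c(1, 2, 3)) {
    set.seed(400 + s)
    n <- 20
    rec <- tibble::tibble(x = c(rnorm(n)), time = rexp(n, 0.1),
                          event = rbinom(n, 1, 0.7))
    if (sum(rec$event) == 0) rec$event[1] <- 1L
    sc <- budquant:::logrank_scan(rec$x, rec$time, rec$event, 0.1)
    bf <- vapply(sc$cutoff, function(cc) {
      survival::survdiff(survival::Surv(time, event) ~ factor(x > cc),
                         data = rec)$chisq
    }, numeric(1))
    expect_equal(sc$statistic, bf, tolerance = 1e-8)
    cp <- find_optimal_cutpoint(rec, "x")
    expect_equal(cp$statistic, max(bf), tolerance = 1e-8)
    expect_true(cp$cutoff %in% sc$cutoff)
  }
})

test_that("cut-point edge cases behave per contract", {
  rec <- tibble::tibble(x = rep(c(1, 2), each = 6), time = c(rexp(12, 0.2)),
                        event = rep(1L, 12))
  cp <- find_optimal_cutpoint(rec, "x")
  expect_identical(cp$cutoff, 1.5)  # single admissible midpoint
  expect_error(find_optimal_cutpoint(rec[1:8, ], "x"),
               class = "budquant_survival_error")
  rec$x <- 1
  expect_error(find_optimal_cutpoint(rec, "x"),
               class = "budquant_survival_error")
})

test_that("ties in the scan resolve to the smaller cut-off", {
  # exchangeable survival makes many candidate statistics equal (often 0)
  rec <- tibble::tibble(x = 1:12, time = rep(5, 12), event = rep(0L, 12))
  rec$event[1] <- 1L
  rec$time[1] <- 1
  sc <- budquant:::logrank_scan(rec$x, rec$time, rec$event, 0.1)
  cp <- find_optimal_cutpoint(rec, "x")
  best <- sc$cutoff[sc$statistic == max(sc$statistic)]
  expect_identical(cp$cutoff, min(best))
})

test_that("the Monte Carlo correction is deterministic and hits its
           boundary for overwhelming signals", {
  coh <- generate_cohort(cohort_spec(n_patients = 100, log_hr = log(10),
                                     censoring_rate = 0.1, seed = 8))
  rec <- dplyr::left_join(coh$features, coh$survival, by = "patient_id")
  expect_warning(
    cp1 <- monte_carlo_corrected_p(rec, "tb_total", n_sim = 99, seed = 5),
    regexp = "unstable")
  expect_warning(
    cp2 <- monte_carlo_corrected_p(rec, "tb_total", n_sim = 99, seed = 5),
    regexp = "unstable")
  expect_identical(cp1$corrected_p, cp2$corrected_p)
  # no permutation should beat a planted HR of 10: estimator boundary
  expect_equal(cp1$corrected_p, 1 / 100)
  expect_identical(cp1$n_monte_carlo, 99L)
})

test_that("split-sample mode derives on one half and tests on the other", {
  coh <- generate_cohort(cohort_spec(n_patients = 120, seed = 12))
  rec <- dplyr::left_join(coh$features, coh$survival, by = "patient_id")
  cp <- find_optimal_cutpoint(rec, "tb_total", method = "split",
                              split_seed = 2)
  expect_identical(cp$method, "split")
  expect_true(is.finite(cp$raw_p))
  expect_lt(cp$raw_p, 0.5)  # strong planted signal survives the holdout
})

test_that("Cox regression recovers a planted hazard ratio and rejects
           degenerate inputs", {
  coh <- generate_cohort(cohort_spec(n_patients = 500, seed = 31))
  rec <- dplyr::left_join(coh$features, coh$survival, by = "patient_id")
  rec$above <- as.integer(coh$truth$above)
  fit <- cox_regression(rec, "above")
  expect_gt(fit$hr, 2.4); expect_lt(fit$hr, 3.75)
  expect_true(fit$conf_low < fit$hr & fit$hr < fit$conf_high)
  expect_identical(fit$model_type, "univariate")
  rec$above2 <- rec$above
  expect_error(cox_regression(rec, c("above", "above")),
               class = "budquant_survival_error")
  rec$const <- 1
  expect_error(cox_regression(rec, "const"),
               class = "budquant_survival_error")
  # multivariable mode fits jointly
  rec$noise <- rnorm(nrow(rec))
  mv <- cox_regression(rec, c("above", "noise"), "multivariable")
  expect_identical(nrow(tidy(mv)), 2L)
  expect_identical(unique(mv$model_type), "multivariable")
  # few events warn (events spread over both groups so the fit is proper)
  small <- tibble::tibble(time = rexp(30, 0.1) + 0.1,
                          event = rep(0L, 30),
                          above = rep(0:1, 15))
  small$event[c(1, 2, 3, 4)] <- 1L
  small$above[c(1, 2)] <- 0L; small$above[c(3, 4)] <- 1L
  expect_warning(cox_regression(small, "above"), regexp = "events")
})

test_that("Pearson correlation with Bonferroni adjustment matches the
           textbook formula", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  pb <- pearson_bonferroni(x, y, n_tests = 3)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pb$r, r_direct, tolerance = 1e-12)
  expect_equal(pb$p_adjusted, min(1, pb$p_value * 3))
  ident <- pearson_bonferroni(x, x + 0:4 * 0)
  expect_equal(ident$r, 1)
  expect_lt(ident$p_adjusted, 1e-6)
  raw <- pearson_bonferroni(x, y, n_tests = 1)
  expect_equal(raw$p_adjusted, raw$p_value)
  expect_error(pearson_bonferroni(x, rep(2, 5)),
               class = "budquant_survival_error")
  expect_error(pearson_bonferroni(1:2, 2:3),
               class = "budquant_survival_error")
})

test_that("BH adjustment matches the direct step-up formula", {
  bh_direct <- function(p) {
    n <- length(p); o <- order(p); ro <- order(o)
    pmin(1, cummin((n / (n:1)) * p[o][n:1])[n:1])[ro]
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(14)
  for (rep in 1:10) {
    p <- runif(sample(3:30, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bh_direct(p), tolerance = 1e-12)
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in rank order
  }
  expect_error(bh_fdr(c(0.5, 0)), class = "budquant_survival_error")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "budquant_survival_error")
})
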