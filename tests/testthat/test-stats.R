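test_that("normality gate picks the test the data warrant", {
  set.seed(14)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(choose_test(list(a, b)), "t_test")
  expect_equal(choose_test(list(rexp(50), b)), "wilcoxon")
  expect_error(choose_test(list(c(1, 2), b)), "n >= 3")
})

test_that("group comparisons reproduce the study's APOE4 contrast", {
  tab <- data.frame(apoe4 = c(rep(1, 3), rep(0, 13), rep(1, 9), rep(0, 4)),
                    dx = c(rep("NL", 16), rep("MCIAD", 13)))
  res <- group_compare(tab, "apoe4", kind = "chi2")
  expect_equal(res$p_value, 0.018, tolerance = 0.02)
  # without Yates correction the printed value is not reproduced
  res_nc <- group_compare(tab, "apoe4", kind = "chi2", yates = FALSE)
  expect_lt(res_nc$p_value, 0.01)
})

test_that("continuous group comparisons behave at the extremes", {
  tab_same <- data.frame(y = rep(c(1, 2, 3, 4), 2),
                         dx = rep(c("NL", "MCIAD"), each = 4))
  res <- group_compare(tab_same, "y", kind = "wilcoxon")
  expect_equal(res$p_value, 1)
  set.seed(5)
  tab_far <- data.frame(y = c(rnorm(20), rnorm(20) + 10),
                        dx = rep(c("NL", "MCIAD"), each = 20))
  expect_lt(group_compare(tab_far, "y", kind = "t")$p_value, 1e-6)
  tab_const <- data.frame(y = rep(1, 10), dx = rep(c("NL", "MCIAD"), 5))
  expect_error(group_compare(tab_const, "y"), "degenerate")
})

test_that("Spearman matrix equals the rank-then-Pearson oracle", {
  set.seed(77)
  tab <- data.frame(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  tab$b <- tab$a + tab$b          # induce correlation
  cm <- spearman_matrix(tab, c("a", "b", "c"))
  oracle <- stats::cor(apply(tab, 2, rank))
  expect_equal(unname(cm$rho), unname(oracle), tolerance = 1e-12)
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(diag(cm$rho), c(a = 1, b = 1, c = 1))
  # monotone limits
  inc <- data.frame(x = 1:8, y = (1:8)^3, z = -(1:8))
  ci <- spearman_matrix(inc, c("x", "y", "z"))
  expect_equal(ci$rho["x", "y"], 1)
  expect_equal(ci$rho["x", "z"], -1)
  # constant column flagged
  k <- data.frame(x = 1:6, y = rep(2, 6))
  ck <- spearman_matrix(k, c("x", "y"))
  expect_true(ck$constant[["y"]])
  expect_true(is.na(ck$rho["x", "y"]))
})

test_that("linear model uses the study coding and recovers planted slopes", {
  set.seed(8)
  n <- 200
  tab <- data.frame(age = rnorm(n, 70, 8),
                    sex = sample(c("F", "M"), n, replace = TRUE),
                    dx = sample(c("NL", "MCIAD"), n, replace = TRUE))
  tab$y <- 1 + 0.5 * tab$age + 0.3 * (tab$sex == "M") -
    0.4 * (tab$dx == "NL") + rnorm(n, 0, 0.5)
  fit <- fit_linear_model(tab, "y", c("age", "sex", "dx"))
  expect_true(all(c("sexM", "dxNL") %in% fit$terms$term))
  est <- fit$terms$estimate[fit$terms$term == "age"]
  se <- fit$terms$se[fit$terms$term == "age"]
  expect_lt(abs(est - 0.5), 3 * se)
  expect_true(fit$r2 >= 0 && fit$r2 <= 1 && fit$r2_adj <= fit$r2)
  # exact linear data: r2 = 1, residuals 0
  tab$y0 <- 2 * tab$age + 1
  fit0 <- suppressWarnings(fit_linear_model(tab, "y0", c("age", "sex", "dx")))
  expect_equal(fit0$r2, 1)
  expect_lt(max(abs(fit0$residuals)), 1e-8)
  # collinear design errors informatively
  tab$age2 <- tab$age
  expect_error(fit_linear_model(tab, "y", c("age", "age2")), "collinear")
})

test_that("partial regression satisfies the Frisch-Waugh identity", {
  set.seed(23)
  for (i in 1:20) {
    n <- 40
    tab <- data.frame(y = rnorm(n), x = rnorm(n), a = rnorm(n),
                      sex = sample(c("F", "M"), n, replace = TRUE))
    fit <- fit_linear_model(tab, "y", c("x", "a", "sex"))
    pr <- partial_regression(tab, "y", c("x", "a", "sex"), "x")
    expect_equal(pr$slope, fit$terms$estimate[fit$terms$term == "x"],
                 tolerance = 1e-10)
  }
  # intercept-only adjustment reduces to the simple regression slope
  tab <- data.frame(y = rnorm(20), x = rnorm(20))
  pr <- partial_regression(tab, "y", "x", "x")
  expect_equal(pr$slope, unname(coef(lm(y ~ x, tab))[2]), tolerance = 1e-12)
})

test_that("multiplicity corrections match hand-computed step-down/step-up", {
  expect_equal(adjust_pvalues(0.03, "holm"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  p <- c(0.001, 0.02, 0.5, 0.9)
  expect_true(all(adjust_pvalues(p, "holm") >= p))
  expect_true(all(adjust_pvalues(p, "holm") >= adjust_pvalues(p, "bh")))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0,1")
})

test_that("percent increase reproduces the group-sensitivity arithmetic", {
  expect_equal(percent_increase(4.41, 4.83), 9.5)
  expect_equal(percent_increase(1.52, 1.68), 10.5)
  expect_equal(percent_increase(25.15, 25.77), 2.5)
  expect_error(percent_increase(0, 1), "positive")
})

test_that("the full battery runs on a default cohort", {
  co <- make_cohort(cohort_spec(seed = 3), make_phantoms = FALSE)
  tab <- cohort_truth_table(co)
  tab$suvr <- tab$suvr_truth
  res <- run_stats_battery(tab)
  expect_named(res$group_tests,
               c("wm_pcsf", "gm_pcsf", "wm_fw", "pvs_wmv", "suvr"))
  expect_true(all(res$adjusted_p >= vapply(res$group_tests, `[[`, 1, "p_value")))
  expect_equal(res$partial$slope,
               res$amyloid_model$terms$estimate[
                 res$amyloid_model$terms$term == "wm_pcsf"],
               tolerance = 1e-10)
  expect_equal(dim(res$spearman$all$rho), c(4L, 4L))
})
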