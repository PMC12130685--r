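#' Choose between t-test and Wilcoxon by Shapiro-Wilk gating
#'
#' Returns `"t_test"` when the Shapiro-Wilk normality test does not reject
#' (p >= `alpha`) in every group, `"wilcoxon"` otherwise.
#'
#' @param values_by_group list of numeric vectors, each of length >= 3
#' @param alpha normality gate level
#' @return `"t_test"` or `"wilcoxon"`
#' @export
choose_test <- function(values_by_group, alpha = 0.05) {
  if (any(vapply(values_by_group, length, 1L) < 3))
    stop_invalid("each group needs n >= 3 for the normality gate")
  p <- vapply(values_by_group, function(v) stats::shapiro.test(v)$p.value, 1)
  if (all(p >= alpha)) "t_test" else "wilcoxon"
}

#' Two-group comparison for one table variable
#'
#' Continuous variables: two-sided t-test or Wilcoxon rank-sum, with
#' `kind = "auto"` gated by Shapiro-Wilk per group. Binary variables
#' (`kind = "chi2"`): 2x2 chi-squared test with Yates continuity correction
#' by default.
#'
#' @param table data.frame with a `dx` group column
#' @param variable column to compare
#' @param kind `"auto"`, `"t"`, `"wilcoxon"` or `"chi2"`
#' @param group grouping column (two levels)
#' @param yates apply continuity correction for `"chi2"`
#' @return list: `test`, `statistic`, `p_value`
#' @export
group_compare <- function(table, variable, kind = c("auto", "t", "wilcoxon", "chi2"),
                          group = "dx", yates = TRUE) {
  kind <- match.arg(kind)
  if (!variable %in% names(table)) stop_invalid("variable not in table")
  g <- factor(table[[group]])
  if (nlevels(g) != 2) stop_invalid("group column must have exactly two levels")
  x <- table[[variable]]
  if (kind == "chi2") {
    tab <- stats::xtabs(~ x + g)
    if (!all(dim(tab) == c(2, 2))) stop_invalid("chi2 requires a 2x2 count table")
    ht <- stats::chisq.test(tab, correct = yates)
    return(list(test = "chi2", statistic = unname(ht$statistic),
                p_value = ht$p.value))
  }
  xs <- split(x, g)
  if (stats::var(x) == 0) stop_invalid("degenerate test: variable is constant")
  if (kind == "auto") kind <- if (choose_test(xs) == "t_test") "t" else "wilcoxon"
  if (kind == "t") {
    ht <- stats::t.test(xs[[1]], xs[[2]])
    list(test = "t", statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    exact <- length(x) <= 20
    ht <- suppressWarnings(
      stats::wilcox.test(xs[[1]], xs[[2]], exact = exact, correct = !exact))
    list(test = "wilcoxon", statistic = unname(ht$statistic),
         p_value = ht$p.value)
  }
}

#' Pairwise Spearman correlation matrix
#'
#' Spearman rho on average ranks with the corresponding test p-values,
#' optionally restricted to a subgroup (whole group / NL / MCIAD panels).
#' Constant variables yield `NA` for their pairs and are flagged.
#'
#' @param table data.frame
#' @param variables columns to correlate
#' @param group_filter optional logical vector or expression result selecting
#'   rows
#' @return list of class `glymap_corrmat`: `variables`, `rho`, `p`, `n`,
#'   `constant` (flag per variable)
#' @export
spearman_matrix <- function(table, variables, group_filter = NULL) {
  dat <- table[, variables, drop = FALSE]
  if (!is.null(group_filter)) dat <- dat[group_filter, , drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 3) stop_invalid("need >= 3 complete rows")
  k <- length(variables)
  constant <- vapply(dat, function(v) stats::var(v) == 0, TRUE)
  rho <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  p <- rho
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (constant[i] || constant[j]) next
    ct <- suppressWarnings(
      stats::cor.test(dat[[i]], dat[[j]], method = "spearman", exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(variables = variables, rho = rho, p = p, n = n,
                 constant = constant),
            class = "glymap_corrmat")
}

# treatment-coded analysis frame: female and MCIAD are the reference levels,
# so reported terms are "sexM" and "dxNL"
coded_frame <- function(table) {
  d <- as.data.frame(table)
  if ("sex" %in% names(d)) d$sex <- factor(d$sex, levels = c("F", "M"))
  if ("dx" %in% names(d)) d$dx <- factor(d$dx, levels = c("MCIAD", "NL"))
  d
}

#' Ordinary least squares with the study's covariate coding
#'
#' Fits `response ~ covariates` with treatment coding (female / MCIAD
#' references, so coefficients appear as `sexM` and `dxNL`), two-sided t
#' tests per coefficient, and R^2 / adjusted R^2.
#'
#' @param table data.frame
#' @param response response column
#' @param covariates character vector of covariate columns
#' @return list of class `glymap_lm`: `terms` (data.frame with estimate, se,
#'   t, p per term), `r2`, `r2_adj`, `n`, `residuals`, and the underlying
#'   `fit`
#' @export
fit_linear_model <- function(table, response, covariates) {
  d <- coded_frame(table)
  n <- nrow(d)
  if (n <= length(covariates) + 1)
    stop_invalid("need n > number of terms + 1")
  form <- stats::reformulate(covariates, response)
  fit <- stats::lm(form, data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop_invalid("rank-deficient design; collinear terms: ",
                 paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)
  terms <- data.frame(term = rownames(sm$coefficients),
                      estimate = sm$coefficients[, 1],
                      se = sm$coefficients[, 2],
                      t = sm$coefficients[, 3],
                      p = sm$coefficients[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(terms = terms, r2 = sm$r.squared, r2_adj = sm$adj.r.squared,
                 n = n, residuals = stats::residuals(fit), fit = fit),
            class = "glymap_lm")
}

#' Partial regression (added-variable) coordinates and slope
#'
#' Residualizes both the response and the focus covariate on the remaining
#' covariates; the slope of the y-residuals on the x-residuals equals the
#' focus coefficient of the full model (Frisch-Waugh-Lovell).
#'
#' @param table data.frame
#' @param response response column
#' @param covariates all model covariates (including `focus`)
#' @param focus covariate whose adjusted association is displayed
#' @return list: `x_residual`, `y_residual`, `slope`
#' @export
partial_regression <- function(table, response, covariates, focus) {
  if (!focus %in% covariates) stop_invalid("focus variable must be a covariate")
  d <- coded_frame(table)
  others <- setdiff(covariates, focus)
  rhs <- if (length(others)) others else "1"
  y_res <- stats::residuals(stats::lm(stats::reformulate(rhs, response), data = d))
  x_res <- stats::residuals(stats::lm(stats::reformulate(rhs, focus), data = d))
  slope <- unname(stats::coef(stats::lm(y_res ~ x_res))[2])
  list(x_residual = unname(x_res), y_residual = unname(y_res), slope = slope)
}

#' Multiplicity correction (Holm or Benjamini-Hochberg)
#'
#' @param p p-values in [0,1]
#' @param method `"holm"` (step-down family-wise control) or `"bh"`
#'   (step-up false-discovery-rate control)
#' @return adjusted p-values, in input order
#' @export
adjust_pvalues <- function(p, method = c("holm", "bh")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_invalid("p-values must lie in [0,1]")
  stats::p.adjust(p, method = if (method == "holm") "holm" else "BH")
}

#' Percent increase of a comparison group mean over a reference mean
#'
#' 100 * (comparison - reference) / reference, rounded to one decimal (the
#' reporting convention for group-sensitivity summaries).
#'
#' @param mean_reference reference group mean (> 0)
#' @param mean_comparison comparison group mean
#' @return percent increase, one decimal
#' @export
percent_increase <- function(mean_reference, mean_comparison) {
  if (mean_reference <= 0) stop_invalid("reference mean must be positive")
  round(100 * (mean_comparison - mean_reference) / mean_reference, 1)
}

#' Run the comparative statistical battery on a biomarker table
#'
#' Group comparisons (Shapiro-Wilk-gated) for each biomarker, the Spearman
#' correlation matrix between the fluid measures (whole group and per
#' diagnosis), the covariate regressions `biomarker ~ age + sex + dx`, the
#' amyloid model `suvr ~ wm_pcsf + age + sex` with its partial-regression
#' coordinates, and multiplicity-adjusted p-values.
#'
#' @param table biomarker table (see [build_subject_table()])
#' @param biomarkers columns analysed
#' @param adjust `"holm"` or `"bh"`
#' @return list of class `glymap_stats`: `group_tests`, `adjusted_p`,
#'   `spearman` (list: all/nl/mciad), `regressions`, `amyloid_model`,
#'   `partial`
#' @export
run_stats_battery <- function(table,
                              biomarkers = c("wm_pcsf", "gm_pcsf", "wm_fw",
                                             "pvs_wmv", "suvr"),
                              adjust = c("holm", "bh")) {
  adjust <- match.arg(adjust)
  group_tests <- lapply(biomarkers, function(v)
    group_compare(table, v, kind = "auto"))
  names(group_tests) <- biomarkers
  p_raw <- vapply(group_tests, `[[`, 1, "p_value")
  fluid <- intersect(c("wm_pcsf", "gm_pcsf", "wm_fw", "pvs_wmv"), names(table))
  spearman <- list(
    all = spearman_matrix(table, fluid),
    nl = tryCatch(spearman_matrix(table, fluid, table$dx == "NL"),
                  error = function(e) NULL),
    mciad = tryCatch(spearman_matrix(table, fluid, table$dx == "MCIAD"),
                     error = function(e) NULL))
  regressions <- lapply(setdiff(biomarkers, "suvr"), function(v)
    fit_linear_model(table, v, c("age", "sex", "dx")))
  names(regressions) <- setdiff(biomarkers, "suvr")
  amyloid <- fit_linear_model(table, "suvr", c("wm_pcsf", "age", "sex"))
  partial <- partial_regression(table, "suvr", c("wm_pcsf", "age", "sex"),
                                "wm_pcsf")
  structure(list(group_tests = group_tests,
                 adjusted_p = adjust_pvalues(p_raw, adjust),
                 spearman = spearman, regressions = regressions,
                 amyloid_model = amyloid, partial = partial),
            class = "glymap_stats")
}
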