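# Subject-level outcome and cohort statistics: growth-rate classification,
# normality-routed group comparisons, correlation matrix, multivariable
# regression with heteroskedasticity-consistent standard errors, and
# Bland-Altman agreement.

#' Aortic growth rate and stable/enlarging classification
#'
#' Growth rate is the change in maximal aortic diameter between baseline and
#' follow-up divided by the interval; subjects at or above 3 mm/year are
#' classified as enlarging (the boundary value 3.0 is enlarging).
#'
#' @param baseline_mm,followup_mm maximal aortic diameters, mm.
#' @param interval_years time between scans, years (> 0).
#' @return list `(rate_mm_yr, group)`.
#' @export
growth_rate_and_group <- function(baseline_mm, followup_mm, interval_years) {
  if (any(interval_years <= 0)) stop("interval must be positive")
  rate <- (followup_mm - baseline_mm) / interval_years
  list(rate_mm_yr = rate,
       group = ifelse(rate >= 3, "enlarging", "stable"))
}

#' Compare a variable between the stable and enlarging groups
#'
#' Continuous variables route to an unpaired t-test when both groups pass
#' Shapiro-Wilk normality at alpha = 0.05 (groups of n < 3 cannot be tested
#' and route nonparametric), otherwise to a Mann-Whitney U test. Categorical
#' variables use Fisher's exact test when any expected cell count is below
#' 5, otherwise chi-square. All tests two-sided.
#'
#' @param table a data.frame with a `group` column (`"stable"` /
#'   `"enlarging"`).
#' @param variable column name to compare.
#' @param categorical force categorical handling (default: autodetect
#'   non-numeric columns).
#' @return list of class `group_comparison`: `test`, `statistic`, `p_value`,
#'   `descriptives` (mean +/- SD under normality, else median (Q1-Q3) with
#'   linear-interpolation quartiles), `degenerate` flag for constant
#'   variables.
#' @export
compare_groups <- function(table, variable, categorical = NULL) {
  if (!variable %in% names(table)) stop("no column ", variable)
  g <- table$group
  if (!all(c("stable", "enlarging") %in% g))
    stop("both groups must be non-empty")
  x <- table[[variable]]
  if (is.null(categorical)) categorical <- !is.numeric(x)
  if (categorical) {
    tab <- table(factor(x), factor(g))
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts < 5)) {
      ht <- stats::fisher.test(tab)
      return(structure(list(test = "fisher", statistic = NA_real_,
                            p_value = ht$p.value, table = tab,
                            degenerate = FALSE),
                       class = "group_comparison"))
    }
    ht <- stats::chisq.test(tab, correct = FALSE)
    return(structure(list(test = "chi-square",
                          statistic = unname(ht$statistic),
                          p_value = ht$p.value, table = tab,
                          degenerate = FALSE),
                     class = "group_comparison"))
  }
  xs <- x[g == "stable" & !is.na(x)]
  xe <- x[g == "enlarging" & !is.na(x)]
  if (length(xs) == 0 || length(xe) == 0)
    stop("both groups must be non-empty after removing missing values")
  degenerate <- stats::sd(c(xs, xe)) == 0
  if (degenerate)
    return(structure(list(test = "degenerate", statistic = NA_real_,
                          p_value = 1, degenerate = TRUE,
                          descriptives = NULL),
                     class = "group_comparison"))
  normal <- function(v) {
    if (length(v) < 3 || stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value >= 0.05
  }
  both_normal <- normal(xs) && normal(xe)
  desc <- function(v) {
    if (both_normal)
      sprintf("%.1f ± %.1f", mean(v), stats::sd(v))
    else {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7)  # linear interp
      sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
    }
  }
  if (both_normal) {
    ht <- stats::t.test(xs, xe, var.equal = TRUE)
    test <- "t-test"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(xs, xe, exact = FALSE))
    test <- "mann-whitney"
  }
  structure(list(test = test, statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 descriptives = c(stable = desc(xs), enlarging = desc(xe)),
                 degenerate = FALSE),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: p = %.4g%s\n", x$test, x$p_value,
              if (x$degenerate) " [degenerate]" else ""))
  if (!is.null(x$descriptives))
    cat(sprintf("  stable %s | enlarging %s\n", x$descriptives["stable"],
                x$descriptives["enlarging"]))
  invisible(x)
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Pairwise-complete handling: subjects with missing cells (e.g. TL pressure
#' values excluded by the lumen-radius rule) drop out of the affected pairs
#' only. Cells with fewer than 3 complete pairs are flagged (`NA`).
#'
#' @param table data.frame.
#' @param variables column names to correlate.
#' @return list `(r, p, n)`: square matrices of coefficients, two-sided
#'   p-values and complete-pair counts.
#' @export
correlation_matrix <- function(table, variables) {
  k <- length(variables)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(variables,
                                                           variables))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    xi <- table[[variables[i]]]; xj <- table[[variables[j]]]
    ok <- stats::complete.cases(xi, xj)
    nmat[i, j] <- sum(ok)
    if (sum(ok) < 3) next
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    if (stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) next
    ct <- stats::cor.test(xi[ok], xj[ok], method = "pearson")
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(r = r, p = p, n = nmat)
}

#' Linear regression with heteroskedasticity-consistent standard errors
#'
#' OLS point estimates with HC robust covariance (default HC1, matching the
#' convention of clinical statistics packages), t(n - k) inference, 95\%
#' confidence intervals and adjusted R^2. One two-predictor model per
#' hemodynamic metric avoids multicollinearity in small cohorts.
#'
#' @param table data.frame.
#' @param outcome outcome column (default `"growth_rate_mm_yr"`).
#' @param predictors character vector of predictor columns.
#' @param hc_type `"HC0"`, `"HC1"`, `"HC2"` or `"HC3"`.
#' @return list of class `regression_result`: `coefficients` data.frame
#'   (estimate, robust SE, t, p, CI), `adj_r_squared`, `n`, `model`.
#' @export
robust_regression <- function(table, outcome = "growth_rate_mm_yr",
                              predictors, hc_type = "HC1") {
  cols <- c(outcome, predictors)
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dat <- table[stats::complete.cases(table[, cols]), cols, drop = FALSE]
  n <- nrow(dat)
  k <- length(predictors) + 1L
  if (n <= k + 2) stop("too few subjects (n = ", n, ") for ", k,
                       " parameters")
  f <- stats::as.formula(paste(outcome, "~",
                               paste(predictors, collapse = " + ")))
  fit <- stats::lm(f, data = dat)
  X <- stats::model.matrix(fit)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design: collinear columns among ",
         paste(colnames(X), collapse = ", "))
  }
  e <- stats::residuals(fit)
  XtXi <- solve(crossprod(X))
  hdiag <- rowSums((X %*% XtXi) * X)
  omega <- switch(hc_type,
                  HC0 = e^2,
                  HC1 = e^2 * n / (n - k),
                  HC2 = e^2 / (1 - hdiag),
                  HC3 = e^2 / (1 - hdiag)^2,
                  stop("unknown hc_type ", hc_type))
  meat <- crossprod(X * sqrt(omega))
  vc <- XtXi %*% meat %*% XtXi
  se <- sqrt(diag(vc))
  b <- stats::coef(fit)
  tval <- b / se
  df <- n - k
  pval <- 2 * stats::pt(-abs(tval), df)
  crit <- stats::qt(0.975, df)
  coefs <- data.frame(term = names(b), estimate = unname(b),
                      robust_se = unname(se), t = unname(tval),
                      p_value = unname(pval),
                      ci_lo = unname(b - crit * se),
                      ci_hi = unname(b + crit * se))
  structure(list(coefficients = coefs,
                 adj_r_squared = summary(fit)$adj.r.squared,
                 n = n, df = df, hc_type = hc_type,
                 model = paste(outcome, "~",
                               paste(predictors, collapse = " + "))),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("robust OLS (%s), n = %d, adj R^2 = %.2f\n  %s\n",
              x$hc_type, x$n, x$adj_r_squared, x$model))
  print(x$coefficients, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Bland-Altman agreement between two measurement series
#'
#' Bias (mean difference), SD of differences, 95\% limits of agreement
#' (bias +/- 1.96 SD) and the Pearson correlation between raters, plus the
#' (mean, difference) pairs for plotting.
#'
#' @param x,y paired measurement vectors (equal length >= 3). Differences
#'   are `y - x`.
#' @return list of class `bland_altman`: `bias`, `sd_diff`, `loa`
#'   (length 2), `pearson_r`, `pairs` data.frame.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("vectors have different lengths")
  if (length(x) < 3) stop("need at least 3 pairs")
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
    stats::cor(x, y)
  structure(list(bias = bias, sd_diff = s,
                 loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
                 pearson_r = r,
                 pairs = data.frame(mean = (x + y) / 2, difference = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("bias %.2f ± %.2f, LOA [%.2f, %.2f], r = %.3f\n",
              x$bias, x$sd_diff, x$loa[1], x$loa[2], x$pearson_r))
  invisible(x)
}

#' Full cohort analysis report
#'
#' Runs the statistical layer of the pipeline on a cohort table: group
#' comparisons for each hemodynamic metric, the growth-rate correlation
#' matrix, and one adjusted robust-SE regression per metric (metric +
#' baseline diameter), mirroring the three-model design that avoids
#' multicollinearity.
#'
#' @param table a cohort data.frame (see [simulate_cohort] for the schema).
#' @param metrics metric columns to analyze.
#' @return list of class `cohort_analysis` with `comparisons`,
#'   `correlations`, `regressions`, and growth-rate summaries (both
#'   mean +/- SD and median (IQR), which are reported in different places).
#' @export
analyze_cohort <- function(table,
                           metrics = c("flef_pct", "msdr_cm_s3",
                                       "dp_max_fl_mmhg_m")) {
  stopifnot(all(c("group", "growth_rate_mm_yr") %in% names(table)))
  comparisons <- lapply(metrics, function(m) compare_groups(table, m))
  names(comparisons) <- metrics
  correlations <- correlation_matrix(
    table, c("growth_rate_mm_yr", metrics, "baseline_diameter_mm"))
  regressions <- lapply(metrics, function(m)
    robust_regression(table, "growth_rate_mm_yr",
                      c(m, "baseline_diameter_mm")))
  names(regressions) <- metrics
  gr <- table$growth_rate_mm_yr
  q <- stats::quantile(gr, c(0.25, 0.5, 0.75), type = 7)
  structure(list(
    comparisons = comparisons, correlations = correlations,
    regressions = regressions,
    growth_mean_sd = c(mean = mean(gr), sd = stats::sd(gr)),
    growth_median_iqr = c(median = unname(q[2]), q1 = unname(q[1]),
                          q3 = unname(q[3])),
    n = nrow(table),
    n_enlarging = sum(table$group == "enlarging")),
    class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("cohort: n = %d (%d enlarging), growth %.1f +/- %.1f mm/yr, median %.1f (%.1f-%.1f)\n",
              x$n, x$n_enlarging, x$growth_mean_sd["mean"],
              x$growth_mean_sd["sd"], x$growth_median_iqr["median"],
              x$growth_median_iqr["q1"], x$growth_median_iqr["q3"]))
  for (m in names(x$comparisons)) {
    cat(sprintf("- %s: ", m)); print(x$comparisons[[m]])
  }
  invisible(x)
}
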