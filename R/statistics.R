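# Cohort-level statistics: two-group comparisons, one-way ANOVA with
# Bonferroni-corrected pairwise contrasts, proportion tests, and uni-/
# multivariate regression of ECV on covariates.

.new_test_result <- function(method, statistic, df, p_value, summaries,
                             extra = list()) {
  structure(c(list(method = method, statistic = unname(statistic),
                   df = unname(df), p_value = unname(p_value),
                   summaries = summaries), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(format(x$df), collapse = ","), x$p_value))
  if (!is.null(x$summaries)) print(x$summaries)
  invisible(x)
}

#' Two-group comparison of a continuous variable
#'
#' Two-sided comparison with group summaries (mean +- SD). Default is the
#' pooled-variance Student's t-test; Welch's t and the Mann-Whitney
#' (Wilcoxon rank-sum) test are available as the non-parametric fallback.
#'
#' @param table Data frame, one row per observation.
#' @param value_column Name of the numeric column to compare.
#' @param group_column Name of the grouping column (exactly two levels, each
#'   with >= 2 observations).
#' @param method `"student_t"`, `"welch_t"` or `"mann_whitney"`.
#' @return A `test_result`: statistic, df, two-sided p, per-group summaries.
#' @export
compare_groups <- function(table, value_column, group_column,
                           method = c("student_t", "welch_t", "mann_whitney")) {
  method <- match.arg(method)
  v <- table[[value_column]]; g <- factor(table[[group_column]])
  abort_if(is.null(v) || is.null(table[[group_column]]), "column not found")
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  abort_if(nlevels(g) != 2L, "exactly two groups required, got %d", nlevels(g))
  ns <- tabulate(g)
  abort_if(any(ns < 2L), "each group needs at least 2 observations")
  x <- v[g == levels(g)[1]]; y <- v[g == levels(g)[2]]
  summaries <- data.frame(group = levels(g), n = ns,
                          mean = c(mean(x), mean(y)),
                          sd = c(stats::sd(x), stats::sd(y)))
  if (method == "mann_whitney") {
    ht <- suppressWarnings(stats::wilcox.test(x, y))
    return(.new_test_result("Mann-Whitney U", ht$statistic, NA_real_,
                            ht$p.value, summaries))
  }
  if (identical(x, y)) {
    # degenerate identical samples: zero difference by definition
    return(.new_test_result(
      if (method == "student_t") "Student's t (pooled)" else "Welch's t",
      0, if (method == "student_t") sum(ns) - 2 else NA_real_, 1, summaries))
  }
  ht <- stats::t.test(x, y, var.equal = (method == "student_t"))
  .new_test_result(if (method == "student_t") "Student's t (pooled)" else "Welch's t",
                   ht$statistic, ht$parameter, ht$p.value, summaries)
}

#' One-way ANOVA with Bonferroni-corrected pairwise contrasts
#'
#' Overall F-test across >= 3 levels plus all pairwise pooled t-tests with
#' Bonferroni adjustment (`p_adj = min(1, p_raw * n_pairs)`).
#'
#' @param table Data frame.
#' @param value_column Numeric column name.
#' @param factor_column Factor column name (>= 3 levels, each with >= 2
#'   observations).
#' @return A `test_result` with `pairwise` (data frame of raw and adjusted
#'   pairwise p-values) attached.
#' @export
anova_bonferroni <- function(table, value_column, factor_column) {
  v <- table[[value_column]]; g <- factor(table[[factor_column]])
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  abort_if(nlevels(g) < 3L, "ANOVA requires at least 3 levels")
  abort_if(any(tabulate(g) < 2L), "every level needs at least 2 observations")
  fit <- stats::aov(v ~ g)
  s <- summary(fit)[[1]]
  fstat <- s[["F value"]][1]
  p <- s[["Pr(>F)"]][1]
  if (!is.finite(fstat)) { fstat <- 0; p <- 1 }  # zero between-group variance
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  n_pairs <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(n_pairs), function(j) {
    a <- v[g == pairs[1, j]]; b <- v[g == pairs[2, j]]
    p_raw <- if (identical(a, b)) 1 else
      stats::t.test(a, b, var.equal = TRUE)$p.value
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j], p_raw = p_raw,
               p_adjusted = min(1, p_raw * n_pairs))
  }))
  summaries <- do.call(rbind, lapply(lev, function(l) {
    data.frame(group = l, n = sum(g == l), mean = mean(v[g == l]),
               sd = stats::sd(v[g == l]))
  }))
  .new_test_result("One-way ANOVA (Bonferroni pairwise)", fstat,
                   c(s[["Df"]][1], s[["Df"]][2]), p, summaries,
                   extra = list(pairwise = pw))
}

#' Chi-square test of a 2x2 proportion table
#'
#' Pearson chi-square without continuity correction by default (df = 1); the
#' Yates correction is available behind `correct = TRUE`. All margins must be
#' positive.
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @param correct Apply the continuity correction.
#' @return A `test_result` with per-row proportions as summaries.
#' @export
proportion_test <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  abort_if(!all(dim(counts) == c(2L, 2L)), "a 2x2 count table is required")
  abort_if(any(counts < 0) || any(counts != round(counts)),
           "counts must be non-negative integers")
  abort_if(any(rowSums(counts) == 0) || any(colSums(counts) == 0),
           "all table margins must be positive")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  summaries <- data.frame(row = c(1, 2), n = rowSums(counts),
                          proportion = counts[, 1] / rowSums(counts))
  .new_test_result(paste0("Chi-square", if (correct) " (Yates)" else ""),
                   ht$statistic, ht$parameter, ht$p.value, summaries)
}

#' Uni-/multivariate linear regression of ECV on covariates
#'
#' Univariate mode reports, per predictor, the Pearson correlation R and its
#' p-value. Multivariate mode jointly fits the predictors whose univariate p
#' is below `enter_p` (the screening rule); binary factors are 0/1 encoded.
#' A near-singular design (condition number above `kappa_max`) is flagged,
#' not silently accepted.
#'
#' @param table Data frame.
#' @param response Response column name (numeric).
#' @param predictors Character vector of predictor column names.
#' @param multivariate Fit the joint model after univariate screening.
#' @param enter_p Univariate screening threshold.
#' @param kappa_max Condition-number threshold for the collinearity flag.
#' @return Object of class `regression_result`: `univariate` (data frame
#'   predictor/R/p), and when `multivariate = TRUE` also `coefficients`,
#'   `entered`, `collinear`.
#' @export
regress_ecv <- function(table, response, predictors, multivariate = FALSE,
                        enter_p = 0.05, kappa_max = 1e8) {
  y <- table[[response]]
  abort_if(!is.numeric(y), "response must be numeric")
  enc <- lapply(predictors, function(p) {
    x <- table[[p]]
    abort_if(is.null(x), "predictor '%s' not found", p)
    if (is.numeric(x)) return(x)
    f <- factor(x)
    abort_if(nlevels(f) != 2L, "predictor '%s' must be numeric or binary", p)
    as.numeric(f) - 1
  })
  names(enc) <- predictors
  uni <- do.call(rbind, lapply(predictors, function(p) {
    ct <- stats::cor.test(enc[[p]], y)
    data.frame(predictor = p, R = unname(ct$estimate), p_value = ct$p.value)
  }))
  out <- list(univariate = uni, model = if (multivariate) "multivariate" else "univariate")
  if (multivariate) {
    entered <- uni$predictor[uni$p_value < enter_p]
    out$entered <- entered
    if (length(entered)) {
      X <- do.call(cbind, enc[entered])
      colnames(X) <- entered
      d <- as.data.frame(X)
      d$.y <- y
      fit <- stats::lm(.y ~ ., data = d)
      out$coefficients <- stats::coef(summary(fit))
      Xs <- scale(cbind(1, X), center = FALSE)
      out$collinear <- kappa(Xs, exact = TRUE) > kappa_max
    } else {
      out$coefficients <- NULL
      out$collinear <- FALSE
    }
  }
  structure(out, class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Regression (%s)\n", x$model))
  print(x$univariate)
  if (!is.null(x$coefficients)) print(x$coefficients)
  invisible(x)
}
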