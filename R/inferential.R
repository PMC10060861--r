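#' Welch two-sample t test
#'
#' Unequal-variance t test with Satterthwaite degrees of freedom, the
#' default group-contrast statistic for continuous variables.
#'
#' @param x,y Numeric samples (n >= 2 each).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_x`,
#'   `mean_y`.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("both samples have zero variance; t statistic undefined")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_x = mean(x), mean_y = mean(y)
  )
}

#' Pooled one-way ANOVA F from group summaries
#'
#' Recomputes the two-group pooled-variance F statistic (the square of the
#' pooled t) from printed summary statistics: means, SDs, and group sizes.
#' Useful for checking reported group contrasts when only the summary table
#' is available.
#'
#' @param mean1,sd1,n1 Summary of the first group.
#' @param mean2,sd2,n2 Summary of the second group.
#' @return A one-row tibble: `f`, `df1`, `df2`, `p_value`.
#' @examples
#' anova_f_from_summary(25.36, 3.72, 214, 26.86, 5.40, 133)
#' @export
anova_f_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 == 0) stop("pooled variance is zero; F undefined")
  tstat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  f <- tstat^2
  df2 <- n1 + n2 - 2
  tibble::tibble(f = f, df1 = 1, df2 = df2,
                 p_value = stats::pf(f, 1, df2, lower.tail = FALSE))
}

#' Pearson chi-square for a two-group proportion contrast
#'
#' Rebuilds the 2x2 count table from group sizes and proportions (cells
#' rounded to the nearest integer) and computes the Pearson chi-square
#' without continuity correction.
#'
#' @param p1,n1 Proportion and size of the first group.
#' @param p2,n2 Proportion and size of the second group.
#' @return A one-row tibble: `chi2`, `df`, `p_value`, plus the
#'   reconstructed counts as a `counts` matrix attribute.
#' @examples
#' chi2_from_proportions(0.472, 214, 0.632, 133)
#' @export
chi2_from_proportions <- function(p1, n1, p2, n2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, n1 >= 1, n2 >= 1)
  counts <- rbind(
    c(round(p1 * n1), n1 - round(p1 * n1)),
    c(round(p2 * n2), n2 - round(p2 * n2))
  )
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 1)) warning("expected cell count below 1; chi-square unreliable")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  out <- tibble::tibble(chi2 = unname(ht$statistic), df = unname(ht$parameter),
                        p_value = ht$p.value)
  attr(out, "counts") <- counts
  out
}

#' Partial correlation by the residual method
#'
#' Pearson correlation between the residuals of `x` and `y` after each is
#' regressed on an intercept and the covariates; the p-value uses a t
#' reference with `n - k - 2` degrees of freedom (k covariates). With no
#' covariates this is the ordinary bivariate correlation. Collinear
#' covariate columns are dropped with a warning.
#'
#' @param data Data frame holding all variables.
#' @param x,y Column names of the two variables of interest.
#' @param covariates Character vector of covariate column names (possibly
#'   empty).
#' @return A one-row tibble: `r`, `df`, `p_value`, `n`, `n_covariates`.
#' @export
partial_correlation <- function(data, x, y, covariates = character()) {
  vars <- c(x, y, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "))
  }
  d <- stats::na.omit(as.data.frame(data)[, vars, drop = FALSE])
  # coerce factors/logicals (e.g. sex) to numeric codes
  d[] <- lapply(d, function(v) if (is.numeric(v)) v else as.numeric(as.factor(v)))
  n <- nrow(d)
  Z <- cbind(1, as.matrix(d[, covariates, drop = FALSE]))
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    warning("dropping ", ncol(Z) - qrz$rank, " collinear covariate column(s)")
    qrz <- qr(Z[, sort(qrz$pivot[seq_len(qrz$rank)]), drop = FALSE])
  }
  k <- qrz$rank - 1  # covariates actually used
  if (n <= k + 2) stop("need n > number of covariates + 2")
  rx <- qr.resid(qrz, d[[x]])
  ry <- qr.resid(qrz, d[[y]])
  r <- stats::cor(rx, ry)
  df <- n - k - 2
  tstat <- r * sqrt(df / (1 - r^2))
  tibble::tibble(r = r, df = df,
                 p_value = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
                 n = n, n_covariates = k)
}

#' Multiple regression with standardized coefficients and VIF
#'
#' Fits an ordinary least-squares model of the outcome on the regressors
#' after z-scoring every variable, so the coefficients are standardized
#' betas (invariant to linear rescaling of any variable). The variance
#' inflation factor of each regressor, `1 / (1 - R^2_j)` from regressing it
#' on the other regressors, diagnoses collinearity; values above
#' `vif_flag` are flagged.
#'
#' @param data Data frame holding outcome and regressors.
#' @param outcome Outcome column name.
#' @param regressors Character vector of regressor column names (covariates
#'   are simply further regressors here).
#' @param vif_flag VIF threshold above which a regressor is flagged
#'   (default 10).
#' @return An object of class `std_ols` with [generics::tidy()] and
#'   [generics::glance()] methods; `tidy()` gives one row per regressor
#'   with `estimate` (standardized beta), `std.error`, `statistic`,
#'   `p.value`, `vif`, `vif_flagged`.
#' @export
ols_standardized <- function(data, outcome, regressors, vif_flag = 10) {
  vars <- c(outcome, regressors)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "))
  }
  d <- stats::na.omit(as.data.frame(data)[, vars, drop = FALSE])
  d[] <- lapply(d, function(v) if (is.numeric(v)) v else as.numeric(as.factor(v)))
  if (any(vapply(d, stats::sd, 1) == 0)) {
    stop("constant variable(s) cannot be z-scored: ",
         paste(vars[vapply(d, stats::sd, 1) == 0], collapse = ", "))
  }
  zd <- as.data.frame(scale(d))
  X <- as.matrix(zd[, regressors, drop = FALSE])
  if (qr(cbind(1, X))$rank < length(regressors) + 1) {
    stop("rank-deficient design: regressors are linearly dependent")
  }
  fml <- stats::reformulate(sprintf("`%s`", regressors), sprintf("`%s`", outcome))
  fit <- stats::lm(fml, data = zd)
  coefs <- summary(fit)$coefficients
  vif <- vapply(seq_along(regressors), function(j) {
    if (length(regressors) == 1) return(1)
    rsq <- 1 - sum(stats::lm.fit(cbind(1, X[, -j, drop = FALSE]),
                                 X[, j])$residuals^2) / sum(X[, j]^2)
    1 / (1 - rsq)
  }, numeric(1))
  structure(
    list(
      terms = tibble::tibble(
        term = regressors,
        estimate = unname(coefs[-1, 1]),
        std.error = unname(coefs[-1, 2]),
        statistic = unname(coefs[-1, 3]),
        p.value = unname(coefs[-1, 4]),
        vif = vif,
        vif_flagged = vif > vif_flag
      ),
      r.squared = summary(fit)$r.squared,
      adj.r.squared = summary(fit)$adj.r.squared,
      n = nrow(d),
      outcome = outcome,
      fit = fit
    ),
    class = "std_ols"
  )
}

#' @export
print.std_ols <- function(x, ...) {
  cat("Standardized OLS:", x$outcome, "~", paste(x$terms$term, collapse = " + "),
      sprintf("\n  n = %d, R^2 = %.3f\n", x$n, x$r.squared))
  print(x$terms)
  invisible(x)
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Tests the group effect on an outcome after adjusting for covariates via
#' the linear model `outcome ~ covariates + group`, using the partial F of
#' adding the group factor. Also returns covariate-adjusted group means
#' (predictions at the covariate grand means).
#'
#' @param data Data frame.
#' @param outcome Outcome column name.
#' @param group Grouping column name (factor or character; >= 2 levels
#'   present).
#' @param covariates Character vector of covariate column names.
#' @return A list with `test` (tibble: `f`, `df1`, `df2`, `p_value`) and
#'   `adjusted_means` (tibble: group level, adjusted mean).
#' @export
ancova_group_compare <- function(data, outcome, group, covariates = character()) {
  d <- stats::na.omit(as.data.frame(data)[, c(outcome, group, covariates),
                                          drop = FALSE])
  d[[group]] <- droplevels(as.factor(d[[group]]))
  if (nlevels(d[[group]]) < 2) stop("need at least two non-empty groups")
  d[covariates] <- lapply(d[covariates], function(v) {
    if (is.numeric(v)) v else as.numeric(as.factor(v))
  })
  rhs_red <- if (length(covariates)) sprintf("`%s`", covariates) else "1"
  f_red <- stats::reformulate(rhs_red, sprintf("`%s`", outcome))
  f_full <- stats::reformulate(c(rhs_red[rhs_red != "1"], sprintf("`%s`", group)),
                               sprintf("`%s`", outcome))
  fit_red <- stats::lm(f_red, data = d)
  fit_full <- stats::lm(f_full, data = d)
  an <- stats::anova(fit_red, fit_full)
  if (stats::var(d[[outcome]]) == 0) {
    # degenerate constant outcome: no group effect by definition
    test <- tibble::tibble(f = 0, df1 = an$Df[2], df2 = an$Res.Df[2],
                           p_value = 1)
  } else {
    test <- tibble::tibble(
      f = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2],
      p_value = an$`Pr(>F)`[2]
    )
  }
  newdata <- d[rep(1, nlevels(d[[group]])), , drop = FALSE]
  newdata[[group]] <- factor(levels(d[[group]]), levels = levels(d[[group]]))
  for (cv in covariates) newdata[[cv]] <- mean(d[[cv]])
  adj <- tibble::tibble(
    group = levels(d[[group]]),
    adjusted_mean = unname(stats::predict(fit_full, newdata = newdata))
  )
  list(test = test, adjusted_means = adj)
}

#' Group-contrast summary table
#'
#' Builds a two-group descriptive and inferential summary for a set of
#' continuous variables: per-group mean, SD and n, the Welch t test, and
#' the pooled one-way ANOVA F recomputed from the summaries.
#'
#' @param data Data frame.
#' @param variables Character vector of numeric column names.
#' @param group Grouping column (exactly 2 levels used, in level order).
#' @return A tibble with one row per variable.
#' @export
group_compare_table <- function(data, variables, group) {
  g <- droplevels(as.factor(data[[group]]))
  lev <- levels(g)
  if (length(lev) != 2) stop("group_compare_table expects exactly two groups")
  purrr::map_dfr(variables, function(v) {
    x <- data[[v]][g == lev[1]]
    y <- data[[v]][g == lev[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    wt <- welch_t(x, y)
    fa <- anova_f_from_summary(mean(x), stats::sd(x), length(x),
                               mean(y), stats::sd(y), length(y))
    tibble::tibble(
      variable = v,
      mean_1 = mean(x), sd_1 = stats::sd(x), n_1 = length(x),
      mean_2 = mean(y), sd_2 = stats::sd(y), n_2 = length(y),
      welch_t = wt$statistic, welch_df = wt$df, welch_p = wt$p_value,
      f = fa$f, f_p = fa$p_value
    )
  })
}
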