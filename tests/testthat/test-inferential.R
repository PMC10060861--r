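test_that("Welch t matches the textbook formula and is antisymmetric", {
  set.seed(101)
  for (i in 1:50) {
    x <- rnorm(sample(5:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    got <- welch_t(x, y)
    vx <- var(x) / length(x); vy <- var(y) / length(y)
    t_oracle <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df_oracle <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    expect_equal(got$statistic, t_oracle, tolerance = 1e-12)
    expect_equal(got$df, df_oracle, tolerance = 1e-12)
    swapped <- welch_t(y, x)
    expect_equal(swapped$statistic, -got$statistic, tolerance = 1e-12)
    expect_equal(swapped$p_value, got$p_value, tolerance = 1e-12)
  }
  x <- rnorm(10)
  expect_equal(welch_t(x, x)$statistic, 0)
  expect_error(welch_t(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("pooled ANOVA F from summaries matches direct computation", {
  # equal means give F = 0
  expect_equal(anova_f_from_summary(5, 1, 20, 5, 2, 30)$f, 0)
  expect_error(anova_f_from_summary(1, 0, 10, 1, 0, 10), "pooled variance")

  # F from summaries equals aov on reconstructed data with those summaries
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(12, 1)
    g <- factor(rep(1:2, c(15, 12)))
    f_aov <- unname(summary(stats::aov(c(x, y) ~ g))[[1]]$`F value`[1])
    got <- anova_f_from_summary(mean(x), sd(x), 15, mean(y), sd(y), 12)
    expect_equal(got$f, f_aov, tolerance = 1e-10)
  }
})

test_that("chi-square from proportions matches the Sigma (O-E)^2/E oracle", {
  expect_equal(chi2_from_proportions(0.3, 100, 0.3, 50)$chi2, 0)
  set.seed(13)
  for (i in 1:30) {
    p1 <- runif(1, 0.1, 0.9); p2 <- runif(1, 0.1, 0.9)
    n1 <- sample(30:300, 1); n2 <- sample(30:300, 1)
    got <- chi2_from_proportions(p1, n1, p2, n2)
    counts <- attr(got, "counts")
    expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    expect_equal(got$chi2, sum((counts - expected)^2 / expected),
                 tolerance = 1e-10)
  }
})

test_that("partial correlation equals the precision-matrix identity", {
  set.seed(19)
  n <- 120
  d <- tibble::tibble(x = rnorm(n), y = rnorm(n),
                      c1 = rnorm(n), c2 = rnorm(n))
  d$x <- d$x + 0.5 * d$c1
  d$y <- d$y + 0.5 * d$c1 - 0.3 * d$c2

  # no covariates -> bivariate Pearson
  expect_equal(partial_correlation(d, "x", "y")$r, cor(d$x, d$y),
               tolerance = 1e-12)

  # y driven by the covariates plus noise independent of x -> r ~ 0
  set.seed(20)
  n_big <- 4000
  d2 <- tibble::tibble(x = rnorm(n_big), c1 = rnorm(n_big), c2 = rnorm(n_big))
  d2$x <- d2$x + d2$c1
  d2$y <- 2 * d2$c1 - d2$c2 + rnorm(n_big)
  expect_gt(abs(cor(d2$x, d2$y)), 0.2)  # confounded bivariate association
  expect_lt(abs(partial_correlation(d2, "x", "y", c("c1", "c2"))$r),
            3 / sqrt(n_big))

  # precision-matrix oracle: -P_xy / sqrt(P_xx P_yy)
  for (i in 1:20) {
    set.seed(200 + i)
    dd <- as.data.frame(matrix(rnorm(60 * 4), 60, 4))
    names(dd) <- c("x", "y", "c1", "c2")
    got <- partial_correlation(dd, "x", "y", c("c1", "c2"))
    P <- solve(cor(dd))
    oracle <- -P["x", "y"] / sqrt(P["x", "x"] * P["y", "y"])
    expect_equal(got$r, oracle, tolerance = 1e-10)
  }

  # collinear covariates are dropped with a warning
  d$c3 <- d$c1 * 2
  expect_warning(pc <- partial_correlation(d, "x", "y", c("c1", "c2", "c3")),
                 "collinear")
  expect_equal(pc$r, partial_correlation(d, "x", "y", c("c1", "c2"))$r)
})

test_that("standardized regression identities and VIF hold", {
  set.seed(23)
  n <- 150
  d <- tibble::tibble(y = rnorm(n), a = rnorm(n), b = rnorm(n))
  d$y <- 0.4 * d$a + rnorm(n)

  # single regressor: standardized beta equals Pearson r
  fit1 <- ols_standardized(d, "y", "a")
  expect_equal(tidy(fit1)$estimate, cor(d$y, d$a), tolerance = 1e-12)
  expect_equal(tidy(fit1)$vif, 1)

  # exactly orthogonal centered regressors have VIF exactly 1
  d$ao <- rep_len(c(1, -1), n)
  bo_raw <- rep_len(c(1, 1, -1, -1), n)
  d$bo <- bo_raw - mean(bo_raw)
  stopifnot(abs(sum(d$ao * d$bo)) < 1e-12)
  fit2 <- ols_standardized(d, "y", c("ao", "bo"))
  expect_equal(tidy(fit2)$vif, c(1, 1), tolerance = 1e-10)

  # standardized betas invariant to linear rescaling of inputs
  d$a_resc <- 100 * d$a + 7
  fit3 <- ols_standardized(d, "y", c("a_resc", "b"))
  fit4 <- ols_standardized(d, "y", c("a", "b"))
  expect_equal(tidy(fit3)$estimate, tidy(fit4)$estimate, tolerance = 1e-10)

  # duplicated regressor -> rank error
  d$a2 <- d$a
  expect_error(ols_standardized(d, "y", c("a", "a2")), "rank-deficient")

  # collinear-but-not-identical regressors produce large flagged VIF
  d$almost <- d$a + rnorm(n, sd = 0.01)
  fit5 <- ols_standardized(d, "y", c("a", "almost"))
  expect_true(all(tidy(fit5)$vif_flagged))
})

test_that("ANCOVA group F reduces to one-way ANOVA and matches the partial-F oracle", {
  set.seed(29)
  n <- 90
  d <- tibble::tibble(y = rnorm(n),
                      g = factor(sample(c("a", "b"), n, TRUE)),
                      c1 = rnorm(n))
  # no covariates: equals one-way ANOVA F
  a0 <- ancova_group_compare(d, "y", "g")
  f_aov <- unname(summary(stats::aov(y ~ g, d))[[1]]$`F value`[1])
  expect_equal(a0$test$f, f_aov, tolerance = 1e-10)

  # identical outcome -> F = 0
  d2 <- d; d2$y <- 5
  expect_equal(ancova_group_compare(d2, "y", "g")$test$f, 0)

  # partial-F oracle from nested RSS
  a1 <- ancova_group_compare(d, "y", "g", "c1")
  rss_red <- sum(resid(lm(y ~ c1, d))^2)
  fit_full <- lm(y ~ c1 + g, d)
  rss_full <- sum(resid(fit_full)^2)
  f_oracle <- (rss_red - rss_full) / (rss_full / df.residual(fit_full))
  expect_equal(a1$test$f, f_oracle, tolerance = 1e-10)
  expect_equal(nrow(a1$adjusted_means), 2)

  expect_error(ancova_group_compare(d[d$g == "a", ], "y", "g"), "two non-empty")
})
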