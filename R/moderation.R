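#' Moderation (interaction) model with percentile-bootstrap CI
#'
#' Fits the moderation model
#' `outcome ~ focal + moderator + focal:moderator + covariates` by ordinary
#' least squares, with the focal predictor and the moderator mean-centered
#' before forming their product (so the lower-order coefficients are
#' conditional effects at the mean). The sampling distribution of the
#' interaction coefficient is obtained by a case-resampling percentile
#' bootstrap; the reported CI is the corresponding quantile interval.
#' Bootstrap resamples with a rank-deficient design are redrawn and the
#' number of redraws reported.
#'
#' @param data Data frame.
#' @param outcome,focal,moderator Column names.
#' @param covariates Character vector of covariate column names.
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param ci_level Confidence level (default 0.95).
#' @param center Mean-center focal and moderator before forming the
#'   interaction (default `TRUE`).
#' @param seed Integer seed making the bootstrap reproducible.
#' @return An object of class `moderation_fit`: coefficient table, `vcov`,
#'   bootstrap CI (`boot_ci`), bootstrap draws of the interaction
#'   (`boot_interaction`), centering constants, observed moderator range,
#'   residual df. Has `tidy()`, `glance()` and `autoplot()` methods.
#' @export
fit_moderation <- function(data, outcome, focal, moderator,
                           covariates = character(), n_boot = 5000,
                           ci_level = 0.95, center = TRUE, seed = 1L) {
  vars <- c(outcome, focal, moderator, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "))
  }
  d <- stats::na.omit(as.data.frame(data)[, vars, drop = FALSE])
  d[] <- lapply(d, function(v) if (is.numeric(v)) v else as.numeric(as.factor(v)))
  n <- nrow(d)
  p <- 4 + length(covariates)
  if (n <= p + 2) stop("need n > number of parameters + 2")

  focal_mean <- if (center) mean(d[[focal]]) else 0
  mod_mean <- if (center) mean(d[[moderator]]) else 0
  fc <- d[[focal]] - focal_mean
  mc <- d[[moderator]] - mod_mean
  X <- cbind(`(Intercept)` = 1, focal = fc, moderator = mc,
             interaction = fc * mc)
  if (length(covariates) > 0) {
    X <- cbind(X, as.matrix(d[, covariates, drop = FALSE]))
  }
  y <- d[[outcome]]
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("rank-deficient moderation design")
  beta <- qr.coef(qrx, y)
  res <- y - X %*% beta
  df_resid <- n - ncol(X)
  sigma2 <- sum(res^2) / df_resid
  XtXinv <- chol2inv(qr.R(qrx))
  vc <- sigma2 * XtXinv
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc))
  tstat <- beta / se
  coef_tab <- tibble::tibble(
    term = colnames(X),
    estimate = unname(beta),
    std.error = unname(se),
    statistic = unname(tstat),
    p.value = 2 * stats::pt(abs(unname(tstat)), df_resid, lower.tail = FALSE)
  )

  # percentile bootstrap over cases for the interaction coefficient
  int_col <- which(colnames(X) == "interaction")
  boot_draws <- numeric(n_boot)
  redraws <- 0L
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      fit_b <- .lm.fit(X[idx, , drop = FALSE], y[idx])
      if (fit_b$rank == ncol(X)) break
      redraws <- redraws + 1L
      if (redraws > 100L * n_boot) stop("bootstrap designs persistently degenerate")
    }
    cb <- fit_b$coefficients
    # .lm.fit pivots columns; map back
    cb_full <- numeric(ncol(X))
    cb_full[fit_b$pivot] <- cb
    boot_draws[b] <- cb_full[int_col]
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  alpha <- 1 - ci_level
  ci <- unname(stats::quantile(boot_draws, c(alpha / 2, 1 - alpha / 2),
                               type = 6))

  structure(
    list(
      coefficients = coef_tab,
      vcov = vc,
      df_resid = df_resid,
      sigma2 = sigma2,
      n = n,
      r.squared = 1 - sum(res^2) / sum((y - mean(y))^2),
      boot_ci = ci,
      boot_interaction = boot_draws,
      n_boot = n_boot,
      n_redraws = redraws,
      ci_level = ci_level,
      seed = seed,
      centered = center,
      focal_mean = focal_mean,
      mod_mean = mod_mean,
      moderator_range = range(d[[moderator]]),
      variables = list(outcome = outcome, focal = focal,
                       moderator = moderator, covariates = covariates)
    ),
    class = "moderation_fit"
  )
}

#' @export
print.moderation_fit <- function(x, ...) {
  v <- x$variables
  cat(sprintf("Moderation model: %s ~ %s * %s%s (n = %d)\n", v$outcome,
              v$focal, v$moderator,
              if (length(v$covariates)) paste0(" + ",
                paste(v$covariates, collapse = " + ")) else "", x$n))
  print(x$coefficients)
  cat(sprintf("Interaction %d%%%% percentile bootstrap CI (%d resamples): [%.4f, %.4f]\n",
              round(100 * x$ci_level), x$n_boot, x$boot_ci[1], x$boot_ci[2]))
  invisible(x)
}

#' Conditional effect of the focal predictor at a moderator value
#'
#' @param fit A `moderation_fit`.
#' @param moderator_values Moderator values on the raw scale.
#' @param alpha Significance level for the pointwise CI.
#' @return Tibble with `moderator`, `effect`, `se`, `statistic`,
#'   `p_value`, `conf.low`, `conf.high`.
#' @export
conditional_effect <- function(fit, moderator_values, alpha = 0.05) {
  stopifnot(inherits(fit, "moderation_fit"))
  w <- moderator_values - fit$mod_mean
  b <- fit$coefficients$estimate
  names(b) <- fit$coefficients$term
  v <- fit$vcov
  eff <- b["focal"] + b["interaction"] * w
  se <- sqrt(v["focal", "focal"] + 2 * w * v["focal", "interaction"] +
               w^2 * v["interaction", "interaction"])
  tcrit <- stats::qt(1 - alpha / 2, fit$df_resid)
  tibble::tibble(
    moderator = moderator_values,
    effect = unname(eff),
    se = unname(se),
    statistic = unname(eff / se),
    p_value = 2 * stats::pt(abs(unname(eff / se)), fit$df_resid,
                            lower.tail = FALSE),
    conf.low = unname(eff - tcrit * se),
    conf.high = unname(eff + tcrit * se)
  )
}

#' Johnson-Neyman region of significance
#'
#' Finds the moderator values at which the conditional effect of the focal
#' predictor switches between significant and non-significant: the real
#' roots of `(b1 + b3 w)^2 = t_crit^2 * Var(b1 + b3 w)`, a quadratic in the
#' (centered) moderator `w`. Roots are reported on the raw moderator scale
#' and restricted to `moderator_range` (default: the observed range); the
#' significance of each segment between boundaries is evaluated at its
#' midpoint.
#'
#' @param fit A `moderation_fit`.
#' @param moderator_range Length-2 numeric range to search (raw scale).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `jn_result`: tibble `boundaries`
#'   (`moderator`, 0-2 rows), tibble `segments` (`lower`, `upper`,
#'   `significant`, `sign`), plus `alpha` and the range searched.
#' @export
johnson_neyman <- function(fit, moderator_range = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "moderation_fit"))
  if (is.null(moderator_range)) moderator_range <- fit$moderator_range
  stopifnot(length(moderator_range) == 2, diff(moderator_range) > 0)
  v <- fit$vcov
  ev <- eigen(v[c("focal", "interaction"), c("focal", "interaction")],
              symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("coefficient covariance not positive definite")
  b <- fit$coefficients$estimate
  names(b) <- fit$coefficients$term
  b1 <- unname(b["focal"]); b3 <- unname(b["interaction"])
  v11 <- v["focal", "focal"]; v13 <- v["focal", "interaction"]
  v33 <- v["interaction", "interaction"]
  t2 <- stats::qt(1 - alpha / 2, fit$df_resid)^2
  # quadratic a w^2 + 2 c w + e = 0 in centered moderator w
  a <- b3^2 - t2 * v33
  cc <- b1 * b3 - t2 * v13
  e <- b1^2 - t2 * v11
  roots <- numeric(0)
  if (abs(a) < 1e-300 * max(1, abs(cc), abs(e))) {
    if (cc != 0) roots <- -e / (2 * cc)
  } else {
    disc <- cc^2 - a * e
    if (disc >= 0) roots <- (-cc + c(-1, 1) * sqrt(disc)) / a
  }
  raw <- sort(roots) + fit$mod_mean
  in_range <- raw >= moderator_range[1] & raw <= moderator_range[2]
  boundaries <- raw[in_range]

  edges <- c(moderator_range[1], boundaries, moderator_range[2])
  segs <- purrr::map_dfr(seq_len(length(edges) - 1), function(i) {
    mid <- (edges[i] + edges[i + 1]) / 2
    ce <- conditional_effect(fit, mid, alpha)
    tibble::tibble(lower = edges[i], upper = edges[i + 1],
                   significant = ce$p_value < alpha,
                   sign = sign(ce$effect))
  })
  structure(
    list(
      boundaries = tibble::tibble(moderator = boundaries),
      segments = segs,
      alpha = alpha,
      moderator_range = moderator_range,
      fit = fit
    ),
    class = "jn_result"
  )
}

#' @export
print.jn_result <- function(x, ...) {
  if (nrow(x$boundaries) == 0) {
    cat("Johnson-Neyman: no significance boundary in the moderator range [",
        sprintf("%.3f, %.3f", x$moderator_range[1], x$moderator_range[2]),
        "]\n", sep = "")
  } else {
    cat("Johnson-Neyman boundaries at alpha =", x$alpha, ":",
        sprintf("%.4f", x$boundaries$moderator), "\n")
  }
  print(x$segments)
  invisible(x)
}
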