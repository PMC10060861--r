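#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a standardized OLS fit
#'
#' @param x A `std_ols` object from [ols_standardized()].
#' @param ... Unused.
#' @return One row per regressor: standardized `estimate`, `std.error`,
#'   `statistic`, `p.value`, `vif`, `vif_flagged`.
#' @method tidy std_ols
#' @export
tidy.std_ols <- function(x, ...) x$terms

#' @rdname tidy.std_ols
#' @return For `glance()`: a one-row tibble with `r.squared`,
#'   `adj.r.squared`, `n`.
#' @method glance std_ols
#' @export
glance.std_ols <- function(x, ...) {
  tibble::tibble(r.squared = x$r.squared, adj.r.squared = x$adj.r.squared,
                 n = x$n)
}

#' Tidy a moderation fit
#'
#' @param x A `moderation_fit` from [fit_moderation()].
#' @param ... Unused.
#' @return Coefficient tibble; the `interaction` row additionally carries
#'   the percentile-bootstrap `conf.low` / `conf.high`.
#' @method tidy moderation_fit
#' @export
tidy.moderation_fit <- function(x, ...) {
  out <- x$coefficients
  out$conf.low <- ifelse(out$term == "interaction", x$boot_ci[1], NA_real_)
  out$conf.high <- ifelse(out$term == "interaction", x$boot_ci[2], NA_real_)
  out
}

#' @rdname tidy.moderation_fit
#' @return For `glance()`: one-row tibble with `n`, `r.squared`,
#'   `df.residual`, `n_boot`, `ci_level`, `n_redraws`.
#' @export
glance.moderation_fit <- function(x, ...) {
  tibble::tibble(n = x$n, r.squared = x$r.squared, df.residual = x$df_resid,
                 n_boot = x$n_boot, ci_level = x$ci_level,
                 n_redraws = x$n_redraws)
}
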