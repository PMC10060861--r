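#' Plot a segregation profile
#'
#' Bar chart of per-network system segregation, annotated with the
#' within/between connectivity values.
#'
#' @param object A `segregation_profile` tibble from
#'   [compute_segregation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot segregation_profile
#' @export
autoplot.segregation_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$network, .data$sys),
                               y = .data$sys)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "System segregation (W - B) / W") +
    ggplot2::theme_minimal()
}

#' Johnson-Neyman plot
#'
#' Conditional effect of the focal predictor across the moderator range
#' with its pointwise confidence band; vertical lines mark the
#' Johnson-Neyman boundaries and shading marks the region(s) of
#' significance.
#'
#' @param object A `jn_result` from [johnson_neyman()].
#' @param n_points Grid resolution for the effect curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot jn_result
#' @export
autoplot.jn_result <- function(object, n_points = 200, ...) {
  grid <- seq(object$moderator_range[1], object$moderator_range[2],
              length.out = n_points)
  ce <- conditional_effect(object$fit, grid, object$alpha)
  sig <- object$segments[object$segments$significant, , drop = FALSE]
  p <- ggplot2::ggplot(ce, ggplot2::aes(x = .data$moderator, y = .data$effect))
  if (nrow(sig) > 0) {
    p <- p + ggplot2::geom_rect(
      data = sig, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                   ymin = -Inf, ymax = Inf),
      fill = "firebrick", alpha = 0.08)
  }
  p <- p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed")
  if (nrow(object$boundaries) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = object$boundaries$moderator,
                                 linetype = "dotted", colour = "firebrick")
  }
  v <- object$fit$variables
  p + ggplot2::labs(x = v$moderator,
                    y = sprintf("Conditional effect of %s", v$focal)) +
    ggplot2::theme_minimal()
}

#' Simple-slopes plot for a moderation fit
#'
#' Conditional effect of the focal predictor at the moderator mean and one
#' SD above/below, the conventional probe of an interaction.
#'
#' @param object A `moderation_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot moderation_fit
#' @export
autoplot.moderation_fit <- function(object, ...) {
  probes <- object$mod_mean + c(-1, 0, 1) *
    diff(object$moderator_range) / 4
  ce <- conditional_effect(object, probes)
  ce$probe <- factor(c("low", "mean", "high"), levels = c("low", "mean", "high"))
  ggplot2::ggplot(ce, ggplot2::aes(x = .data$probe, y = .data$effect)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = sprintf("%s probe value", object$variables$moderator),
                  y = sprintf("Conditional effect of %s",
                              object$variables$focal)) +
    ggplot2::theme_minimal()
}

#' Plot a framewise-displacement series
#'
#' @param fd Numeric FD vector (mm).
#' @param fd_threshold Threshold line (default 0.5 mm).
#' @return A ggplot object.
#' @export
plot_fd <- function(fd, fd_threshold = 0.5) {
  d <- tibble::tibble(frame = seq_along(fd) + 1, fd = fd)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame, y = .data$fd)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = fd_threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "Volume", y = "Framewise displacement (mm)") +
    ggplot2::theme_minimal()
}
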