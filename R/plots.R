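#' Plot a simulated concentration-time profile
#'
#' Venous plasma concentration against time, on a log10 concentration
#' scale by default.
#'
#' @param object A `pbpk_simulation`.
#' @param log_y Log-scale the concentration axis (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pbpk_simulation <- function(object, log_y = TRUE, ...) {
  d <- object$plasma
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h,
                                       y = .data$conc_ug_per_L)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::labs(x = "Time (h)", y = "Venous plasma concentration (µg/L)",
                  title = object$compound_name) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot an optimization trajectory
#'
#' Cost per evaluation across the coarse-grid and descent phases, with the
#' running minimum overlaid; the flat tail of the running minimum is the
#' visual convergence check.
#'
#' @param object A `pbpk_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pbpk_fit <- function(object, ...) {
  d <- object$trajectory
  d$running_min <- cummin(d$cost)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$eval)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cost, color = .data$phase),
                        alpha = 0.4, size = 0.8) +
    ggplot2::geom_step(ggplot2::aes(y = .data$running_min)) +
    ggplot2::geom_vline(xintercept = object$phase_boundary,
                        linetype = "dashed", alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Evaluation", y = "GMFE cost",
                  title = sprintf("%s (%s)", object$compound_name,
                                  object$method)) +
    ggplot2::theme_minimal()
}

#' Predicted-versus-observed fold-error plot
#'
#' Scatter of predicted against observed PK outputs on log-log axes with
#' identity and fold-threshold guides, one panel per metric.
#'
#' @param object An [accuracy_report()] (needs its `"pairs"` attribute,
#'   present when built by [evaluate_fits()]) or a long pairs tibble from
#'   [pk_pairs()].
#' @param fold Fold guide lines (default 3).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_fold_error <- function(object, fold = 3, ...) {
  pairs <- if (inherits(object, "accuracy_report")) {
    attr(object, "pairs") %||%
      abort_pbpk("report carries no pairs table; pass the pk_pairs tibble",
                 class = "pbpkfit_report_error")
  } else object
  d <- pairs[is.finite(pairs$observed) & is.finite(pairs$predicted) &
               pairs$observed > 0 & pairs$predicted > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$predicted,
                                  color = .data$configuration)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = log10(fold),
                         linetype = "dotted", alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = -log10(fold),
                         linetype = "dotted", alpha = 0.6) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "Observed", y = "Predicted") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
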