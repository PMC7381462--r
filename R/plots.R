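#' Plot methods
#'
#' `autoplot()` methods give the standard diagnostic figures: predicted vs
#' measured scatter for a `panel_model` (or a completed
#' `translation_record`), per-category overlap bars against the chance
#' line for an `overlap_table`, and the cross-cohort correlation scatter
#' for a `concordance_result`.
#'
#' @param object The fitted object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @export
autoplot.panel_model <- function(object, ...) {
  pr <- object$predictions
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$measured,
                                   y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = sprintf("Measured %s (mmol/L)", object$target),
      y = sprintf("Predicted %s (mmol/L)", object$target),
      title = sprintf("%s: %d-lipid panel", object$target,
                      length(object$panel)),
      subtitle = sprintf("test r = %.3f, p = %.2e, MSR = %.3f",
                         object$test_r, object$test_p, object$test_msr)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.translation_record <- function(object, ...) {
  if (is.null(object$model)) {
    abort("Translation record not yet validated; nothing to plot.")
  }
  autoplot(object$model, ...)
}

#' @rdname plots
#' @export
autoplot.overlap_table <- function(object, ...) {
  chance <- 100 / nrow(object)
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category,
                                   y = .data$percentage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = chance, linetype = 2) +
    ggplot2::labs(
      x = NULL, y = "% overlap",
      title = sprintf("Measured vs predicted category overlap (%s)",
                      attr(object, "scheme")),
      subtitle = sprintf("total accuracy %.1f%% (chance %.1f%%)",
                         attr(object, "total_accuracy"), chance)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.concordance_result <- function(object, ...) {
  ggplot2::ggplot(object$shared,
                  ggplot2::aes(x = .data$correlation_a,
                               y = .data$correlation_b)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "Per-lipid correlation, cohort A",
      y = "Per-lipid correlation, cohort B",
      title = "Cross-cohort concordance of univariate associations",
      subtitle = sprintf("r = %.3f over %d shared lipids",
                         object$r, object$n_shared)
    ) +
    ggplot2::theme_minimal()
}
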