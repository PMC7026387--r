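#' Plot methods
#'
#' `autoplot()` methods for the main result types: predicted-vs-experimental
#' scatter for an evaluation, training curves for a fitted model, per-fold
#' metric dot plot for a cross-validation, and mean +- 95% CI for bootstrap
#' summaries.
#'
#' @param object A deepsol result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name deepsol-plots
NULL

#' @rdname deepsol-plots
#' @method autoplot sol_eval
#' @export
autoplot.sol_eval <- function(object, ...) {
  d <- tidy(object)
  lab <- sprintf("n = %d   R² = %.3f   RMSE = %.3f   within 10-fold = %.1f%%",
                 object$n, object$r2, object$rmse, object$pct_within_10fold)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$y, y = .data$y_hat)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_abline(slope = 1, intercept = c(-1, 1), linetype = 3,
                         colour = "grey70") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "experimental logS (mol/L)", y = "predicted logS",
                  subtitle = lab) +
    ggplot2::theme_minimal()
}

#' @rdname deepsol-plots
#' @method autoplot sol_model
#' @export
autoplot.sol_model <- function(object, ...) {
  if (is.null(object$history) || nrow(object$history) == 0) {
    abort_data("model has no training history to plot.")
  }
  d <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "series", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname deepsol-plots
#' @method autoplot sol_cv
#' @export
autoplot.sol_cv <- function(object, ...) {
  d <- tidyr::pivot_longer(object$folds[object$folds$status == "ok", ],
                           c("r2", "rmse"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "held-out fold", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname deepsol-plots
#' @method autoplot sol_bootstrap
#' @export
autoplot.sol_bootstrap <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = NULL, y = "bootstrap mean (95% percentile CI)") +
    ggplot2::theme_minimal()
}
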