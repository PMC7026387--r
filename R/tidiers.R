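#' Tidiers for deepsol objects
#'
#' broom-style accessors: `tidy()` returns the detailed per-unit table
#' (layers, folds, compounds, bootstrap metrics), `glance()` a one-row
#' summary.
#'
#' @param x A deepsol object.
#' @param ... Unused.
#' @return A tibble.
#' @name deepsol-tidiers
NULL

#' @rdname deepsol-tidiers
#' @method tidy sol_model
#' @export
tidy.sol_model <- function(x, ...) layer_audit(x)

#' @rdname deepsol-tidiers
#' @method glance sol_model
#' @export
glance.sol_model <- function(x, ...) {
  audit <- layer_audit(x)
  hist <- x$history
  tibble(
    architecture = if (inherits(x, "sol_resnet")) "resnet" else "dnn",
    n_param_layers = sum(audit$counted),
    n_conv_layers = sum(audit$counted & audit$kind == "conv"),
    n_parameters = n_parameters(x),
    trained = x$trained,
    epochs = if (is.null(hist)) NA_integer_ else nrow(hist),
    best_val_r2 = if (is.null(hist) || nrow(hist) == 0) NA_real_
                  else max(hist$val_r2)
  )
}

#' @rdname deepsol-tidiers
#' @method tidy sol_cv
#' @export
tidy.sol_cv <- function(x, ...) x$folds

#' @rdname deepsol-tidiers
#' @method glance sol_cv
#' @export
glance.sol_cv <- function(x, ...) {
  tibble(k = x$assignment$k,
         folds_ok = sum(x$folds$status == "ok"),
         r2_min = x$ranges$r2[1], r2_max = x$ranges$r2[2],
         rmse_min = x$ranges$rmse[1], rmse_max = x$ranges$rmse[2])
}

#' @rdname deepsol-tidiers
#' @method tidy sol_eval
#' @export
tidy.sol_eval <- function(x, ...) {
  d <- x$data
  has_mw <- all(is.finite(d$molecular_weight)) && all(d$molecular_weight > 0)
  out <- dplyr::mutate(d,
    abs_error = abs(.data$y_hat - .data$y),
    within_10fold = .data$abs_error <= 1)
  if (has_mw) {
    out$category_true <- as.character(classify_category(d$y, d$molecular_weight))
    out$category_pred <- as.character(classify_category(d$y_hat, d$molecular_weight))
  }
  out
}

#' @rdname deepsol-tidiers
#' @method glance sol_eval
#' @export
glance.sol_eval <- function(x, ...) {
  tibble(n = x$n, r2 = x$r2, rmse = x$rmse,
         pct_within_10fold = x$pct_within_10fold,
         category_accuracy = x$category_accuracy)
}

#' @rdname deepsol-tidiers
#' @method tidy sol_bootstrap
#' @export
tidy.sol_bootstrap <- function(x, ...) as_tibble(x)

#' @rdname deepsol-tidiers
#' @method tidy curated_tbl
#' @export
tidy.curated_tbl <- function(x, ...) as_tibble(x)

#' @rdname deepsol-tidiers
#' @method glance curated_tbl
#' @export
glance.curated_tbl <- function(x, ...) {
  tibble(n_records = nrow(x), n_censored = sum(x$censored),
         n_provenance = nrow(provenance(x)),
         log_s_min = suppressWarnings(min(x$log_s, na.rm = TRUE)),
         log_s_max = suppressWarnings(max(x$log_s, na.rm = TRUE)))
}
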