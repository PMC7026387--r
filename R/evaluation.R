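#' Regression metrics for logS prediction
#'
#' `r_squared()` is the coefficient of determination
#' `1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)`; it can take any value
#' from minus infinity up to 1 and is computed on the raw predictions (no
#' refitting). `rmse()` is the square root of the mean squared error.
#' `pct_within_10fold()` is the percentage of compounds whose predicted
#' solubility lies within a factor of 10 of experiment: one unit in log10,
#' counted inclusively (`|y_hat - y| <= 1`).
#'
#' @param y Experimental logS values.
#' @param y_hat Predicted logS values, same length.
#' @return A single number (`r_squared` unbounded below; `rmse >= 0`;
#'   `pct_within_10fold` in `[0, 100]`).
#' @export
r_squared <- function(y, y_hat) {
  check_paired(y, y_hat)
  if (length(y) < 2L) abort_data("r_squared needs n >= 2.")
  sst <- sum((y - mean(y))^2)
  if (sst <= .Machine$double.eps * length(y)) {
    abort_data("r_squared is undefined when the observed values have zero variance.")
  }
  1 - sum((y - y_hat)^2) / sst
}

#' @rdname r_squared
#' @export
rmse <- function(y, y_hat) {
  check_paired(y, y_hat)
  sqrt(mean((y - y_hat)^2))
}

#' @rdname r_squared
#' @export
pct_within_10fold <- function(y, y_hat) {
  check_paired(y, y_hat)
  100 * mean(abs(y_hat - y) <= 1)
}

check_paired <- function(y, y_hat) {
  if (length(y) != length(y_hat)) abort_data("y and y_hat must have the same length.")
  if (length(y) == 0L) abort_data("empty input.")
  if (any(!is.finite(y)) || any(!is.finite(y_hat))) {
    abort_data("metrics require finite y and y_hat.")
  }
  invisible(TRUE)
}

#' Coarse solubility categories
#'
#' Converts logS (log10 mol/L) to g/L as `10^log_s * MW` and bins it into
#' the four pharmacopoeia-style categories: practically insoluble
#' (< 0.1 g/L), slightly soluble (0.1 to 10 g/L), soluble (10 to 100 g/L)
#' and freely soluble (>= 100 g/L). Interval lower bounds are inclusive, so
#' exactly 0.1 g/L is slightly soluble; the four bins partition every
#' positive value exactly once.
#'
#' @param log_s Finite logS value(s), log10 mol/L.
#' @param molecular_weight Positive molecular weight(s), g/mol.
#' @return Factor with levels `practically_insoluble`, `slightly_soluble`,
#'   `soluble`, `freely_soluble`.
#' @export
classify_category <- function(log_s, molecular_weight) {
  if (any(!is.finite(log_s))) abort_data("log_s must be finite.")
  mw <- rep_len(as.numeric(molecular_weight), length(log_s))
  if (any(!is.finite(mw)) || any(mw <= 0)) {
    abort_data("molecular_weight must be positive and finite.")
  }
  g_per_l <- 10^log_s * mw
  cut(g_per_l, breaks = c(0, 0.1, 10, 100, Inf), right = FALSE,
      labels = solubility_categories())
}

#' @rdname classify_category
#' @export
solubility_categories <- function() {
  c("practically_insoluble", "slightly_soluble", "soluble", "freely_soluble")
}

#' @rdname classify_category
#' @param y,y_hat Experimental and predicted logS vectors.
#' @return `category_accuracy()`: percentage of compounds whose predicted
#'   and experimental categories agree.
#' @export
category_accuracy <- function(y, y_hat, molecular_weight) {
  check_paired(y, y_hat)
  100 * mean(classify_category(y, molecular_weight) ==
               classify_category(y_hat, molecular_weight))
}

#' Evaluate predictions against experimental logS
#'
#' Computes the full metric panel on a table of paired values. Category
#' accuracy is included when a molecular-weight column is present.
#'
#' @param data Data frame with columns `y` (experimental logS) and `y_hat`
#'   (predicted logS); optional `molecular_weight` and `compound_id`.
#' @return A `sol_eval` object; see [tidy()] for the per-compound table and
#'   [glance()] for the one-row metric summary.
#' @export
evaluate_predictions <- function(data) {
  data <- as_tibble(data)
  if (!all(c("y", "y_hat") %in% names(data))) {
    abort_config("`data` must contain columns y and y_hat.")
  }
  y <- data$y
  y_hat <- data$y_hat
  check_paired(y, y_hat)
  mw <- if ("molecular_weight" %in% names(data)) data$molecular_weight
        else rep(NA_real_, length(y))
  has_mw <- all(is.finite(mw)) && all(mw > 0)
  ids <- if ("compound_id" %in% names(data)) data$compound_id
         else sprintf("row%05d", seq_along(y))
  out <- list(
    data = tibble(compound_id = ids, y = y, y_hat = y_hat,
                  molecular_weight = mw),
    n = length(y),
    r2 = if (length(y) >= 2 && sum((y - mean(y))^2) > .Machine$double.eps * length(y))
      r_squared(y, y_hat) else NA_real_,
    rmse = rmse(y, y_hat),
    pct_within_10fold = pct_within_10fold(y, y_hat),
    category_accuracy = if (has_mw) category_accuracy(y, y_hat, mw) else NA_real_
  )
  structure(out, class = "sol_eval")
}

#' Display an R-squared value the way report tables do
#'
#' Small positive R-squared values are conventionally reported as `"<0.2"`;
#' this is presentation only — the raw value is always retained.
#'
#' @param r2 Numeric R-squared value(s).
#' @param floor_at Display floor (default 0.2).
#' @return Character vector.
#' @export
format_r2 <- function(r2, floor_at = 0.2) {
  ifelse(is.finite(r2) & r2 < floor_at, paste0("<", format(floor_at)),
         formatC(r2, digits = 3, format = "f"))
}

#' @export
print.sol_eval <- function(x, ...) {
  cat(sprintf("# Evaluation of %d compounds\n", x$n))
  cat(sprintf("#   R^2 %s | RMSE %.3f | within 10-fold %.1f%%",
              if (is.na(x$r2)) "NA" else sprintf("%.3f", x$r2),
              x$rmse, x$pct_within_10fold))
  if (!is.na(x$category_accuracy)) {
    cat(sprintf(" | category accuracy %.1f%%", x$category_accuracy))
  }
  cat("\n")
  invisible(x)
}

#' Bootstrap summaries of R-squared and RMSE
#'
#' Resamples (y, y_hat) pairs with replacement `b` times (seeded) and
#' summarises each metric by its mean, standard deviation and percentile 95%
#' confidence interval. Resamples with zero variance in the resampled `y`
#' leave R-squared undefined; they are skipped and counted (`b_used`).
#'
#' @param y,y_hat Paired logS vectors, n >= 2.
#' @param b Number of bootstrap resamples (default 10,000).
#' @param seed Integer seed.
#' @return A `sol_bootstrap` tibble: one row per metric with columns
#'   `metric`, `b`, `b_used`, `mean`, `sd`, `ci_low`, `ci_high`, `seed`.
#' @export
bootstrap_metrics <- function(y, y_hat, b = 10000L, seed = 1L) {
  check_paired(y, y_hat)
  n <- length(y)
  if (n < 2L) abort_data("bootstrap needs n >= 2.")
  b <- as.integer(b)
  if (b < 1L) abort_config("b must be at least 1.")
  idx <- withr::with_seed(as.integer(seed),
                          matrix(sample.int(n, n * b, replace = TRUE), n, b))
  Y <- matrix(y[idx], n, b)
  Yh <- matrix(y_hat[idx], n, b)
  sse <- colSums((Y - Yh)^2)
  m <- colMeans(Y)
  sst <- colSums(Y^2) - n * m^2
  ok <- sst > .Machine$double.eps * n
  if (!any(ok)) abort_data("all bootstrap resamples had zero variance in y.")
  r2 <- 1 - sse[ok] / sst[ok]
  rmse_b <- sqrt(sse / n)
  summarise_one <- function(metric, v) {
    ci <- unname(quantile(v, c(0.025, 0.975), type = 7))
    tibble(metric = metric, b = b, b_used = length(v),
           mean = mean(v), sd = if (length(v) > 1L) sd(v) else 0,
           ci_low = ci[1], ci_high = ci[2], seed = as.integer(seed))
  }
  out <- dplyr::bind_rows(summarise_one("r2", r2),
                          summarise_one("rmse", rmse_b))
  class(out) <- c("sol_bootstrap", class(out))
  out
}
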