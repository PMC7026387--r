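#' k-fold cross-validation of a solubility regressor
#'
#' Splits the data into `k` near-equal folds ([make_folds()]) on rows sorted
#' by compound id (so the assignment is invariant to input row order), trains
#' one independently initialized model per fold on the remaining folds, and
#' evaluates it on the held-out fold. Per-fold failures are caught, marked
#' and do not stop the remaining folds. Results are reported per fold plus
#' min-max ranges of R-squared and RMSE, mirroring the conventional
#' "R^2 = a-b" cross-validation reporting style.
#'
#' @param arch A [resnet_spec()] or [dnn_spec()].
#' @param data A `feature_matrix`.
#' @param k Fold count (>= 2).
#' @param config A [train_config()]; fold `i` trains with seed
#'   `config$seed + i`.
#' @return A `sol_cv` object: `$folds` (tibble of per-fold metrics and
#'   status), `$reports` (list of `sol_eval`), `$ranges`, `$assignment`,
#'   `$arch`, `$config`.
#' @export
cross_validate <- function(arch, data, k = 10L, config = train_config()) {
  stopifnot(inherits(data, "feature_matrix"))
  ord <- order(data$ids)
  data <- fm_subset(data, ord)
  n <- nrow(data$x)
  folds <- make_folds(n, k, config$seed)
  rows <- list()
  reports <- vector("list", k)
  for (i in seq_len(k)) {
    te <- which(folds$fold_of == i)
    tr <- which(folds$fold_of != i)
    fold_config <- config
    fold_config$seed <- config$seed + i
    res <- tryCatch({
      fit <- train_model(arch, fm_subset(data, tr), fold_config)
      pred <- predict(fit, fm_subset(data, te))
      rep <- evaluate_predictions(tibble(
        compound_id = data$ids[te], y = data$y[te], y_hat = unname(pred),
        molecular_weight = data$mw[te]))
      list(report = rep, status = "ok", error = NA_character_,
           epochs = nrow(fit$history))
    }, error = function(e) {
      list(report = NULL, status = "failed", error = conditionMessage(e),
           epochs = NA_integer_)
    })
    reports[[i]] <- res$report
    rows[[i]] <- tibble(
      fold = i, n_test = length(te), status = res$status,
      r2 = if (is.null(res$report)) NA_real_ else res$report$r2,
      rmse = if (is.null(res$report)) NA_real_ else res$report$rmse,
      pct_within_10fold = if (is.null(res$report)) NA_real_
                          else res$report$pct_within_10fold,
      epochs = res$epochs, error = res$error
    )
  }
  folds_tbl <- dplyr::bind_rows(rows)
  ok <- folds_tbl$status == "ok"
  ranges <- list(
    r2 = if (any(ok)) range(folds_tbl$r2[ok]) else c(NA_real_, NA_real_),
    rmse = if (any(ok)) range(folds_tbl$rmse[ok]) else c(NA_real_, NA_real_)
  )
  structure(list(folds = folds_tbl, reports = reports, ranges = ranges,
                 assignment = folds, arch = arch, config = config),
            class = "sol_cv")
}

#' @export
print.sol_cv <- function(x, ...) {
  ok <- sum(x$folds$status == "ok")
  cat(sprintf("# %d-fold cross-validation (%d folds ok)\n", x$assignment$k, ok))
  if (ok > 0) {
    cat(sprintf("#   R^2 = %.3f-%.3f, RMSE = %.3f-%.3f\n",
                x$ranges$r2[1], x$ranges$r2[2],
                x$ranges$rmse[1], x$ranges$rmse[2]))
  }
  invisible(x)
}
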