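#' Grid search over training hyperparameters
#'
#' Hyperparameter optimisation driver in the style used for these models:
#' every row of `grid` overrides fields of the base [train_config()] (and,
#' for columns named like [resnet_spec()]/[dnn_spec()] fields, of the
#' architecture spec), the model is trained on a seeded train/test split,
#' and the held-out metric panel is reported per configuration. No
#' automated tuner: the grid is explicit and every cell is evaluated.
#'
#' @param spec A [resnet_spec()] or [dnn_spec()] giving the base
#'   architecture.
#' @param data A `feature_matrix`.
#' @param grid Data frame; each column names a `train_config` or spec field,
#'   each row is one configuration to evaluate.
#' @param config Base [train_config()].
#' @param test_fraction Held-out fraction used to score each configuration.
#' @return A tibble: the grid columns plus `r2`, `rmse`,
#'   `pct_within_10fold`, `epochs` and `status` per configuration, sorted
#'   by decreasing held-out `r2`.
#' @export
grid_search <- function(spec, data, grid, config = train_config(),
                        test_fraction = 0.1) {
  stopifnot(inherits(data, "feature_matrix"))
  grid <- as_tibble(grid)
  if (nrow(grid) == 0) abort_config("`grid` must contain at least one row.")
  cfg_fields <- names(config)
  spec_fields <- names(spec)
  unknown <- setdiff(names(grid), c(cfg_fields, spec_fields))
  if (length(unknown) > 0) {
    abort_config(paste0("unknown grid column(s): ",
                        paste(unknown, collapse = ", ")))
  }
  sp <- split_train_test(nrow(data$x), test_fraction, config$seed)
  tr <- fm_subset(data, sp$train)
  te <- fm_subset(data, sp$test)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    cfg_i <- config
    spec_i <- spec
    for (nm in names(grid)) {
      if (nm %in% cfg_fields) cfg_i[[nm]] <- grid[[nm]][i]
      else spec_i[[nm]] <- grid[[nm]][i]
    }
    res <- tryCatch({
      fit <- train_model(spec_i, tr, cfg_i)
      pred <- predict(fit, te)
      tibble(r2 = r_squared(te$y, unname(pred)),
             rmse = rmse(te$y, unname(pred)),
             pct_within_10fold = pct_within_10fold(te$y, unname(pred)),
             epochs = nrow(fit$history), status = "ok")
    }, error = function(e) {
      tibble(r2 = NA_real_, rmse = NA_real_, pct_within_10fold = NA_real_,
             epochs = NA_integer_, status = conditionMessage(e))
    })
    dplyr::bind_cols(grid[i, ], res)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$r2))
}
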