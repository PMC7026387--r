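#' Negative R-squared training loss
#'
#' The least-squares objective used to train the solubility regressors:
#' `-(1 - SSE/SStot)` over the given batch, where `SSE = sum((y - y_hat)^2)`
#' and `SStot = sum((y - mean(y))^2)`. Minimising it is equivalent to
#' minimising SSE for a fixed batch. A batch with (numerically) zero target
#' variance falls back to plain `SSE/n` with a logged notice rather than
#' producing NaN; the returned value carries a `"degenerate"` attribute in
#' that case.
#'
#' @param predicted,observed Equal-length numeric vectors, length >= 2 for
#'   the R-squared form.
#' @param quiet Suppress the degenerate-batch notice.
#' @return Scalar loss (`-1` for a perfect fit, `0` for predicting the batch
#'   mean).
#' @export
neg_r2_loss <- function(predicted, observed, quiet = FALSE) {
  if (length(predicted) != length(observed)) {
    abort_data("predicted and observed must have the same length.")
  }
  if (length(observed) < 2L) abort_data("neg_r2_loss needs n >= 2.")
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  if (sst <= .Machine$double.eps * length(observed)) {
    if (!quiet) inform("neg_r2_loss: zero target variance in batch; using SSE/n.")
    out <- sse / length(observed)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  sse / sst - 1
}

# loss value + gradient wrt predictions, for the training loop
loss_grad <- function(predicted, observed, loss = c("neg_r2", "mse")) {
  loss <- match.arg(loss)
  n <- length(observed)
  r <- predicted - observed
  if (loss == "mse") {
    return(list(value = sum(r^2) / n, grad = 2 * r / n))
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst <= .Machine$double.eps * n) {
    return(list(value = sum(r^2) / n, grad = 2 * r / n, degenerate = TRUE))
  }
  list(value = sum(r^2) / sst - 1, grad = 2 * r / sst)
}

#' Random 90/10-style train/test split
#'
#' Seed-deterministic partition of `1:n` with `round(n * test_fraction)`
#' test indices (9,943 compounds at 0.1 give 994 test / 8,949 train).
#'
#' @param n Number of records (>= 2).
#' @param test_fraction Fraction held out, strictly between 0 and 1.
#' @param seed Integer seed.
#' @return List with sorted integer vectors `train` and `test`.
#' @export
split_train_test <- function(n, test_fraction = 0.1, seed = 1L) {
  n <- as.integer(n)
  if (n < 2L) abort_data("need at least 2 records to split.")
  if (!(test_fraction > 0 && test_fraction < 1)) {
    abort_config("test_fraction must lie strictly between 0 and 1.")
  }
  n_test <- as.integer(round(n * test_fraction))
  if (n_test < 1L || n_test >= n) {
    abort_data(sprintf("degenerate split: %d of %d records in test.", n_test, n))
  }
  test <- withr::with_seed(as.integer(seed), sort(sample.int(n, n_test)))
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Random k-fold assignment
#'
#' Partitions `1:n` into `k` folds whose sizes differ by at most one
#' (9,943 records in 10 folds give 7 folds of 994 and 3 of 995), via a
#' seed-deterministic permutation.
#'
#' @param n Number of records.
#' @param k Fold count, `2 <= k <= n`.
#' @param seed Integer seed.
#' @return A `fold_assignment`: list with `n`, `k`, `seed` and `fold_of`
#'   (integer vector of fold ids `1..k` per record).
#' @export
make_folds <- function(n, k, seed = 1L) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (k < 2L) abort_config("k must be at least 2.")
  if (n < k) abort_data(sprintf("cannot split %d records into %d folds.", n, k))
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold_of <- integer(n)
  fold_of[perm] <- rep(seq_len(k), times = sizes)
  structure(list(n = n, k = k, seed = as.integer(seed), fold_of = fold_of),
            class = "fold_assignment")
}

#' Training configuration
#'
#' Defaults: Adam, learning rate 3e-3 with a plateau schedule (multiplied
#' by `lr_factor` whenever the validation metric stalls for `lr_patience`
#' epochs), batch size 64, at most 200 epochs, early stopping with patience
#' 20 on an inner 10% validation slice of the training data,
#' negative-R-squared loss. Batch composition is reshuffled every epoch
#' (seeded); `batch_size >= 2` is required for the negative-R-squared loss
#' so batch variance is definable.
#'
#' @param optimizer `"adam"` or `"sgd"`.
#' @param learning_rate Positive step size.
#' @param batch_size Minibatch size (>= 2 when `loss = "neg_r2"`).
#' @param max_epochs Maximum epochs (0 returns the initialized model).
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (`Inf` disables).
#' @param lr_patience Epochs without validation improvement before the
#'   learning rate is multiplied by `lr_factor` (plateau schedule; `Inf`
#'   disables).
#' @param lr_factor Multiplicative learning-rate decay on plateau.
#' @param l2_lambda Optional override of the spec's L2 coefficient.
#' @param val_fraction Inner validation fraction of the training data.
#' @param loss `"neg_r2"` (default) or `"mse"`.
#' @param seed Integer seed for initialization, the validation slice, batch
#'   shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), learning_rate = 3e-3,
                         batch_size = 64L, max_epochs = 200L,
                         early_stop_patience = 20L, lr_patience = 5L,
                         lr_factor = 0.3, l2_lambda = NULL,
                         val_fraction = 0.1, loss = c("neg_r2", "mse"),
                         seed = 1L) {
  optimizer <- match.arg(optimizer)
  loss <- match.arg(loss)
  if (learning_rate <= 0) abort_config("learning_rate must be positive.")
  batch_size <- as.integer(batch_size)
  if (batch_size < 1L) abort_config("batch_size must be positive.")
  if (loss == "neg_r2" && batch_size < 2L) {
    abort_config("batch_size must be >= 2 with the neg_r2 loss (batch variance must be definable).")
  }
  if (!(lr_factor > 0 && lr_factor <= 1)) {
    abort_config("lr_factor must lie in (0, 1].")
  }
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = batch_size, max_epochs = as.integer(max_epochs),
                 early_stop_patience = early_stop_patience,
                 lr_patience = lr_patience, lr_factor = lr_factor,
                 l2_lambda = l2_lambda, val_fraction = val_fraction,
                 loss = loss, seed = as.integer(seed)),
            class = "train_config")
}

#' Train a solubility regressor
#'
#' Minibatch training with the configured optimizer and loss, an inner
#' validation slice for early stopping (best-validation weights are
#' restored), and full seed determinism: one seed fixes the weight
#' initialization, the validation slice, every epoch's batch composition
#' and the dropout masks, so two runs with the same seed produce identical
#' histories on one platform (single-threaded BLAS assumed).
#'
#' @param arch A [resnet_spec()]/[dnn_spec()], or an already-built
#'   `sol_model` whose weights are used as the starting point.
#' @param data A `feature_matrix` ([align_features()] or
#'   [generate_dataset()]).
#' @param config A [train_config()].
#' @param verbose Print one line per epoch to stderr.
#' @return The trained `sol_model`, with `$history` (tibble: epoch,
#'   train_loss, val_r2, val_rmse) and `$trained = TRUE`.
#' @export
train_model <- function(arch, data, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(data, "feature_matrix"), inherits(config, "train_config"))
  model <- if (inherits(arch, "sol_model")) {
    arch
  } else {
    build_model(arch, input_length = ncol(data$x), seed = config$seed)
  }
  n <- nrow(data$x)
  if (n < 2L) abort_data("training data must contain at least 2 rows.")
  lambda <- config$l2_lambda %||% model$spec$l2_lambda
  history <- tibble(epoch = integer(), train_loss = numeric(),
                    val_r2 = numeric(), val_rmse = numeric())
  if (config$max_epochs == 0L) {
    model$history <- history
    return(model)
  }

  withr::with_seed(config$seed + 1L, {
    n_val <- max(2L, as.integer(round(n * config$val_fraction)))
    if (n_val >= n - 1L) abort_data("training data too small for the validation slice.")
    val_idx <- sort(sample.int(n, n_val))
  })
  tr_idx <- setdiff(seq_len(n), val_idx)
  x_tr <- data$x[tr_idx, , drop = FALSE]
  y_tr <- data$y[tr_idx]
  x_val <- data$x[val_idx, , drop = FALSE]
  y_val <- data$y[val_idx]

  params <- model$params
  state <- model$bn_state
  opt_state <- adam_init(params)
  stepper <- if (config$optimizer == "adam") adam_step_one else sgd_step_one
  best <- list(val_r2 = -Inf, params = params, state = state, epoch = 0L)
  stall <- 0L
  lr_stall <- 0L
  lr <- config$learning_rate
  lr_patience <- config$lr_patience %||% Inf
  t_step <- 0L
  n_tr <- length(tr_idx)

  withr::with_seed(config$seed + 2L, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      starts <- seq(1L, n_tr, by = config$batch_size)
      # fold a trailing singleton into the previous batch
      if (length(starts) > 1L && n_tr - starts[length(starts)] + 1L < 2L) {
        starts <- starts[-length(starts)]
      }
      epoch_loss <- 0
      n_batches <- 0L
      for (s in starts) {
        e <- min(s + config$batch_size - 1L, n_tr)
        idx <- ord[s:e]
        model$params <- params
        model$bn_state <- state
        if (inherits(model, "sol_resnet")) {
          st <- resnet_step(model, x_tr[idx, , drop = FALSE], y_tr[idx],
                            training = TRUE, want_grads = TRUE,
                            loss = config$loss)
          state <- st$state
          loss_value <- st$loss
          grads <- st$grads
        } else {
          fw <- model_forward(model, x_tr[idx, , drop = FALSE], training = TRUE)
          state <- fw$state
          lg <- loss_grad(fw$pred, y_tr[idx], config$loss)
          loss_value <- lg$value
          grads <- if (is.finite(loss_value))
            model_backward(model, fw$cache, lg$grad) else NULL
        }
        if (!is.finite(loss_value)) {
          abort_numeric(sprintf(
            "non-finite loss at epoch %d (learning_rate %g, batch %d); try a smaller learning rate or init_scale.",
            epoch, config$learning_rate, n_batches + 1L))
        }
        if (config$optimizer == "sgd") {
          grads <- l2_add_grads(grads, params, lambda)
        }
        t_step <- t_step + 1L
        upd <- optim_walk(params, grads, opt_state, stepper, lr, t_step)
        params <- upd$p
        opt_state <- upd$s
        if (config$optimizer == "adam") {
          params <- l2_decay_params(params, lambda, lr)
        }
        epoch_loss <- epoch_loss + loss_value
        n_batches <- n_batches + 1L
      }
      model$params <- params
      model$bn_state <- state
      val_pred <- predict(model, x_val)
      v_r2 <- r_squared(y_val, val_pred)
      v_rmse <- rmse(y_val, val_pred)
      history <- dplyr::bind_rows(history, tibble(
        epoch = epoch, train_loss = epoch_loss / n_batches,
        val_r2 = v_r2, val_rmse = v_rmse))
      if (verbose) {
        message(sprintf("epoch %3d  train_loss %8.4f  val_r2 %7.4f  val_rmse %6.4f",
                        epoch, epoch_loss / n_batches, v_r2, v_rmse))
      }
      if (v_r2 > best$val_r2) {
        best <- list(val_r2 = v_r2, params = params, state = state,
                     epoch = epoch)
        stall <- 0L
        lr_stall <- 0L
      } else {
        stall <- stall + 1L
        lr_stall <- lr_stall + 1L
        if (stall >= config$early_stop_patience) break
        if (lr_stall >= lr_patience) {
          lr <- max(lr * config$lr_factor, 1e-6)
          lr_stall <- 0L
          if (verbose) message(sprintf("  lr -> %g", lr))
        }
      }
    }
  })
  model$params <- best$params
  model$bn_state <- best$state
  model$trained <- TRUE
  model$history <- history
  model$best_epoch <- best$epoch
  model$train_config <- config
  model
}
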