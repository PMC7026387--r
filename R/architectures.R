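#' Declare a vector-form residual CNN regressor
#'
#' Describes an N-parameter-layer residual 1D CNN mapping an 881-bit
#' fingerprint to a scalar logS: one stem convolution, a stack of
#' two-convolution pre-activation residual blocks arranged in stages whose
#' channel widths follow `stage_channels` (default 9 -> 18 -> 36), and a
#' single fully connected output layer. N counts the stem, the block
#' convolutions and the output layer; projection shortcuts (used where a
#' stage transition changes dimensions) are parameterised but not counted,
#' so an N-layer spec has N-1 convolutional layers plus 1 fully connected
#' layer. Valid depths satisfy `(N - 2) %% (2 * length(stage_channels)) == 0`:
#' 8, 14, 20 and 26 with three stages.
#'
#' @param n_param_layers Total parameter layers N (default 20).
#' @param stage_channels Strictly increasing channel widths per stage.
#' @param stem_kernel,block_kernel Odd kernel sizes (defaults 7 and 3).
#' @param downsample_stride Stride of the first convolution (and projection
#'   shortcut) of each stage after the first (default 2).
#' @param activation `"relu"` (default), `"sigmoid"` or `"softmax"`.
#' @param weight_init Only `"uniform_scaled"` (fan-in-scaled uniform).
#' @param init_scale Multiplier on the `sqrt(6/fan_in)` init limit.
#' @param l2_lambda Weight-decay coefficient for conv/dense weight matrices
#'   (decoupled decay under Adam, multiplying weights by
#'   `1 - learning_rate * l2_lambda` each step; classic L2-in-gradient under
#'   SGD). Default 1, selected by planted-signal recovery on synthetic data.
#' @param use_batch_norm Include batch normalisation (default `TRUE`).
#' @param head `"flatten"` (default; the fully connected layer sees every
#'   position of the final feature map) or `"gap"` (global average pooling
#'   first).
#' @return A `resnet_spec` object.
#' @export
resnet_spec <- function(n_param_layers = 20L, stage_channels = c(9L, 18L, 36L),
                        stem_kernel = 7L, block_kernel = 3L,
                        downsample_stride = 2L, activation = "relu",
                        weight_init = "uniform_scaled", init_scale = 1,
                        l2_lambda = 1, use_batch_norm = TRUE,
                        head = "flatten") {
  n <- as.integer(n_param_layers)
  if (n < 2L) abort_config("n_param_layers must be >= 2 (stem + output layer).")
  n_res <- n - 2L
  if (n_res %% 2L != 0L) {
    abort_config(sprintf(
      "invalid depth %d: after the stem conv and the fully connected layer, %d layers remain, which is not divisible by the 2 convolutions per residual block.",
      n, n_res))
  }
  n_blocks <- n_res %/% 2L
  n_stages <- length(stage_channels)
  if (n_blocks %% n_stages != 0L) {
    abort_config(sprintf(
      "invalid depth %d: %d residual blocks cannot be spread evenly over %d stages; (N-2)/2 must be a multiple of %d.",
      n, n_blocks, n_stages, n_stages))
  }
  if (n_stages < 1L || any(diff(stage_channels) <= 0)) {
    abort_config("stage_channels must be strictly increasing.")
  }
  if (!activation %in% c("relu", "sigmoid", "softmax")) {
    abort_config("activation must be relu, sigmoid or softmax.")
  }
  if (!identical(weight_init, "uniform_scaled")) {
    abort_config("only uniform_scaled weight initialization is supported.")
  }
  if (!head %in% c("flatten", "gap")) abort_config("head must be flatten or gap.")
  if (l2_lambda < 0) abort_config("l2_lambda must be non-negative.")
  structure(list(
    n_param_layers = n, stage_channels = as.integer(stage_channels),
    stem_kernel = as.integer(stem_kernel),
    block_kernel = as.integer(block_kernel),
    downsample_stride = as.integer(downsample_stride),
    activation = activation, weight_init = weight_init,
    init_scale = init_scale, l2_lambda = l2_lambda,
    use_batch_norm = isTRUE(use_batch_norm), head = head
  ), class = "resnet_spec")
}

#' Declare a fully connected (DNN) baseline regressor
#'
#' The shallow-net baseline: a plain multilayer perceptron on the 881-bit
#' fingerprint with ReLU activations, dropout and L2 regularisation. The
#' default follows the 4-hidden-layer reference configuration with hidden
#' sizes 512, 1024, 2048, 4096, L2 0.001 and dropout 0.5; `hidden_sizes =
#' 512` gives the 1-layer baseline. Baselines are conventionally named by
#' their hidden-layer count.
#'
#' @param hidden_sizes Positive integers, one per hidden layer.
#' @param l2_lambda L2 coefficient (default 0.001).
#' @param dropout_rate Dropout probability in `[0, 1]` (default 0.5).
#' @param activation Hidden activation (default `"relu"`).
#' @param init_scale Multiplier on the fan-in-scaled uniform init limit.
#' @return A `dnn_spec` object.
#' @export
dnn_spec <- function(hidden_sizes = c(512L, 1024L, 2048L, 4096L),
                     l2_lambda = 0.001, dropout_rate = 0.5,
                     activation = "relu", init_scale = 1) {
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) == 0L) {
    abort_config("hidden_sizes must declare at least one hidden layer.")
  }
  if (any(hidden_sizes <= 0L)) abort_config("hidden sizes must be positive.")
  if (dropout_rate < 0 || dropout_rate > 1) {
    abort_config("dropout_rate must lie in [0, 1].")
  }
  if (!activation %in% c("relu", "sigmoid", "softmax")) {
    abort_config("activation must be relu, sigmoid or softmax.")
  }
  structure(list(hidden_sizes = hidden_sizes, l2_lambda = l2_lambda,
                 dropout_rate = dropout_rate, activation = activation,
                 init_scale = init_scale),
            class = "dnn_spec")
}

# ---- geometry ---------------------------------------------------------------

conv_geo <- function(l_in, c_in, c_out, k, stride, pad = (k - 1L) %/% 2L) {
  l_out <- (l_in + 2L * pad - k) %/% stride + 1L
  list(l_in = as.integer(l_in), l_out = as.integer(l_out),
       c_in = as.integer(c_in), c_out = as.integer(c_out),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad))
}

resolve_resnet_geometry <- function(spec, input_length) {
  ch <- spec$stage_channels
  n_blocks <- (spec$n_param_layers - 2L) %/% 2L
  per_stage <- n_blocks %/% length(ch)
  stem <- conv_geo(input_length, 1L, ch[1], spec$stem_kernel, 1L)
  blocks <- list()
  l <- stem$l_out
  c_prev <- ch[1]
  for (s in seq_along(ch)) {
    for (b in seq_len(per_stage)) {
      down <- s > 1L && b == 1L
      stride1 <- if (down) spec$downsample_stride else 1L
      g1 <- conv_geo(l, c_prev, ch[s], spec$block_kernel, stride1)
      g2 <- conv_geo(g1$l_out, ch[s], ch[s], spec$block_kernel, 1L)
      proj <- if (stride1 != 1L || c_prev != ch[s]) {
        conv_geo(l, c_prev, ch[s], 1L, stride1, pad = 0L)
      }
      blocks[[length(blocks) + 1L]] <-
        list(stage = s, conv1 = g1, conv2 = g2, proj = proj)
      l <- g2$l_out
      c_prev <- ch[s]
    }
  }
  names(blocks) <- paste0("block", seq_along(blocks))
  feat <- if (spec$head == "flatten") c_prev * l else c_prev
  list(stem = stem, blocks = blocks, final_channels = c_prev,
       final_length = l, n_features = as.integer(feat))
}

# ---- builders ---------------------------------------------------------------

#' Build an untrained model from a spec
#'
#' Instantiates weights (fan-in-scaled uniform initialization, seeded) and a
#' per-layer audit. The audit of a residual CNN contains exactly
#' `n_param_layers - 1` counted convolution layers plus one fully connected
#' layer; projection shortcuts appear with `counted = FALSE`.
#'
#' @param spec A [resnet_spec()] or [dnn_spec()].
#' @param input_length Input vector length (default 881).
#' @param seed Integer seed for weight initialization.
#' @return A `sol_model` object (untrained).
#' @export
build_model <- function(spec, input_length = fingerprint_length(), seed = 0L) {
  if (inherits(spec, "resnet_spec")) {
    build_resnet(spec, input_length, seed)
  } else if (inherits(spec, "dnn_spec")) {
    build_dnn(spec, input_length, seed)
  } else {
    abort_config("spec must be a resnet_spec or dnn_spec.")
  }
}

#' @rdname build_model
#' @export
build_resnet <- function(spec, input_length = fingerprint_length(), seed = 0L) {
  stopifnot(inherits(spec, "resnet_spec"))
  geo <- resolve_resnet_geometry(spec, input_length)
  sc <- spec$init_scale
  withr::with_seed(as.integer(seed), {
    params <- list(stem = init_conv(geo$stem$k, 1L, geo$stem$c_out, sc))
    state <- list()
    blocks <- list()
    bstate <- list()
    for (nm in names(geo$blocks)) {
      g <- geo$blocks[[nm]]
      blk <- list(
        bn1 = if (spec$use_batch_norm) init_bn(g$conv1$c_in),
        conv1 = init_conv(g$conv1$k, g$conv1$c_in, g$conv1$c_out, sc),
        bn2 = if (spec$use_batch_norm) init_bn(g$conv2$c_in),
        conv2 = init_conv(g$conv2$k, g$conv2$c_in, g$conv2$c_out, sc),
        proj = if (!is.null(g$proj)) init_conv(1L, g$proj$c_in, g$proj$c_out, sc)
      )
      blocks[[nm]] <- blk[!vapply(blk, is.null, logical(1))]
      st <- list(
        bn1 = if (spec$use_batch_norm) init_bn_state(g$conv1$c_in),
        bn2 = if (spec$use_batch_norm) init_bn_state(g$conv2$c_in)
      )
      bstate[[nm]] <- st[!vapply(st, is.null, logical(1))]
    }
    params$blocks <- blocks
    if (spec$use_batch_norm) {
      params$bn_final <- init_bn(geo$final_channels)
      state$bn_final <- init_bn_state(geo$final_channels)
    }
    state$blocks <- bstate
    params$fc <- init_dense(geo$n_features, 1L, sc)
  })
  audit <- resnet_audit(spec, geo)
  structure(list(spec = spec, input_length = as.integer(input_length),
                 geometry = geo, params = params, bn_state = state,
                 layer_audit = audit, trained = FALSE, history = NULL,
                 seed = as.integer(seed)),
            class = c("sol_resnet", "sol_model"))
}

#' @rdname build_model
#' @export
build_dnn <- function(spec, input_length = fingerprint_length(), seed = 0L) {
  stopifnot(inherits(spec, "dnn_spec"))
  sizes <- c(input_length, spec$hidden_sizes, 1L)
  withr::with_seed(as.integer(seed), {
    layers <- list()
    for (i in seq_len(length(sizes) - 1L)) {
      layers[[paste0("dense", i)]] <-
        init_dense(sizes[i], sizes[i + 1L], spec$init_scale)
    }
  })
  audit <- dnn_audit(spec, input_length)
  structure(list(spec = spec, input_length = as.integer(input_length),
                 sizes = as.integer(sizes), params = layers, bn_state = list(),
                 layer_audit = audit, trained = FALSE, history = NULL,
                 seed = as.integer(seed)),
            class = c("sol_dnn", "sol_model"))
}

resnet_audit <- function(spec, geo) {
  row <- function(layer, kind, g, counted) {
    tibble(layer = layer, kind = kind,
           in_shape = sprintf("%dx%d", g$c_in, g$l_in),
           out_shape = sprintf("%dx%d", g$c_out, g$l_out),
           kernel = g$k, stride = g$stride,
           n_params = g$c_out * (g$k * g$c_in + 1L), counted = counted)
  }
  out <- row("stem", "conv", geo$stem, TRUE)
  for (nm in names(geo$blocks)) {
    g <- geo$blocks[[nm]]
    out <- dplyr::bind_rows(
      out,
      row(paste0(nm, ".conv1"), "conv", g$conv1, TRUE),
      row(paste0(nm, ".conv2"), "conv", g$conv2, TRUE),
      if (!is.null(g$proj)) row(paste0(nm, ".proj"), "conv_projection", g$proj, FALSE)
    )
  }
  fc <- tibble(layer = "fc", kind = "dense",
               in_shape = as.character(geo$n_features), out_shape = "1",
               kernel = NA_integer_, stride = NA_integer_,
               n_params = geo$n_features + 1L, counted = TRUE)
  dplyr::bind_rows(out, fc)
}

dnn_audit <- function(spec, input_length) {
  sizes <- c(input_length, spec$hidden_sizes, 1L)
  tibble(
    layer = paste0("dense", seq_len(length(sizes) - 1L)),
    kind = "dense",
    in_shape = as.character(sizes[-length(sizes)]),
    out_shape = as.character(sizes[-1]),
    kernel = NA_integer_, stride = NA_integer_,
    n_params = sizes[-length(sizes)] * sizes[-1] + sizes[-1],
    counted = TRUE
  )
}

#' Layer audit of a model
#'
#' One row per parameter layer (plus projection shortcuts, marked
#' `counted = FALSE`), with shapes and parameter counts.
#'
#' @param model A `sol_model`.
#' @return A tibble.
#' @export
layer_audit <- function(model) {
  stopifnot(inherits(model, "sol_model"))
  model$layer_audit
}

#' Total number of trainable parameters
#' @param model A `sol_model`.
#' @return Integer count over all tensors (conv, dense, batch norm,
#'   projections).
#' @export
n_parameters <- function(model) {
  tot <- 0L
  walk <- function(x) {
    if (is.numeric(x)) tot <<- tot + length(x)
    else if (is.list(x)) for (el in x) walk(el)
  }
  walk(model$params)
  tot
}

# ---- forward / backward: residual CNN ---------------------------------------

# activations flow as (L*B x C) matrices; see nn_core.R for the layout
resnet_forward <- function(model, xmat, training = FALSE, trace = FALSE) {
  spec <- model$spec
  geo <- model$geometry
  params <- model$params
  state <- model$bn_state
  B <- nrow(xmat)
  act <- spec$activation
  use_bn <- spec$use_batch_norm
  X <- matrix(as.numeric(t(xmat)), ncol = 1L)

  cache <- list()
  stem <- conv_fwd(X, params$stem, geo$stem, B)
  cache$stem <- stem
  x <- stem$Y
  blocks_cache <- list()
  traces <- list()
  for (nm in names(geo$blocks)) {
    g <- geo$blocks[[nm]]
    p <- params$blocks[[nm]]
    bc <- list()
    if (use_bn) {
      b1 <- bn_act_fwd(x, p$bn1, state$blocks[[nm]]$bn1, act, training)
      state$blocks[[nm]]$bn1 <- b1$state
      bc$bn1 <- b1$cache
      h <- b1$Y
    } else {
      a1 <- cact_fwd(x, act)
      bc$act1 <- a1$Y
      h <- a1$Y
    }
    c1 <- conv_fwd(h, p$conv1, g$conv1, B)
    bc$conv1 <- c1
    h <- c1$Y
    if (use_bn) {
      b2 <- bn_act_fwd(h, p$bn2, state$blocks[[nm]]$bn2, act, training)
      state$blocks[[nm]]$bn2 <- b2$state
      bc$bn2 <- b2$cache
      h <- b2$Y
    } else {
      a2 <- cact_fwd(h, act)
      bc$act2 <- a2$Y
      h <- a2$Y
    }
    c2 <- conv_fwd(h, p$conv2, g$conv2, B)
    bc$conv2 <- c2
    sc <- if (!is.null(g$proj)) {
      pr <- conv_fwd(x, p$proj, g$proj, B)
      bc$proj <- pr
      pr$Y
    } else {
      x
    }
    x <- c2$Y + sc
    if (trace) traces[[nm]] <- list(out = x, shortcut = sc)
    blocks_cache[[nm]] <- bc
  }
  cache$blocks <- blocks_cache
  if (use_bn) {
    bf <- bn_act_fwd(x, params$bn_final, state$bn_final, act, training)
    state$bn_final <- bf$state
    cache$bn_final <- bf$cache
    x <- bf$Y
  } else {
    af <- cact_fwd(x, act)
    cache$act_final <- af$Y
    x <- af$Y
  }
  # head: (Lf*B x Cf) -> per-sample feature columns
  cf <- geo$final_channels
  lf <- geo$final_length
  if (spec$head == "flatten") {
    H <- array(x, c(lf, B, cf))
    H <- aperm(H, c(1L, 3L, 2L))
    dim(H) <- c(lf * cf, B)
  } else { # global average pooling over positions
    H <- t(colMeans(array(x, c(lf, B, cf)), dims = 1L))
  }
  dn <- dense_fwd(H, params$fc)
  cache$fc <- dn
  list(pred = as.numeric(dn$Y), cache = cache, state = state,
       trace = if (trace) traces)
}

resnet_backward <- function(model, cache, dpred) {
  spec <- model$spec
  geo <- model$geometry
  params <- model$params
  act <- spec$activation
  use_bn <- spec$use_batch_norm
  B <- length(dpred)
  grads <- list()

  dfc <- dense_bwd(cache$fc, params$fc, matrix(dpred, nrow = 1L))
  grads$fc <- list(W = dfc$dW, b = dfc$db)
  cf <- geo$final_channels
  lf <- geo$final_length
  if (spec$head == "flatten") {
    dx <- array(dfc$dX, c(lf, cf, B))
    dx <- aperm(dx, c(1L, 3L, 2L))
    dim(dx) <- c(lf * B, cf)
  } else {
    dx <- matrix(rep(as.numeric(t(dfc$dX)) / lf, each = lf), lf * B, cf)
  }
  if (use_bn) {
    bb <- bn_act_bwd(cache$bn_final, params$bn_final, act, dx)
    grads$bn_final <- list(gamma = as.numeric(bb$dgamma),
                           beta = as.numeric(bb$dbeta))
    dx <- bb$dX
  } else {
    dx <- cact_bwd(dx, cache$act_final, act)
  }
  gblocks <- list()
  for (nm in rev(names(geo$blocks))) {
    g <- geo$blocks[[nm]]
    p <- params$blocks[[nm]]
    bc <- cache$blocks[[nm]]
    gb <- list()
    # residual branch
    d2 <- conv_bwd(bc$conv2, p$conv2, g$conv2, B, dx)
    gb$conv2 <- list(W = d2$dW, b = as.numeric(d2$db))
    dh <- d2$dX
    if (use_bn) {
      b2 <- bn_act_bwd(bc$bn2, p$bn2, act, dh)
      gb$bn2 <- list(gamma = as.numeric(b2$dgamma), beta = as.numeric(b2$dbeta))
      dh <- b2$dX
    } else {
      dh <- cact_bwd(dh, bc$act2, act)
    }
    d1 <- conv_bwd(bc$conv1, p$conv1, g$conv1, B, dh)
    gb$conv1 <- list(W = d1$dW, b = as.numeric(d1$db))
    dh <- d1$dX
    if (use_bn) {
      b1 <- bn_act_bwd(bc$bn1, p$bn1, act, dh)
      gb$bn1 <- list(gamma = as.numeric(b1$dgamma), beta = as.numeric(b1$dbeta))
      dh <- b1$dX
    } else {
      dh <- cact_bwd(dh, bc$act1, act)
    }
    # shortcut
    if (!is.null(g$proj)) {
      dpj <- conv_bwd(bc$proj, p$proj, g$proj, B, dx)
      gb$proj <- list(W = dpj$dW, b = as.numeric(dpj$db))
      dsc <- dpj$dX
    } else {
      dsc <- dx
    }
    dx <- dh + dsc
    gblocks[[nm]] <- gb
  }
  grads$blocks <- gblocks[names(geo$blocks)]
  dst <- conv_bwd(cache$stem, params$stem, geo$stem, B, dx, want_dx = FALSE)
  grads$stem <- list(W = dst$dW, b = as.numeric(dst$db))
  grads
}

# ---- forward / backward: DNN ------------------------------------------------

dnn_forward <- function(model, xmat, training = FALSE) {
  spec <- model$spec
  params <- model$params
  H <- t(xmat) # (n_in x B)
  nh <- length(spec$hidden_sizes)
  cache <- list()
  for (i in seq_len(nh)) {
    nm <- paste0("dense", i)
    dn <- dense_fwd(H, params[[nm]])
    af <- act_fwd(dn$Y, spec$activation)
    mask <- NULL
    H <- af$A
    if (training && spec$dropout_rate > 0) {
      keep <- 1 - spec$dropout_rate
      mask <- matrix(rbinom(length(H), 1L, keep), nrow(H)) / keep
      H <- H * mask
    }
    cache[[nm]] <- list(dense = dn, act = af$cache, mask = mask)
  }
  out <- dense_fwd(H, params[[paste0("dense", nh + 1L)]])
  cache$out <- out
  list(pred = as.numeric(out$Y), cache = cache, state = model$bn_state)
}

dnn_backward <- function(model, cache, dpred) {
  spec <- model$spec
  params <- model$params
  nh <- length(spec$hidden_sizes)
  grads <- list()
  nm_out <- paste0("dense", nh + 1L)
  dout <- dense_bwd(cache$out, params[[nm_out]], matrix(dpred, nrow = 1L))
  grads[[nm_out]] <- list(W = dout$dW, b = dout$db)
  dH <- dout$dX
  for (i in rev(seq_len(nh))) {
    nm <- paste0("dense", i)
    cc <- cache[[nm]]
    if (!is.null(cc$mask)) dH <- dH * cc$mask
    dZ <- act_bwd(dH, cc$act, spec$activation)
    dd <- dense_bwd(cc$dense, params[[nm]], dZ)
    grads[[nm]] <- list(W = dd$dW, b = dd$db)
    dH <- dd$dX
  }
  grads[names(params)]
}

model_forward <- function(model, xmat, training = FALSE, ...) {
  if (inherits(model, "sol_resnet")) resnet_forward(model, xmat, training, ...)
  else dnn_forward(model, xmat, training)
}

model_backward <- function(model, cache, dpred) {
  if (inherits(model, "sol_resnet")) resnet_backward(model, cache, dpred)
  else dnn_backward(model, cache, dpred)
}

#' Predict logS for fingerprint inputs
#'
#' Evaluation-mode forward pass (dropout off, batch norm on running
#' statistics): deterministic for fixed weights.
#'
#' @param object A `sol_model` (trained, or untrained if you ask for a
#'   baseline forward pass).
#' @param newdata A `feature_matrix` or a binary matrix with
#'   `input_length` columns.
#' @param batch_size Forward batch size (memory control only).
#' @param ... Unused.
#' @return Named numeric vector of predicted logS values.
#' @export
predict.sol_model <- function(object, newdata, batch_size = 512L, ...) {
  xmat <- if (inherits(newdata, "feature_matrix")) newdata$x else as.matrix(newdata)
  if (ncol(xmat) != object$input_length) {
    abort_data(sprintf("feature length mismatch: model expects %d, got %d.",
                       object$input_length, ncol(xmat)))
  }
  ids <- if (inherits(newdata, "feature_matrix")) newdata$ids else rownames(xmat)
  n <- nrow(xmat)
  if (n == 0) abort_data("no rows to predict.")
  preds <- numeric(n)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    e <- min(s + batch_size - 1L, n)
    xb <- xmat[s:e, , drop = FALSE]
    preds[s:e] <- if (inherits(object, "sol_resnet")) {
      resnet_step(object, xb, training = FALSE)$pred
    } else {
      model_forward(object, xb, training = FALSE)$pred
    }
  }
  if (!is.null(ids)) names(preds) <- ids
  preds
}

#' Zero every residual branch of a residual CNN
#'
#' Diagnostic utility: sets the branch convolution weights and biases of
#' every residual block to zero so each block reduces to its shortcut path.
#' Used to verify the identity-mapping property of the architecture.
#'
#' @param model A `sol_resnet` model.
#' @return The modified model.
#' @export
zero_residual_branches <- function(model) {
  stopifnot(inherits(model, "sol_resnet"))
  for (nm in names(model$params$blocks)) {
    for (cv in c("conv1", "conv2")) {
      model$params$blocks[[nm]][[cv]]$W[] <- 0
      model$params$blocks[[nm]][[cv]]$b[] <- 0
    }
  }
  model
}

#' @export
print.sol_model <- function(x, ...) {
  kind <- if (inherits(x, "sol_resnet")) {
    sprintf("%d-layer residual CNN (channels %s, head %s)",
            x$spec$n_param_layers,
            paste(x$spec$stage_channels, collapse = "->"), x$spec$head)
  } else {
    sprintf("%d-hidden-layer DNN (sizes %s)", length(x$spec$hidden_sizes),
            paste(x$spec$hidden_sizes, collapse = ", "))
  }
  cat(sprintf("# deepsol model: %s\n", kind))
  cat(sprintf("#   input length %d, %d trainable parameters, %s\n",
              x$input_length, n_parameters(x),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' @export
print.resnet_spec <- function(x, ...) {
  cat(sprintf("# resnet_spec: N = %d (%d conv + 1 fc), channels %s, activation %s\n",
              x$n_param_layers, x$n_param_layers - 1L,
              paste(x$stage_channels, collapse = "->"), x$activation))
  invisible(x)
}

#' @export
print.dnn_spec <- function(x, ...) {
  cat(sprintf("# dnn_spec: hidden sizes %s, dropout %.2f, L2 %g\n",
              paste(x$hidden_sizes, collapse = ", "), x$dropout_rate,
              x$l2_lambda))
  invisible(x)
}
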