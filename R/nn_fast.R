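# Glue for the fused C++ residual-network step (src/conv1d.cpp). Parameters,
# gradients and batch-norm statistics are passed as flat ordered lists; the
# nested R structures stay the interface for the optimizer and checkpoints.

resnet_geo_vectors <- function(model) {
  geo <- model$geometry
  spec <- model$spec
  nb <- length(geo$blocks)
  bg <- matrix(0L, nb, 6L)
  for (i in seq_len(nb)) {
    g <- geo$blocks[[i]]
    bg[i, ] <- c(g$conv1$l_in, g$conv1$c_in, g$conv1$c_out, g$conv1$stride,
                 as.integer(!is.null(g$proj)), g$conv1$l_out)
  }
  gv <- c(geo$stem$l_in, geo$stem$k, geo$stem$c_out, spec$block_kernel, nb,
          geo$final_length, geo$final_channels,
          if (spec$head == "flatten") 0L else 1L,
          act_code(spec$activation), as.integer(spec$use_batch_norm))
  list(gv = as.integer(gv), bg = bg)
}

resnet_pack_params <- function(model) {
  p <- model$params
  use_bn <- model$spec$use_batch_norm
  z <- numeric(0)
  flat <- list(p$stem$W, p$stem$b)
  for (nm in names(p$blocks)) {
    b <- p$blocks[[nm]]
    flat <- c(flat, list(
      if (use_bn) b$bn1$gamma else z, if (use_bn) b$bn1$beta else z,
      b$conv1$W, b$conv1$b,
      if (use_bn) b$bn2$gamma else z, if (use_bn) b$bn2$beta else z,
      b$conv2$W, b$conv2$b))
    if (!is.null(b$proj)) flat <- c(flat, list(b$proj$W, b$proj$b))
  }
  flat <- c(flat, list(
    if (use_bn) p$bn_final$gamma else z, if (use_bn) p$bn_final$beta else z,
    p$fc$W, p$fc$b))
  flat
}

resnet_pack_state <- function(model) {
  if (!model$spec$use_batch_norm) return(list())
  s <- model$bn_state
  flat <- list()
  for (nm in names(s$blocks)) {
    b <- s$blocks[[nm]]
    flat <- c(flat, list(b$bn1$mean, b$bn1$var, b$bn2$mean, b$bn2$var))
  }
  c(flat, list(s$bn_final$mean, s$bn_final$var))
}

resnet_unpack_state <- function(model, flat) {
  if (!model$spec$use_batch_norm) return(model$bn_state)
  s <- model$bn_state
  i <- 1L
  for (nm in names(s$blocks)) {
    s$blocks[[nm]]$bn1$mean <- as.numeric(flat[[i]])
    s$blocks[[nm]]$bn1$var <- as.numeric(flat[[i + 1L]])
    s$blocks[[nm]]$bn2$mean <- as.numeric(flat[[i + 2L]])
    s$blocks[[nm]]$bn2$var <- as.numeric(flat[[i + 3L]])
    i <- i + 4L
  }
  s$bn_final$mean <- as.numeric(flat[[i]])
  s$bn_final$var <- as.numeric(flat[[i + 1L]])
  s
}

resnet_unpack_grads <- function(model, flat) {
  p <- model$params
  use_bn <- model$spec$use_batch_norm
  i <- 1L
  take <- function() {
    v <- flat[[i]]
    i <<- i + 1L
    v
  }
  g <- list()
  g$stem <- list(W = matrix(take(), nrow = nrow(p$stem$W)),
                 b = as.numeric(take()))
  g$blocks <- list()
  for (nm in names(p$blocks)) {
    b <- p$blocks[[nm]]
    gb <- list()
    if (use_bn) {
      gb$bn1 <- list(gamma = as.numeric(take()), beta = as.numeric(take()))
    } else {
      take(); take()
    }
    gb$conv1 <- list(W = matrix(take(), nrow = nrow(b$conv1$W)),
                     b = as.numeric(take()))
    if (use_bn) {
      gb$bn2 <- list(gamma = as.numeric(take()), beta = as.numeric(take()))
    } else {
      take(); take()
    }
    gb$conv2 <- list(W = matrix(take(), nrow = nrow(b$conv2$W)),
                     b = as.numeric(take()))
    if (!is.null(b$proj)) {
      gb$proj <- list(W = matrix(take(), nrow = nrow(b$proj$W)),
                      b = as.numeric(take()))
    }
    # keep optimizer-facing order identical to the parameter order
    g$blocks[[nm]] <- gb[intersect(names(b), names(gb))]
  }
  if (use_bn) {
    g$bn_final <- list(gamma = as.numeric(take()), beta = as.numeric(take()))
  } else {
    take(); take()
  }
  g$fc <- list(W = matrix(take(), nrow = nrow(p$fc$W)), b = as.numeric(take()))
  g[names(p)]
}

# one fused forward(/loss/backward) call; y may be NULL for pure prediction
resnet_step <- function(model, xmat, y = NULL, training = FALSE,
                        want_grads = FALSE, loss = "neg_r2") {
  gvs <- resnet_geo_vectors(model)
  out <- cpp_resnet_step(
    as.numeric(t(xmat)), if (is.null(y)) numeric(nrow(xmat)) else y,
    resnet_pack_params(model), resnet_pack_state(model),
    gvs$gv, gvs$bg, training, if (loss == "mse") 1L else 0L,
    want_grads, 0.1, 1e-5)
  res <- list(pred = as.numeric(out$pred),
              state = resnet_unpack_state(model, out$state))
  if (want_grads) {
    res$loss <- out$loss
    res$grads <- resnet_unpack_grads(model, out$grads)
  }
  res
}
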