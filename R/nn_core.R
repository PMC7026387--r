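# Internal neural-network primitives.
#
# Convolutional activations are stored as (L*B x C) matrices: row (b-1)*L + l
# holds position l of sample b, one column per channel, so channels are
# contiguous per sample and stride-1 im2col is a handful of long memcpys.
# The conv and fused batchnorm+activation kernels live in src/conv1d.cpp;
# dense layers, the DNN path and Adam are plain vectorised R.

# ---- initialization ---------------------------------------------------------

# fan-in-scaled uniform draw: U(-scale*sqrt(6/fan_in), +scale*sqrt(6/fan_in))
init_uniform_scaled <- function(n, fan_in, scale = 1) {
  lim <- scale * sqrt(6 / fan_in)
  runif(n, -lim, lim)
}

init_conv <- function(k, c_in, c_out, scale = 1) {
  list(W = matrix(init_uniform_scaled(c_out * k * c_in, k * c_in, scale),
                  nrow = k * c_in, ncol = c_out),
       b = numeric(c_out))
}

init_dense <- function(n_in, n_out, scale = 1) {
  list(W = matrix(init_uniform_scaled(n_in * n_out, n_in, scale), n_in, n_out),
       b = numeric(n_out))
}

init_bn <- function(c) list(gamma = rep(1, c), beta = numeric(c))
init_bn_state <- function(c) list(mean = numeric(c), var = rep(1, c))

# ---- conv1d (C++ kernels) ---------------------------------------------------

conv_fwd <- function(X, layer, geo, B) {
  cpp_conv1d_forward(X, layer$W, layer$b, geo$l_in, B, geo$k,
                     geo$stride, geo$pad) # list(Y, Xcol)
}

conv_bwd <- function(cache, layer, geo, B, dY, want_dx = TRUE) {
  cpp_conv1d_backward(cache$Xcol, layer$W, dY, geo$l_in, B, geo$k,
                      geo$stride, geo$pad, geo$c_in, want_dx)
}

# ---- fused batch norm + activation (per channel = per column) ---------------

act_code <- function(kind) {
  switch(kind, identity = 0L, relu = 1L, sigmoid = 2L, softmax = 3L,
         abort_config(paste0("unknown activation: ", kind)))
}

bn_act_fwd <- function(X, layer, state, act, training,
                       momentum = 0.1, eps = 1e-5) {
  out <- cpp_bn_act_forward(X, layer$gamma, layer$beta, state$mean, state$var,
                            training, momentum, eps, act_code(act))
  list(Y = out$Y,
       cache = list(Y = out$Y, xhat = out$xhat, istd = as.numeric(out$istd)),
       state = list(mean = as.numeric(out$mean), var = as.numeric(out$var)))
}

bn_act_bwd <- function(cache, layer, act, dA) {
  cpp_bn_act_backward(dA, cache$Y, cache$xhat, cache$istd, layer$gamma,
                      act_code(act))
}

# plain activation (batch-norm-free residual path); acts across columns of
# each row for softmax, matching the (L*B x C) layout
cact_fwd <- function(Z, act) cpp_act_forward(Z, act_code(act))
cact_bwd <- function(dA, Y, act) cpp_act_backward(dA, Y, act_code(act))

# ---- activations for the dense (units x batch) layout -----------------------

act_fwd <- function(Z, kind) {
  switch(kind,
    relu = {
      A <- Z * (Z > 0)
      list(A = A, cache = Z)
    },
    sigmoid = {
      A <- 1 / (1 + exp(-Z))
      list(A = A, cache = A)
    },
    softmax = { # over units, per sample column
      E <- exp(sweep(Z, 2, apply(Z, 2, max)))
      A <- sweep(E, 2, colSums(E), "/")
      list(A = A, cache = A)
    },
    abort_config(paste0("unknown activation: ", kind))
  )
}

act_bwd <- function(dA, cache, kind) {
  switch(kind,
    relu = dA * (cache > 0),
    sigmoid = dA * cache * (1 - cache),
    softmax = {
      s <- colSums(dA * cache)
      cache * sweep(dA, 2, s)
    }
  )
}

# ---- dense ------------------------------------------------------------------

dense_fwd <- function(X, layer) { # X: (n_in x B)
  list(Y = crossprod(layer$W, X) + layer$b, X = X)
}

dense_bwd <- function(cache, layer, dY) {
  list(dX = layer$W %*% dY,
       dW = cache$X %*% t(dY),
       db = rowSums(dY))
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         classes = c("numeric", "matrix", "array"), how = "list")
}

# single-tensor Adam step; called via the recursive walker below
adam_step_one <- function(p, g, s, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  s$m <- beta1 * s$m + (1 - beta1) * g
  s$v <- beta2 * s$v + (1 - beta2) * g * g
  mhat <- s$m / (1 - beta1^t)
  vhat <- s$v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
}

sgd_step_one <- function(p, g, s, lr, t) list(p = p - lr * g, s = s)

# walk params/grads/state in parallel (same nesting); leaves are numeric
optim_walk <- function(params, grads, state, step, lr, t) {
  if (is.numeric(params)) {
    out <- step(params, grads, state, lr, t)
    return(out)
  }
  ps <- params
  ss <- state
  for (nm in names(params)) {
    if (is.null(params[[nm]]) || is.null(grads[[nm]])) next
    r <- optim_walk(params[[nm]], grads[[nm]], state[[nm]], step, lr, t)
    ps[[nm]] <- r$p
    ss[[nm]] <- r$s
  }
  list(p = ps, s = ss)
}

# sum of squares of conv/dense weight matrices (L2 penalty term)
l2_weight_sumsq <- function(params) {
  tot <- 0
  walk <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$W)) tot <<- tot + sum(x$W^2)
      for (el in x) if (is.list(el)) walk(el)
    }
  }
  walk(params)
  tot
}

# add 2*lambda*W to every weight gradient, in the same nesting as params
# (classic L2-in-gradient; used with plain SGD)
l2_add_grads <- function(grads, params, lambda) {
  if (lambda == 0) return(grads)
  walk <- function(g, p) {
    if (is.list(p) && !is.null(p$W)) g$W <- g$W + 2 * lambda * p$W
    if (is.list(p)) {
      for (nm in names(p)) {
        if (is.list(p[[nm]]) && !is.null(g[[nm]])) {
          g[[nm]] <- walk(g[[nm]], p[[nm]])
        }
      }
    }
    g
  }
  walk(grads, params)
}

# decoupled weight decay (the AdamW formulation): shrink conv/dense weight
# matrices directly, leaving the adaptive gradient statistics untouched;
# biases and batch-norm parameters are never decayed
l2_decay_params <- function(params, lambda, lr) {
  if (lambda == 0) return(params)
  f <- 1 - lr * lambda
  walk <- function(p) {
    if (is.list(p)) {
      if (!is.null(p$W)) p$W <- p$W * f
      for (nm in names(p)) if (is.list(p[[nm]])) p[[nm]] <- walk(p[[nm]])
    }
    p
  }
  walk(params)
}
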