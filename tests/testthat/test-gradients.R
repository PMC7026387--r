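# Backpropagation correctness: the R reference implementation is checked
# against central finite differences, and the fused C++ step is checked
# against the R reference, for every architecture variant.

set_param <- function(params, path, i, v) {
  if (length(path) == 1L) {
    params[[path[1]]][i] <- v
    return(params)
  }
  params[[path[1]]] <- set_param(params[[path[1]]], path[-1], i, v)
  params
}

num_vs_analytic <- function(m, x, y, paths, loss = "neg_r2", eps = 1e-6) {
  fw <- deepsol:::model_forward(m, x, training = TRUE)
  lg <- deepsol:::loss_grad(fw$pred, y, loss)
  gr <- deepsol:::model_backward(m, fw$cache, lg$grad)
  worst <- 0
  for (pth in paths) {
    p <- m$params
    g <- gr
    for (k in pth) {
      p <- p[[k]]
      g <- g[[k]]
    }
    idx <- withr::with_seed(1, sample(length(p), min(4L, length(p))))
    for (i in idx) {
      m2 <- m
      m2$params <- set_param(m$params, pth, i, p[i] + eps)
      lp <- deepsol:::loss_grad(
        deepsol:::model_forward(m2, x, training = TRUE)$pred, y, loss)$value
      m2$params <- set_param(m$params, pth, i, p[i] - eps)
      lm <- deepsol:::loss_grad(
        deepsol:::model_forward(m2, x, training = TRUE)$pred, y, loss)$value
      num <- (lp - lm) / (2 * eps)
      worst <- max(worst, abs(num - g[i]) / max(1e-8, abs(num) + abs(g[i])))
    }
  }
  worst
}

test_that("residual-CNN backprop matches finite differences", {
  withr::with_seed(21, {
    x <- matrix(rbinom(5 * 30, 1, 0.3), 5, 30)
    y <- rnorm(5)
  })
  paths <- list(c("stem", "W"), c("blocks", "block1", "conv1", "W"),
                c("blocks", "block2", "proj", "W"),
                c("blocks", "block3", "bn1", "gamma"),
                c("blocks", "block1", "bn2", "beta"),
                c("fc", "W"), c("fc", "b"))
  m <- tiny_resnet(30L)
  expect_lt(num_vs_analytic(m, x, y, paths), 1e-5)
  expect_lt(num_vs_analytic(m, x, y, paths, loss = "mse"), 1e-5)
})

test_that("DNN backprop matches finite differences", {
  withr::with_seed(22, {
    x <- matrix(rbinom(6 * 24, 1, 0.4), 6, 24)
    y <- rnorm(6)
  })
  m <- build_dnn(dnn_spec(hidden_sizes = c(7L, 5L), dropout_rate = 0),
                 input_length = 24L, seed = 5L)
  paths <- list(c("dense1", "W"), c("dense2", "b"), c("dense3", "W"))
  expect_lt(num_vs_analytic(m, x, y, paths), 1e-5)
})

test_that("fused C++ step reproduces the R reference exactly", {
  withr::with_seed(23, {
    x <- matrix(rbinom(6 * 30, 1, 0.3), 6, 30)
    y <- rnorm(6)
  })
  cmp <- function(a, b) {
    if (is.list(a)) {
      return(max(vapply(names(a), function(nm) cmp(a[[nm]], b[[nm]]),
                        numeric(1))))
    }
    max(abs(as.numeric(a) - as.numeric(b)))
  }
  for (use_bn in c(TRUE, FALSE)) {
    for (act in c("relu", "sigmoid", "softmax")) {
      for (head in c("flatten", "gap")) {
        spec <- resnet_spec(8L, stage_channels = c(3L, 5L, 7L),
                            stem_kernel = 5L, activation = act,
                            use_batch_norm = use_bn, head = head)
        m <- build_resnet(spec, input_length = 30L, seed = 11L)
        fw <- deepsol:::resnet_forward(m, x, training = TRUE)
        lg <- deepsol:::loss_grad(fw$pred, y, "neg_r2")
        gr <- deepsol:::resnet_backward(m, fw$cache, lg$grad)
        st <- deepsol:::resnet_step(m, x, y, training = TRUE,
                                    want_grads = TRUE)
        expect_lt(max(abs(fw$pred - st$pred)), 1e-10)
        expect_lt(abs(lg$value - st$loss), 1e-10)
        expect_lt(cmp(gr, st$grads), 1e-8)
        if (use_bn) {
          expect_lt(max(abs(unlist(fw$state) - unlist(st$state))), 1e-12)
        }
        # evaluation-mode forward agrees as well
        fe <- deepsol:::resnet_forward(m, x, training = FALSE)
        se <- deepsol:::resnet_step(m, x, training = FALSE)
        expect_lt(max(abs(fe$pred - se$pred)), 1e-10)
      }
    }
  }
})
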