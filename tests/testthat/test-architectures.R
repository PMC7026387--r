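test_that("layer audits count exactly N parameter layers for every depth", {
  for (n in c(8L, 14L, 20L, 26L)) {
    m <- build_resnet(resnet_spec(n), seed = 1L)
    audit <- layer_audit(m)
    expect_equal(sum(audit$counted), n)
    expect_equal(sum(audit$counted & audit$kind == "conv"), n - 1L)
    expect_equal(sum(audit$counted & audit$kind == "dense"), 1L)
    # projection shortcuts exist but are not counted
    expect_true(all(!audit$counted[audit$kind == "conv_projection"]))
    expect_lt(n_parameters(m), 2e6)
  }
})

test_that("channel progression is non-decreasing and visits 9, 18, 36", {
  m <- build_resnet(resnet_spec(20L), seed = 1L)
  audit <- layer_audit(m)
  conv <- audit[audit$kind == "conv", ]
  out_ch <- as.integer(sub("x.*", "", conv$out_shape))
  expect_true(all(diff(out_ch) >= 0))
  expect_setequal(unique(out_ch), c(9L, 18L, 36L))
})

test_that("depths 14 and 26 differ only in residual-block count", {
  m14 <- build_resnet(resnet_spec(14L), seed = 1L)
  m26 <- build_resnet(resnet_spec(26L), seed = 1L)
  expect_equal(length(m14$geometry$blocks), 6L)
  expect_equal(length(m26$geometry$blocks), 12L)
  expect_equal(m14$geometry$final_channels, m26$geometry$final_channels)
  expect_equal(m14$geometry$final_length, m26$geometry$final_length)
})

test_that("invalid depths raise a spec error explaining the arithmetic", {
  expect_error(resnet_spec(9L), "not divisible",
               class = "deepsol_config_error")
  expect_error(resnet_spec(12L), "multiple of 3",
               class = "deepsol_config_error")
  expect_error(resnet_spec(1L), class = "deepsol_config_error")
  expect_error(resnet_spec(20L, stage_channels = c(9L, 9L, 36L)),
               class = "deepsol_config_error")
})

test_that("a zeroed residual branch makes every block an identity mapping", {
  m <- zero_residual_branches(tiny_resnet(40L))
  withr::with_seed(3, x <- matrix(rbinom(5 * 40, 1, 0.3), 5, 40))
  fw <- deepsol:::resnet_forward(m, x, training = FALSE, trace = TRUE)
  for (tr in fw$trace) {
    expect_equal(max(abs(tr$out - tr$shortcut)), 0)
  }
})

test_that("the default DNN matches the reference baseline configuration", {
  spec <- dnn_spec()
  expect_equal(spec$hidden_sizes, c(512L, 1024L, 2048L, 4096L))
  expect_equal(spec$l2_lambda, 0.001)
  expect_equal(spec$dropout_rate, 0.5)
  m <- build_dnn(spec, seed = 1L)
  audit <- layer_audit(m)
  expect_equal(nrow(audit), 5L) # 4 hidden + 1 output
  expect_equal(as.integer(audit$out_shape[1:4]), c(512L, 1024L, 2048L, 4096L))
  # 1-layer baseline
  m1 <- build_dnn(dnn_spec(hidden_sizes = 512L), seed = 1L)
  expect_equal(nrow(layer_audit(m1)), 2L)
  expect_error(dnn_spec(hidden_sizes = integer()),
               class = "deepsol_config_error")
})

test_that("evaluation-mode prediction is deterministic and shape-checked", {
  m <- tiny_resnet(40L)
  withr::with_seed(8, x <- matrix(rbinom(6 * 40, 1, 0.3), 6, 40))
  p1 <- predict(m, x)
  p2 <- predict(m, x)
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1)))
  expect_error(predict(m, x[, 1:30]), class = "deepsol_data_error")

  md <- build_dnn(dnn_spec(hidden_sizes = c(8L, 4L)), input_length = 40L,
                  seed = 2L)
  expect_identical(predict(md, x), predict(md, x)) # dropout off at eval
})

test_that("permuting input rows permutes predictions identically", {
  m <- tiny_resnet(40L)
  withr::with_seed(9, x <- matrix(rbinom(8 * 40, 1, 0.3), 8, 40))
  perm <- c(5, 1, 8, 2, 7, 3, 6, 4)
  expect_equal(unname(predict(m, x)[perm]), unname(predict(m, x[perm, ])))
})

test_that("a zero-weight output layer predicts its bias everywhere", {
  m <- tiny_resnet(40L)
  m$params$fc$W[] <- 0
  m$params$fc$b[] <- -3.25
  withr::with_seed(10, x <- matrix(rbinom(4 * 40, 1, 0.3), 4, 40))
  expect_equal(unname(predict(m, x)), rep(-3.25, 4))
})

test_that("untrained weight initialization is seed-reproducible", {
  a <- build_resnet(resnet_spec(14L), seed = 7L)
  b <- build_resnet(resnet_spec(14L), seed = 7L)
  expect_identical(a$params, b$params)
  c <- build_resnet(resnet_spec(14L), seed = 8L)
  expect_false(identical(a$params, c$params))
})
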