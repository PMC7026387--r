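test_that("checkpoints round-trip weights, spec and history", {
  fm <- tiny_features(n = 50, seed = 71)
  cfg <- train_config(max_epochs = 2L, batch_size = 16L, seed = 72L)
  fit <- train_model(resnet_spec(8L, stage_channels = c(3L, 5L, 7L),
                                 stem_kernel = 5L), fm, cfg)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_identical(predict(back, fm), predict(fit, fm))
  expect_identical(back$history, fit$history)
  expect_identical(back$spec, fit$spec)
  expect_error(load_checkpoint("nope.ckpt"), class = "deepsol_config_error")
  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), junk)
  expect_error(load_checkpoint(junk), class = "deepsol_data_error")
})

test_that("YAML run configs resolve architecture and training sections", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "architecture:",
    "  kind: resnet",
    "  n_param_layers: 14",
    "training:",
    "  max_epochs: 5",
    "  batch_size: 32",
    "  seed: 99"
  ), path)
  cfg <- read_run_config(path)
  expect_s3_class(cfg$spec, "resnet_spec")
  expect_equal(cfg$spec$n_param_layers, 14L)
  expect_equal(cfg$train$max_epochs, 5L)
  expect_equal(cfg$train$seed, 99L)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("architecture:", "  kind: transformer"), bad)
  expect_error(read_run_config(bad), class = "deepsol_config_error")
  expect_error(read_run_config("missing.yaml"),
               class = "deepsol_config_error")

  dnn <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("architecture:", "  kind: dnn", "  hidden_sizes: [64, 32]"),
             dnn)
  cfg2 <- read_run_config(dnn)
  expect_s3_class(cfg2$spec, "dnn_spec")
  expect_equal(cfg2$spec$hidden_sizes, c(64L, 32L))
})
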