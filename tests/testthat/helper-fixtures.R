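# Shared helpers: tiny architectures and feature matrices so unit tests run
# in seconds; full-size (881-bit) runs live in the acceptance tests.

tiny_resnet <- function(input_length = 30L, ...) {
  spec <- resnet_spec(n_param_layers = 8L, stage_channels = c(3L, 5L, 7L),
                      stem_kernel = 5L, ...)
  build_resnet(spec, input_length = input_length, seed = 42L)
}

# feature matrix of arbitrary width (unit tests only; the exported
# constructor enforces the 881-bit contract)
tiny_features <- function(n = 40L, p = 30L, seed = 1L, noise_sd = 0.1) {
  withr::with_seed(seed, {
    x <- matrix(rbinom(n * p, 1L, 0.3), n, p)
    w <- numeric(p)
    w[sample.int(p, 5L)] <- runif(5L, -1, 1)
    y <- -2 + as.numeric(x %*% w) + rnorm(n, 0, noise_sd)
  })
  deepsol:::new_feature_matrix(x, y, sprintf("T%03d", seq_len(n)),
                               rep(200, n))
}

write_tmp_csv <- function(df, name = "tmp.csv") {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path)
  path
}

has_openbabel <- function() {
  requireNamespace("ChemmineOB", quietly = TRUE) &&
    requireNamespace("ChemmineR", quietly = TRUE)
}
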