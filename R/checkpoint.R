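#' Save / load a model checkpoint
#'
#' A checkpoint is a single versioned file embedding the architecture spec,
#' all weights, batch-norm statistics, the layer audit, the training history
#' and the training configuration.
#'
#' @param model A `sol_model`.
#' @param path Checkpoint file path.
#' @return `path` invisibly (writer); a `sol_model` (reader).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "sol_model"))
  obj <- list(format = "deepsol-checkpoint", format_version = 1L,
              package_version = as.character(utils::packageVersion("deepsol")),
              model = model)
  saveRDS(obj, path, version = 2)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) abort_config(paste0("checkpoint not found: ", path))
  obj <- tryCatch(readRDS(path), error = function(e)
    abort_data(paste0("not a readable checkpoint: ", path)))
  if (!identical(obj$format, "deepsol-checkpoint")) {
    abort_data(paste0("not a deepsol checkpoint: ", path))
  }
  obj$model
}

#' Read a run configuration file
#'
#' YAML with optional sections `data`, `architecture`, `training`,
#' `evaluation` and `simulate`. The architecture section selects `kind:
#' resnet` (fields of [resnet_spec()]) or `kind: dnn` (fields of
#' [dnn_spec()]); the training section holds [train_config()] fields.
#'
#' @param path YAML file path.
#' @return A named list with the parsed sections and resolved spec/config
#'   objects (`$spec`, `$train`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("config file not found: ", path))
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    abort_config(paste0("could not parse config: ", conditionMessage(e))))
  cfg <- cfg %||% list()
  arch <- cfg$architecture %||% list()
  kind <- arch$kind %||% "resnet"
  arch$kind <- NULL
  spec <- tryCatch({
    if (identical(kind, "resnet")) do.call(resnet_spec, arch)
    else if (identical(kind, "dnn")) do.call(dnn_spec, arch)
    else abort_config(paste0("unknown architecture kind: ", kind))
  }, error = function(e) {
    if (inherits(e, "deepsol_config_error")) stop(e)
    abort_config(paste0("invalid architecture section: ", conditionMessage(e)))
  })
  train <- tryCatch(do.call(train_config, cfg$training %||% list()),
                    error = function(e) {
                      if (inherits(e, "deepsol_config_error")) stop(e)
                      abort_config(paste0("invalid training section: ",
                                          conditionMessage(e)))
                    })
  c(cfg, list(spec = spec, train = train))
}

# one manifest per run: config snapshot, seeds, versions, input digests,
# output paths
write_manifest <- function(path, command, inputs = character(),
                           outputs = character(), config = NULL,
                           seed = NULL) {
  digest_of <- function(files) {
    files <- files[file.exists(files)]
    as.list(setNames(unname(tools::md5sum(files)), files))
  }
  manifest <- list(
    command = command,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("deepsol")),
    seed = seed,
    config = config,
    input_digests = digest_of(inputs),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
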