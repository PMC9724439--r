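# YAML run configuration: nested keys map onto the constructor arguments of
# paase_config() / gin_config() / ppihop_config() / train_config().

#' Read a run configuration from YAML
#'
#' Recognized top-level keys: `paase`, `gin`, `model` (hops, max_len,
#' variant), `train`, `seed`.  Any omitted key falls back to the package
#' defaults, so an empty file is a valid configuration.
#'
#' @param path YAML file path (`NULL` for all defaults).
#' @return List with `model_cfg` ([ppihop_config()]), `train_cfg`
#'   ([train_config()]), and `seed`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  seed <- raw$seed %||% 1L
  paase <- do.call(paase_config, raw$paase %||% list())
  gin <- do.call(gin_config, raw$gin %||% list())
  model_args <- raw$model %||% list()
  model_args$paase <- paase
  model_args$gin <- gin
  model_cfg <- do.call(ppihop_config, model_args)
  train_args <- raw$train %||% list()
  if (is.null(train_args$seed)) train_args$seed <- seed
  train_cfg <- do.call(train_config, train_args)
  list(model_cfg = model_cfg, train_cfg = train_cfg, seed = as.integer(seed))
}

#' Write a reproducibility manifest
#'
#' Records the seed, an md5 of the effective configuration, and an md5 per
#' input file, sufficient to reproduce a CPU run bit-for-bit.
#'
#' @param path Output JSON path.
#' @param config Any serializable configuration object.
#' @param seed Integer seed of the run.
#' @param inputs Named character vector of input file paths.
#' @param extra Optional named list appended verbatim.
#' @export
write_manifest <- function(path, config, seed, inputs = character(), extra = list()) {
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  writeLines(yaml::as.yaml(config), cfg_file)
  manifest <- c(list(
    seed = as.integer(seed),
    config_md5 = unname(tools::md5sum(cfg_file)),
    inputs = as.list(vapply(inputs, function(f) unname(tools::md5sum(f)), ""))
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
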