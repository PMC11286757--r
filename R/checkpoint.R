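# Checkpointing: native serialized weights plus a JSON sidecar recording
# the architectural configuration, so a checkpoint is self-describing.

#' Save / load a model checkpoint
#'
#' `save_checkpoint()` writes the model (parameters + normalization state)
#' as an RDS file and a `<path>.json` sidecar holding the full
#' [model_config()], so the checkpoint can be inspected without R.
#'
#' @param model a `ddrnet_model`.
#' @param path checkpoint file path (e.g. `model.rds`).
#' @return `load_checkpoint()` returns the restored `ddrnet_model` (the
#'   sidecar, when present, is checked against the stored config).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ddrnet_model"))
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ddrnet_model"))
    stop("'", path, "' is not a DDRNet checkpoint")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!identical(as.integer(side$input_size),
                   model$config$input_size))
      warning("checkpoint sidecar disagrees with the stored configuration")
  }
  model
}
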