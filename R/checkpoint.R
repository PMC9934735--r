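#' @title Checkpoints
#' @name checkpoints
#' @description Single-file, versioned containers bundling a trained
#' denoiser (parameters + config + vocabulary + condition statistics), the
#' noise schedule it was trained with, and the training size distribution,
#' so sampling needs nothing else.
NULL

CHECKPOINT_VERSION <- 1L

#' Save a checkpoint
#' @param net a `denoiser_network`.
#' @param schedule the `noise_schedule` used in training.
#' @param path output file.
#' @param meta optional named list of run metadata (seed, config hash, ...).
#' @export
save_checkpoint <- function(net, schedule, path, meta = list()) {
  obj <- list(version = CHECKPOINT_VERSION, net = net, schedule = schedule,
              meta = meta)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a checkpoint
#' @param path checkpoint file.
#' @return list with `net`, `schedule`, `meta`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, CHECKPOINT_VERSION))
    stop("unsupported checkpoint version: ", obj$version)
  obj
}
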