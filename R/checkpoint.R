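# Checkpoints and configuration files ----------------------------------------

.CHECKPOINT_VERSION <- 1L

#' Save a fitted model checkpoint
#'
#' The checkpoint is a single archive holding the parameters, both
#' configurations, the selected thresholds and the feature-vocabulary
#' dimensions (used to detect incompatible checkpoints on load).
#'
#' @param fit A `rxn_fit`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "rxn_fit"))
  saveRDS(list(
    version = .CHECKPOINT_VERSION,
    feature_dims = feature_dims(),
    fit = fit
  ), path)
  invisible(path)
}

#' Load a fitted model checkpoint
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return The `rxn_fit`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, .CHECKPOINT_VERSION)) {
    stop("checkpoint version ", obj$version, " is incompatible with ",
         .CHECKPOINT_VERSION)
  }
  if (!identical(obj$feature_dims, feature_dims())) {
    stop("checkpoint feature vocabulary (d_x=", obj$feature_dims$d_x,
         ", d_e=", obj$feature_dims$d_e, ") does not match this package build")
  }
  obj$fit
}

#' Write a run configuration to YAML
#'
#' @param model_config An [encoder_config()].
#' @param loss A [loss_config()].
#' @param training Named list of training settings (epochs, batch size,
#'   optimizer settings, mode, seed, ...).
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(model_config, loss = loss_config(),
                             training = list(), path) {
  yaml::write_yaml(list(
    model = unclass(model_config),
    loss = unclass(loss),
    training = training
  ), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file written by [write_run_config()].
#' @return List with `model` ([encoder_config()]), `loss`
#'   ([loss_config()]) and `training` (plain list).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  list(
    model = do.call(encoder_config, raw$model),
    loss = do.call(loss_config, raw$loss),
    training = raw$training
  )
}
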