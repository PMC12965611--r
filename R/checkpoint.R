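# Checkpoint persistence: one archive holding the deep weights, the
# refiner, the configurations and the featurizer/scaler versions.

CHECKPOINT_FORMAT <- 1L

#' Save a fitted model to a checkpoint file
#'
#' Writes the complete fit — deep-stage weights, refiner, model and
#' training configurations, scalers and featurizer versions — as one
#' versioned archive.
#'
#' @param fit A [train_drp()] fit.
#' @param path Destination file (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  if (!inherits(fit, "drp_fit"))
    drp_abort("`fit` must be a drp_fit", "drp_state_error")
  saveRDS(list(format = CHECKPOINT_FORMAT, fit = fit), path)
  invisible(path)
}

#' Load a checkpoint
#'
#' Restores a [save_checkpoint()] archive.  If `config` is supplied the
#' stored model configuration must match it exactly; a mismatch (for
#' example, a checkpoint trained with different embedding sizes or
#' fingerprint kinds) is an error rather than a silent reinterpretation.
#'
#' @param path Checkpoint file.
#' @param config Optional [model_config()] the checkpoint must match.
#' @return The stored `drp_fit`.
#' @export
load_checkpoint <- function(path, config = NULL) {
  if (!file.exists(path))
    drp_abort(sprintf("checkpoint not found: %s", path), "drp_data_error")
  obj <- tryCatch(readRDS(path), error = function(e)
    drp_abort(sprintf("cannot read checkpoint %s: %s", path,
                      conditionMessage(e)), "drp_data_error"))
  if (!is.list(obj) || is.null(obj$format) ||
      !inherits(obj$fit, "drp_fit"))
    drp_abort("file is not a model checkpoint", "drp_data_error")
  if (obj$format > CHECKPOINT_FORMAT)
    drp_abort(sprintf("checkpoint format %d is newer than supported (%d)",
                      obj$format, CHECKPOINT_FORMAT), "drp_config_error")
  if (!is.null(config)) {
    stored <- unclass(obj$fit$config)
    wanted <- unclass(config)
    for (nm in union(names(stored), names(wanted)))
      if (!identical(stored[[nm]], wanted[[nm]]))
        drp_abort(sprintf(
          "checkpoint configuration mismatch on '%s' (stored: %s, requested: %s)",
          nm, paste(stored[[nm]], collapse = ","),
          paste(wanted[[nm]], collapse = ",")), "drp_config_error")
  }
  obj$fit
}
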