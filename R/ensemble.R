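# The refinement stage: gradient-boosted regression trees fitted on the
# deep model's interaction vector f and initial prediction, correcting
# residual error.  xgboost provides the boosting; this module owns the
# feature contract (f0..f127 then predicted_ic50) and the split-count
# importance export.

REFINER_FEATURES <- function(latent_dim = 128L)
  c(paste0("f", seq_len(latent_dim) - 1L), "predicted_ic50")

#' Assemble refiner inputs from deep-model outputs
#'
#' Concatenates the interaction vector and the initial prediction into
#' one feature row per pair: `z = [f_0 .. f_{l-1}, y_hat]`, with the
#' initial prediction always in the final position.
#'
#' @param f Matrix of interaction vectors (pairs x latent).
#' @param y_hat Initial predictions, one per row of `f`.
#' @return Numeric matrix with `latent + 1` named columns
#'   (`f0`..`f127`, `predicted_ic50` at defaults).
#' @export
assemble_features <- function(f, y_hat) {
  if (is.list(f) && !is.null(f$f)) { y_hat <- f$y_hat; f <- f$f }
  if (nrow(f) != length(y_hat))
    drp_abort("f and y_hat describe different numbers of pairs",
              "drp_shape_error")
  z <- cbind(f, y_hat)
  colnames(z) <- REFINER_FEATURES(ncol(f))
  z
}

#' Fit the gradient-boosted refiner
#'
#' Fits an additive regression-tree ensemble on the assembled features
#' under squared-error loss with L2 regularization.  Subsampling is
#' seeded, so refits on identical inputs are identical.
#'
#' @param z Feature matrix from [assemble_features()].
#' @param y Observed responses.
#' @param config A [refiner_config()].
#' @return An object of class `drp_refiner`.
#' @export
fit_refiner <- function(z, y, config = refiner_config()) {
  if (nrow(z) < 2L)
    drp_abort("refiner needs at least two training rows", "drp_data_error")
  if (nrow(z) != length(y))
    drp_abort("z and y describe different numbers of pairs",
              "drp_shape_error")
  dtrain <- xgboost::xgb.DMatrix(z, label = y, nthread = 1)
  params <- list(max_depth = max(1L, config$max_depth),
                 eta = config$learning_rate,
                 subsample = config$subsample,
                 lambda = config$reg_lambda,
                 objective = "reg:squarederror",
                 nthread = 1, seed = config$seed)
  # depth 0 = trees that may not split at all (constant correction);
  # the boosting library reads max_depth = 0 as "unlimited" instead
  if (config$max_depth == 0L) params$gamma <- 1e15
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config$n_trees, verbose = 0)
  structure(list(booster = booster, config = config,
                 features = colnames(z), n_train = nrow(z)),
            class = "drp_refiner")
}

#' Refined predictions
#'
#' @param refiner A fitted [fit_refiner()] model.
#' @param z Feature matrix with the training feature layout.
#' @return Numeric vector of final predictions.
#' @export
refine <- function(refiner, z) {
  if (!inherits(refiner, "drp_refiner"))
    drp_abort("`refiner` must be a fitted drp_refiner", "drp_state_error")
  if (ncol(z) != length(refiner$features))
    drp_abort(sprintf("refiner expects %d features, got %d",
                      length(refiner$features), ncol(z)),
              "drp_shape_error")
  predict(refiner$booster, xgboost::xgb.DMatrix(z, nthread = 1))
}

#' Split-count feature importance of the refiner
#'
#' Counts, for every feature, how many internal tree nodes split on it
#' across the whole ensemble (the boosting "F score").  Features never
#' used are reported with a count of zero.
#'
#' @param refiner A fitted [fit_refiner()] model.
#' @return Tibble with columns `feature`, `f_score`, sorted decreasing.
#' @export
refiner_importance <- function(refiner) {
  if (!inherits(refiner, "drp_refiner"))
    drp_abort("`refiner` must be a fitted drp_refiner", "drp_state_error")
  tree <- xgboost::xgb.model.dt.tree(model = refiner$booster)
  splits <- tree$Feature[tree$Feature != "Leaf"]
  counts <- table(factor(splits, levels = refiner$features))
  tibble::tibble(feature = names(counts),
                 f_score = as.integer(counts)) |>
    dplyr::arrange(dplyr::desc(.data$f_score))
}

#' @export
print.drp_refiner <- function(x, ...) {
  cat(sprintf("<drp_refiner: %d trees, depth %d, eta %g, %d features>\n",
              x$config$n_trees, x$config$max_depth,
              x$config$learning_rate, length(x$features)))
  invisible(x)
}
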