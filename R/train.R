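# End-to-end training of the deep stage (Adam, MSE, reduce-on-plateau on
# validation loss, best-checkpoint restore) followed by fitting the
# boosted refiner on the frozen deep model's training-split outputs.

#' Train the full drug-response model
#'
#' Runs the complete two-stage procedure: decile-stratified splitting
#' (unless `pairs` already carries split labels), per-feature scaling of
#' the continuous omics matrices with training-split statistics,
#' minibatch Adam optimization of the deep network under MSE with a
#' reduce-on-plateau learning-rate schedule monitoring validation loss,
#' restoration of the best-validation weights, and finally fitting of
#' the gradient-boosted refiner on the frozen model's training outputs.
#'
#' @param pairs A `pair_dataset` (see [load_response_table()] or
#'   [generate_responses()]).
#' @param omics An unscaled `omics_profile_set`.
#' @param features A [featurize_drugs()] result covering all drugs in
#'   `pairs`.
#' @param config A [model_config()].
#' @param tconfig A [train_config()].
#' @param rconfig A [refiner_config()]; `NULL` skips the refiner.
#' @param verbose Print a progress line every 10 epochs.
#' @return An object of class `drp_fit`: the trained `model`, the
#'   `refiner`, per-epoch `history` (tibble: epoch, lr, train_loss,
#'   val_loss, val_pcc), the split `pairs`, fitted `scalers` and
#'   featurizer version metadata.
#' @export
train_drp <- function(pairs, omics, features, config = model_config(),
                      tconfig = train_config(),
                      rconfig = refiner_config(), verbose = FALSE) {
  cfg <- config; tc <- tconfig
  if (!"split" %in% names(pairs) || all(pairs$split == "none"))
    pairs <- stratified_split(pairs, tc$split, seed = tc$seed)
  for (s in c("train", "val"))
    if (!any(pairs$split == s))
      drp_abort(sprintf("split '%s' is empty", s), "drp_config_error")

  train_cells <- unique(pairs$cell_id[pairs$split == "train"])
  sc <- scale_omics_set(omics, train_cells)
  data <- build_model_data(pairs, sc$omics, features, cfg)
  model <- build_drp_model(data$input_dims, cfg)
  model$versions <- features$versions

  rows_train <- which(pairs$split == "train")
  rows_val <- which(pairs$split == "val")
  y <- data$y

  opt <- adam_init(model$params)
  lr <- tc$lr
  best_val <- Inf; best_params <- model$params
  since_improve <- 0L
  history <- vector("list", tc$epochs)

  set.seed(derive_seed(tc$seed, 7L))
  for (epoch in seq_len(tc$epochs)) {
    ord <- sample(rows_train)
    n_batches <- ceiling(length(ord) / tc$batch_size)
    ep_loss <- 0
    for (b in seq_len(n_batches)) {
      idx <- ord[((b - 1L) * tc$batch_size + 1L):
                   min(b * tc$batch_size, length(ord))]
      batch <- make_batch(data, idx)
      fw <- model_forward(model, batch, train = TRUE)
      model <- fw$model  # batch-norm running statistics
      loss <- mse_loss(fw$y_hat, y[idx])
      if (!is.finite(loss))
        drp_abort(sprintf(
          "non-finite training loss at epoch %d batch %d; try a lower lr",
          epoch, b), "drp_training_error")
      grads <- model_backward(model, fw, mse_grad(fw$y_hat, y[idx]))
      st <- adam_step(opt, model$params, grads, lr)
      opt <- st$opt; model$params <- st$params
      ep_loss <- ep_loss + loss * length(idx)
    }
    ep_loss <- ep_loss / length(rows_train)

    vp <- predict_forward(model, data, rows_val)
    val_loss <- mse_loss(vp$y_hat, y[rows_val])
    val_pcc <- if (stats::sd(vp$y_hat) > 0)
      stats::cor(vp$y_hat, y[rows_val]) else NA_real_

    if (val_loss < best_val - 1e-9) {
      best_val <- val_loss; best_params <- model$params
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= tc$lr_patience && lr > tc$lr_min) {
        lr <- max(lr * tc$lr_factor, tc$lr_min)
        since_improve <- 0L
      }
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, train_loss = ep_loss,
      val_loss = val_loss, val_pcc = val_pcc)
    if (verbose && (epoch %% 10L == 0L || epoch == 1L))
      message(sprintf("epoch %3d  train %.4f  val %.4f  pcc %.3f  lr %g",
                      epoch, ep_loss, val_loss, val_pcc, lr))
  }
  if (tc$keep_best) model$params <- best_params

  refiner <- NULL
  if (!is.null(rconfig)) {
    rrows <- if (tc$refiner_on == "train+val")
      c(rows_train, rows_val) else rows_train
    rp <- predict_forward(model, data, rrows)
    z <- assemble_features(rp$f, rp$y_hat)
    refiner <- fit_refiner(z, y[rrows], rconfig)
  }

  structure(list(model = model, refiner = refiner,
                 history = dplyr::bind_rows(history),
                 pairs = pairs, scalers = sc$scalers,
                 config = cfg, tconfig = tc,
                 versions = features$versions),
            class = "drp_fit")
}

#' @export
print.drp_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<drp_fit: %d epochs; best val MSE %.4f; refiner: %s>\n",
    nrow(h), min(h$val_loss),
    if (is.null(x$refiner)) "none" else
      sprintf("%d trees", x$refiner$config$n_trees)))
  invisible(x)
}

#' Predict responses for drug/cell pairs
#'
#' Applies the frozen deep model (and, by default, the boosted refiner)
#' to new pairs.  Omics matrices are scaled with the training-split
#' statistics stored in the fit.
#'
#' @param object A [train_drp()] fit.
#' @param pairs Data frame with `drug_id`, `cell_id` (a `ln_ic50` column
#'   is carried through if present).
#' @param omics The unscaled `omics_profile_set` covering the cells.
#' @param features A [featurize_drugs()] result covering the drugs.
#' @param refined Apply the refiner when one was fitted.
#' @param ... Unused.
#' @return Tibble: the input pairs plus `y_deep` (initial prediction)
#'   and `y_pred` (refined when available, else `y_deep`); the
#'   interaction vectors are attached as attribute `"f"`.
#' @export
predict.drp_fit <- function(object, pairs, omics, features,
                            refined = TRUE, ...) {
  for (name in c("expression", "methylation", "pathway"))
    omics[[name]] <- apply_scaler(object$scalers[[name]], omics[[name]])
  if (!"ln_ic50" %in% names(pairs)) pairs$ln_ic50 <- NA_real_
  data <- build_model_data(pairs, omics, features, object$config)
  fw <- predict_forward(object$model, data)
  out <- tibble::as_tibble(pairs)
  out$y_deep <- fw$y_hat
  out$y_pred <- if (refined && !is.null(object$refiner))
    refine(object$refiner, assemble_features(fw$f, fw$y_hat))
  else fw$y_hat
  attr(out, "f") <- fw$f
  out
}

#' Evaluate a fit on one of its splits
#'
#' @param fit A [train_drp()] fit.
#' @param omics,features The data the fit was trained with.
#' @param split Which split to evaluate (default `"test"`).
#' @param refined Use the refined predictions.
#' @return One-row metrics tibble (see [compute_metrics()]).
#' @export
evaluate_drp <- function(fit, omics, features, split = "test",
                         refined = TRUE) {
  rows <- fit$pairs[fit$pairs$split == split, ]
  if (nrow(rows) == 0L)
    drp_abort(sprintf("split '%s' is empty", split), "drp_config_error")
  pred <- predict(fit, rows, omics, features, refined = refined)
  compute_metrics(rows$ln_ic50, pred$y_pred)
}

#' Evaluate a fit on an external response table
#'
#' Scores a second response table after removing every (drug, cell) pair
#' already present in the fit's own dataset, so the evaluation set is
#' disjoint from anything seen in training, validation or internal
#' testing.
#'
#' @param fit A [train_drp()] fit.
#' @param pairs External `pair_dataset`.
#' @param omics,features Feature sets covering the external pairs.
#' @param refined Use the refined predictions.
#' @return One-row metrics tibble with an `n_overlap_removed` column.
#' @export
evaluate_external <- function(fit, pairs, omics, features,
                              refined = TRUE) {
  key <- function(d) paste(d$drug_id, d$cell_id, sep = "\r")
  overlap <- key(pairs) %in% key(fit$pairs)
  pairs <- pairs[!overlap, ]
  if (nrow(pairs) < 2L)
    drp_abort("fewer than two external pairs remain after overlap removal",
              "drp_data_error")
  pred <- predict(fit, pairs, omics, features, refined = refined)
  met <- compute_metrics(pairs$ln_ic50, pred$y_pred)
  met$n_overlap_removed <- sum(overlap)
  met
}
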