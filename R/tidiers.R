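# broom-style accessors and ggplot2 displays for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted drug-response model
#'
#' Returns the per-epoch training history (epoch, learning rate,
#' training loss, validation loss, validation Pearson correlation).
#'
#' @param x A [train_drp()] fit.
#' @param ... Unused.
#' @method tidy drp_fit
#' @export
tidy.drp_fit <- function(x, ...) x$history

#' One-row summary of a fitted drug-response model
#'
#' @param x A [train_drp()] fit.
#' @param ... Unused.
#' @method glance drp_fit
#' @export
glance.drp_fit <- function(x, ...) {
  h <- x$history
  best <- which.min(h$val_loss)
  tibble::tibble(
    epochs = nrow(h),
    best_epoch = best,
    best_val_mse = h$val_loss[best],
    final_train_mse = h$train_loss[nrow(h)],
    final_val_pcc = h$val_pcc[nrow(h)],
    final_lr = h$lr[nrow(h)],
    n_train = sum(x$pairs$split == "train"),
    n_val = sum(x$pairs$split == "val"),
    n_test = sum(x$pairs$split == "test"),
    refined = !is.null(x$refiner))
}

#' Tidy the boosted refiner
#'
#' Returns the split-count feature importance table (see
#' [refiner_importance()]).
#'
#' @param x A `drp_refiner`.
#' @param ... Unused.
#' @method tidy drp_refiner
#' @export
tidy.drp_refiner <- function(x, ...) refiner_importance(x)

#' @method glance drp_refiner
#' @export
glance.drp_refiner <- function(x, ...) {
  imp <- refiner_importance(x)
  tibble::tibble(n_trees = x$config$n_trees,
                 max_depth = x$config$max_depth,
                 learning_rate = x$config$learning_rate,
                 subsample = x$config$subsample,
                 n_features = length(x$features),
                 n_features_used = sum(imp$f_score > 0),
                 total_splits = sum(imp$f_score))
}

#' Training-history curves
#'
#' Loss curves (training and validation MSE) and the validation Pearson
#' correlation trend over epochs.
#'
#' @param object A [train_drp()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot drp_fit
#' @export
autoplot.drp_fit <- function(object, ...) {
  h <- object$history |>
    tidyr::pivot_longer(c("train_loss", "val_loss", "val_pcc"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ifelse(series == "val_pcc",
                                "validation PCC", "MSE loss"),
                        scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of refiner feature importance
#'
#' @param refiner A `drp_refiner`.
#' @param n_top Number of features shown.
#' @return A ggplot object.
#' @export
plot_importance <- function(refiner, n_top = 20L) {
  imp <- utils::head(refiner_importance(refiner), n_top)
  ggplot2::ggplot(imp, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$f_score),
    y = .data$f_score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "F score (split count)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a completed response matrix
#'
#' @param imputation An [impute_and_rank()] result.
#' @param n_cells,n_drugs Subset shown (first rows/columns).
#' @return A ggplot object.
#' @export
plot_response_heatmap <- function(imputation, n_cells = 30L,
                                  n_drugs = 30L) {
  m <- imputation$matrix
  m <- m[seq_len(min(n_cells, nrow(m))),
         seq_len(min(n_drugs, ncol(m))), drop = FALSE]
  long <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(long) <- c("cell_id", "drug_id", "ln_ic50")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$drug_id, y = .data$cell_id,
                                     fill = .data$ln_ic50)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "ln IC50") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Distribution plot for extreme drugs
#'
#' @param imputation An [impute_and_rank()] result.
#' @param n_top Drugs at each extreme.
#' @return A ggplot object.
#' @export
plot_extreme_drugs <- function(imputation, n_top = 10L) {
  d <- extreme_drug_distributions(imputation, n_top)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$drug_id, .data$ln_ic50, median),
    y = .data$ln_ic50, fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "predicted ln IC50", fill = NULL) +
    ggplot2::theme_minimal()
}
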