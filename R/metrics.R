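#' Regression metrics for drug-response prediction
#'
#' Computes the six standard metrics: mean squared error, its square
#' root, mean absolute error, the coefficient of determination
#' (1 - SSres/SStot), Pearson correlation and Spearman correlation
#' (average ranks for ties).  If either vector has zero variance the
#' correlations are undefined and returned as `NaN` with a warning.
#'
#' @param y_true,y_pred Equal-length finite numeric vectors, `n >= 2`.
#' @return A one-row tibble with columns `mse`, `rmse`, `mae`, `r2`,
#'   `pcc`, `scc`, `n`.
#' @export
#' @examples
#' compute_metrics(c(1, 2, 3), c(2, 2, 2))
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    drp_abort("y_true and y_pred must have equal length",
              "drp_shape_error")
  if (length(y_true) < 2L)
    drp_abort("metrics need at least two observations", "drp_data_error")
  if (!all(is.finite(y_true)) || !all(is.finite(y_pred)))
    drp_abort("metrics require finite inputs", "drp_data_error")

  err <- y_pred - y_true
  mse <- mean(err^2)
  sstot <- sum((y_true - mean(y_true))^2)
  r2 <- 1 - sum(err^2) / sstot
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) {
    rlang::warn("zero variance in predictions or truth; correlations undefined")
    pcc <- scc <- NaN
    if (sstot == 0) r2 <- NaN
  } else {
    pcc <- stats::cor(y_pred, y_true, method = "pearson")
    scc <- stats::cor(y_pred, y_true, method = "spearman")
  }
  tibble::tibble(mse = mse, rmse = sqrt(mse), mae = mean(abs(err)),
                 r2 = r2, pcc = pcc, scc = scc,
                 n = length(y_true))
}
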