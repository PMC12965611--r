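#' Impute missing response-matrix entries and rank drugs
#'
#' Predicts every unobserved (drug, cell) combination of the grid,
#' assembles the completed response matrix (observed values where
#' measured, predictions elsewhere), and ranks drugs by their mean
#' predicted ln IC50 ascending, so rank 1 is the most potent candidate.
#' By default the ranking is computed over the imputed entries only;
#' `rank_on = "all"` averages over the full completed matrix.
#'
#' @param fit A [train_drp()] fit.
#' @param omics The unscaled `omics_profile_set` (all cells of the grid).
#' @param features A [featurize_drugs()] result (all drugs of the grid).
#' @param observed A data frame of observed pairs (`drug_id`, `cell_id`,
#'   `ln_ic50`); defaults to all pairs stored in the fit.
#' @param rank_on `"imputed"` (default) or `"all"`.
#' @return List with `completed` (long tibble: `cell_id`, `drug_id`,
#'   `ln_ic50`, `source` = observed/imputed), `matrix` (cells x drugs),
#'   `imputed` (the predicted pairs only) and `ranking` (tibble:
#'   `rank`, `drug_id`, `mean_pred_ic50`, `n`).
#' @export
impute_and_rank <- function(fit, omics, features, observed = NULL,
                            rank_on = c("imputed", "all")) {
  rank_on <- match.arg(rank_on)
  observed <- observed %||% fit$pairs
  cells <- omics$cell_ids
  drugs <- features$drug_ids

  grid <- tidyr::expand_grid(cell_id = cells, drug_id = drugs)
  key <- function(d) paste(d$cell_id, d$drug_id, sep = "\r")
  obs_key <- key(observed)
  todo <- grid[!key(grid) %in% obs_key, ]

  imputed <- NULL
  if (nrow(todo) > 0L) {
    pred <- predict(fit, todo, omics, features)
    imputed <- tibble::tibble(cell_id = todo$cell_id,
                              drug_id = todo$drug_id,
                              ln_ic50 = pred$y_pred,
                              source = "imputed")
  }
  completed <- dplyr::bind_rows(
    tibble::tibble(cell_id = observed$cell_id,
                   drug_id = observed$drug_id,
                   ln_ic50 = observed$ln_ic50, source = "observed"),
    imputed)

  mat <- matrix(NA_real_, length(cells), length(drugs),
                dimnames = list(cells, drugs))
  mat[cbind(match(completed$cell_id, cells),
            match(completed$drug_id, drugs))] <- completed$ln_ic50

  rank_src <- if (rank_on == "imputed" && !is.null(imputed)) imputed
              else completed
  ranking <- rank_src |>
    dplyr::group_by(.data$drug_id) |>
    dplyr::summarise(mean_pred_ic50 = mean(.data$ln_ic50),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$mean_pred_ic50) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "drug_id", "mean_pred_ic50", "n")

  list(completed = completed, matrix = mat,
       imputed = imputed %||% tibble::tibble(), ranking = ranking)
}

#' Per-drug predicted-response distributions for extreme drugs
#'
#' Returns the long table behind a "top sensitive vs top resistant"
#' figure: the imputed response values for the `n_top` drugs with the
#' lowest and highest mean predicted ln IC50.
#'
#' @param imputation An [impute_and_rank()] result.
#' @param n_top Number of drugs at each extreme.
#' @return Tibble: `drug_id`, `group` (sensitive/resistant), `ln_ic50`.
#' @export
extreme_drug_distributions <- function(imputation, n_top = 10L) {
  rk <- imputation$ranking
  n_top <- min(n_top, floor(nrow(rk) / 2))
  sens <- utils::head(rk$drug_id, n_top)
  res <- utils::tail(rk$drug_id, n_top)
  src <- if (nrow(imputation$imputed) > 0L) imputation$imputed
         else imputation$completed
  src |>
    dplyr::filter(.data$drug_id %in% c(sens, res)) |>
    dplyr::mutate(group = ifelse(.data$drug_id %in% sens,
                                 "sensitive", "resistant")) |>
    dplyr::select("drug_id", "group", "ln_ic50")
}
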