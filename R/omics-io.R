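# Loading, alignment, filtering and scaling of the four per-cell omics
# matrices and the drug-response table.
#
# File dialect: delimited text (tab or comma, auto-detected), first
# column = cell_id, header row = feature names.  Cells are restricted to
# those present in all four matrices; expression / mutation / methylation
# columns can additionally be restricted to a gene whitelist (e.g. a
# COSMIC export, one symbol per line).

OMICS_NAMES <- c("expression", "mutation", "methylation", "pathway")

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

read_omics_matrix <- function(path, name) {
  if (!file.exists(path))
    drp_abort(sprintf("%s matrix file not found: %s", name, path),
              "drp_data_error")
  tab <- tryCatch(
    data.table::fread(path, sep = detect_delim(path), header = TRUE,
                      data.table = FALSE, check.names = FALSE),
    error = function(e)
      drp_abort(sprintf("failed to parse %s matrix %s: %s", name, path,
                        conditionMessage(e)), "drp_parse_error"))
  if (ncol(tab) < 2L)
    drp_abort(sprintf("%s matrix %s has no feature columns", name, path),
              "drp_parse_error")
  ids <- trimws(as.character(tab[[1]]))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(tab[-1], is.numeric, logical(1)))[1]
    drp_abort(sprintf("non-numeric entries in %s matrix %s (column '%s')",
                      name, path, names(tab)[-1][bad]), "drp_parse_error")
  }
  if (anyNA(m))
    drp_abort(sprintf("missing values in %s matrix %s", name, path),
              "drp_parse_error")
  rownames(m) <- ids
  m
}

#' Load and align a four-profile omics set
#'
#' Reads the four omics matrices, restricts cells to those present in all
#' four files, and optionally restricts expression / mutation /
#' methylation columns to a gene whitelist (the pathway matrix is never
#' gene-filtered).  Column order is deterministic: whitelist order where a
#' whitelist applies, file order otherwise.  Cells present in only some
#' files are dropped with a warning.
#'
#' @param expression,mutation,methylation,pathway Paths to delimited
#'   matrices (first column cell_id, header = feature names).
#' @param gene_whitelist Optional path to a one-symbol-per-line gene list,
#'   or a character vector of symbols.
#' @return An object of class `omics_profile_set`: the four matrices with
#'   identical row (cell) order, plus `cell_ids`.
#' @export
load_omics_set <- function(expression, mutation, methylation, pathway,
                           gene_whitelist = NULL) {
  paths <- list(expression = expression, mutation = mutation,
                methylation = methylation, pathway = pathway)
  mats <- Map(read_omics_matrix, paths, names(paths))

  if (!is.null(gene_whitelist)) {
    wl <- if (length(gene_whitelist) == 1L && file.exists(gene_whitelist))
      readLines(gene_whitelist) else as.character(gene_whitelist)
    wl <- trimws(wl)
    wl <- wl[nzchar(wl)]
    for (name in c("expression", "mutation", "methylation")) {
      keep <- intersect(wl, colnames(mats[[name]]))  # whitelist order
      if (length(keep) == 0L)
        drp_abort(sprintf(
          "gene whitelist shares no genes with the %s matrix", name),
          "drp_data_error")
      mats[[name]] <- mats[[name]][, keep, drop = FALSE]
    }
  }

  common <- Reduce(intersect, lapply(mats, rownames))
  if (length(common) == 0L)
    drp_abort("no cell line is present in all four omics files",
              "drp_data_error")
  n_dropped <- vapply(mats, function(m) nrow(m) - length(common), integer(1))
  if (any(n_dropped > 0L))
    rlang::warn(sprintf(
      "dropped cells absent from some files: %s",
      paste(sprintf("%s=%d", names(n_dropped), n_dropped), collapse = ", ")))
  common <- sort(common)
  mats <- lapply(mats, function(m) m[common, , drop = FALSE])

  if (!all(mats$mutation %in% c(0, 1)))
    drp_abort("mutation matrix must be binary 0/1", "drp_data_error")

  structure(c(mats, list(cell_ids = common)), class = "omics_profile_set")
}

#' @export
print.omics_profile_set <- function(x, ...) {
  cat(sprintf("<omics_profile_set: %d cells; %s>\n", length(x$cell_ids),
              paste(sprintf("%s[%d]", OMICS_NAMES,
                            vapply(x[OMICS_NAMES], ncol, integer(1))),
                    collapse = " ")))
  invisible(x)
}

#' Aggregate per-type mutation records to a binary gene matrix
#'
#' Collapses raw mutation calls so that entry (cell, gene) is 1 when at
#' least one record of any mutation type exists for that gene in that
#' cell, and 0 otherwise.  Idempotent under re-aggregation.
#'
#' @param records Data frame with columns `cell_id`, `gene` (and
#'   optionally `mutation_type`, which is ignored beyond existence).
#' @param cells,genes Optional row/column universes; defaults to the
#'   values observed in `records`.
#' @return Binary matrix, cells x genes.
#' @export
aggregate_mutations <- function(records, cells = NULL, genes = NULL) {
  if (!all(c("cell_id", "gene") %in% names(records)))
    drp_abort("mutation records need columns cell_id, gene",
              "drp_data_error")
  cells <- cells %||% sort(unique(trimws(as.character(records$cell_id))))
  genes <- genes %||% sort(unique(trimws(as.character(records$gene))))
  m <- matrix(0L, nrow = length(cells), ncol = length(genes),
              dimnames = list(cells, genes))
  ri <- match(trimws(as.character(records$cell_id)), cells)
  ci <- match(trimws(as.character(records$gene)), genes)
  keep <- !is.na(ri) & !is.na(ci)
  m[cbind(ri[keep], ci[keep])] <- 1L
  m
}

#' Fit a per-feature z-score scaler on training rows
#'
#' Columns are centred and scaled with training means / standard
#' deviations; constant columns map to all zeros.  The returned object
#' applies the same parameters to any later matrix (validation, test,
#' unseen cells), so no statistics leak across splits.
#'
#' @param train_matrix Numeric matrix whose rows are the training cells.
#' @return An object of class `omics_scaler` with `mean` and `sd` per
#'   column; apply with [apply_scaler()].
#' @export
fit_scaler <- function(train_matrix) {
  if (!is.matrix(train_matrix) || nrow(train_matrix) == 0L)
    drp_abort("training matrix must be a non-empty matrix",
              "drp_data_error")
  mu <- colMeans(train_matrix)
  sdv <- apply(train_matrix, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 0
  structure(list(mean = mu, sd = sdv, n_train = nrow(train_matrix)),
            class = "omics_scaler")
}

#' Apply a fitted scaler
#'
#' @param scaler An [fit_scaler()] result.
#' @param m Matrix with the same columns as the training matrix.
#' @return The scaled matrix; constant-in-training columns become zero.
#' @export
apply_scaler <- function(scaler, m) {
  if (ncol(m) != length(scaler$mean))
    drp_abort("matrix has a different number of columns than the scaler",
              "drp_shape_error")
  centred <- sweep(m, 2, scaler$mean, "-")
  denom <- ifelse(scaler$sd == 0, 1, scaler$sd)
  scaled <- sweep(centred, 2, denom, "/")
  scaled[, scaler$sd == 0] <- 0
  scaled
}

#' Scale an omics set with training-cell statistics
#'
#' Fits one scaler per continuous profile (expression, methylation,
#' pathway) on the rows named in `train_cells` and applies it to all
#' rows.  The mutation matrix stays binary and is never scaled.
#'
#' @param omics An `omics_profile_set`.
#' @param train_cells Cell ids forming the training split.
#' @return List with the scaled `omics` and the named `scalers`.
#' @export
scale_omics_set <- function(omics, train_cells) {
  train_cells <- intersect(train_cells, omics$cell_ids)
  if (length(train_cells) == 0L)
    drp_abort("no training cells found in the omics set", "drp_data_error")
  scalers <- list()
  for (name in c("expression", "methylation", "pathway")) {
    scalers[[name]] <- fit_scaler(omics[[name]][train_cells, , drop = FALSE])
    omics[[name]] <- apply_scaler(scalers[[name]], omics[[name]])
  }
  list(omics = omics, scalers = scalers)
}

#' Load a drug-response table
#'
#' Reads (drug_id, cell_id, ln_ic50) rows; drops rows with missing or
#' non-finite response, rows whose drug or cell cannot be resolved
#' against the supplied feature sets, and duplicate (drug, cell) pairs
#' (first occurrence kept).  Each category of drop is reported.
#'
#' @param path Path to a delimited table with columns `drug_id`,
#'   `cell_id`, `ln_ic50`, or a data frame with those columns.
#' @param drug_ids Character vector of featurizable drug ids (optional).
#' @param cell_ids Character vector of known cell ids (optional).
#' @return A `pair_dataset`: tibble with columns `drug_id`, `cell_id`,
#'   `ln_ic50`, `split` (initially `"none"`).
#' @export
load_response_table <- function(path, drug_ids = NULL, cell_ids = NULL) {
  tab <- if (is.data.frame(path)) path else {
    if (!file.exists(path))
      drp_abort(sprintf("response table not found: %s", path),
                "drp_data_error")
    data.table::fread(path, sep = detect_delim(path), header = TRUE,
                      data.table = FALSE)
  }
  need <- c("drug_id", "cell_id", "ln_ic50")
  if (!all(need %in% names(tab)))
    drp_abort("response table needs columns drug_id, cell_id, ln_ic50",
              "drp_data_error")
  tab <- tibble::as_tibble(tab[need])
  tab$drug_id <- trimws(as.character(tab$drug_id))
  tab$cell_id <- trimws(as.character(tab$cell_id))
  tab$ln_ic50 <- suppressWarnings(as.numeric(tab$ln_ic50))

  n0 <- nrow(tab)
  tab <- tab[is.finite(tab$ln_ic50), ]
  n_miss <- n0 - nrow(tab)
  n_drug <- n_cell <- 0L
  if (!is.null(drug_ids)) {
    keep <- tab$drug_id %in% drug_ids
    n_drug <- sum(!keep); tab <- tab[keep, ]
  }
  if (!is.null(cell_ids)) {
    keep <- tab$cell_id %in% cell_ids
    n_cell <- sum(!keep); tab <- tab[keep, ]
  }
  dup <- duplicated(tab[c("drug_id", "cell_id")])
  n_dup <- sum(dup)
  tab <- tab[!dup, ]
  if (n_miss + n_drug + n_cell + n_dup > 0L)
    rlang::warn(sprintf(
      "response rows dropped: %d missing ln_ic50, %d unknown drug, %d unknown cell, %d duplicate pair",
      n_miss, n_drug, n_cell, n_dup))
  if (nrow(tab) == 0L)
    drp_abort("no usable response rows survive filtering", "drp_data_error")
  tab$split <- "none"
  class(tab) <- c("pair_dataset", class(tab))
  tab
}
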