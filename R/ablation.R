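#' Ablation harness
#'
#' Trains and evaluates a modified architecture under a shared training
#' configuration.  In every ablation variant the boosted refiner is
#' omitted, so the table isolates the deep stage (the refiner's own
#' contribution is read off by comparing `"none"` — the full deep model
#' without refiner, i.e. the "without boosting" row — against a full
#' [train_drp()] run).
#'
#' Variants: `gnn_gat` / `gnn_gin` / `gnn_gin_transformer` / `gnn_gcn`
#' swap the graph encoder; `fp_only_morgan` / `fp_only_pubchem` /
#' `fp_only_espf` keep a single fingerprint; `drop_omics_expression` /
#' `_mutation` / `_methylation` / `_pathway` remove one cell branch;
#' `no_graph` removes the graph path; `weighted_fp` learns softmax
#' weights over the fingerprint encodings; `no_autoencoder` replaces the
#' two-layer fingerprint encoders with single layers; `none` is the
#' unmodified deep stage.
#'
#' @param variant One of the variant names above.
#' @param pairs,omics,features The dataset (as for [train_drp()]).
#' @param config Base [model_config()] the variant modifies.
#' @param tconfig Shared [train_config()].
#' @param split Evaluation split.
#' @return One-row tibble: `variant` plus the [compute_metrics()]
#'   columns.
#' @export
run_ablation <- function(variant, pairs, omics, features,
                         config = model_config(),
                         tconfig = train_config(), split = "test") {
  cfg <- ablation_config(variant, config)
  fit <- train_drp(pairs, omics, features, cfg, tconfig, rconfig = NULL)
  met <- evaluate_drp(fit, omics, features, split = split,
                      refined = FALSE)
  dplyr::bind_cols(tibble::tibble(variant = variant), met)
}

ABLATION_VARIANTS <- c(
  "none", "gnn_gat", "gnn_gin", "gnn_gin_transformer", "gnn_gcn",
  "fp_only_morgan", "fp_only_pubchem", "fp_only_espf",
  "drop_omics_expression", "drop_omics_mutation",
  "drop_omics_methylation", "drop_omics_pathway",
  "no_graph", "weighted_fp", "no_autoencoder", "no_xgboost")

# translate a variant name into a modified model configuration
ablation_config <- function(variant, config = model_config()) {
  if (!variant %in% ABLATION_VARIANTS)
    drp_abort(sprintf("unknown ablation variant '%s' (see ?run_ablation)",
                      variant), "drp_config_error")
  cfg <- unclass(config)
  if (startsWith(variant, "gnn_")) {
    cfg$gnn_type <- sub("^gnn_", "", variant)
  } else if (startsWith(variant, "fp_only_")) {
    cfg$fp_kinds <- sub("^fp_only_", "", variant)
  } else if (startsWith(variant, "drop_omics_")) {
    dropped <- sub("^drop_omics_", "", variant)
    cfg$omics_used <- setdiff(cfg$omics_used, dropped)
    cfg$cell_dim <- cfg$latent_dim * length(cfg$omics_used)
  } else if (variant == "no_graph") {
    cfg$use_graph <- FALSE
  } else if (variant == "weighted_fp") {
    cfg$weighted_fp <- TRUE
  } else if (variant == "no_autoencoder") {
    cfg$fp_encoder_layers <- 1L
  }
  # "none" and "no_xgboost" leave the architecture unchanged; the
  # harness never fits the refiner
  class(cfg) <- "model_config"
  cfg
}

#' Run a set of ablation variants and tabulate the comparison
#'
#' @param variants Character vector of variant names.
#' @inheritParams run_ablation
#' @return Tibble with one row per variant.
#' @export
ablation_table <- function(variants, pairs, omics, features,
                           config = model_config(),
                           tconfig = train_config(), split = "test") {
  dplyr::bind_rows(lapply(variants, run_ablation, pairs = pairs,
                          omics = omics, features = features,
                          config = config, tconfig = tconfig,
                          split = split))
}
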