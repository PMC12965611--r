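#' Model configuration
#'
#' Architecture hyperparameters for the deep stage.  Defaults follow the
#' reference configuration: 128-dimensional latent embeddings per branch,
#' a 512-dimensional cell vector (four branches concatenated), a
#' 128-dimensional drug vector, a 256-dimensional shared bilinear space,
#' 4 attention heads, 3 graph-convolution layers and dropout 0.4.
#'
#' @param latent_dim Per-branch embedding length `l`.
#' @param shared_dim Shared bilinear projection dimension `d`.
#' @param n_heads Number of bilinear attention heads `K`.
#' @param gcn_layers Number of message-passing rounds.
#' @param dropout Dropout rate wherever dropout applies.
#' @param hidden_omics,hidden_fp Hidden width of the two-layer branch
#'   encoders.
#' @param head_hidden Hidden width of the prediction MLP.
#' @param drug_dim Fused drug embedding length.
#' @param gnn_type Graph encoder: `"gcn"` (default), `"gat"`, `"gin"` or
#'   `"gin_transformer"` (ablation variants).
#' @param fp_kinds Fingerprint kinds consumed (subset for ablations).
#' @param omics_used Omics branches consumed (subset for ablations).
#' @param use_graph If `FALSE`, the drug is encoded from fingerprints only.
#' @param weighted_fp Learn softmax weights over the fingerprint
#'   encodings before concatenation (ablation variant).
#' @param fp_encoder_layers 2 for the standard two-layer encoders, 1 for
#'   the single-layer ablation.
#' @param bn_fingerprint Apply batch normalization in the first layer of
#'   the fingerprint encoders (it is always applied in the omics
#'   branches).
#' @param morgan_radius Circular fingerprint radius.
#' @param seed Seed for weight initialization.
#' @return A `model_config` list; `cell_dim` is derived as
#'   `latent_dim * length(omics_used)`.
#' @export
model_config <- function(latent_dim = 128L, shared_dim = 256L,
                         n_heads = 4L, gcn_layers = 3L, dropout = 0.4,
                         hidden_omics = 128L, hidden_fp = 128L,
                         head_hidden = 64L, drug_dim = 128L,
                         gnn_type = c("gcn", "gat", "gin",
                                      "gin_transformer"),
                         fp_kinds = c("morgan", "pubchem", "espf"),
                         omics_used = c("expression", "mutation",
                                        "methylation", "pathway"),
                         use_graph = TRUE, weighted_fp = FALSE,
                         fp_encoder_layers = 2L, bn_fingerprint = TRUE,
                         morgan_radius = 2L, seed = 42L) {
  gnn_type <- match.arg(gnn_type)
  fp_kinds <- match.arg(fp_kinds, several.ok = TRUE)
  omics_used <- match.arg(omics_used, several.ok = TRUE)
  cfg <- list(
    latent_dim = chk_count(latent_dim, "latent_dim"),
    shared_dim = chk_count(shared_dim, "shared_dim"),
    n_heads = chk_count(n_heads, "n_heads"),
    gcn_layers = chk_count(gcn_layers, "gcn_layers"),
    dropout = chk_fraction(dropout, "dropout"),
    hidden_omics = chk_count(hidden_omics, "hidden_omics"),
    hidden_fp = chk_count(hidden_fp, "hidden_fp"),
    head_hidden = chk_count(head_hidden, "head_hidden"),
    drug_dim = chk_count(drug_dim, "drug_dim"),
    gnn_type = gnn_type, fp_kinds = fp_kinds, omics_used = omics_used,
    use_graph = isTRUE(use_graph), weighted_fp = isTRUE(weighted_fp),
    fp_encoder_layers = chk_count(fp_encoder_layers, "fp_encoder_layers"),
    bn_fingerprint = isTRUE(bn_fingerprint),
    morgan_radius = chk_count(morgan_radius, "morgan_radius"),
    seed = chk_count(seed, "seed"))
  cfg$cell_dim <- cfg$latent_dim * length(cfg$omics_used)
  if (length(cfg$fp_kinds) == 0L && !cfg$use_graph)
    drp_abort("model needs at least one drug representation",
              "drp_config_error")
  structure(cfg, class = "model_config")
}

#' Training configuration
#'
#' Optimization settings for the deep stage: Adam with initial learning
#' rate 1e-4, batch size 128, 200 epochs, MSE loss, and a
#' reduce-on-plateau schedule (factor 0.5, patience 10, minimum learning
#' rate 1e-6) monitoring validation loss.  The split is 80/10/10,
#' stratified by response deciles.
#'
#' @param lr Initial learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Number of epochs.
#' @param lr_factor,lr_patience,lr_min Reduce-on-plateau schedule.
#' @param split Numeric length-3 train/val/test fractions, summing to 1.
#' @param keep_best Restore the weights with minimal validation loss
#'   after training.
#' @param refiner_on What the boosted refiner is fitted on: the training
#'   split (default) or training plus validation.
#' @param seed Seed for splitting, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, batch_size = 128L, epochs = 200L,
                         lr_factor = 0.5, lr_patience = 10L,
                         lr_min = 1e-6, split = c(0.8, 0.1, 0.1),
                         keep_best = TRUE,
                         refiner_on = c("train", "train+val"),
                         seed = 42L) {
  if (length(split) != 3L || abs(sum(split) - 1) > 1e-8 || any(split < 0))
    drp_abort("`split` must be three non-negative fractions summing to 1",
              "drp_config_error")
  structure(list(
    lr = chk_fraction(lr, "lr", lo = 1e-12, hi = 1),
    batch_size = chk_count(batch_size, "batch_size"),
    epochs = chk_count(epochs, "epochs"),
    lr_factor = chk_fraction(lr_factor, "lr_factor", lo = 1e-6, hi = 1),
    lr_patience = chk_count(lr_patience, "lr_patience"),
    lr_min = lr_min,
    split = as.numeric(split),
    keep_best = isTRUE(keep_best),
    refiner_on = match.arg(refiner_on),
    seed = chk_count(seed, "seed")), class = "train_config")
}

#' Refiner configuration
#'
#' Gradient-boosted tree settings for the refinement stage: 100 trees of
#' maximum depth 6, learning rate 0.05, subsample ratio 0.8, squared
#' error objective with the boosting library's default L2 regularization
#' (lambda = 1).
#'
#' @param n_trees,max_depth,learning_rate,subsample,reg_lambda Boosting
#'   hyperparameters.
#' @param seed Seed for subsampling.
#' @return A `refiner_config` list.
#' @export
refiner_config <- function(n_trees = 100L, max_depth = 6L,
                           learning_rate = 0.05, subsample = 0.8,
                           reg_lambda = 1, seed = 42L) {
  structure(list(
    n_trees = chk_count(n_trees, "n_trees"),
    max_depth = as.integer(max_depth),
    learning_rate = chk_fraction(learning_rate, "learning_rate",
                                 lo = 1e-12, hi = 1),
    subsample = chk_fraction(subsample, "subsample", lo = 1e-6, hi = 1 + 1e-9),
    reg_lambda = as.numeric(reg_lambda),
    seed = chk_count(seed, "seed")), class = "refiner_config")
}
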