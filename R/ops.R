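# Evaluation-mode, single-entity views of the network's building blocks.
# These wrap the same code paths the training forward uses, so their
# outputs are exactly what the full model computes internally.

as_row <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1L) else x

#' Encode one omics profile through its branch
#'
#' Two affine layers with batch normalization, ReLU and dropout between
#' them (dropout inactive here: evaluation mode), compressing the profile
#' to the shared latent length.
#'
#' @param model A `drp_model`.
#' @param a Numeric vector (or matrix of rows) of the branch's input
#'   width.
#' @param branch One of the configured omics branches.
#' @return Matrix of latent vectors (rows x `latent_dim`), non-negative.
#' @export
omics_branch_forward <- function(model, a, branch) {
  if (!branch %in% model$config$omics_used)
    drp_abort(sprintf("unknown omics branch '%s'", branch),
              "drp_shape_error")
  branch_fwd(as_row(a), model$params$omics[[branch]],
             dropout = 0, train = FALSE, use_bn = TRUE, name = branch)$T
}

#' Encode a cell from its four omics profiles
#'
#' Concatenates the branch encodings in the fixed order expression,
#' mutation, methylation, pathway.
#'
#' @param model A `drp_model`.
#' @param profiles Named list with one vector (or row matrix) per
#'   configured branch.
#' @return Matrix (rows x `cell_dim`, 512 at defaults).
#' @export
cell_encode <- function(model, profiles) {
  parts <- lapply(model$config$omics_used, function(v) {
    if (is.null(profiles[[v]]))
      drp_abort(sprintf("missing profile for branch '%s'", v),
                "drp_shape_error")
    omics_branch_forward(model, profiles[[v]], v)
  })
  do.call(cbind, parts)
}

#' Encode a fingerprint set
#'
#' Each fingerprint kind passes through its own two-layer encoder to the
#' latent length; the encodings are concatenated (morgan, pubchem, espf
#' order at defaults).
#'
#' @param model A `drp_model`.
#' @param fps Named list with one binary vector (or row matrix) per
#'   configured kind.
#' @return Matrix (rows x `3 * latent_dim`, 384 at defaults).
#' @export
fingerprint_encode <- function(model, fps) {
  cfg <- model$config
  parts <- lapply(cfg$fp_kinds, function(k) {
    if (is.null(fps[[k]]))
      drp_abort(sprintf("missing fingerprint '%s'", k), "drp_shape_error")
    branch_fwd(as_row(fps[[k]]), model$params$fp[[k]], dropout = 0,
               train = FALSE,
               use_bn = cfg$bn_fingerprint && cfg$fp_encoder_layers >= 2L,
               name = k)$T
  })
  if (cfg$weighted_fp) {
    w <- softmax(model$params$fp_logits)
    parts <- Map(function(h, wk) h * wk, parts, as.list(w))
  }
  do.call(cbind, parts)
}

#' Encode a molecular graph
#'
#' Three rounds of mean message passing over neighbours plus self with
#' affine transform and ReLU, then mean pooling over atoms.
#'
#' @param model A `drp_model`.
#' @param graph A [smiles_to_graph()] result, or a list of them.
#' @return Matrix (graphs x `latent_dim`).
#' @export
gcn_encode <- function(model, graph) {
  if (!model$config$use_graph)
    drp_abort("this model was built without a graph encoder",
              "drp_config_error")
  graphs <- if (inherits(graph, "molecular_graph")) list(graph) else graph
  gb <- build_graph_batch(graphs)
  gnn_fwd(model$config$gnn_type, gb, model$params$gnn, dropout = 0,
          train = FALSE)$pooled
}

#' Fuse graph and fingerprint drug representations
#'
#' Concatenates the two encodings and projects them through a learned
#' affine map with ReLU to the drug embedding length.
#'
#' @param model A `drp_model`.
#' @param h_gcn Graph encoding (rows x `latent_dim`), or `NULL` for a
#'   fingerprint-only model.
#' @param h_fp Fingerprint encoding (rows x `3 * latent_dim`).
#' @return Matrix (rows x `drug_dim`, 128 at defaults), non-negative.
#' @export
drug_fuse <- function(model, h_gcn, h_fp) {
  drug_in <- cbind(if (model$config$use_graph) as_row(h_gcn),
                   as_row(h_fp))
  if (ncol(drug_in) != nrow(model$params$fuse$W))
    drp_abort(sprintf("drug fusion expects %d inputs, got %d",
                      nrow(model$params$fuse$W), ncol(drug_in)),
              "drp_shape_error")
  relu(dense_fwd(drug_in, model$params$fuse))
}

# shared bilinear scoring: one scalar per head per row; the cached form
# keeps the per-head projections for backpropagation
bilinear_scores_cached <- function(Ct, Dt, U_list) {
  CU <- lapply(U_list, function(U) Ct %*% U)
  I <- matrix(0, nrow(Ct), length(U_list))
  for (k in seq_along(U_list))
    I[, k] <- rowSums(CU[[k]] * Dt)
  list(I = I, CU = CU)
}

bilinear_scores <- function(Ct, Dt, U_list)
  bilinear_scores_cached(Ct, Dt, U_list)$I

#' Multi-head bilinear attention fusion
#'
#' Projects the cell and drug embeddings into the shared space, scores
#' each attention head with its bilinear form, and maps the head scores
#' through an affine layer with ReLU to the interaction vector `f`.
#'
#' @param model A `drp_model`.
#' @param h_cell Cell embeddings (rows x `cell_dim`).
#' @param h_drug Drug embeddings (rows x `drug_dim`).
#' @return List with `scores` (rows x `n_heads`) and `f`
#'   (rows x `latent_dim`).
#' @export
bilinear_fuse <- function(model, h_cell, h_drug) {
  p <- model$params$ban
  h_cell <- as_row(h_cell); h_drug <- as_row(h_drug)
  if (ncol(h_cell) != nrow(p$Wc$W) || ncol(h_drug) != nrow(p$Wd$W))
    drp_abort("cell or drug embedding width does not match the model",
              "drp_shape_error")
  Ct <- dense_fwd(h_cell, p$Wc)
  Dt <- dense_fwd(h_drug, p$Wd)
  I <- bilinear_scores(Ct, Dt, p$U)
  list(scores = I, f = relu(dense_fwd(I, p$Wf)),
       cell_proj = Ct, drug_proj = Dt)
}

#' Initial response prediction from an interaction vector
#'
#' The prediction MLP: affine (latent to 64), ReLU, dropout (inactive in
#' evaluation), affine (64 to 1).
#'
#' @param model A `drp_model`.
#' @param f Interaction vectors (rows x `latent_dim`).
#' @return Numeric vector of initial ln IC50 predictions.
#' @export
predict_ic50 <- function(model, f) {
  f <- as_row(f)
  if (ncol(f) != nrow(model$params$head$l1$W))
    drp_abort("interaction vector width does not match the model",
              "drp_shape_error")
  drop(dense_fwd(relu(dense_fwd(f, model$params$head$l1)),
                 model$params$head$l2))
}
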