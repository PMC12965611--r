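# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# first n molecules of the packaged corpus
fixture_drugs <- function(n = 12L) {
  utils::head(drug_corpus(), n)
}

fixture_features <- function(n = 12L) {
  cached(paste0("feats", n), function() featurize_drugs(fixture_drugs(n)))
}

# a small synthetic dataset with reduced omics widths, for fast training
small_sim <- function(seed = 1L, mechanism = "bilinear", n_cells = 30L,
                      n_drugs = 15L, noise_sd = 0.3) {
  key <- paste("sim", seed, mechanism, n_cells, n_drugs, noise_sd,
               sep = "_")
  cached(key, function() {
    cfg <- sim_config(n_cells = n_cells, n_drugs = n_drugs,
                      dim_expression = 50L, dim_mutation = 40L,
                      dim_methylation = 30L, dim_pathway = 60L,
                      noise_sd = noise_sd, mechanism = mechanism,
                      seed = seed)
    cells <- generate_cells(cfg)
    drugs <- generate_drugs(cfg)
    pairs <- generate_responses(cells, drugs, cfg)
    feats <- featurize_drugs(drugs)
    list(cfg = cfg, cells = cells, drugs = drugs, pairs = pairs,
         feats = feats)
  })
}

# a tiny randomly-initialized model over small input dims
tiny_model <- function(seed = 11L, ...) {
  cfg <- model_config(latent_dim = 8L, shared_dim = 6L, n_heads = 3L,
                      gcn_layers = 2L, dropout = 0.2, hidden_omics = 10L,
                      hidden_fp = 9L, head_hidden = 5L, drug_dim = 8L,
                      seed = seed, ...)
  dims <- list(
    omics = stats::setNames(rep(12L, length(cfg$omics_used)),
                            cfg$omics_used),
    fp = stats::setNames(rep(14L, length(cfg$fp_kinds)), cfg$fp_kinds))
  build_drp_model(dims, cfg)
}

tiny_batch_for <- function(model, n_pairs = 9L, n_cells = 5L,
                           n_drugs = 4L, seed = 21L) {
  cfg <- model$config
  set.seed(seed)
  graphs <- lapply(fixture_drugs(n_drugs)$smiles, smiles_to_graph)
  gb <- mographdrp:::build_graph_batch(graphs)
  list(
    cellX = lapply(stats::setNames(nm = cfg$omics_used), function(v)
      matrix(rnorm(n_cells * 12L), n_cells, 12L)),
    fp = lapply(stats::setNames(nm = cfg$fp_kinds), function(k)
      matrix(rbinom(n_drugs * 14L, 1, 0.4), n_drugs, 14L)),
    graphs = mographdrp:::subset_graph_batch(gb, seq_len(n_drugs)),
    cell_of_pair = sample(n_cells, n_pairs, replace = TRUE),
    drug_of_pair = sample(n_drugs, n_pairs, replace = TRUE))
}
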