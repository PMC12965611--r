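# Seeded synthetic benchmark generator.  Cells carry a low-dimensional
# latent state embedded (noisily) in all four omics profiles; drugs are
# real molecules sampled from the packaged corpus; responses follow a
# low-rank bilinear mechanism between the latent cell state and a fixed
# random projection of the drug's Morgan fingerprint, so the generating
# process lives in the model class the network is built to capture while
# staying independent of the network's own featurization weights.

#' Simulation configuration
#'
#' Defaults emulate the shapes of the real benchmark this package
#' targets: 536 cells x 169 drugs, omics widths 714 (expression),
#' 715 (mutation), 603 (methylation) and 1283 (pathway), and 10% of the
#' response grid missing.  The bilinear signal is scaled to standard
#' deviation 2 on the ln IC50 scale, so the default noise (sd 0.4) gives
#' a roughly 5:1 signal-to-noise ratio.
#'
#' @param n_cells,n_drugs Grid dimensions.
#' @param dim_expression,dim_mutation,dim_methylation,dim_pathway
#'   Feature counts per omics profile.
#' @param latent_dim Latent cell-state dimension.
#' @param missing_fraction Fraction of the grid masked as unmeasured.
#' @param noise_sd Observation noise on ln IC50.
#' @param mechanism `"bilinear"` (default), `"linear"` (rank-1), or
#'   `"step_residual"` (bilinear plus a drug-level threshold term that a
#'   smooth regressor underfits, exercising the refiner).
#' @param bilinear_rank Rank of the latent interaction matrix.
#' @param seed Master seed; all draws derive from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 536L, n_drugs = 169L,
                       dim_expression = 714L, dim_mutation = 715L,
                       dim_methylation = 603L, dim_pathway = 1283L,
                       latent_dim = 16L, missing_fraction = 0.10,
                       noise_sd = 0.4,
                       mechanism = c("bilinear", "linear",
                                     "step_residual"),
                       bilinear_rank = 4L, seed = 42L) {
  mechanism <- match.arg(mechanism)
  if (noise_sd < 0)
    drp_abort("noise_sd must be non-negative", "drp_config_error")
  structure(list(
    n_cells = chk_count(n_cells, "n_cells"),
    n_drugs = chk_count(n_drugs, "n_drugs"),
    dims = c(expression = chk_count(dim_expression, "dim_expression"),
             mutation = chk_count(dim_mutation, "dim_mutation"),
             methylation = chk_count(dim_methylation, "dim_methylation"),
             pathway = chk_count(dim_pathway, "dim_pathway")),
    latent_dim = chk_count(latent_dim, "latent_dim"),
    missing_fraction = chk_fraction(missing_fraction, "missing_fraction"),
    noise_sd = as.numeric(noise_sd),
    mechanism = mechanism,
    bilinear_rank = chk_count(bilinear_rank, "bilinear_rank"),
    seed = chk_count(seed, "seed")), class = "sim_config")
}

#' The packaged drug corpus
#'
#' @return Tibble of 200 named drugs with valid SMILES.
#' @export
drug_corpus <- function() {
  path <- system.file("extdata", "drug_smiles.tsv",
                      package = "mographdrp", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Generate synthetic cell-line omics profiles
#'
#' Draws a latent cell state and embeds it in all four profiles:
#' Gaussian expression / methylation / pathway matrices with per-feature
#' scale variation, and a binary mutation matrix whose per-gene
#' probabilities (base rate 0.05) are modulated by the latent state.
#'
#' @param config A [sim_config()].
#' @return An `omics_profile_set`; the latent matrix is attached as
#'   attribute `"latent"`.
#' @export
generate_cells <- function(config = sim_config()) {
  cfg <- config
  set.seed(derive_seed(cfg$seed, 101L))
  nc <- cfg$n_cells; ld <- cfg$latent_dim
  cell_ids <- sprintf("cell_%04d", seq_len(nc))
  latent <- matrix(rnorm(nc * ld), nc, ld)

  cont_profile <- function(g) {
    load <- matrix(rnorm(ld * g, 0, 0.6), ld, g)
    scales <- exp(rnorm(g, 0, 0.25))
    m <- latent %*% load + matrix(rnorm(nc * g, 0, 0.5), nc, g)
    m <- sweep(m, 2, scales, "*")
    dimnames(m) <- list(cell_ids, NULL)
    m
  }
  expression <- cont_profile(cfg$dims[["expression"]])
  colnames(expression) <- sprintf("EXP_%04d", seq_len(ncol(expression)))
  methylation <- cont_profile(cfg$dims[["methylation"]])
  colnames(methylation) <- sprintf("METH_%04d", seq_len(ncol(methylation)))
  pathway <- cont_profile(cfg$dims[["pathway"]])
  colnames(pathway) <- sprintf("PATH_%04d", seq_len(ncol(pathway)))

  gmut <- cfg$dims[["mutation"]]
  mut_load <- matrix(rnorm(ld * gmut, 0, 0.4), ld, gmut)
  logit_p <- stats::qlogis(0.05) + latent %*% mut_load
  mutation <- matrix(rbinom(nc * gmut, 1L, stats::plogis(logit_p)),
                     nc, gmut,
                     dimnames = list(cell_ids,
                                     sprintf("MUT_%04d", seq_len(gmut))))

  out <- structure(list(expression = expression, mutation = mutation,
                        methylation = methylation, pathway = pathway,
                        cell_ids = cell_ids),
                   class = "omics_profile_set")
  attr(out, "latent") <- latent
  out
}

#' Sample drugs from the packaged corpus
#'
#' @param config A [sim_config()].
#' @return Tibble with `drug_id`, `smiles`; sampling is without
#'   replacement and seeded.
#' @export
generate_drugs <- function(config = sim_config()) {
  corpus <- drug_corpus()
  if (config$n_drugs > nrow(corpus))
    drp_abort(sprintf(
      "n_drugs = %d exceeds the %d-molecule corpus; sample with a smaller grid",
      config$n_drugs, nrow(corpus)), "drp_config_error")
  set.seed(derive_seed(config$seed, 202L))
  corpus[sample(nrow(corpus), config$n_drugs), ]
}

#' Generate ground-truth responses for a synthetic grid
#'
#' Responses follow `y = mu + s * (latent_cell' A proj(drug)) + step +
#' noise`: a low-rank bilinear interaction between the latent cell state
#' and a fixed random projection of the drug's Morgan fingerprint,
#' standardized to signal sd 2 around a ln IC50 location of 2.  The
#' `"step_residual"` mechanism adds a drug-level threshold term; a
#' `missing_fraction` of the grid is masked uniformly at random.
#'
#' @param cells A [generate_cells()] result.
#' @param drugs A drug table from [generate_drugs()].
#' @param config The same [sim_config()].
#' @return A `pair_dataset` of observed pairs, with attributes
#'   `"ground_truth"` (generator parameters and the full response
#'   matrix) and `"missing"` (the masked pairs).
#' @export
generate_responses <- function(cells, drugs, config = sim_config()) {
  cfg <- config
  latent <- attr(cells, "latent")
  if (is.null(latent))
    drp_abort("cells must come from generate_cells()", "drp_data_error")
  nc <- length(cells$cell_ids); nd <- nrow(drugs)
  ld <- cfg$latent_dim

  fp <- morgan_matrix(drugs$smiles)
  set.seed(derive_seed(cfg$seed, 303L))
  proj <- matrix(rnorm(ncol(fp) * ld, 0, 1 / sqrt(ncol(fp))),
                 ncol(fp), ld)
  dproj <- fp %*% proj
  dproj <- scale(dproj)
  dproj[is.nan(dproj)] <- 0

  rank <- if (cfg$mechanism == "linear") 1L else cfg$bilinear_rank
  A <- matrix(0, ld, ld)
  for (k in seq_len(rank))
    A <- A + tcrossprod(rnorm(ld), rnorm(ld)) / sqrt(rank)
  raw <- latent %*% A %*% t(dproj)
  s <- stats::sd(raw)
  raw <- if (s > 0) (raw - mean(raw)) / s else raw

  step_term <- 0
  step_drug <- NULL
  if (cfg$mechanism == "step_residual") {
    step_drug <- as.numeric(dproj[, 1] > stats::median(dproj[, 1]))
    step_term <- matrix(step_drug, nc, nd, byrow = TRUE) * 1.5
  }

  mu <- 2; sig <- 2
  y_clean <- mu + sig * raw + step_term
  y <- y_clean + matrix(rnorm(nc * nd, 0, cfg$noise_sd), nc, nd)
  dimnames(y) <- list(cells$cell_ids, drugs$drug_id)

  mask <- matrix(stats::runif(nc * nd) < cfg$missing_fraction, nc, nd)
  grid <- tidyr::expand_grid(cell_id = cells$cell_ids,
                             drug_id = drugs$drug_id)
  grid$ln_ic50 <- y[cbind(match(grid$cell_id, cells$cell_ids),
                          match(grid$drug_id, drugs$drug_id))]
  grid$missing <- mask[cbind(match(grid$cell_id, cells$cell_ids),
                             match(grid$drug_id, drugs$drug_id))]

  observed <- grid[!grid$missing, c("drug_id", "cell_id", "ln_ic50")]
  observed$split <- "none"
  class(observed) <- c("pair_dataset", class(observed))
  attr(observed, "ground_truth") <- list(
    A = A, latent = latent, dproj = dproj, proj = proj,
    intercept = mu, scale = sig, step_drug = step_drug,
    y_clean = y_clean, y_full = y)
  attr(observed, "missing") <- grid[grid$missing,
                                    c("drug_id", "cell_id")]
  observed
}

#' Write a complete synthetic benchmark to disk
#'
#' Generates cells, drugs and responses and writes them in exactly the
#' formats the loaders consume (tab-delimited matrices with a cell_id
#' first column; drug and response TSVs), plus a flat key=value
#' manifest.  Same seed, same bytes.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file paths and record counts.
#' @export
generate_benchmark <- function(config = sim_config(), dir) {
  if (missing(dir)) drp_abort("an output directory is required",
                              "drp_config_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- generate_cells(config)
  drugs <- generate_drugs(config)
  pairs <- generate_responses(cells, drugs, config)

  wtsv <- function(x, file) utils::write.table(
    x, file.path(dir, file), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE)
  wmat <- function(m, file) {
    df <- data.frame(cell_id = rownames(m), m, check.names = FALSE)
    wtsv(df, file)
  }
  wtsv(drugs, "drugs.tsv")
  wmat(cells$expression, "expression.tsv")
  wmat(cells$mutation, "mutation.tsv")
  wmat(cells$methylation, "methylation.tsv")
  wmat(cells$pathway, "pathway.tsv")
  wtsv(pairs[c("drug_id", "cell_id", "ln_ic50")], "responses.tsv")

  manifest <- c(
    sprintf("seed=%d", config$seed),
    sprintf("mechanism=%s", config$mechanism),
    sprintf("n_cells=%d", config$n_cells),
    sprintf("n_drugs=%d", config$n_drugs),
    sprintf("missing_fraction=%g", config$missing_fraction),
    sprintf("noise_sd=%g", config$noise_sd),
    sprintf("n_observed=%d", nrow(pairs)),
    sprintf("n_missing=%d", nrow(attr(pairs, "missing"))))
  writeLines(manifest, file.path(dir, "manifest.txt"))

  invisible(list(dir = dir, n_observed = nrow(pairs),
                 n_missing = nrow(attr(pairs, "missing")),
                 files = list.files(dir)))
}
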