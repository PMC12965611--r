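# The seeded synthetic benchmark generator.

test_that("generated profiles match the configured shapes", {
  cfg <- sim_config(n_cells = 12L, n_drugs = 5L, seed = 3L)
  cells <- generate_cells(cfg)
  expect_identical(dim(cells$expression), c(12L, 714L))
  expect_identical(dim(cells$mutation), c(12L, 715L))
  expect_identical(dim(cells$methylation), c(12L, 603L))
  expect_identical(dim(cells$pathway), c(12L, 1283L))
  expect_true(all(cells$mutation %in% c(0L, 1L)))
  expect_identical(dim(attr(cells, "latent")), c(12L, 16L))
  # same seed, identical matrices
  cells2 <- generate_cells(cfg)
  expect_identical(cells$expression, cells2$expression)
  expect_identical(cells$mutation, cells2$mutation)
})

test_that("drug sampling is unique, seeded and parseable", {
  cfg <- sim_config(n_cells = 5L, n_drugs = 8L, seed = 4L)
  d1 <- generate_drugs(cfg)
  expect_identical(nrow(d1), 8L)
  expect_identical(anyDuplicated(d1$drug_id), 0L)
  expect_identical(d1, generate_drugs(cfg))
  for (s in d1$smiles) expect_s3_class(smiles_to_graph(s),
                                       "molecular_graph")
  expect_error(generate_drugs(sim_config(n_drugs = 10000L)),
               class = "drp_config_error")
})

test_that("zero missingness yields the full grid; truth is recomputable", {
  cfg <- sim_config(n_cells = 10L, n_drugs = 6L, missing_fraction = 0,
                    noise_sd = 0, seed = 5L)
  cells <- generate_cells(cfg)
  drugs <- generate_drugs(cfg)
  pairs <- generate_responses(cells, drugs, cfg)
  expect_identical(nrow(pairs), 60L)
  gt <- attr(pairs, "ground_truth")
  # with no noise the observed values equal the mechanism exactly
  recomputed <- gt$y_clean[cbind(match(pairs$cell_id, cells$cell_ids),
                                 match(pairs$drug_id, drugs$drug_id))]
  expect_equal(pairs$ln_ic50, unname(recomputed), tolerance = 1e-12)
  # and the bilinear form reproduces y_clean up to the affine scaling
  raw <- gt$latent %*% gt$A %*% t(gt$dproj)
  raw <- (raw - mean(raw)) / sd(raw)
  expect_equal(unname(gt$y_clean),
               unname(gt$intercept + gt$scale * raw), tolerance = 1e-9)
})

test_that("masking has binomial scale and is roughly uniform over drugs", {
  cfg <- sim_config(n_cells = 100L, n_drugs = 40L,
                    dim_expression = 30L, dim_mutation = 30L,
                    dim_methylation = 30L, dim_pathway = 30L,
                    missing_fraction = 0.1, seed = 6L)
  cells <- generate_cells(cfg)
  drugs <- generate_drugs(cfg)
  pairs <- generate_responses(cells, drugs, cfg)
  n_missing <- nrow(attr(pairs, "missing"))
  expect_identical(nrow(pairs) + n_missing, 4000L)
  # binomial(4000, 0.1) within 4 sd
  expect_lt(abs(n_missing - 400), 4 * sqrt(4000 * 0.1 * 0.9))
  # chi-square uniformity of missingness across drugs
  counts <- table(factor(attr(pairs, "missing")$drug_id,
                         levels = drugs$drug_id))
  chi <- suppressWarnings(chisq.test(counts))
  expect_gt(chi$p.value, 0.01)
})

test_that("the step-residual mechanism shifts exactly half the drugs", {
  cfg <- sim_config(n_cells = 20L, n_drugs = 10L, noise_sd = 0,
                    missing_fraction = 0, mechanism = "step_residual",
                    dim_expression = 20L, dim_mutation = 20L,
                    dim_methylation = 20L, dim_pathway = 20L, seed = 7L)
  cells <- generate_cells(cfg)
  drugs <- generate_drugs(cfg)
  pairs <- generate_responses(cells, drugs, cfg)
  gt <- attr(pairs, "ground_truth")
  expect_identical(sum(gt$step_drug), 5)
})

test_that("benchmark round-trips through the loaders byte-identically", {
  cfg <- sim_config(n_cells = 8L, n_drugs = 5L,
                    dim_expression = 15L, dim_mutation = 12L,
                    dim_methylation = 10L, dim_pathway = 20L, seed = 8L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- generate_benchmark(cfg, d1)
  r2 <- generate_benchmark(cfg, d2)
  for (f in r1$files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  om <- load_omics_set(file.path(d1, "expression.tsv"),
                       file.path(d1, "mutation.tsv"),
                       file.path(d1, "methylation.tsv"),
                       file.path(d1, "pathway.tsv"))
  expect_identical(length(om$cell_ids), 8L)
  drugs <- utils::read.delim(file.path(d1, "drugs.tsv"))
  pd <- load_response_table(file.path(d1, "responses.tsv"),
                            drug_ids = drugs$drug_id,
                            cell_ids = om$cell_ids)
  manifest <- readLines(file.path(d1, "manifest.txt"))
  n_obs <- as.integer(sub("n_observed=", "",
                          grep("n_observed", manifest, value = TRUE)))
  expect_identical(nrow(pd), n_obs)
  expect_identical(r1$n_observed, n_obs)
})
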