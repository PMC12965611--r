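# Molecular graphs and fingerprints.

test_that("smiles_to_graph counts atoms and bonds correctly", {
  cases <- list(
    list(smiles = "C", atoms = 1L, bonds = 0L),          # methane
    list(smiles = "CCO", atoms = 3L, bonds = 2L),        # ethanol
    list(smiles = "CC(=O)OC1=CC=CC=C1C(=O)O",            # aspirin
         atoms = 13L, bonds = 13L))
  for (cs in cases) {
    g <- smiles_to_graph(cs$smiles)
    expect_s3_class(g, "molecular_graph")
    expect_identical(g$n_atoms, cs$atoms)
    expect_identical(nrow(g$edges), cs$bonds)
    expect_identical(dim(g$node_features), c(cs$atoms, 78L))
    if (nrow(g$edges) > 0) {
      expect_true(all(g$edges >= 1 & g$edges <= g$n_atoms))
      expect_true(all(g$edges[, 1] < g$edges[, 2]))  # no self/dup edges
      expect_identical(nrow(unique(g$edges)), nrow(g$edges))
    }
  }
})

test_that("atom feature rows are valid one-hot blocks", {
  for (smiles in c("CC(=O)OC1=CC=CC=C1C(=O)O", "c1ccncc1", "ClCCl",
                   "CC(=O)[O-]", "C[N+](C)(C)C")) {
    f <- smiles_to_graph(smiles)$node_features
    expect_true(all(abs(rowSums(f[, 1:44, drop = FALSE]) - 1) < 1e-12))
    expect_true(all(abs(rowSums(f[, 45:55, drop = FALSE]) - 1) < 1e-12))
    expect_true(all(abs(rowSums(f[, 56:66, drop = FALSE]) - 1) < 1e-12))
    expect_true(all(abs(rowSums(f[, 67:77, drop = FALSE]) - 1) < 1e-12))
    expect_true(all(f[, 78] %in% c(0, 1)))
  }
})

test_that("methane atom descriptor puts degree at 0 and four hydrogens", {
  f <- smiles_to_graph("C")$node_features
  expect_equal(unname(f[1, 45]), 1)        # degree one-hot slot 0
  expect_equal(unname(f[1, 56 + 4]), 1)    # H-count one-hot slot 4
  expect_equal(unname(f[1, 78]), 0)        # not aromatic
  v <- atom_feature_vector("C", degree = 0, n_h = 4,
                           implicit_valence = 4, aromatic = FALSE)
  expect_length(v, 78)
  expect_equal(unname(f[1, ]), v)
})

test_that("aromatic atoms are flagged in both input forms of benzene", {
  g1 <- smiles_to_graph("c1ccccc1")
  g2 <- smiles_to_graph("C1=CC=CC=C1")
  expect_equal(sum(g1$node_features[, 78]), 6)
  expect_equal(sum(g2$node_features[, 78]), 6)
})

test_that("graph shape is invariant to aromatic vs kekulized input", {
  forms <- list(
    c("c1ccccc1C(=O)O", "C1=CC=CC=C1C(=O)O"),
    c("c1ccc2[nH]ccc2c1", "C1=CC2=C(C=C1)NC=C2"))
  for (pair in forms) {
    ga <- smiles_to_graph(pair[1]); gk <- smiles_to_graph(pair[2])
    expect_identical(ga$n_atoms, gk$n_atoms)
    expect_identical(nrow(ga$edges), nrow(gk$edges))
    degseq <- function(g) sort(tabulate(c(g$edges), nbins = g$n_atoms))
    expect_identical(degseq(ga), degseq(gk))
  }
})

test_that("unparseable SMILES raise a featurization error naming the drug", {
  err <- expect_error(smiles_to_graph("not a smiles((", drug_id = "d42"),
                      class = "drp_featurization_error")
  expect_match(conditionMessage(err), "d42")
  expect_error(smiles_to_graph(""), class = "drp_featurization_error")
})

test_that("fingerprints have the documented lengths and are binary", {
  fp <- fixture_features(6L)$fingerprints
  expect_identical(ncol(fp$morgan), 2048L)
  expect_identical(ncol(fp$pubchem), 881L)
  expect_identical(ncol(fp$espf), 2586L)
  for (k in names(fp)) {
    expect_true(all(fp[[k]] %in% c(0L, 1L)))
    expect_true(all(rowSums(fp[[k]]) >= 1))
  }
})

test_that("fingerprints are deterministic and input-form invariant", {
  for (kind in c("morgan", "pubchem", "espf")) {
    a <- fingerprint("CC(=O)OC1=CC=CC=C1C(=O)O", kind)
    b <- fingerprint("CC(=O)OC1=CC=CC=C1C(=O)O", kind)
    expect_identical(a, b)
  }
  # same molecule, aromatic vs kekulized notation
  m1 <- fingerprint("c1ccccc1O", "morgan")
  m2 <- fingerprint("C1=CC=CC=C1O", "morgan")
  expect_identical(m1, m2)
})

test_that("methane sets at least one circular-fingerprint bit", {
  expect_gte(sum(fingerprint("C", "morgan")), 1)
})

test_that("a smaller fixture vocabulary yields a matching espf length", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# fixture vocabulary", "C", "O", "C C", "C O", "( C"), tmp)
  tbl <- tibble::tibble(drug_id = c("ethanol", "benzene"),
                        smiles = c("CCO", "c1ccccc1"))
  feats <- featurize_drugs(tbl, kinds = "espf", vocab_path = tmp)
  expect_identical(ncol(feats$fingerprints$espf), 5L)
  # ethanol CCO contains "C", "O", "C C" and "C O" but not "( C"
  expect_equal(unname(feats$fingerprints$espf["ethanol", ]),
               c(1L, 1L, 1L, 1L, 0L))
})

test_that("missing vocabulary or rule table is a configuration error", {
  expect_error(load_espf_vocab("/nonexistent/vocab.txt"),
               class = "drp_config_error")
  expect_error(load_substructure_keys("/nonexistent/keys.tsv"),
               class = "drp_config_error")
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines("# only a header", empty)
  expect_error(load_espf_vocab(empty), class = "drp_config_error")
})

test_that("featurize_drugs validates ids and records versions", {
  bad <- tibble::tibble(drug_id = c("a", "a"), smiles = c("C", "CC"))
  expect_error(featurize_drugs(bad), class = "drp_data_error")
  feats <- fixture_features(6L)
  expect_true(!is.null(feats$versions$featurizer))
  expect_true(!is.null(feats$versions$substructure_keys))
  expect_true(!is.null(feats$versions$espf_vocab))
  expect_identical(feats$versions$morgan_radius, 2L)
})
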