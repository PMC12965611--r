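# The deep model: encoders, graph network, bilinear attention, head.

mfwd <- function(model, batch, train = FALSE)
  mographdrp:::model_forward(model, batch, train = train)

test_that("forward output shapes and eval-mode determinism", {
  model <- tiny_model()
  batch <- tiny_batch_for(model)
  fw1 <- mfwd(model, batch)
  fw2 <- mfwd(model, batch)
  expect_length(fw1$y_hat, 9L)
  expect_identical(dim(fw1$f), c(9L, model$config$latent_dim))
  expect_identical(dim(fw1$scores), c(9L, model$config$n_heads))
  expect_true(all(is.finite(fw1$y_hat)))
  expect_true(all(fw1$f >= 0))           # post-ReLU
  expect_identical(fw1$y_hat, fw2$y_hat)  # eval mode is deterministic
  expect_identical(fw1$f, fw2$f)
})

test_that("training mode is stochastic through dropout", {
  model <- tiny_model()
  batch <- tiny_batch_for(model)
  set.seed(1); a <- mfwd(model, batch, train = TRUE)$y_hat
  set.seed(2); b <- mfwd(model, batch, train = TRUE)$y_hat
  expect_false(identical(a, b))
  set.seed(7); c1 <- mfwd(model, batch, train = TRUE)$y_hat
  set.seed(7); c2 <- mfwd(model, batch, train = TRUE)$y_hat
  expect_identical(c1, c2)  # but reproducible under a fixed seed
})

test_that("omics branches are independent in the concatenated cell vector", {
  model <- tiny_model()
  batch <- tiny_batch_for(model)
  fw1 <- mfwd(model, batch)
  batch2 <- batch
  batch2$cellX$mutation <- batch2$cellX$mutation +
    matrix(rnorm(length(batch2$cellX$mutation)), nrow(batch2$cellX$mutation))
  fw2 <- mfwd(model, batch2)
  l <- model$config$latent_dim
  c1 <- fw1$cache$cellmat; c2 <- fw2$cache$cellmat
  expect_identical(c1[, 1:l], c2[, 1:l])                  # expression block
  expect_false(identical(c1[, l + 1:l], c2[, l + 1:l]))   # mutation block
  expect_identical(c1[, 2 * l + 1:l], c2[, 2 * l + 1:l])  # methylation
})

test_that("graph encoding is invariant to node permutation", {
  model <- tiny_model()
  smiles <- utils::head(drug_corpus(), 8L)$smiles
  set.seed(5)
  for (s in smiles[c(1, 4, 8)]) {
    g <- smiles_to_graph(s)
    perm <- sample(g$n_atoms)
    gp <- g
    gp$node_features <- g$node_features[order(perm), , drop = FALSE]
    gp$edges <- matrix(perm[g$edges], ncol = 2)
    gb1 <- mographdrp:::build_graph_batch(list(g))
    gb2 <- mographdrp:::build_graph_batch(list(gp))
    o1 <- mographdrp:::gnn_fwd("gcn", gb1, model$params$gnn,
                               dropout = 0, train = FALSE)$pooled
    o2 <- mographdrp:::gnn_fwd("gcn", gb2, model$params$gnn,
                               dropout = 0, train = FALSE)$pooled
    expect_equal(o1, o2, tolerance = 1e-6)
  }
})

test_that("homogeneous node features stay homogeneous through GCN layers", {
  model <- tiny_model()
  g <- smiles_to_graph("CC(=O)OC1=CC=CC=C1C(=O)O")
  shared <- g$node_features[1, ]
  g$node_features <- matrix(shared, g$n_atoms, 78, byrow = TRUE)
  gb <- mographdrp:::build_graph_batch(list(g))
  fw <- mographdrp:::gnn_fwd("gcn", gb, model$params$gnn,
                             dropout = 0, train = FALSE)
  for (cache in fw$caches) {
    spread <- apply(cache$Y, 2, function(col) diff(range(col)))
    expect_lt(max(spread), 1e-10)
  }
  # pooling over identical nodes equals the single-node case
  g1 <- g; g1$node_features <- matrix(shared, 1, 78)
  g1$edges <- g1$edges[0, , drop = FALSE]; g1$n_atoms <- 1L
  gb1 <- mographdrp:::build_graph_batch(list(g1))
  fw1 <- mographdrp:::gnn_fwd("gcn", gb1, model$params$gnn,
                              dropout = 0, train = FALSE)
  expect_equal(fw$pooled, fw1$pooled, tolerance = 1e-10)
})

test_that("bilinear scores equal the explicit double sum", {
  model <- tiny_model()
  batch <- tiny_batch_for(model)
  fw <- mfwd(model, batch)
  d <- model$config$shared_dim
  for (k in seq_len(model$config$n_heads)) {
    U <- model$params$ban$U[[k]]
    for (i in c(1L, 5L)) {
      hc <- fw$cache$Ct[i, ]; hd <- fw$cache$Dt[i, ]
      manual <- 0
      for (a in seq_len(d)) for (b in seq_len(d))
        manual <- manual + hc[a] * U[a, b] * hd[b]
      expect_equal(fw$scores[i, k], manual, tolerance = 1e-10)
    }
  }
  # identity matrix with basis vectors scores exactly one
  e1 <- c(1, rep(0, d - 1))
  expect_equal(drop(e1 %*% diag(d) %*% e1), 1)
})

test_that("batch forward equals per-pair forward", {
  model <- tiny_model()
  batch <- tiny_batch_for(model, n_pairs = 6L)
  full <- mfwd(model, batch)
  for (i in seq_len(6L)) {
    single <- batch
    single$cell_of_pair <- batch$cell_of_pair[i]
    single$drug_of_pair <- batch$drug_of_pair[i]
    fi <- mfwd(model, single)
    expect_equal(fi$y_hat, full$y_hat[i], tolerance = 1e-12)
    expect_equal(fi$f[1, ], full$f[i, ], tolerance = 1e-12)
  }
})

test_that("same drug with different cells gives different predictions", {
  model <- tiny_model()
  batch <- tiny_batch_for(model)
  batch$cell_of_pair <- c(1L, 2L)
  batch$drug_of_pair <- c(1L, 1L)
  fw <- mfwd(model, batch)
  expect_false(isTRUE(all.equal(fw$y_hat[1], fw$y_hat[2])))
})

test_that("dimension mismatches raise shape errors naming the branch", {
  model <- tiny_model()
  batch <- tiny_batch_for(model)
  batch$cellX$pathway <- batch$cellX$pathway[, 1:5]
  err <- expect_error(mfwd(model, batch), class = "drp_shape_error")
  expect_match(conditionMessage(err), "pathway")
})

test_that("analytic gradients match finite differences", {
  model <- tiny_model()
  model$config$dropout <- 0
  # move off exact ReLU kinks created by zero bias initialization
  set.seed(31)
  for (pp in mographdrp:::collect_leaf_paths(model$params))
    model$params[[pp]] <- model$params[[pp]] +
      rnorm(length(model$params[[pp]]), 0, 0.03)
  batch <- tiny_batch_for(model)
  y <- rnorm(9)
  fw <- mfwd(model, batch, train = TRUE)
  grads <- mographdrp:::model_backward(model, fw,
                                       mographdrp:::mse_grad(fw$y_hat, y))
  lossfn <- function(m) {
    f <- mfwd(m, batch, train = TRUE)
    mographdrp:::mse_loss(f$y_hat, y)
  }
  eps <- 1e-6
  paths <- list(c("ban", "U", "U2"), c("omics", "mutation", "l1", "W"),
                c("fp", "espf", "l2", "W"), c("gnn", "layers", "L1", "W"),
                c("fuse", "W"), c("head", "l1", "W"),
                c("omics", "expression", "bn", "gamma"))
  for (pp in paths) {
    leaf <- model$params[[pp]]
    for (i in sample(length(leaf), 2L)) {
      m2 <- model
      m2$params[[pp]][i] <- m2$params[[pp]][i] + eps
      up <- lossfn(m2)
      m2$params[[pp]][i] <- m2$params[[pp]][i] - 2 * eps
      dn <- lossfn(m2)
      num <- (up - dn) / (2 * eps)
      ana <- grads[[pp]][i]
      expect_equal(ana, num, tolerance = 1e-3)
    }
  }
})
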