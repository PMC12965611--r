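# The deep stage: per-omics branch encoders with batch normalization,
# fingerprint encoders, a graph encoder over the molecular graph, drug
# fusion, multi-head bilinear attention and the MLP prediction head.
# Forward passes cache every intermediate; backward passes walk the cache
# and return gradients shaped like the parameter list.

#' Build a drug-response model
#'
#' Initializes all weights (uniform fan-based init under the
#' configuration seed) for the configured architecture.  `input_dims`
#' fixes the per-branch input widths; they are normally inferred from the
#' data via [build_model_data()].
#'
#' @param input_dims List with named integer vectors `omics` (one entry
#'   per used branch) and `fp` (one entry per fingerprint kind).
#' @param config A [model_config()].
#' @return An object of class `drp_model`.
#' @export
build_drp_model <- function(input_dims, config = model_config()) {
  cfg <- config
  for (v in cfg$omics_used)
    if (is.na(input_dims$omics[v]))
      drp_abort(sprintf("missing input dim for omics branch '%s'", v),
                "drp_shape_error")
  for (k in cfg$fp_kinds)
    if (is.na(input_dims$fp[k]))
      drp_abort(sprintf("missing input dim for fingerprint '%s'", k),
                "drp_shape_error")

  set.seed(cfg$seed)
  l <- cfg$latent_dim
  p <- list()
  p$omics <- lapply(stats::setNames(nm = cfg$omics_used), function(v)
    list(l1 = init_dense(input_dims$omics[[v]], cfg$hidden_omics),
         bn = init_bn(cfg$hidden_omics),
         l2 = init_dense(cfg$hidden_omics, l)))
  p$fp <- lapply(stats::setNames(nm = cfg$fp_kinds), function(k) {
    if (cfg$fp_encoder_layers >= 2L) {
      br <- list(l1 = init_dense(input_dims$fp[[k]], cfg$hidden_fp),
                 l2 = init_dense(cfg$hidden_fp, l))
      if (cfg$bn_fingerprint) br$bn <- init_bn(cfg$hidden_fp)
      br
    } else {
      list(l1 = init_dense(input_dims$fp[[k]], l))
    }
  })
  if (cfg$weighted_fp) p$fp_logits <- numeric(length(cfg$fp_kinds))
  if (cfg$use_graph)
    p$gnn <- init_gnn(cfg$gnn_type, ATOM_FEATURE_DIM, l, cfg$gcn_layers)
  drug_in <- (if (cfg$use_graph) l else 0L) + l * length(cfg$fp_kinds)
  p$fuse <- init_dense(drug_in, cfg$drug_dim)
  a <- sqrt(6 / (2 * cfg$shared_dim))
  p$ban <- list(
    Wc = init_dense(cfg$cell_dim, cfg$shared_dim),
    Wd = init_dense(cfg$drug_dim, cfg$shared_dim),
    U = stats::setNames(
      lapply(seq_len(cfg$n_heads), function(k)
        matrix(stats::runif(cfg$shared_dim^2, -a, a),
               cfg$shared_dim, cfg$shared_dim)),
      paste0("U", seq_len(cfg$n_heads))),
    Wf = init_dense(cfg$n_heads, l))
  p$head <- list(l1 = init_dense(l, cfg$head_hidden),
                 l2 = init_dense(cfg$head_hidden, 1L))

  structure(list(params = p, config = cfg, input_dims = input_dims),
            class = "drp_model")
}

#' @export
print.drp_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<drp_model: cell %d-d (%s), drug %d-d (%s%s), %d bilinear heads>\n",
    cfg$cell_dim, paste(cfg$omics_used, collapse = "+"), cfg$drug_dim,
    if (cfg$use_graph) paste0(cfg$gnn_type, "+") else "",
    paste(cfg$fp_kinds, collapse = "+"), cfg$n_heads))
  invisible(x)
}

# ---- branch encoders ----------------------------------------------------

branch_fwd <- function(X, p, dropout, train, use_bn, name) {
  if (ncol(X) != nrow(p$l1$W))
    drp_abort(sprintf("branch '%s': input has %d features, expected %d",
                      name, ncol(X), nrow(p$l1$W)), "drp_shape_error")
  two_layer <- !is.null(p$l2)
  Z1 <- dense_fwd(X, p$l1)
  cache <- list(X = X)
  if (two_layer) {
    if (use_bn) {
      bnr <- bn_fwd(Z1, p$bn, train)
      Y1 <- bnr$Y; cache$bnr <- bnr; p$bn <- bnr$p
    } else Y1 <- Z1
    R1 <- relu(Y1)
    dp <- dropout_fwd(R1, dropout, train)
    Z2 <- dense_fwd(dp$Y, p$l2)
    Tout <- relu(Z2)
    cache <- c(cache, list(R1 = R1, mask = dp$mask, H1 = dp$Y,
                           Tout = Tout))
  } else {
    Tout <- relu(Z1)
    cache$Tout <- Tout
  }
  list(T = Tout, cache = cache, p = p)
}

branch_bwd <- function(p, cache, dT, use_bn) {
  two_layer <- !is.null(p$l2)
  if (two_layer) {
    dZ2 <- relu_bwd(dT, cache$Tout)
    bw2 <- dense_bwd(cache$H1, p$l2, dZ2)
    dR1 <- dropout_bwd(bw2$dX, cache$mask)
    dY1 <- relu_bwd(dR1, cache$R1)
    grad <- list(l2 = bw2$grad)
    if (use_bn) {
      bnb <- bn_bwd(cache$bnr, p$bn, dY1)
      dZ1 <- bnb$dX; grad$bn <- bnb$grad
    } else dZ1 <- dY1
    bw1 <- dense_bwd(cache$X, p$l1, dZ1)
    grad$l1 <- bw1$grad
  } else {
    dZ1 <- relu_bwd(dT, cache$Tout)
    bw1 <- dense_bwd(cache$X, p$l1, dZ1)
    grad <- list(l1 = bw1$grad)
  }
  list(grad = grad, dX = bw1$dX)
}

softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }

# ---- full forward -------------------------------------------------------

# batch: list(cellX = named list of unique-cell matrices,
#             fp = named list of unique-drug fingerprint matrices,
#             graphs = subset graph batch or NULL,
#             cell_of_pair, drug_of_pair = indices into the unique sets)
model_forward <- function(model, batch, train = FALSE) {
  cfg <- model$config; p <- model$params
  cache <- list()

  cellT <- vector("list", length(cfg$omics_used))
  names(cellT) <- cfg$omics_used
  cache$omics <- list()
  for (v in cfg$omics_used) {
    r <- branch_fwd(batch$cellX[[v]], p$omics[[v]], cfg$dropout, train,
                    use_bn = TRUE, name = v)
    cellT[[v]] <- r$T; cache$omics[[v]] <- r$cache
    p$omics[[v]] <- r$p
  }
  cellmat <- do.call(cbind, cellT)

  fpH <- vector("list", length(cfg$fp_kinds))
  names(fpH) <- cfg$fp_kinds
  cache$fp <- list()
  for (k in cfg$fp_kinds) {
    r <- branch_fwd(batch$fp[[k]], p$fp[[k]], cfg$dropout, train,
                    use_bn = cfg$bn_fingerprint, name = k)
    fpH[[k]] <- r$T; cache$fp[[k]] <- r$cache
    p$fp[[k]] <- r$p
  }
  if (cfg$weighted_fp) {
    w <- softmax(p$fp_logits)
    cache$fp_raw <- fpH
    cache$fp_w <- w
    fpH <- Map(function(h, wk) h * wk, fpH, as.list(w))
  }
  fpcat <- if (length(fpH)) do.call(cbind, fpH) else NULL

  if (cfg$use_graph) {
    gfw <- gnn_fwd(cfg$gnn_type, batch$graphs, p$gnn, cfg$dropout, train)
    cache$gnn <- gfw
    drug_in <- cbind(gfw$pooled, fpcat)
  } else {
    drug_in <- fpcat
  }
  Zf <- dense_fwd(drug_in, p$fuse)
  Hd <- relu(Zf)
  cache$drug_in <- drug_in; cache$Hd <- Hd

  Ctu <- dense_fwd(cellmat, p$ban$Wc)
  Dtu <- dense_fwd(Hd, p$ban$Wd)
  Ct <- Ctu[batch$cell_of_pair, , drop = FALSE]
  Dt <- Dtu[batch$drug_of_pair, , drop = FALSE]
  n <- nrow(Ct)
  bs <- bilinear_scores_cached(Ct, Dt, p$ban$U)
  I <- bs$I; CU <- bs$CU
  Zf2 <- dense_fwd(I, p$ban$Wf)
  Fv <- relu(Zf2)

  Z1h <- dense_fwd(Fv, p$head$l1)
  R1h <- relu(Z1h)
  dph <- dropout_fwd(R1h, cfg$dropout, train)
  yhat <- drop(dense_fwd(dph$Y, p$head$l2))

  cache <- c(cache, list(
    cellmat = cellmat, Ctu = Ctu, Dtu = Dtu, Ct = Ct, Dt = Dt, CU = CU,
    I = I, Fv = Fv, R1h = R1h, head_mask = dph$mask, H1h = dph$Y,
    n_pairs = n, batch = batch))
  model$params <- p  # batch-norm running statistics updated in training
  list(y_hat = yhat, f = Fv, scores = I, cache = cache, model = model)
}

# dY: gradient of the loss wrt y_hat (length n); returns nested grads
model_backward <- function(model, fw, dY) {
  cfg <- model$config; p <- model$params; cache <- fw$cache
  batch <- cache$batch
  grads <- list()

  dy <- matrix(dY, ncol = 1L)
  bw2h <- dense_bwd(cache$H1h, p$head$l2, dy)
  dR1h <- dropout_bwd(bw2h$dX, cache$head_mask)
  dZ1h <- relu_bwd(dR1h, cache$R1h)
  bw1h <- dense_bwd(cache$Fv, p$head$l1, dZ1h)
  grads$head <- list(l1 = bw1h$grad, l2 = bw2h$grad)

  dF <- bw1h$dX
  dZf2 <- relu_bwd(dF, cache$Fv)
  bwf <- dense_bwd(cache$I, p$ban$Wf, dZf2)
  dI <- bwf$dX

  dCt <- matrix(0, nrow(cache$Ct), ncol(cache$Ct))
  dDt <- matrix(0, nrow(cache$Dt), ncol(cache$Dt))
  dU <- vector("list", cfg$n_heads)
  for (k in seq_len(cfg$n_heads)) {
    dIk <- dI[, k]
    dCt <- dCt + tcrossprod(cache$Dt, p$ban$U[[k]]) * dIk
    dDt <- dDt + cache$CU[[k]] * dIk
    dU[[k]] <- crossprod(cache$Ct * dIk, cache$Dt)
  }
  nuc <- nrow(cache$Ctu); nud <- nrow(cache$Dtu)
  dCtu <- rowsum_full(dCt, batch$cell_of_pair, nuc)
  dDtu <- rowsum_full(dDt, batch$drug_of_pair, nud)
  bwWc <- dense_bwd(cache$cellmat, p$ban$Wc, dCtu)
  bwWd <- dense_bwd(cache$Hd, p$ban$Wd, dDtu)
  names(dU) <- paste0("U", seq_len(cfg$n_heads))
  grads$ban <- list(Wc = bwWc$grad, Wd = bwWd$grad, U = dU,
                    Wf = bwf$grad)

  dHd <- bwWd$dX
  dZf <- relu_bwd(dHd, cache$Hd)
  bwfuse <- dense_bwd(cache$drug_in, p$fuse, dZf)
  grads$fuse <- bwfuse$grad
  d_drug_in <- bwfuse$dX

  l <- cfg$latent_dim
  off <- 0L
  if (cfg$use_graph) {
    dPool <- d_drug_in[, seq_len(l), drop = FALSE]
    gbw <- gnn_bwd(cfg$gnn_type, batch$graphs, p$gnn, cache$gnn, dPool)
    grads$gnn <- gbw$grad
    off <- l
  }
  grads$fp <- list()
  if (length(cfg$fp_kinds)) {
    if (cfg$weighted_fp) dlog <- numeric(length(cfg$fp_kinds))
    for (ki in seq_along(cfg$fp_kinds)) {
      k <- cfg$fp_kinds[ki]
      dhk <- d_drug_in[, off + seq_len(l), drop = FALSE]
      off <- off + l
      if (cfg$weighted_fp) {
        w <- cache$fp_w
        dlog[ki] <- sum(dhk * cache$fp_raw[[k]])
        dhk <- dhk * w[ki]
      }
      grads$fp[[k]] <- branch_bwd(p$fp[[k]], cache$fp[[k]], dhk,
                                  use_bn = cfg$bn_fingerprint &&
                                    cfg$fp_encoder_layers >= 2L)$grad
    }
    if (cfg$weighted_fp) {
      w <- cache$fp_w
      grads$fp_logits <- w * (dlog - sum(w * dlog))
    }
  }

  dcell <- bwWc$dX
  grads$omics <- list()
  for (vi in seq_along(cfg$omics_used)) {
    v <- cfg$omics_used[vi]
    dTv <- dcell[, (vi - 1L) * l + seq_len(l), drop = FALSE]
    grads$omics[[v]] <- branch_bwd(p$omics[[v]], cache$omics[[v]], dTv,
                                   use_bn = TRUE)$grad
  }
  grads
}

mse_loss <- function(y_hat, y) mean((y_hat - y)^2)
mse_grad <- function(y_hat, y) 2 * (y_hat - y) / length(y)

# ---- dataset / batch assembly ------------------------------------------

#' Assemble model-ready tensors from features and pairs
#'
#' Binds the scaled omics matrices, fingerprint matrices and stacked
#' graph batch together with integer-indexed pairs, so training and
#' prediction only do index arithmetic.
#'
#' @param pairs A `pair_dataset` (or data frame with `drug_id`,
#'   `cell_id`, `ln_ic50`).
#' @param omics An `omics_profile_set` (already scaled for training).
#' @param features A [featurize_drugs()] result.
#' @param config A [model_config()].
#' @return A `drp_model_data` list.
#' @export
build_model_data <- function(pairs, omics, features,
                             config = model_config()) {
  cfg <- config
  cell_ids <- omics$cell_ids
  drug_ids <- features$drug_ids
  ci <- match(pairs$cell_id, cell_ids)
  di <- match(pairs$drug_id, drug_ids)
  if (anyNA(ci) || anyNA(di))
    drp_abort("pairs reference drugs or cells missing from the features",
              "drp_data_error")
  cellX <- lapply(stats::setNames(nm = cfg$omics_used),
                  function(v) unname(omics[[v]]))
  fp <- lapply(stats::setNames(nm = cfg$fp_kinds), function(k) {
    m <- features$fingerprints[[k]]
    if (is.null(m))
      drp_abort(sprintf("fingerprint kind '%s' missing from features", k),
                "drp_config_error")
    unname(m)
  })
  gb <- if (cfg$use_graph) build_graph_batch(features$graphs) else NULL
  input_dims <- list(
    omics = vapply(cellX, ncol, integer(1)),
    fp = if (length(fp)) vapply(fp, ncol, integer(1)) else integer(0))
  structure(list(
    pairs = tibble::as_tibble(pairs), cell_i = ci, drug_i = di,
    cellX = cellX, fp = fp, graph_batch = gb,
    cell_ids = cell_ids, drug_ids = drug_ids,
    y = pairs$ln_ic50, input_dims = input_dims, config = cfg),
    class = "drp_model_data")
}

make_batch <- function(data, rows) {
  ci <- data$cell_i[rows]; di <- data$drug_i[rows]
  ucells <- sort(unique(ci)); udrugs <- sort(unique(di))
  list(
    cellX = lapply(data$cellX, function(m) m[ucells, , drop = FALSE]),
    fp = lapply(data$fp, function(m) m[udrugs, , drop = FALSE]),
    graphs = if (!is.null(data$graph_batch))
      subset_graph_batch(data$graph_batch, udrugs) else NULL,
    cell_of_pair = match(ci, ucells),
    drug_of_pair = match(di, udrugs))
}

# eval-mode forward over arbitrary row sets, in chunks
predict_forward <- function(model, data, rows = seq_len(nrow(data$pairs)),
                            chunk = 4096L) {
  n <- length(rows)
  y <- numeric(n)
  f <- matrix(0, n, model$config$latent_dim)
  for (s in seq(1L, n, by = chunk)) {
    idx <- rows[s:min(s + chunk - 1L, n)]
    fw <- model_forward(model, make_batch(data, idx), train = FALSE)
    pos <- seq_along(idx) + s - 1L
    y[pos] <- fw$y_hat
    f[pos, ] <- fw$f
  }
  list(y_hat = y, f = f)
}
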