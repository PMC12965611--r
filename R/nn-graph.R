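# Graph encoders over batched molecular graphs.  Graphs are stacked into
# one node-feature matrix with a per-node graph index; neighbourhood
# aggregation is a single sparse matrix product over the block-diagonal
# adjacency, and graph readout is mean pooling via rowsum().
#
# Four message-passing flavours are provided: mean aggregation with a
# self-loop ("gcn", the default), sum aggregation with a two-layer MLP
# ("gin"), single-head additive attention ("gat"), and "gin_transformer"
# (GIN stack followed by one residual self-attention block per graph).

build_graph_batch <- function(graphs) {
  n_nodes <- vapply(graphs, function(g) g$n_atoms, integer(1))
  offsets <- cumsum(c(0L, n_nodes[-length(n_nodes)]))
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  gidx <- rep(seq_along(graphs), n_nodes)

  src <- integer(0); dst <- integer(0)
  for (k in seq_along(graphs)) {
    e <- graphs[[k]]$edges
    if (nrow(e) > 0L) {
      src <- c(src, e[, 1] + offsets[k], e[, 2] + offsets[k])
      dst <- c(dst, e[, 2] + offsets[k], e[, 1] + offsets[k])
    }
  }
  N <- nrow(X)
  deg <- tabulate(dst, nbins = N)
  # mean over {neighbours union self}: row i carries 1/(deg_i + 1)
  w <- c(1 / (deg[dst] + 1), 1 / (deg + 1))
  ahat <- Matrix::sparseMatrix(i = c(dst, seq_len(N)),
                               j = c(src, seq_len(N)),
                               x = w, dims = c(N, N))
  aplus <- Matrix::sparseMatrix(i = c(dst, seq_len(N)),
                                j = c(src, seq_len(N)),
                                x = 1, dims = c(N, N))
  # directed edges including self-loops, for attention variants
  esrc <- c(src, seq_len(N)); edst <- c(dst, seq_len(N))
  ord <- order(edst, esrc)

  list(X = X, gidx = gidx, n_graphs = length(graphs),
       n_nodes = n_nodes, ahat = ahat, aplus = aplus,
       esrc = esrc[ord], edst = edst[ord])
}

# restrict a stacked batch to a subset of graphs (indices into the batch)
subset_graph_batch <- function(gb, which_graphs) {
  keep_nodes <- which(gb$gidx %in% which_graphs)
  node_map <- integer(nrow(gb$X)); node_map[keep_nodes] <-
    seq_along(keep_nodes)
  gmap <- integer(gb$n_graphs); gmap[which_graphs] <-
    seq_along(which_graphs)
  ekeep <- gb$esrc %in% keep_nodes & gb$edst %in% keep_nodes
  list(X = gb$X[keep_nodes, , drop = FALSE],
       gidx = gmap[gb$gidx[keep_nodes]],
       n_graphs = length(which_graphs),
       n_nodes = gb$n_nodes[which_graphs],
       ahat = gb$ahat[keep_nodes, keep_nodes, drop = FALSE],
       aplus = gb$aplus[keep_nodes, keep_nodes, drop = FALSE],
       esrc = node_map[gb$esrc[ekeep]],
       edst = node_map[gb$edst[ekeep]])
}

init_gnn <- function(type, in_dim, hidden, n_layers) {
  dims <- c(in_dim, rep(hidden, n_layers))
  layers <- vector("list", n_layers)
  for (t in seq_len(n_layers)) {
    layers[[t]] <- switch(
      type,
      gcn = init_dense(dims[t], dims[t + 1]),
      gat = c(init_dense(dims[t], dims[t + 1]),
              list(a_src = stats::runif(dims[t + 1], -0.1, 0.1),
                   a_dst = stats::runif(dims[t + 1], -0.1, 0.1))),
      gin = ,
      gin_transformer = list(l1 = init_dense(dims[t], dims[t + 1]),
                             l2 = init_dense(dims[t + 1], dims[t + 1])))
  }
  names(layers) <- paste0("L", seq_len(n_layers))
  p <- list(layers = layers)
  if (type == "gin_transformer") {
    p$attn <- list(Wq = init_dense(hidden, hidden)$W,
                   Wk = init_dense(hidden, hidden)$W,
                   Wv = init_dense(hidden, hidden)$W)
  }
  p
}

mean_pool <- function(H, gidx, n_graphs, n_nodes) {
  rowsum(H, group = factor(gidx, levels = seq_len(n_graphs))) / n_nodes
}

gnn_fwd <- function(type, gb, params, dropout, train) {
  H <- gb$X
  caches <- vector("list", length(params$layers))
  for (t in seq_along(params$layers)) {
    p <- params$layers[[t]]
    cache <- list(H_in = H)
    if (type == "gcn") {
      M <- as.matrix(gb$ahat %*% H)
      Z <- dense_fwd(M, p)
      cache$M <- M
    } else if (type %in% c("gin", "gin_transformer")) {
      S <- as.matrix(gb$aplus %*% H)
      A1 <- relu(dense_fwd(S, p$l1))
      Z <- dense_fwd(A1, p$l2)
      cache$S <- S; cache$A1 <- A1
    } else if (type == "gat") {
      HW <- dense_fwd(H, p)
      s_src <- drop(HW %*% p$a_src)
      s_dst <- drop(HW %*% p$a_dst)
      e <- s_src[gb$esrc] + s_dst[gb$edst]
      pre <- e
      e <- ifelse(e > 0, e, 0.2 * e)  # LeakyReLU
      gfac <- factor(gb$edst, levels = seq_len(nrow(H)))
      emax <- as.vector(tapply(e, gfac, max))
      ex <- exp(e - emax[gb$edst])
      denom <- rowsum(ex, gfac)
      alpha <- as.vector(ex / denom[gb$edst])
      Z <- rowsum(HW[gb$esrc, , drop = FALSE] * alpha, gfac)
      cache$HW <- HW; cache$alpha <- alpha; cache$pre <- pre
    }
    Y <- relu(Z)
    dp <- dropout_fwd(Y, dropout, train)
    cache$Y <- Y; cache$mask <- dp$mask
    caches[[t]] <- cache
    H <- dp$Y
  }
  attn_cache <- NULL
  if (type == "gin_transformer") {
    res <- attn_fwd(H, gb, params$attn)
    attn_cache <- res$cache
    H <- res$H
  }
  pooled <- mean_pool(H, gb$gidx, gb$n_graphs, gb$n_nodes)
  list(pooled = pooled, caches = caches, attn_cache = attn_cache,
       H_final = H)
}

gnn_bwd <- function(type, gb, params, fw, dP) {
  dH <- (dP / gb$n_nodes)[gb$gidx, , drop = FALSE]
  grads <- list(layers = stats::setNames(
    vector("list", length(params$layers)), names(params$layers)))
  if (type == "gin_transformer") {
    res <- attn_bwd(gb, params$attn, fw$attn_cache, dH)
    grads$attn <- res$grad
    dH <- res$dH
  }
  for (t in rev(seq_along(params$layers))) {
    p <- params$layers[[t]]
    cache <- fw$caches[[t]]
    dY <- dropout_bwd(dH, cache$mask)
    dZ <- relu_bwd(dY, cache$Y)
    if (type == "gcn") {
      bw <- dense_bwd(cache$M, p, dZ)
      grads$layers[[t]] <- bw$grad
      dH <- as.matrix(Matrix::crossprod(gb$ahat, bw$dX))
    } else if (type %in% c("gin", "gin_transformer")) {
      bw2 <- dense_bwd(cache$A1, p$l2, dZ)
      dA1 <- relu_bwd(bw2$dX, cache$A1)
      bw1 <- dense_bwd(cache$S, p$l1, dA1)
      grads$layers[[t]] <- list(l1 = bw1$grad, l2 = bw2$grad)
      dH <- as.matrix(Matrix::crossprod(gb$aplus, bw1$dX))
    } else if (type == "gat") {
      HW <- cache$HW; alpha <- cache$alpha; pre <- cache$pre
      gfac <- factor(gb$edst, levels = seq_len(nrow(HW)))
      dHW <- rowsum(dZ[gb$edst, , drop = FALSE] * alpha,
                    factor(gb$esrc, levels = seq_len(nrow(HW))))
      dalpha <- rowSums(dZ[gb$edst, , drop = FALSE] *
                          HW[gb$esrc, , drop = FALSE])
      wsum <- rowsum(alpha * dalpha, gfac)
      de <- alpha * (dalpha - wsum[gb$edst])
      dpre <- de * ifelse(pre > 0, 1, 0.2)
      ds_src <- rowsum(dpre, factor(gb$esrc, levels = seq_len(nrow(HW))))
      ds_dst <- rowsum(dpre, gfac)
      dHW <- dHW + drop(ds_src) %o% p$a_src + drop(ds_dst) %o% p$a_dst
      da_src <- drop(crossprod(HW, ds_src))
      da_dst <- drop(crossprod(HW, ds_dst))
      bw <- dense_bwd(cache$H_in, p, dHW)
      grads$layers[[t]] <- c(bw$grad, list(a_src = da_src, a_dst = da_dst))
      dH <- bw$dX
      next
    }
  }
  list(dX = dH, grad = grads)
}

# one residual scaled-dot-product self-attention block, per graph
attn_fwd <- function(H, gb, p) {
  d <- ncol(p$Wq)
  Hout <- H
  caches <- vector("list", gb$n_graphs)
  for (g in seq_len(gb$n_graphs)) {
    idx <- which(gb$gidx == g)
    Hg <- H[idx, , drop = FALSE]
    Q <- Hg %*% p$Wq; K <- Hg %*% p$Wk; V <- Hg %*% p$Wv
    S <- Q %*% t(K) / sqrt(d)
    S <- S - apply(S, 1, max)
    E <- exp(S)
    A <- E / rowSums(E)
    Hout[idx, ] <- Hg + A %*% V
    caches[[g]] <- list(idx = idx, Hg = Hg, Q = Q, K = K, V = V, A = A)
  }
  list(H = Hout, cache = caches)
}

attn_bwd <- function(gb, p, caches, dHout) {
  d <- ncol(p$Wq)
  dH <- dHout
  gWq <- p$Wq * 0; gWk <- p$Wk * 0; gWv <- p$Wv * 0
  for (g in seq_len(gb$n_graphs)) {
    cc <- caches[[g]]
    dOg <- dHout[cc$idx, , drop = FALSE]
    dA <- dOg %*% t(cc$V)
    dV <- t(cc$A) %*% dOg
    dS <- cc$A * (dA - rowSums(cc$A * dA))
    dQ <- dS %*% cc$K / sqrt(d)
    dK <- t(dS) %*% cc$Q / sqrt(d)
    gWq <- gWq + crossprod(cc$Hg, dQ)
    gWk <- gWk + crossprod(cc$Hg, dK)
    gWv <- gWv + crossprod(cc$Hg, dV)
    dH[cc$idx, ] <- dOg + dQ %*% t(p$Wq) + dK %*% t(p$Wk) +
      dV %*% t(p$Wv)
  }
  list(dH = dH, grad = list(Wq = gWq, Wk = gWk, Wv = gWv))
}
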