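# Minimal dense-network machinery: fan-based uniform init, affine layers,
# batch normalization, inverted dropout and Adam, all as explicit
# forward/backward pairs over base matrices.  Written for the fixed
# architectures in this package rather than as a general autodiff.

# fast column-wise ops (avoid sweep()'s aperm overhead)
add_cols <- function(X, b) X + rep(b, each = nrow(X))
mul_cols <- function(X, s) X * rep(s, each = nrow(X))

init_dense <- function(fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  list(W = matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out),
       b = numeric(fan_out))
}

dense_fwd <- function(X, p) add_cols(X %*% p$W, p$b)

dense_bwd <- function(X, p, dY) {
  list(dX = tcrossprod(dY, p$W),
       grad = list(W = crossprod(X, dY), b = colSums(dY)))
}

relu <- function(X) { X[X < 0] <- 0; X }
relu_bwd <- function(dY, Y) { dY[Y <= 0] <- 0; dY }

init_bn <- function(d) {
  list(gamma = rep(1, d), beta = numeric(d),
       run_mean = numeric(d), run_var = rep(1, d))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_fwd <- function(X, p, train) {
  if (train && nrow(X) > 1L) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    v[v < 0] <- 0
    p$run_mean <- (1 - BN_MOMENTUM) * p$run_mean + BN_MOMENTUM * mu
    p$run_var <- (1 - BN_MOMENTUM) * p$run_var + BN_MOMENTUM * v
  } else {
    mu <- p$run_mean; v <- p$run_var
  }
  inv_sd <- 1 / sqrt(v + BN_EPS)
  xhat <- mul_cols(add_cols(X, -mu), inv_sd)
  Y <- add_cols(mul_cols(xhat, p$gamma), p$beta)
  list(Y = Y, xhat = xhat, inv_sd = inv_sd, batch = train && nrow(X) > 1L,
       p = p)
}

bn_bwd <- function(cache, p, dY) {
  xhat <- cache$xhat; inv_sd <- cache$inv_sd
  n <- nrow(xhat)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- mul_cols(dY, p$gamma)
  if (cache$batch) {
    # backprop through the batch statistics
    dX <- mul_cols(
      dxhat - rep(colMeans(dxhat), each = n) -
        xhat * rep(colMeans(dxhat * xhat), each = n),
      inv_sd)
  } else {
    dX <- mul_cols(dxhat, inv_sd)
  }
  list(dX = dX, grad = list(gamma = dgamma, beta = dbeta))
}

dropout_fwd <- function(X, rate, train) {
  if (!train || rate <= 0)
    return(list(Y = X, mask = NULL))
  keep <- 1 - rate
  mask <- matrix((stats::runif(length(X)) < keep) / keep,
                 nrow(X), ncol(X))
  list(Y = X * mask, mask = mask)
}

dropout_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

# ---- Adam ---------------------------------------------------------------

# Parameters live in a nested named list whose leaves are numeric.
# Leaf paths are collected once; updates then address leaves directly
# (x[[c("a","b")]]), which avoids copying whole subtrees every step.
collect_leaf_paths <- function(params) {
  out <- list()
  walk <- function(p, path) {
    if (is.numeric(p)) {
      out[[length(out) + 1L]] <<- path
    } else {
      nms <- names(p)
      for (i in seq_along(p)) {
        if (!is.null(nms) && nms[i] %in% c("run_mean", "run_var")) next
        walk(p[[i]], c(path, nms[i]))
      }
    }
  }
  walk(params, character())
  out
}

# The optimizer is an environment (reference semantics): the flat
# parameter copy `th` and the moment vectors are mutated in place by the
# compiled fused update; only the gather of gradients and the scatter of
# updated leaves touch the nested parameter list.
adam_init <- function(params) {
  paths <- collect_leaf_paths(params)
  sizes <- vapply(paths, function(pp) length(params[[pp]]), integer(1))
  ends <- cumsum(sizes)
  ntot <- sum(sizes)
  opt <- new.env(parent = emptyenv())
  opt$paths <- paths
  opt$starts <- ends - sizes + 1L
  opt$ends <- ends
  opt$dims <- lapply(paths, function(pp) dim(params[[pp]]))
  th <- numeric(ntot)
  for (i in seq_along(paths))
    th[opt$starts[i]:ends[i]] <- params[[paths[[i]]]]
  opt$th <- th
  opt$m <- numeric(ntot)
  opt$v <- numeric(ntot)
  opt$t <- 0L
  opt$beta1 <- 0.9; opt$beta2 <- 0.999; opt$eps <- 1e-8
  opt
}

# updates `params` from the optimizer's canonical flat copy; `opt` is
# mutated by reference
adam_step <- function(opt, params, grads, lr) {
  opt$t <- opt$t + 1L
  # gather into a fresh unshared buffer: subassignment stays in place
  g <- numeric(length(opt$m))
  for (i in seq_along(opt$paths)) {
    gi <- grads[[opt$paths[[i]]]]
    if (!is.null(gi)) g[opt$starts[i]:opt$ends[i]] <- gi
  }
  adam_update_cpp(opt$th, opt$m, opt$v, g,
                  opt$beta1, opt$beta2,
                  1 / (1 - opt$beta1^opt$t), 1 / (1 - opt$beta2^opt$t),
                  lr, opt$eps)
  for (i in seq_along(opt$paths)) {
    new <- opt$th[opt$starts[i]:opt$ends[i]]
    if (!is.null(opt$dims[[i]])) dim(new) <- opt$dims[[i]]
    params[[opt$paths[[i]]]] <- new
  }
  list(opt = opt, params = params)
}

# rowsum() that keeps groups with no members as zero rows
rowsum_full <- function(x, idx, n) {
  out <- matrix(0, n, ncol(x))
  rs <- rowsum(x, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# elementwise sum of two nested gradient lists (NULL-tolerant)
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  for (nm in union(names(a), names(b)))
    a[[nm]] <- grad_add(a[[nm]], b[[nm]])
  a
}
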