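# Minimal neural-network primitives in base R matrix code. Every forward
# function returns list(out, cache); the paired backward consumes the cache
# and the upstream gradient and returns gradients for inputs and parameters.
# Analytic gradients are cross-checked against finite differences in the
# test suite.

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

dense_init <- function(nin, nout) list(W = glorot(nin, nout), b = rep(0, nout))

# add a bias row-vector without sweep()'s aperm overhead
add_bias <- function(M, b) M + rep(b, each = nrow(M))

dense_fwd <- function(X, p) {
  list(out = add_bias(X %*% p$W, p$b), cache = list(X = X))
}

dense_bwd <- function(dY, p, cache) {
  list(dX = dY %*% t(p$W),
       dW = crossprod(cache$X, dY),
       db = colSums(dY))
}

relu_fwd <- function(X) list(out = pmax(X, 0), cache = X > 0)
relu_bwd <- function(dY, cache) dY * cache

elu_fwd <- function(X, alpha = 1) {
  neg <- which(X <= 0)
  out <- X
  out[neg] <- alpha * (exp(X[neg]) - 1)
  list(out = out, cache = list(neg = neg, out = out, alpha = alpha))
}
elu_bwd <- function(dY, cache) {
  dX <- dY
  dX[cache$neg] <- dY[cache$neg] * (cache$out[cache$neg] + cache$alpha)
  dX
}

leaky_relu_fwd <- function(x, slope = 0.2) {
  neg <- which(x <= 0)
  out <- x
  out[neg] <- slope * x[neg]
  list(out = out, cache = list(neg = neg, slope = slope))
}
leaky_relu_bwd <- function(dy, cache) {
  dx <- dy
  dx[cache$neg] <- dy[cache$neg] * cache$slope
  dx
}

# Row-wise layer normalization with learned gain/bias vectors.
layernorm_init <- function(d) list(g = rep(1, d), b = rep(0, d))

layernorm_fwd <- function(X, p, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  out <- add_bias(xhat * rep(p$g, each = nrow(X)), p$b)
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

layernorm_bwd <- function(dY, p, cache) {
  xhat <- cache$xhat; inv <- cache$inv; d <- ncol(dY)
  dxhat <- dY * rep(p$g, each = nrow(dY))
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
  list(dX = dX,
       dg = colSums(dY * xhat),
       db = colSums(dY))
}

# Inverted dropout; identity when `train` is FALSE or rate is 0.
dropout_fwd <- function(X, rate, train) {
  if (!train || rate <= 0) return(list(out = X, cache = NULL))
  mask <- matrix(stats::rbinom(length(X), 1L, 1 - rate), nrow(X)) / (1 - rate)
  list(out = X * mask, cache = mask)
}
dropout_bwd <- function(dY, cache) if (is.null(cache)) dY else dY * cache

# Numerically stable row-wise softmax; -Inf entries get zero probability.
softmax_rows <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}
# d(softmax)/dS given dP, applied row-wise.
softmax_rows_bwd <- function(dP, P) {
  P * (dP - rowSums(dP * P))
}

# Group-wise softmax over a vector of scores `s` with integer groups `g`
# (1..ng); used for attention over variable-size hypergraph neighborhoods.
# Stabilized by the global maximum; falls back to exact per-group
# stabilization in the (pathological) case of underflow.
group_softmax <- function(s, g, ng) {
  e <- exp(s - max(s))
  tot <- group_sum_vec(e, g, ng)
  p <- e / tot[g]
  if (anyNA(p) || any(is.infinite(p))) {
    m <- rep(-Inf, ng)
    mt <- tapply(s, g, max)
    m[as.integer(names(mt))] <- mt
    e <- exp(s - m[g])
    tot <- group_sum_vec(e, g, ng)
    p <- e / tot[g]
  }
  p
}
group_softmax_bwd <- function(dp, p, g, ng) {
  inner <- group_sum_vec(dp * p, g, ng)
  p * (dp - inner[g])
}

group_sum_vec <- function(x, g, ng) {
  as.vector(.group_sum_vec_cpp(x, as.integer(g), ng))
}

group_sum_mat <- function(X, g, ng) {
  .group_sum_mat_cpp(X, as.integer(g), ng)
}

# ---------------------------------------------------------------------------
# Flat parameter trees and the Adam optimizer with linear warmup/decay
# ("BertAdam"-style decoupled weight decay and preheating).

flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p[[nm]])) out <- c(out, flatten_params(p[[nm]], key))
    else out[[key]] <- p[[nm]]
  }
  out
}

assign_flat <- function(p, key, value) {
  path <- strsplit(key, ".", fixed = TRUE)[[1L]]
  expr <- Reduce(function(acc, k) call("[[", acc, k), path, quote(p))
  eval(call("<-", expr, quote(value)))
  p
}

unflatten_into <- function(p, flat) {
  for (key in names(flat)) p <- assign_flat(p, key, flat[[key]])
  p
}

adam_init <- function(params) {
  flat <- flatten_params(params)
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

# One optimizer step. lr schedule: linear warmup over `warmup` steps then
# linear decay to zero at `total` steps. `no_decay` marks parameter paths
# exempt from weight decay (biases, layernorm gains).
adam_step <- function(params, grads, state, lr,
                      total, warmup,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0.01) {
  fp <- flatten_params(params)
  fg <- flatten_params(grads)
  state$t <- state$t + 1L
  t <- state$t
  sched <- if (t <= warmup && warmup > 0) t / warmup
           else max(1e-3, (total - t) / max(1, total - warmup))
  lr_t <- lr * sched
  for (key in names(fp)) {
    g <- fg[[key]]
    if (is.null(g)) next
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g * g
    mhat <- state$m[[key]] / (1 - beta1^t)
    vhat <- state$v[[key]] / (1 - beta2^t)
    upd <- mhat / (sqrt(vhat) + eps)
    decay <- if (grepl("(\\.b$|\\.g$|ln)", key)) 0 else weight_decay
    fp[[key]] <- fp[[key]] - lr_t * (upd + decay * fp[[key]])
  }
  list(params = unflatten_into(params, fp), state = state)
}

# Elementwise sum of two parameter/gradient trees with identical shape.
tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (nm in names(b)) a[[nm]] <- tree_add(a[[nm]], b[[nm]])
    a
  } else a + b
}

# Sinusoidal positional embedding matrix (n positions x d dimensions):
# entry (pos, 2i) = sin(pos / 10000^(2i/d)), (pos, 2i+1) = cos(...), with
# pos counted from 0.
#' Sinusoidal positional embedding
#'
#' Fixed transformer-style positional encoding: even columns carry
#' `sin(pos / 10000^(2i/d))`, odd columns the matching cosine, positions
#' counted from zero. Deterministic, parameter-free, all entries in
#' `[-1, 1]`.
#'
#' @param n Number of positions.
#' @param d Embedding dimension (must be even).
#' @return `n x d` numeric matrix.
#' @export
positional_embedding <- function(n, d) {
  stopifnot(n >= 1L, d >= 1L)
  if (d %% 2L != 0L) stop("`d` must be even", call. = FALSE)
  pos <- seq_len(n) - 1
  i <- seq_len(d %/% 2L) - 1
  ang <- outer(pos, 1 / 10000^(2 * i / d))
  P <- matrix(0, n, d)
  P[, 2 * i + 1] <- sin(ang)
  P[, 2 * i + 2] <- cos(ang)
  P
}
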