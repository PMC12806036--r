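# Sequence-model building blocks. Batched sequence tensors are stored as
# (B*n) x d matrices in sample-major order: row (b-1)*n + t holds token t of
# sample b. `mask` is a B x n logical matrix, TRUE for real (non-pad)
# positions.

embed_init <- function(vocab, d) {
  list(E = matrix(stats::rnorm(vocab * d, sd = 0.05), vocab, d))
}

# ids: B x n integer matrix with 0-based token ids (0 = pad). Token
# embeddings are scaled by sqrt(d) (standard transformer practice) so the
# token signal is not drowned by the unit-amplitude sinusoidal positions.
embed_fwd <- function(ids, p, P) {
  B <- nrow(ids); n <- ncol(ids)
  scale <- sqrt(ncol(p$E))
  idvec <- as.integer(t(ids)) + 1L              # sample-major, 1-based
  X <- p$E[idvec, , drop = FALSE] * scale +
    P[rep(seq_len(n), B), , drop = FALSE]
  list(out = X, cache = list(idvec = idvec, vocab = nrow(p$E),
                             scale = scale))
}

embed_bwd <- function(dX, cache) {
  list(E = group_sum_mat(dX, cache$idvec, cache$vocab) * cache$scale)
}

mhsa_init <- function(d) {
  list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
       Wo = glorot(d, d), ln = layernorm_init(d))
}

# Multi-head self-attention with post-layer residual + layer norm
# ("Add & Norm"). Pad positions are masked out of the attended keys; an
# all-pad sample is an error (no attendable key).
mhsa_fwd <- function(X, p, heads, mask) {
  B <- nrow(mask); n <- ncol(mask); d <- ncol(X)
  stopifnot(d %% heads == 0L)
  if (any(rowSums(mask) == 0L)) stop("all-pad sequence in batch", call. = FALSE)
  Q <- X %*% p$Wq; K <- X %*% p$Wk; V <- X %*% p$Wv
  att <- .attn_fwd_cpp(Q, K, V, matrix(as.integer(mask), B, n), heads)
  ctx <- att$ctx
  A <- att$A
  proj <- dense_fwd(ctx, list(W = p$Wo, b = rep(0, d)))
  ln <- layernorm_fwd(X + proj$out, p$ln)
  list(out = ln$out,
       cache = list(X = X, Q = Q, K = K, V = V, ctx = ctx, A = A,
                    ln = ln$cache, heads = heads, mask = mask))
}

mhsa_bwd <- function(dY, p, cache) {
  X <- cache$X; heads <- cache$heads; mask <- cache$mask
  B <- nrow(mask); n <- ncol(mask); d <- ncol(X)
  lb <- layernorm_bwd(dY, p$ln, cache$ln)
  dres <- lb$dX                                  # grad wrt (X + Wo ctx)
  dctx <- dres %*% t(p$Wo)
  dWo <- crossprod(cache$ctx, dres)
  gb <- .attn_bwd_cpp(dctx, cache$A, cache$Q, cache$K, cache$V, B, n, heads)
  dQ <- gb$dQ; dK <- gb$dK; dV <- gb$dV
  dX <- dres + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dX = dX,
       grads = list(Wq = crossprod(X, dQ), Wk = crossprod(X, dK),
                    Wv = crossprod(X, dV), Wo = dWo,
                    ln = list(g = lb$dg, b = lb$db)))
}

# Position-wise feed-forward sublayer with residual + layer norm.
ffn_init <- function(d, d_ff) {
  list(fc1 = dense_init(d, d_ff), fc2 = dense_init(d_ff, d),
       ln = layernorm_init(d))
}

ffn_fwd <- function(X, p) {
  h1 <- dense_fwd(X, p$fc1)
  a1 <- relu_fwd(h1$out)
  h2 <- dense_fwd(a1$out, p$fc2)
  ln <- layernorm_fwd(X + h2$out, p$ln)
  list(out = ln$out, cache = list(h1 = h1$cache, a1 = a1$cache,
                                  h2 = h2$cache, ln = ln$cache))
}

ffn_bwd <- function(dY, p, cache) {
  lb <- layernorm_bwd(dY, p$ln, cache$ln)
  d2 <- dense_bwd(lb$dX, p$fc2, cache$h2)
  da1 <- relu_bwd(d2$dX, cache$a1)
  d1 <- dense_bwd(da1, p$fc1, cache$h1)
  list(dX = lb$dX + d1$dX,
       grads = list(fc1 = list(W = d1$dW, b = d1$db),
                    fc2 = list(W = d2$dW, b = d2$db),
                    ln = list(g = lb$dg, b = lb$db)))
}

# ---------------------------------------------------------------------------
# TextCNN: parallel 1-D convolutions of widths `filter_sizes` over the
# position axis, ReLU, then global max-pool per filter; outputs concatenated
# to B x (filters_per_size * length(filter_sizes)).

textcnn_init <- function(d, filter_sizes, filters_per_size) {
  ps <- lapply(filter_sizes, function(w) dense_init(w * d, filters_per_size))
  names(ps) <- paste0("w", filter_sizes)
  ps
}

textcnn_fwd <- function(X, p, B, n, filter_sizes, filters_per_size) {
  d <- ncol(X)
  if (n < max(filter_sizes))
    stop("sequence length shorter than the widest filter", call. = FALSE)
  outs <- list(); caches <- list()
  for (wi in seq_along(filter_sizes)) {
    w <- filter_sizes[wi]
    nw <- n - w + 1L
    starts <- as.integer(outer(seq_len(nw), (seq_len(B) - 1L) * n, "+"))
    Xc <- .im2col_cpp(X, starts, w)             # rows: t fast within b
    pw <- p[[paste0("w", w)]]
    H <- add_bias(Xc %*% pw$W, pw$b)
    act <- H > 0
    H <- pmax(H, 0)
    # global max-pool over positions, all samples and filters at once
    M <- matrix(H, nrow = nw)                   # nw x (B * F)
    mc <- max.col(t(M), ties.method = "first")
    pooled <- matrix(M[cbind(mc, seq_along(mc))], B, filters_per_size)
    amax <- matrix(mc, B, filters_per_size)
    outs[[wi]] <- pooled
    caches[[wi]] <- list(Xc = Xc, act = act, amax = amax, nw = nw,
                         starts = starts, w = w)
  }
  list(out = do.call(cbind, outs),
       cache = list(per_w = caches, B = B, n = n, d = d,
                    filter_sizes = filter_sizes, F = filters_per_size))
}

textcnn_bwd <- function(dY, p, cache) {
  B <- cache$B; n <- cache$n; d <- cache$d; Fn <- cache$F
  dX <- matrix(0, B * n, d)
  grads <- list()
  for (wi in seq_along(cache$filter_sizes)) {
    w <- cache$filter_sizes[wi]
    cw <- cache$per_w[[wi]]
    dpool <- dY[, ((wi - 1L) * Fn + 1L):(wi * Fn), drop = FALSE]
    dH <- matrix(0, B * cw$nw, Fn)
    for (f in seq_len(Fn)) {
      rows <- (seq_len(B) - 1L) * cw$nw + cw$amax[, f]
      dH[cbind(rows, f)] <- dpool[, f]
    }
    dH <- dH * cw$act
    pw <- p[[paste0("w", w)]]
    dXc <- dH %*% t(pw$W)
    grads[[paste0("w", w)]] <- list(W = crossprod(cw$Xc, dH), b = colSums(dH))
    dX <- dX + .col2im_cpp(dXc, cw$starts, w, B * n)
  }
  list(dX = dX, grads = grads)
}
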