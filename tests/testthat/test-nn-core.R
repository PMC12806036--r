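# Finite-difference validation of the hand-derived backprop, block by block
# and through the full fused model.

num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("dense, layernorm and textcnn backprop match finite differences", {
  set.seed(55)
  ns <- asNamespace("pepfusion")
  X <- matrix(rnorm(6 * 4), 6, 4)

  p <- ns$dense_init(4, 3)
  f <- function(W) sum(ns$dense_fwd(X, list(W = matrix(W, 4, 3), b = p$b))$out^2)
  fw <- ns$dense_fwd(X, p)
  bw <- ns$dense_bwd(2 * fw$out, p, fw$cache)
  expect_equal(as.vector(bw$dW), as.vector(num_grad(f, as.vector(p$W))),
               tolerance = 1e-5)

  lp <- ns$layernorm_init(4); lp$g <- rnorm(4, 1, 0.1); lp$b <- rnorm(4, 0, 0.1)
  fl <- function(xv) sum(ns$layernorm_fwd(matrix(xv, 6, 4), lp)$out^3)
  fwl <- ns$layernorm_fwd(X, lp)
  bwl <- ns$layernorm_bwd(3 * fwl$out^2, lp, fwl$cache)
  expect_equal(as.vector(bwl$dX), as.vector(num_grad(fl, as.vector(X))),
               tolerance = 1e-4)

  # textcnn: input gradient through im2col, conv, relu and max-pool
  B <- 3L; n <- 8L; d <- 4L
  Xc <- matrix(rnorm(B * n * d), B * n, d)
  cp <- ns$textcnn_init(d, c(2L, 3L), 2L)
  fc <- function(xv) {
    sum(ns$textcnn_fwd(matrix(xv, B * n, d), cp, B, n, c(2L, 3L), 2L)$out^2)
  }
  fwc <- ns$textcnn_fwd(Xc, cp, B, n, c(2L, 3L), 2L)
  bwc <- ns$textcnn_bwd(2 * fwc$out, cp, fwc$cache)
  expect_equal(as.vector(bwc$dX), as.vector(num_grad(fc, as.vector(Xc))),
               tolerance = 1e-5)
})

test_that("attention block is row-stochastic, masked and grad-correct", {
  set.seed(66)
  ns <- asNamespace("pepfusion")
  B <- 2L; n <- 5L; d <- 6L; heads <- 2L
  X <- matrix(rnorm(B * n * d), B * n, d)
  mask <- matrix(TRUE, B, n); mask[1, 4:5] <- FALSE
  p <- ns$mhsa_init(d)
  fw <- ns$mhsa_fwd(X, p, heads, mask)

  # attention rows sum to one over unmasked keys; masked keys get zero
  A <- fw$cache$A                       # (B*heads*n) x n stacked
  expect_true(all(abs(rowSums(A) - 1) < 1e-6))
  rows_b1 <- seq_len(heads * n)
  expect_true(all(A[rows_b1, 4:5] == 0))

  # n = 1: the single attention weight is exactly 1
  X1 <- matrix(rnorm(d), 1, d)
  fw1 <- ns$mhsa_fwd(X1, p, heads, matrix(TRUE, 1, 1))
  expect_equal(as.vector(fw1$cache$A), rep(1, heads))

  expect_error(ns$mhsa_fwd(X, p, heads, matrix(FALSE, B, n)), "all-pad")

  # input gradient against finite differences
  f <- function(xv) sum(ns$mhsa_fwd(matrix(xv, B * n, d), p, heads, mask)$out^2)
  bw <- ns$mhsa_bwd(2 * fw$out, p, fw$cache)
  expect_equal(as.vector(bw$dX), as.vector(num_grad(f, as.vector(X))),
               tolerance = 1e-4)
})

test_that("full fused model gradients match finite differences", {
  set.seed(42)
  ns <- asNamespace("pepfusion")
  cfg <- tiny_config(n_classes = 4)
  cfg$seq <- utils::modifyList(cfg$seq, list(
    n = 10L, d = 8L, heads = 2L, filters_per_size = 2L,
    d_merge = 6L, d_fuse = 4L, dropout = 0))
  cfg$atomic <- utils::modifyList(cfg$atomic, list(
    L_atom = 16L, d_atom = 8L, n_layers = 1L, heads = 2L,
    d_head = 5L, d_fuse = 4L, dropout = 0))
  cfg$hg <- utils::modifyList(cfg$hg, list(k = 2L, d_hid = 4L, d_fuse = 4L))
  cfg$fusion <- list(hidden = 6L, dropout = 0, threshold = 0.5)

  recs <- generate_peptides(5, n_classes = 4, length_range = c(6L, 10L),
                            seed = 3)
  hg <- build_hypergraph(recs, k = 2L)
  enc <- tiny_transformer_encoder(8L, 1L, 2L, 12L)
  params <- ns$init_model_params(cfg, enc, hg$n_nodes + 1L)
  y <- recs$labels
  cw <- rep(1, 4)
  res_ids <- ns$encode_residue_matrix(recs$sequence, cfg$seq$n)
  str_ids <- ns$encode_structure_matrix(recs$sequence, cfg$seq$n)
  atm_ids <- ns$encode_smiles_batch(recs$sequence, cfg$atomic$L_atom)

  loss_of <- function(params) {
    af <- ns$atomic_branch_fwd(atm_ids, enc, params$atomic, 0, train = FALSE)
    sf <- ns$seq_branch_fwd(res_ids, str_ids, params$seq, cfg$seq,
                            train = FALSE)
    hf <- ns$hypergat_fwd(hg, params$hyper, cfg$hg$leaky_slope)
    fw <- ns$fusion_fwd(cbind(af$out, sf$out, hf$out), params$fusion,
                        0, train = FALSE)
    list(loss = multilabel_loss(fw$probs, y, cw),
         caches = list(a = af$cache, s = sf$cache, h = hf$cache, f = fw))
  }
  r <- loss_of(params)
  dlog <- ns$multilabel_loss_grad(r$caches$f$probs, y, cw)
  fb <- ns$fusion_bwd(dlog, params$fusion, r$caches$f$cache)
  grads <- list(fusion = fb$grads,
                atomic = ns$atomic_branch_bwd(fb$dX[, 1:4, drop = FALSE], enc,
                                              params$atomic, r$caches$a)$grads,
                seq = ns$seq_branch_bwd(fb$dX[, 5:8, drop = FALSE],
                                        params$seq, cfg$seq, r$caches$s)$grads,
                hyper = ns$hypergat_bwd(fb$dX[, 9:12, drop = FALSE],
                                        params$hyper, r$caches$h))

  fp <- ns$flatten_params(params)
  fg <- ns$flatten_params(grads)
  expect_setequal(names(fg), names(fp))
  eps <- 1e-5
  set.seed(7)
  for (key in sample(names(fp), 12)) {
    ii <- sample.int(length(fp[[key]]), 1)
    p2 <- fp; p2[[key]][ii] <- p2[[key]][ii] + eps
    lp <- loss_of(ns$unflatten_into(params, p2))$loss
    p2[[key]][ii] <- p2[[key]][ii] - 2 * eps
    lm <- loss_of(ns$unflatten_into(params, p2))$loss
    num <- (lp - lm) / (2 * eps)
    ana <- fg[[key]][ii]
    expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3,
              label = key)
  }
})

test_that("positional embedding is sinusoidal, bounded and well-shaped", {
  P <- positional_embedding(50, 192)
  expect_equal(dim(P), c(50L, 192L))
  expect_lte(max(abs(P)), 1)
  # position 0: sin(0) = 0 on even-index columns, cos(0) = 1 on odd
  expect_equal(P[1, ], rep(c(0, 1), 96))
  # spot value: entry (pos = 3, i = 2) of the sine channel
  expect_equal(P[4, 5], sin(3 / 10000^(4 / 192)))
  expect_error(positional_embedding(10, 7), "even")
})

test_that("loss has its closed-form values and linear class weighting", {
  y <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_lt(multilabel_loss(abs(y - 1e-9), y), 1e-6)
  expect_equal(multilabel_loss(matrix(0.5, 2, 2), y), log(2), tolerance = 1e-9)
  p <- matrix(c(0.9, 0.3, 0.2, 0.7), 2, 2)
  l1 <- multilabel_loss(p, y, c(1, 1))
  l2 <- multilabel_loss(p, y, c(2, 1))
  # doubling class 1's weight adds exactly that class's positive term
  # (weights act on the positive half of the cross-entropy only)
  pos_term <- mean(-(y[, 1] * log(p[, 1]))) / 2
  expect_equal(l2 - l1, pos_term, tolerance = 1e-9)
})
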