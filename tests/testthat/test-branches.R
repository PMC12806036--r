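make_atomic_params <- function(encoder, d_head = 6L, d_fuse = 4L, seed = 1L) {
  ns <- asNamespace("pepfusion")
  pepfusion:::with_seed(seed, list(
    enc = encoder$init(seed),
    head = ns$atomic_head_init(encoder$d_atom, d_head, d_fuse)))
}

test_that("atomic branch is batch-invariant and shape-stable in eval mode", {
  set.seed(21)
  enc <- tiny_transformer_encoder(d_atom = 8L, n_layers = 1L, heads = 2L)
  params <- make_atomic_params(enc)
  seqs <- c("KWKLFKK", "ACDEF", "GGGGG", "WYWYWYW", "MKVLH", "PPPPPP",
            "ACACAC", "DEDEDED")
  f_batch <- atomic_branch_forward(seqs, enc, params, L_atom = 32L)
  expect_equal(dim(f_batch), c(8L, 4L))
  f_solo <- atomic_branch_forward(seqs[3], enc, params, L_atom = 32L)
  expect_lt(max(abs(f_batch[3, ] - f_solo[1, ])), 1e-6)

  # eval determinism
  expect_identical(f_batch, atomic_branch_forward(seqs, enc, params,
                                                  L_atom = 32L))
})

test_that("random-init encoders separate distinct peptides", {
  set.seed(77)
  differs <- 0L
  for (r in 1:100) {
    enc <- tiny_transformer_encoder(d_atom = 8L, n_layers = 1L, heads = 2L)
    params <- make_atomic_params(enc, seed = r)
    f <- atomic_branch_forward(c("KWKLFKK", "ACDEFGH"), enc, params,
                               L_atom = 32L)
    if (max(abs(f[1, ] - f[2, ])) > 0) differs <- differs + 1L
  }
  # "with probability ~1": a rare dead-ReLU head can collapse an init
  expect_gte(differs, 98L)
})

test_that("encoders are swappable behind the contract without shape changes", {
  seqs <- c("KWKLFKK", "ACDEF")
  for (enc in list(tiny_transformer_encoder(d_atom = 8L, n_layers = 1L,
                                            heads = 2L),
                   bag_of_tokens_encoder(d_atom = 8L))) {
    params <- make_atomic_params(enc)
    f <- atomic_branch_forward(seqs, enc, params, L_atom = 32L)
    expect_equal(dim(f), c(2L, 4L))
    expect_true(enc$deterministic_eval)
  }
})

test_that("textcnn output width and max-pool translation property hold", {
  ns <- asNamespace("pepfusion")
  set.seed(5)
  B <- 1L; n <- 16L; d <- 4L; Fn <- 3L
  p <- ns$textcnn_init(d, c(2L, 3L, 4L, 5L), Fn)
  X <- matrix(0, n, d)
  fw0 <- ns$textcnn_fwd(X, p, B, n, c(2L, 3L, 4L, 5L), Fn)
  expect_equal(ncol(fw0$out), 4L * Fn)
  # constant-zero input pools the bias response
  expect_equal(unname(fw0$out[1, 1:Fn]), unname(pmax(p$w2$b, 0)))

  # planting the same pattern at two interior positions (far enough from
  # the edges that every window overlap exists for both placements) gives
  # identical pooled values: global max-pool is translation invariant
  pat <- matrix(rnorm(3 * d, sd = 3), 3, d)
  X1 <- X; X1[5:7, ] <- pat
  X2 <- X; X2[9:11, ] <- pat
  f1 <- ns$textcnn_fwd(X1, p, B, n, c(2L, 3L, 4L, 5L), Fn)$out
  f2 <- ns$textcnn_fwd(X2, p, B, n, c(2L, 3L, 4L, 5L), Fn)$out
  expect_equal(f1, f2, tolerance = 1e-10)

  expect_error(ns$textcnn_fwd(matrix(0, 3, d), p, 1L, 3L, c(2L, 5L), Fn),
               "shorter than the widest")
})

test_that("sequence branch contract: shape, determinism, batch equivariance", {
  ns <- asNamespace("pepfusion")
  cfg <- tiny_config(4)$seq
  cfg <- utils::modifyList(cfg, list(d = 16L, heads = 2L,
                                     filters_per_size = 3L,
                                     d_merge = 10L, d_fuse = 6L))
  set.seed(9)
  params <- ns$seq_branch_init(cfg)
  seqs <- c("KWKLFKK", "ACDEF", strrep("Y", 50), "MKVLHQQ")
  res <- ns$encode_residue_matrix(seqs, 50L)
  str <- ns$encode_structure_matrix(seqs, 50L)
  out <- sequence_branch_forward(res, str, params, cfg)
  expect_equal(dim(out), c(4L, 6L))
  expect_identical(out, sequence_branch_forward(res, str, params, cfg))

  # permuting the batch permutes outputs identically
  perm <- c(3L, 1L, 4L, 2L)
  out_p <- sequence_branch_forward(res[perm, ], str[perm, ], params, cfg)
  expect_lt(max(abs(out_p - out[perm, ])), 1e-8)

  # every valid 5-50mer produces a feature of the same width
  set.seed(10)
  for (len in c(5L, 17L, 50L)) {
    s <- random_peptide(len)
    o1 <- sequence_branch_forward(ns$encode_residue_matrix(s, 50L),
                                  ns$encode_structure_matrix(s, 50L),
                                  params, cfg)
    expect_equal(dim(o1), c(1L, 6L))
  }
})
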