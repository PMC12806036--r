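# Atomic (SMILES-level) branch: peptide -> SMILES -> token ids -> pluggable
# sequence encoder -> two fully connected layers (with a dropout between)
# -> branch feature. The encoder is a contract object so a pretrained
# chemistry language model can be dropped in without touching shapes; the
# bundled default is a small randomly initialized transformer with the same
# multi-head self-attention + feed-forward block structure.

#' Small transformer encoder for SMILES token streams
#'
#' Constructs an encoder-contract object: token embedding plus sinusoidal
#' positions, `n_layers` blocks of multi-head self-attention and
#' position-wise feed-forward sublayers (each with residual + layer norm),
#' and a masked mean-pool over real token positions. Eval-mode encoding is
#' deterministic for fixed weights and independent of batch companionship.
#'
#' @param d_atom Model width.
#' @param n_layers Number of transformer blocks.
#' @param heads Attention heads (`d_atom` must be divisible).
#' @param d_ff Feed-forward inner width (default `2 * d_atom`).
#' @param pos_scale Damping factor applied to the sinusoidal positional
#'   matrix before it is added to the (sqrt(d)-scaled) token embeddings.
#' @return List with fields `d_atom`, `init(seed)`, `fwd(ids, params,
#'   train)`, `bwd(dH, params, cache)` and `deterministic_eval = TRUE`.
#' @export
tiny_transformer_encoder <- function(d_atom = 32L, n_layers = 2L,
                                     heads = 2L, d_ff = 2L * d_atom,
                                     pos_scale = 0.3) {
  stopifnot(d_atom %% heads == 0L)
  force(d_atom); force(n_layers); force(heads); force(d_ff)
  force(pos_scale)
  vocab <- length(ATOMIC_VOCAB) + 1L            # + pad row
  list(
    d_atom = d_atom,
    deterministic_eval = TRUE,
    init = function(seed) {
      with_seed(seed, {
        layers <- lapply(seq_len(n_layers), function(l)
          list(att = mhsa_init(d_atom), ffn = ffn_init(d_atom, d_ff)))
        names(layers) <- paste0("l", seq_len(n_layers))
        list(emb = embed_init(vocab, d_atom), layers = layers)
      })
    },
    fwd = function(ids, params, train = FALSE) {
      B <- nrow(ids); L <- ncol(ids)
      mask <- ids > 0L
      P <- positional_embedding(L, d_atom) * pos_scale
      em <- embed_fwd(ids, params$emb, P)
      X <- em$out
      caches <- vector("list", n_layers)
      for (l in seq_len(n_layers)) {
        at <- mhsa_fwd(X, params$layers[[l]]$att, heads, mask)
        ff <- ffn_fwd(at$out, params$layers[[l]]$ffn)
        caches[[l]] <- list(att = at$cache, ffn = ff$cache)
        X <- ff$out
      }
      # masked mean-pool over real tokens
      mvec <- as.numeric(t(mask))
      denom <- rowSums(mask)
      H <- rowsum(X * mvec, rep(seq_len(B), each = L)) / denom
      list(H = H, cache = list(layers = caches, em = em$cache, mask = mask,
                               B = B, L = L, denom = denom, mvec = mvec))
    },
    bwd = function(dH, params, cache) {
      B <- cache$B; L <- cache$L
      dX <- (dH / cache$denom)[rep(seq_len(B), each = L), , drop = FALSE] *
        cache$mvec
      grads <- list(layers = vector("list", n_layers))
      for (l in rev(seq_len(n_layers))) {
        fb <- ffn_bwd(dX, params$layers[[l]]$ffn, cache$layers[[l]]$ffn)
        ab <- mhsa_bwd(fb$dX, params$layers[[l]]$att, cache$layers[[l]]$att)
        grads$layers[[l]] <- list(att = ab$grads, ffn = fb$grads)
        dX <- ab$dX
      }
      names(grads$layers) <- paste0("l", seq_len(n_layers))
      grads$emb <- embed_bwd(dX, cache$em)
      grads
    })
}

#' Order-free bag-of-tokens encoder
#'
#' The simplest object satisfying the encoder contract: the mean of learned
#' token embeddings over real positions. Mainly useful to demonstrate that
#' encoders are swappable without changing any downstream shape.
#'
#' @param d_atom Output width.
#' @return An encoder-contract object (same fields as
#'   [tiny_transformer_encoder()]).
#' @export
bag_of_tokens_encoder <- function(d_atom = 32L) {
  force(d_atom)
  vocab <- length(ATOMIC_VOCAB) + 1L
  list(
    d_atom = d_atom,
    deterministic_eval = TRUE,
    init = function(seed) with_seed(seed, list(emb = embed_init(vocab, d_atom))),
    fwd = function(ids, params, train = FALSE) {
      B <- nrow(ids); L <- ncol(ids)
      em <- embed_fwd(ids, params$emb, matrix(0, L, d_atom))
      mask <- ids > 0L
      mvec <- as.numeric(t(mask))
      denom <- rowSums(mask)
      H <- rowsum(em$out * mvec, rep(seq_len(B), each = L)) / denom
      list(H = H, cache = list(em = em$cache, B = B, L = L,
                               denom = denom, mvec = mvec))
    },
    bwd = function(dH, params, cache) {
      dX <- (dH / cache$denom)[rep(seq_len(cache$B), each = cache$L), ,
                               drop = FALSE] * cache$mvec
      list(emb = embed_bwd(dX, cache$em))
    })
}

atomic_head_init <- function(d_atom, d_head, d_fuse) {
  list(fc1 = dense_init(d_atom, d_head), fc2 = dense_init(d_head, d_fuse))
}

# ids -> encoder -> FC -> ReLU -> dropout -> FC -> d_fuse feature.
atomic_branch_fwd <- function(ids, encoder, params, dropout = 0.2,
                              train = FALSE) {
  enc <- encoder$fwd(ids, params$enc, train)
  h1 <- dense_fwd(enc$H, params$head$fc1)
  a1 <- relu_fwd(h1$out)
  dr <- dropout_fwd(a1$out, dropout, train)
  h2 <- dense_fwd(dr$out, params$head$fc2)
  list(out = h2$out,
       cache = list(enc = enc$cache, h1 = h1$cache, a1 = a1$cache,
                    dr = dr$cache, h2 = h2$cache))
}

atomic_branch_bwd <- function(dout, encoder, params, cache) {
  d2 <- dense_bwd(dout, params$head$fc2, cache$h2)
  ddr <- dropout_bwd(d2$dX, cache$dr)
  da1 <- relu_bwd(ddr, cache$a1)
  d1 <- dense_bwd(da1, params$head$fc1, cache$h1)
  denc <- encoder$bwd(d1$dX, params$enc, cache$enc)
  list(grads = list(enc = denc,
                    head = list(fc1 = list(W = d1$dW, b = d1$db),
                                fc2 = list(W = d2$dW, b = d2$db))))
}

#' Atomic branch features for a batch of peptides
#'
#' Converts peptides to SMILES, tokenizes and encodes them with the supplied
#' encoder-contract object, and maps the pooled encoding through the
#' two-layer fully connected head. Eval mode (the default) is deterministic
#' and batch-independent.
#'
#' @param sequences Character vector of peptides.
#' @param encoder Encoder-contract object (see
#'   [tiny_transformer_encoder()]).
#' @param params Branch parameters (`enc`, `head`).
#' @param L_atom Token stream length (pad/truncate).
#' @return `length(sequences) x d_fuse` feature matrix.
#' @export
atomic_branch_forward <- function(sequences, encoder, params, L_atom = 256L) {
  ids <- encode_smiles_batch(sequences, L_atom)
  atomic_branch_fwd(ids, encoder, params, train = FALSE)$out
}
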