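# Amino-acid branch: two parallel pathways merged by a feed-forward block.
# Residue pathway: learned embedding + sinusoidal positions -> multi-head
# self-attention (with Add & Norm) -> multi-width TextCNN. Structure
# pathway: Chou-Fasman class embedding + positions -> TextCNN only (the
# structure string is a coarse heuristic signal, so the attention block is
# deliberately omitted there). The concatenated pooled features pass through
# a two-layer feed-forward to the branch feature.

seq_branch_init <- function(cfg) {
  d <- cfg$d; Fh <- cfg$filters_per_size
  fsz <- cfg$filter_sizes
  Ftot <- 2L * Fh * length(fsz)
  list(emb_res = embed_init(21L, d),            # pad + 20 residues
       emb_str = embed_init(5L, d),             # 4 classes + pad marker
       att = mhsa_init(d),
       cnn_res = textcnn_init(d, fsz, Fh),
       cnn_str = textcnn_init(d, fsz, Fh),
       fc1 = dense_init(Ftot, cfg$d_merge),
       fc2 = dense_init(cfg$d_merge, cfg$d_fuse))
}

seq_branch_fwd <- function(residue_ids, structure_ids, params, cfg,
                           train = FALSE) {
  B <- nrow(residue_ids); n <- ncol(residue_ids)
  P <- positional_embedding(n, cfg$d) * cfg$pos_scale
  mask <- residue_ids > 0L

  emr <- embed_fwd(residue_ids, params$emb_res, P)
  at <- mhsa_fwd(emr$out, params$att, cfg$heads, mask)
  cr <- textcnn_fwd(at$out, params$cnn_res, B, n,
                    cfg$filter_sizes, cfg$filters_per_size)

  ems <- embed_fwd(structure_ids, params$emb_str, P)
  cs <- textcnn_fwd(ems$out, params$cnn_str, B, n,
                    cfg$filter_sizes, cfg$filters_per_size)

  cat_ <- cbind(cr$out, cs$out)
  h1 <- dense_fwd(cat_, params$fc1)
  a1 <- relu_fwd(h1$out)
  dr <- dropout_fwd(a1$out, cfg$dropout, train)
  h2 <- dense_fwd(dr$out, params$fc2)
  list(out = h2$out,
       cache = list(emr = emr$cache, at = at$cache, cr = cr$cache,
                    ems = ems$cache, cs = cs$cache,
                    h1 = h1$cache, a1 = a1$cache, dr = dr$cache,
                    h2 = h2$cache, wres = ncol(cr$out)))
}

seq_branch_bwd <- function(dout, params, cfg, cache) {
  d2 <- dense_bwd(dout, params$fc2, cache$h2)
  ddr <- dropout_bwd(d2$dX, cache$dr)
  da1 <- relu_bwd(ddr, cache$a1)
  d1 <- dense_bwd(da1, params$fc1, cache$h1)
  wres <- cache$wres
  dcr <- d1$dX[, seq_len(wres), drop = FALSE]
  dcs <- d1$dX[, -seq_len(wres), drop = FALSE]

  cb_r <- textcnn_bwd(dcr, params$cnn_res, cache$cr)
  ab <- mhsa_bwd(cb_r$dX, params$att, cache$at)
  der <- embed_bwd(ab$dX, cache$emr)

  cb_s <- textcnn_bwd(dcs, params$cnn_str, cache$cs)
  des <- embed_bwd(cb_s$dX, cache$ems)

  list(grads = list(emb_res = der, emb_str = des,
                    att = ab$grads,
                    cnn_res = cb_r$grads, cnn_str = cb_s$grads,
                    fc1 = list(W = d1$dW, b = d1$db),
                    fc2 = list(W = d2$dW, b = d2$db)))
}

#' Amino-acid branch features for encoded peptides
#'
#' Runs the residue pathway (embedding + positions, multi-head
#' self-attention, TextCNN) and the secondary-structure pathway (embedding +
#' positions, TextCNN), merges them through the feed-forward block, and
#' returns one feature vector per peptide. Deterministic in eval mode.
#'
#' @param residue_ids `B x n` integer matrix from [encode_residues()]
#'   (0 = pad).
#' @param structure_ids `B x n` integer matrix of Chou-Fasman classes
#'   (0-3; 4 = pad).
#' @param params Branch parameter list.
#' @param cfg Branch configuration (see [default_config()], entry `seq`).
#' @return `B x d_fuse` feature matrix.
#' @export
sequence_branch_forward <- function(residue_ids, structure_ids, params, cfg) {
  seq_branch_fwd(residue_ids, structure_ids, params, cfg, train = FALSE)$out
}
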