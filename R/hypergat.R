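# Two-stage hypergraph attention network (HyperGAT) on the k-mer hypergraph.
# Node -> hyperedge aggregation (edge update) and hyperedge -> node
# aggregation (node update) alternate; both score a neighbor by the
# leaky-ReLU of the inner product of the two linearly transformed features,
# normalize with a softmax over the neighborhood, and aggregate with an ELU
# nonlinearity. The tf-idf incidence weights enter the edge-update scores
# multiplicatively (before the softmax).

hypergat_layer_init <- function(d) {
  list(eu = list(Wv = glorot(d, d), We = glorot(d, d)),
       nu = list(Wv = glorot(d, d), We = glorot(d, d)))
}

hypergat_params_init <- function(n_nodes, d_hid, d_fuse, n_layers = 2L) {
  layers <- lapply(seq_len(n_layers), function(l) hypergat_layer_init(d_hid))
  names(layers) <- paste0("l", seq_len(n_layers))
  list(emb = embed_init(n_nodes, d_hid)$E,
       layers = layers,
       final_eu = list(Wv = glorot(d_hid, d_hid), We = glorot(d_hid, d_hid)),
       proj = dense_init(d_hid, d_fuse))
}

# Both update stages share one fused kernel: scores are leaky-ReLU inner
# products of the transformed features, softmax-normalized over each
# center's neighborhood, then attention-weighted sums pass through an ELU.
# The edge update aggregates nodes into edges (tf-idf weighted scores); the
# node update aggregates edges into nodes (unit weights).

edge_update_fwd <- function(hv, he_prev, hg, p, leaky_slope = 0.2) {
  Tv <- hv %*% p$Wv
  Te <- he_prev %*% p$We
  r <- .hgat_update_fwd_cpp(Tv, Te, hg$node, hg$edge, hg$weight,
                            hg$n_edges, leaky_slope)
  list(out = r$out, beta = r$att,
       cache = list(hv = hv, he_prev = he_prev, Tv = Tv, Te = Te,
                    att = r$att, raw = r$raw, out = r$out,
                    slope = leaky_slope))
}

edge_update_bwd <- function(dhe, p, hg, cache) {
  gb <- .hgat_update_bwd_cpp(dhe, cache$out, cache$Tv, cache$Te,
                             hg$node, hg$edge, hg$weight,
                             cache$att, cache$raw, cache$slope)
  list(dhv = gb$dTn %*% t(p$Wv),
       dhe_prev = gb$dTc %*% t(p$We),
       grads = list(Wv = crossprod(cache$hv, gb$dTn),
                    We = crossprod(cache$he_prev, gb$dTc)))
}

node_update_fwd <- function(he, hv, hg, p, leaky_slope = 0.2) {
  Tv <- hv %*% p$Wv
  Te <- he %*% p$We
  r <- .hgat_update_fwd_cpp(Te, Tv, hg$edge, hg$node,
                            rep(1, length(hg$edge)), hg$n_nodes, leaky_slope)
  list(out = r$out, alpha = r$att,
       cache = list(hv = hv, he = he, Tv = Tv, Te = Te,
                    att = r$att, raw = r$raw, out = r$out,
                    slope = leaky_slope))
}

node_update_bwd <- function(dhv_new, p, hg, cache) {
  gb <- .hgat_update_bwd_cpp(dhv_new, cache$out, cache$Te, cache$Tv,
                             hg$edge, hg$node, rep(1, length(hg$edge)),
                             cache$att, cache$raw, cache$slope)
  list(dhv = gb$dTc %*% t(p$Wv),
       dhe = gb$dTn %*% t(p$We),
       grads = list(Wv = crossprod(cache$hv, gb$dTc),
                    We = crossprod(cache$he, gb$dTn)))
}

#' Hyperedge feature update with node-to-edge attention
#'
#' One edge-update stage of the hypergraph attention network: for every
#' hyperedge, member nodes are scored by the leaky-ReLU inner product of
#' their transformed features with the edge's previous feature, multiplied by
#' the tf-idf incidence weight, softmax-normalized within the edge, and
#' aggregated through an ELU.
#'
#' @param node_feats `|V| x d` node feature matrix.
#' @param edge_feats `|E| x d` previous edge feature matrix.
#' @param hypergraph A `pep_hypergraph`.
#' @param Wv,We `d x d` transform matrices for node and edge features.
#' @param leaky_slope Negative slope of the scoring nonlinearity.
#' @return List with `features` (`|E| x d`) and `attention` (one beta weight
#'   per incidence, summing to 1 within each edge).
#' @export
edge_update <- function(node_feats, edge_feats, hypergraph, Wv, We,
                        leaky_slope = 0.2) {
  stopifnot(nrow(node_feats) == hypergraph$n_nodes,
            nrow(edge_feats) == hypergraph$n_edges)
  r <- edge_update_fwd(node_feats, edge_feats, hypergraph,
                       list(Wv = Wv, We = We), leaky_slope)
  list(features = r$out, attention = r$beta)
}

#' Node feature update with edge-to-node attention
#'
#' One node-update stage of the hypergraph attention network: for every
#' node, incident hyperedges are scored by the leaky-ReLU inner product of
#' the transformed node and edge features, softmax-normalized over the
#' node's edges, and aggregated through an ELU.
#'
#' @inheritParams edge_update
#' @return List with `features` (`|V| x d`) and `attention` (one alpha
#'   weight per incidence, summing to 1 within each node's neighborhood).
#' @export
node_update <- function(node_feats, edge_feats, hypergraph, Wv, We,
                        leaky_slope = 0.2) {
  stopifnot(nrow(node_feats) == hypergraph$n_nodes,
            nrow(edge_feats) == hypergraph$n_edges)
  r <- node_update_fwd(edge_feats, node_feats, hypergraph,
                       list(Wv = Wv, We = We), leaky_slope)
  list(features = r$out, attention = r$alpha)
}

# Full relational branch forward. `emb` is the node embedding table (rows >=
# hg$n_nodes; the inference UNK node uses the last row). Initial edge
# features are the mean of member node embeddings; then n_layers of
# (edge update, node update); a final edge update and linear projection give
# one d_fuse feature per sequence.
hypergat_fwd <- function(hg, params, leaky_slope = 0.2) {
  i <- hg$node; j <- hg$edge; E <- hg$n_edges
  hv0 <- params$emb[seq_len(hg$n_nodes), , drop = FALSE]
  esize <- group_sum_vec(rep(1, length(j)), j, E)
  he0 <- group_sum_mat(.row_gather_cpp(hv0, i), j, E) / esize
  hv <- hv0; he <- he0
  layer_caches <- list()
  for (l in seq_along(params$layers)) {
    pl <- params$layers[[l]]
    eu <- edge_update_fwd(hv, he, hg, pl$eu, leaky_slope)
    nu <- node_update_fwd(eu$out, hv, hg, pl$nu, leaky_slope)
    layer_caches[[l]] <- list(eu = eu$cache, nu = nu$cache)
    he <- eu$out; hv <- nu$out
  }
  fin <- edge_update_fwd(hv, he, hg, params$final_eu, leaky_slope)
  proj <- dense_fwd(fin$out, params$proj)
  list(out = proj$out,
       cache = list(layers = layer_caches, fin = fin$cache,
                    proj = proj$cache, esize = esize, hg = hg))
}

hypergat_bwd <- function(dout, params, cache) {
  hg <- cache$hg
  i <- hg$node; j <- hg$edge
  dp <- dense_bwd(dout, params$proj, cache$proj)
  grads <- list(proj = list(W = dp$dW, b = dp$db))
  fb <- edge_update_bwd(dp$dX, params$final_eu, hg, cache$fin)
  grads$final_eu <- fb$grads
  dhv <- fb$dhv; dhe <- fb$dhe_prev
  grads$layers <- vector("list", length(params$layers))
  for (l in rev(seq_along(params$layers))) {
    pl <- params$layers[[l]]
    cl <- cache$layers[[l]]
    nb <- node_update_bwd(dhv, pl$nu, hg, cl$nu)
    dhe <- dhe + nb$dhe
    dhv_prev <- nb$dhv
    eb <- edge_update_bwd(dhe, pl$eu, hg, cl$eu)
    grads$layers[[l]] <- list(eu = eb$grads, nu = nb$grads)
    dhv <- dhv_prev + eb$dhv
    dhe <- eb$dhe_prev
  }
  names(grads$layers) <- names(params$layers)
  # through the mean-initialized edge features back onto node embeddings
  dhv0 <- dhv + group_sum_mat(.row_gather_cpp(dhe / cache$esize, j), i,
                              hg$n_nodes)
  demb <- matrix(0, nrow(params$emb), ncol(params$emb))
  demb[seq_len(hg$n_nodes), ] <- dhv0
  grads$emb <- demb
  grads
}

#' Relational branch features for every hyperedge
#'
#' Runs the full two-stage hypergraph attention stack — initial edge
#' features as the mean of member node embeddings, `n_layers` alternations
#' of edge and node updates, a final edge update and linear projection — and
#' returns one feature vector per sequence (hyperedge).
#'
#' @param hypergraph A `pep_hypergraph`.
#' @param params Parameter list from the trained model (node embedding
#'   table, per-layer transforms, final transforms, projection).
#' @param leaky_slope Negative slope of the scoring nonlinearity.
#' @return `|E| x d_fuse` matrix of per-sequence features.
#' @export
hypergat_forward <- function(hypergraph, params, leaky_slope = 0.2) {
  stopifnot(inherits(hypergraph, "pep_hypergraph"))
  hypergat_fwd(hypergraph, params, leaky_slope)$out
}
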