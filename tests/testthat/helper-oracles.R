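# Independent reference implementations ("oracles") used to validate the
# package's vectorized code paths. These are deliberately naive: explicit
# loops and set arithmetic, no shared code with the implementation.

# --- multi-label metrics via per-sample label sets ------------------------
oracle_metrics <- function(Y_true, Y_pred) {
  N <- nrow(Y_true); M <- ncol(Y_true)
  prec <- cov <- acc <- atrue <- afalse <- numeric(N)
  for (s in seq_len(N)) {
    y <- which(Y_true[s, ] == 1)
    yp <- which(Y_pred[s, ] == 1)
    inter <- length(intersect(y, yp))
    uni <- length(union(y, yp))
    prec[s] <- if (length(yp) == 0) 0 else inter / length(yp)
    cov[s] <- inter / length(y)
    acc[s] <- inter / uni
    atrue[s] <- as.numeric(setequal(y, yp))
    afalse[s] <- (uni - inter) / M
  }
  c(precision = mean(prec), coverage = mean(cov), accuracy = mean(acc),
    absolute_true = mean(atrue), absolute_false = mean(afalse))
}

random_label_pair <- function(n, m) {
  Y_true <- matrix(0L, n, m)
  for (s in seq_len(n)) Y_true[s, sample.int(m, sample.int(min(3L, m), 1L))] <- 1L
  Y_pred <- matrix(rbinom(n * m, 1L, 0.2), n, m)
  list(Y_true = Y_true, Y_pred = Y_pred)
}

# --- Chou-Fasman: a second, loop-naive rule evaluator ---------------------
oracle_chou_fasman <- function(sequence) {
  cf <- chou_fasman_table()
  aa <- strsplit(sequence, "")[[1]]
  ix <- match(aa, cf$residue)
  pa <- cf$p_helix[ix]; pb <- cf$p_sheet[ix]; pt <- cf$p_turn[ix]
  L <- length(aa)

  regions <- function(p, win, min_hits) {
    inreg <- logical(L)
    if (L < win) return(inreg)
    for (s in 1:(L - win + 1)) {
      if (sum(p[s:(s + win - 1)] > 100) >= min_hits) {
        lo <- s; hi <- s + win - 1
        while (hi < L && mean(p[(hi - 2):(hi + 1)]) >= 100) hi <- hi + 1
        while (lo > 1 && mean(p[(lo - 1):(lo + 2)]) >= 100) lo <- lo - 1
        inreg[lo:hi] <- TRUE
      }
    }
    inreg
  }
  helix <- regions(pa, 6, 4)
  sheet <- regions(pb, 5, 3)
  for (s in seq_len(L)) {        # resolve overlaps stretch by stretch
    if (helix[s] && sheet[s]) {
      e <- s
      while (e < L && helix[e + 1] && sheet[e + 1]) e <- e + 1
      if (any(helix[s:e] & sheet[s:e])) {
        span <- s:e
        if (mean(pa[span]) >= mean(pb[span])) sheet[span] <- FALSE
        else helix[span] <- FALSE
      }
    }
  }
  turn <- logical(L)
  if (L >= 4) {
    f1 <- cf$f_i[ix]; f2 <- cf$f_i1[ix]; f3 <- cf$f_i2[ix]; f4 <- cf$f_i3[ix]
    for (i in 1:(L - 3)) {
      w <- i:(i + 3)
      if (f1[i] * f2[i + 1] * f3[i + 2] * f4[i + 3] > 7.5e-5 &&
          mean(pt[w]) > 100 && mean(pt[w]) > mean(pa[w]) &&
          mean(pt[w]) > mean(pb[w]))
        turn[w] <- TRUE
    }
  }
  out <- rep(3L, L)
  out[turn] <- 2L; out[sheet] <- 1L; out[helix] <- 0L
  out
}

random_peptide <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"),
               len, replace = TRUE), collapse = "")
}

# --- HyperGAT: brute-force double-loop evaluation of the update rules -----
oracle_leaky <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
oracle_elu <- function(x) ifelse(x > 0, x, exp(x) - 1)

# H: |E| x |V| binary incidence; W: |E| x |V| tf-idf weights
oracle_edge_update <- function(hv, he_prev, H, W, Wv, We, slope = 0.2) {
  E <- nrow(H); d <- ncol(hv %*% Wv)
  out <- matrix(0, E, d)
  beta_list <- list()
  for (e in seq_len(E)) {
    members <- which(H[e, ] == 1)
    scores <- sapply(members, function(v)
      oracle_leaky(sum((Wv %*% hv[v, ]) * (We %*% he_prev[e, ])), slope) *
        W[e, v])
    beta <- exp(scores - max(scores)); beta <- beta / sum(beta)
    acc <- rep(0, d)
    for (m in seq_along(members))
      acc <- acc + beta[m] * as.vector(Wv %*% hv[members[m], ])
    out[e, ] <- oracle_elu(acc)
    beta_list[[e]] <- beta
  }
  list(features = out, beta = beta_list)
}

oracle_node_update <- function(he, hv, H, Wv, We, slope = 0.2) {
  V <- ncol(H); d <- ncol(he %*% We)
  out <- matrix(0, V, d)
  alpha_list <- list()
  for (v in seq_len(V)) {
    edges <- which(H[, v] == 1)
    scores <- sapply(edges, function(e)
      oracle_leaky(sum((Wv %*% hv[v, ]) * (We %*% he[e, ])), slope))
    alpha <- exp(scores - max(scores)); alpha <- alpha / sum(alpha)
    acc <- rep(0, d)
    for (m in seq_along(edges))
      acc <- acc + alpha[m] * as.vector(We %*% he[edges[m], ])
    out[v, ] <- oracle_elu(acc)
    alpha_list[[v]] <- alpha
  }
  list(features = out, alpha = alpha_list)
}

oracle_hypergat_forward <- function(hg, params, slope = 0.2) {
  H <- matrix(0, hg$n_edges, hg$n_nodes)
  W <- matrix(0, hg$n_edges, hg$n_nodes)
  H[cbind(hg$edge, hg$node)] <- 1
  W[cbind(hg$edge, hg$node)] <- hg$weight
  hv <- params$emb[seq_len(hg$n_nodes), , drop = FALSE]
  esize <- rowSums(H)
  he <- (H %*% hv) / esize
  for (l in seq_along(params$layers)) {
    pl <- params$layers[[l]]
    he_new <- oracle_edge_update(hv, he, H, W, t(pl$eu$Wv), t(pl$eu$We),
                                 slope)$features
    hv <- oracle_node_update(he_new, hv, H, t(pl$nu$Wv), t(pl$nu$We),
                             slope)$features
    he <- he_new
  }
  fin <- oracle_edge_update(hv, he, H, W, t(params$final_eu$Wv),
                            t(params$final_eu$We), slope)$features
  sweep(fin %*% params$proj$W, 2, params$proj$b, "+")
}

# small random hypergraph + matching parameter set
random_hypergraph_setup <- function(n_nodes = 6L, n_edges = 3L, d = 4L,
                                    n_layers = 2L) {
  repeat {
    H <- matrix(rbinom(n_edges * n_nodes, 1L, 0.5), n_edges, n_nodes)
    if (all(rowSums(H) > 0) && all(colSums(H) > 0)) break
  }
  inc <- which(H == 1, arr.ind = TRUE)
  tf <- sample(1:3, nrow(inc), replace = TRUE)
  df <- colSums(H)
  idf <- log(n_edges / df)
  hg <- structure(list(node_vocab = paste0("n", seq_len(n_nodes)),
                       edge = unname(inc[, 1]), node = unname(inc[, 2]),
                       tf = tf, weight = tf * idf[inc[, 2]],
                       df = df, idf = idf,
                       n_nodes = n_nodes, n_edges = n_edges,
                       edge_ids = paste0("e", seq_len(n_edges)), k = 2L,
                       unk_node = NA_integer_),
                  class = "pep_hypergraph")
  params <- list(
    emb = matrix(rnorm(n_nodes * d, sd = 0.5), n_nodes, d),
    layers = stats::setNames(lapply(seq_len(n_layers), function(l)
      list(eu = list(Wv = matrix(rnorm(d * d, sd = 0.5), d, d),
                     We = matrix(rnorm(d * d, sd = 0.5), d, d)),
           nu = list(Wv = matrix(rnorm(d * d, sd = 0.5), d, d),
                     We = matrix(rnorm(d * d, sd = 0.5), d, d)))),
      paste0("l", seq_len(n_layers))),
    final_eu = list(Wv = matrix(rnorm(d * d, sd = 0.5), d, d),
                    We = matrix(rnorm(d * d, sd = 0.5), d, d)),
    proj = list(W = matrix(rnorm(d * d, sd = 0.5), d, d), b = rnorm(d)))
  list(hg = hg, params = params, H = H)
}
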