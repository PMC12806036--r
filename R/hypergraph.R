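#' Overlapping k-mers of a sequence
#'
#' Contiguous substrings of length `k`, stride 1, left to right.
#'
#' @param sequence A single string.
#' @param k Substring length, `1 <= k <= nchar(sequence)`.
#' @return Character vector of `nchar(sequence) - k + 1` k-mers.
#' @export
#' @examples
#' kmers("PAMNH", 3)  # "PAM" "AMN" "MNH"
kmers <- function(sequence, k) {
  stopifnot(length(sequence) == 1L)
  k <- as.integer(k)
  L <- nchar(sequence)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (k > L) stop("`k` exceeds the sequence length", call. = FALSE)
  substring(sequence, seq_len(L - k + 1L), seq.int(k, L))
}

#' Build a k-mer hypergraph over a peptide dataset
#'
#' Every unique k-mer becomes a node; every peptide sequence becomes a
#' hyperedge incident to the nodes of its k-mers. The binary incidence
#' structure is stored in sparse triplet form, and each (edge, node)
#' incidence carries a tf-idf weight: the occurrence count of the k-mer in
#' that sequence times `ln(|E| / df)`, where `df` is the number of sequences
#' containing the k-mer. These weights encode the frequency and diversity of
#' the shared subsequences and modulate the edge-update attention scores.
#'
#' @param records Peptide tibble.
#' @param k k-mer length (default 5).
#' @return An object of class `pep_hypergraph`: node vocabulary in
#'   first-occurrence order, incidence triplets (`edge`, `node`, `tf`,
#'   `weight`), per-node document frequency `df` and `idf`, and bookkeeping
#'   sizes.
#' @export
build_hypergraph <- function(records, k = 5L) {
  validate_peptide_tbl(records)
  k <- as.integer(k)
  short <- nchar(records$sequence) < k
  if (any(short))
    stop("sequences shorter than k = ", k, ": ",
         paste(utils::head(records$id[short], 5L), collapse = ", "),
         call. = FALSE)
  km_list <- lapply(records$sequence, kmers, k = k)
  vocab <- unique(unlist(km_list, use.names = FALSE))
  edge <- integer(0); node <- integer(0); tf <- integer(0)
  for (j in seq_along(km_list)) {
    tt <- table(km_list[[j]])
    edge <- c(edge, rep.int(j, length(tt)))
    node <- c(node, match(names(tt), vocab))
    tf <- c(tf, as.integer(tt))
  }
  n_edges <- length(km_list)
  df <- tabulate(node, nbins = length(vocab))
  idf <- log(n_edges / df)
  structure(list(node_vocab = vocab,
                 edge = edge, node = node, tf = tf,
                 weight = tf * idf[node],
                 df = df, idf = idf,
                 n_nodes = length(vocab), n_edges = n_edges,
                 edge_ids = records$id, k = k,
                 unk_node = NA_integer_),
            class = "pep_hypergraph")
}

#' @export
print.pep_hypergraph <- function(x, ...) {
  cat("k-mer hypergraph (k = ", x$k, "): ", x$n_nodes, " nodes, ",
      x$n_edges, " hyperedges, ", length(x$edge), " incidences\n", sep = "")
  invisible(x)
}

# Dense |E| x |V| 0/1 incidence matrix (for inspection / small graphs).
incidence_matrix <- function(hg) {
  H <- matrix(0L, hg$n_edges, hg$n_nodes,
              dimnames = list(hg$edge_ids, hg$node_vocab))
  H[cbind(hg$edge, hg$node)] <- 1L
  H
}

#' Attach new sequences to a frozen k-mer vocabulary
#'
#' Inductive inference counterpart of [build_hypergraph()]: new sequences
#' form new hyperedges over the training vocabulary; k-mers never seen in
#' training map to a single UNK node (with uninformative idf 0), and df/idf
#' stay frozen at their training values.
#'
#' @param train_hg A `pep_hypergraph` built on the training set.
#' @param new_records Peptide tibble of unseen sequences.
#' @param unk_node Allow the UNK node (default TRUE). With `FALSE`, a
#'   sequence sharing no k-mer with training is an error.
#' @return A `pep_hypergraph` whose nodes are the training vocabulary plus
#'   (optionally) UNK, and whose edges are the new sequences.
#' @export
inference_hypergraph <- function(train_hg, new_records, unk_node = TRUE) {
  stopifnot(inherits(train_hg, "pep_hypergraph"))
  validate_peptide_tbl(new_records)
  k <- train_hg$k
  short <- nchar(new_records$sequence) < k
  if (any(short))
    stop("sequences shorter than k = ", k, ": ",
         paste(utils::head(new_records$id[short], 5L), collapse = ", "),
         call. = FALSE)
  vocab <- train_hg$node_vocab
  unk_id <- length(vocab) + 1L
  edge <- integer(0); node <- integer(0); tf <- integer(0)
  for (j in seq_len(nrow(new_records))) {
    km <- kmers(new_records$sequence[j], k)
    ids <- match(km, vocab)
    if (unk_node) ids[is.na(ids)] <- unk_id
    ids <- ids[!is.na(ids)]
    if (length(ids) == 0L)
      stop("sequence ", new_records$id[j],
           " shares no k-mer with the training vocabulary", call. = FALSE)
    tt <- table(ids)
    edge <- c(edge, rep.int(j, length(tt)))
    node <- c(node, as.integer(names(tt)))
    tf <- c(tf, as.integer(tt))
  }
  idf <- c(train_hg$idf, 0)                    # UNK carries idf 0
  structure(list(node_vocab = c(vocab, if (unk_node) "<unk>"),
                 edge = edge, node = node, tf = tf,
                 weight = tf * idf[node],
                 df = c(train_hg$df, NA_integer_),
                 idf = idf,
                 n_nodes = if (unk_node) unk_id else length(vocab),
                 n_edges = nrow(new_records),
                 edge_ids = new_records$id, k = k,
                 unk_node = if (unk_node) unk_id else NA_integer_),
            class = "pep_hypergraph")
}
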