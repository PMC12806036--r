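#' Default per-class sequence motifs
#'
#' Draws pairwise-distinct random 5-mers (edit distance >= 2 between any two)
#' to act as class-defining motifs in synthetic data. Motif length 5 matches
#' the default k-mer size of the hypergraph branch, so a single hypergraph
#' node can in principle carry a whole class signal.
#'
#' @param n_classes Number of motifs to draw.
#' @param seed Integer seed; the same seed always returns the same table.
#' @param motif_length Motif length (default 5).
#' @return Named list mapping class abbreviation to a single motif string.
#' @export
default_motif_table <- function(n_classes = 21L, seed = 1L, motif_length = 5L) {
  stopifnot(n_classes >= 1L, motif_length >= 1L)
  classes <- label_vocabulary(n_classes)
  with_seed(seed, {
    motifs <- character(0)
    guard <- 0L
    while (length(motifs) < n_classes) {
      guard <- guard + 1L
      if (guard > 10000L) stop("could not draw distinct motifs", call. = FALSE)
      cand <- paste(sample(AA_ALPHABET, motif_length, replace = TRUE),
                    collapse = "")
      if (length(motifs) == 0L ||
          all(utils::adist(cand, motifs) >= 2L)) {
        motifs <- c(motifs, cand)
      }
    }
    stats::setNames(as.list(motifs), classes)
  })
}

# Table-1-style class weights: with 21 classes, 13 rare, 4 medium, 4 abundant.
default_imbalance <- function(n_classes) {
  if (n_classes == 21L) {
    w <- stats::setNames(rep(1, 21), label_vocabulary(21L))
    w[c("AVP", "THP", "ADP", "AHP")] <- 2.5
    w[c("ABP", "ACP", "AFP", "AIP")] <- 5
    unname(w)
  } else {
    # keep roughly the same shape: ~60% rare, ~20% medium, ~20% abundant
    n_ab <- max(1L, round(n_classes * 0.2))
    n_md <- max(1L, round(n_classes * 0.2))
    c(rep(5, n_ab), rep(2.5, n_md), rep(1, n_classes - n_ab - n_md))
  }
}

#' Generate a synthetic multi-label peptide dataset
#'
#' Emulates the structure of the multifunctional-therapeutic-peptide
#' benchmark: variable-length peptides (5-50 residues), multi-hot labels over
#' `n_classes` classes with heavy class imbalance, and label-correlated
#' sequence motifs. For each record a label count is drawn as
#' `1 + Poisson(label_rate - 1)` (capped at `n_classes`), classes are sampled
#' without replacement proportionally to `imbalance`, a background sequence of
#' residues drawn from `background_freqs` is generated with length uniform in
#' `length_range`, and one motif per positive class is implanted at a random
#' position; implants never overlap each other (the length is redrawn from
#' the feasible sub-range when needed). Each implanted motif position is
#' substituted with probability `noise_rate`.
#'
#' With `noise_rate = 0` and disjoint motifs, every positive class of every
#' record has an exact motif occurrence, so a trivial motif-matching
#' classifier attains absolute true = 1 — an upper-bound oracle for any
#' learned model on this generator.
#'
#' @param n_samples Number of records (0 gives an empty tibble).
#' @param n_classes Number of classes (default 21).
#' @param motifs Named list class -> motif string (residue strings, length
#'   3-6); defaults to [default_motif_table()] drawn from `seed`.
#' @param length_range Integer min/max peptide length (default c(5, 50)).
#' @param label_rate Mean number of labels per peptide (default 1.3).
#' @param imbalance Per-class sampling weights (nonnegative, not all zero).
#' @param noise_rate Per-position substitution probability inside implanted
#'   motifs (default 0).
#' @param background_freqs Residue frequencies for background positions
#'   (default uniform over the 20 letters).
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration and seed.
#' @return A peptide tibble (`id`, `sequence`, `labels`).
#' @export
generate_peptides <- function(n_samples,
                              n_classes = 21L,
                              motifs = NULL,
                              length_range = c(5L, 50L),
                              label_rate = 1.3,
                              imbalance = NULL,
                              noise_rate = 0,
                              background_freqs = NULL,
                              seed = 1L) {
  n_classes <- as.integer(n_classes)
  classes <- label_vocabulary(n_classes)
  if (is.null(motifs)) motifs <- default_motif_table(n_classes, seed = seed)
  if (is.null(imbalance)) imbalance <- default_imbalance(n_classes)
  if (is.null(background_freqs)) background_freqs <- rep(1 / 20, 20L)
  stopifnot(length(motifs) == n_classes, length(imbalance) == n_classes,
            length(background_freqs) == 20L, length(length_range) == 2L)
  if (any(imbalance < 0) || all(imbalance == 0))
    stop("imbalance weights must be nonnegative and not all zero", call. = FALSE)
  motif_chr <- unlist(motifs, use.names = FALSE)
  assert_valid_sequences(motif_chr)
  mlen <- nchar(motif_chr)
  if (any(mlen > length_range[1L]))
    stop("motif longer than minimum sequence length", call. = FALSE)
  if (n_samples == 0L) {
    return(new_peptide_tbl(character(), character(),
                           matrix(0L, 0L, n_classes,
                                  dimnames = list(NULL, classes))))
  }

  with_seed(seed, {
    labels <- matrix(0L, n_samples, n_classes, dimnames = list(NULL, classes))
    seqs <- character(n_samples)
    for (s in seq_len(n_samples)) {
      k <- min(n_classes, 1L + stats::rpois(1L, max(0, label_rate - 1)))
      pos_classes <- sample.int(n_classes, k, prob = imbalance)
      labels[s, pos_classes] <- 1L
      need <- sum(mlen[pos_classes])
      if (need > length_range[2L])
        stop("cannot host ", k, " disjoint motifs within max length ",
             length_range[2L], call. = FALSE)
      lo <- max(length_range[1L], need)
      len <- if (lo >= length_range[2L]) length_range[2L] else
        sample(seq.int(lo, length_range[2L]), 1L)
      chars <- sample(AA_ALPHABET, len, replace = TRUE, prob = background_freqs)
      # place motifs left-to-right in random class order without overlap:
      # nondecreasing random offsets into the free gap keep implants disjoint
      order_cls <- pos_classes[sample.int(length(pos_classes))]
      gap <- len - need
      offs <- sort(sample.int(gap + 1L, length(order_cls), replace = TRUE)) - 1L
      prefix <- 0L
      for (j in seq_along(order_cls)) {
        cl <- order_cls[j]
        at <- offs[j] + prefix + 1L
        m <- strsplit(motif_chr[cl], "", fixed = TRUE)[[1L]]
        if (noise_rate > 0) {
          flip <- stats::runif(length(m)) < noise_rate
          if (any(flip)) {
            m[flip] <- vapply(m[flip], function(r)
              sample(setdiff(AA_ALPHABET, r), 1L), "")
          }
        }
        chars[at:(at + length(m) - 1L)] <- m
        prefix <- prefix + length(m)
      }
      seqs[s] <- paste(chars, collapse = "")
    }
    new_peptide_tbl(sprintf("syn%05d", seq_len(n_samples)), seqs, labels)
  })
}
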