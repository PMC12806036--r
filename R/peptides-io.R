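#' The 21 therapeutic peptide classes
#'
#' Ordered abbreviations of the 21 functional classes used by the multi-label
#' benchmark: antiangiogenic (AAP), anti-HIV (AHIVP), surface binding (SBP),
#' antifungal (AFP), antibacterial (ABP), antihypertensive (AHP), antiviral
#' (AVP), anticancer (ACP), anti-inflammatory (AIP), antiparasitic (APP),
#' antiendotoxin (AEP), biofilm inhibitory (BIP), blood-brain barrier (BBP),
#' anticoronavirus (ACVP), anti-MRSA (AMRSAP), cell-penetrating (CPP),
#' dipeptidyl peptidase IV (DPPIP), antidiabetic (ADP), antitubercular (ATP),
#' tumor homing (THP) and quorum-sensing (QSP) peptides. The order fixes the
#' bit order of the FASTA label field and the column order of label matrices.
#'
#' @param n_classes Number of classes. The default 21 returns the standard
#'   vocabulary; smaller values (e.g. for reduced synthetic benchmarks) take
#'   the first `n_classes` names; larger values extend with `C22`, `C23`, ...
#' @return Character vector of class abbreviations, length `n_classes`.
#' @export
#' @examples
#' label_vocabulary()[1:4]
label_vocabulary <- function(n_classes = 21L) {
  base <- c("AAP", "AHIVP", "SBP", "AFP", "ABP", "AHP", "AVP", "ACP", "AIP",
            "APP", "AEP", "BIP", "BBP", "ACVP", "AMRSAP", "CPP", "DPPIP",
            "ADP", "ATP", "THP", "QSP")
  n_classes <- as.integer(n_classes)
  if (n_classes < 1L) stop("`n_classes` must be >= 1", call. = FALSE)
  if (n_classes <= length(base)) return(base[seq_len(n_classes)])
  c(base, paste0("C", seq.int(length(base) + 1L, n_classes)))
}

# Fixed residue alphabet; rank in this vector is the integer code (A=1, C=2, ...).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

assert_valid_sequences <- function(sequences, ids = NULL) {
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), sequences) |
    !nzchar(sequences)
  if (any(bad)) {
    who <- if (is.null(ids)) which(bad) else ids[bad]
    stop("invalid residues (outside the 20-letter alphabet) in record(s): ",
         paste(utils::head(who, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

new_peptide_tbl <- function(id, sequence, labels) {
  stopifnot(is.matrix(labels), nrow(labels) == length(id))
  tibble::tibble(id = as.character(id), sequence = as.character(sequence),
                 labels = labels)
}

validate_peptide_tbl <- function(x, require_positive = FALSE) {
  if (!is.data.frame(x) || !all(c("id", "sequence", "labels") %in% names(x)))
    stop("expected a peptide tibble with columns id, sequence, labels",
         call. = FALSE)
  lab <- x$labels
  if (!is.matrix(lab)) stop("`labels` must be a matrix column", call. = FALSE)
  if (!all(lab %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (anyDuplicated(x$id)) stop("duplicate peptide IDs", call. = FALSE)
  assert_valid_sequences(x$sequence, x$id)
  if (require_positive && any(rowSums(lab) == 0))
    stop("training records must carry at least one positive label",
         call. = FALSE)
  invisible(x)
}

#' Read a multi-label FASTA file
#'
#' Parses the label-bearing FASTA dialect used throughout the package:
#' each record is a header line `>ID|b1b2...bM` — where the `b` field is an
#' `M`-character 0/1 string in [label_vocabulary()] order — followed by a
#' single sequence line over the 20-letter amino-acid alphabet.
#'
#' @param path Path to the FASTA file.
#' @param n_classes Expected width of the label bit-string (default 21).
#' @return A tibble with columns `id` (character), `sequence` (character) and
#'   `labels` (integer matrix, one column per class), in file order.
#' @export
read_multilabel_fasta <- function(path, n_classes = 21L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(new_peptide_tbl(character(), character(),
                           matrix(0L, 0L, n_classes,
                                  dimnames = list(NULL, label_vocabulary(n_classes)))))
  }
  hdr <- startsWith(lines, ">")
  if (!hdr[1L] || length(lines) %% 2L != 0L ||
      !all(hdr == rep(c(TRUE, FALSE), length.out = length(lines))))
    stop("malformed FASTA: expected alternating header/sequence lines",
         call. = FALSE)
  headers <- sub("^>", "", lines[hdr])
  seqs <- toupper(lines[!hdr])
  parts <- strsplit(headers, "|", fixed = TRUE)
  ok <- vapply(parts, length, 1L) == 2L
  if (!all(ok))
    stop("header lacking the '|<bits>' label field at line ",
         which(hdr)[which(!ok)[1L]], call. = FALSE)
  ids <- vapply(parts, `[[`, "", 1L)
  bits <- vapply(parts, `[[`, "", 2L)
  bad_bits <- nchar(bits) != n_classes | grepl("[^01]", bits)
  if (any(bad_bits))
    stop("label field must be a ", n_classes,
         "-character 0/1 string; offending header at line ",
         which(hdr)[which(bad_bits)[1L]], call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate IDs: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  assert_valid_sequences(seqs, ids)
  labels <- matrix(as.integer(unlist(strsplit(bits, "", fixed = TRUE))),
                   nrow = length(ids), ncol = n_classes, byrow = TRUE,
                   dimnames = list(NULL, label_vocabulary(n_classes)))
  new_peptide_tbl(ids, seqs, labels)
}

#' Write a multi-label FASTA file
#'
#' Inverse of [read_multilabel_fasta()]; `read(write(x))` reproduces `x`.
#'
#' @param records Peptide tibble (`id`, `sequence`, `labels`).
#' @param path Output path. UTF-8, LF line endings, single-line sequences.
#' @return `path`, invisibly.
#' @export
write_multilabel_fasta <- function(records, path) {
  validate_peptide_tbl(records)
  bits <- apply(records$labels, 1L, paste, collapse = "")
  txt <- as.vector(rbind(paste0(">", records$id, "|", bits), records$sequence))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Encode a peptide sequence as fixed-length residue indices
#'
#' Residues map to their 1-based rank in the alphabetical order
#' A, C, D, E, F, G, H, I, K, L, M, N, P, Q, R, S, T, V, W, Y (A = 1, C = 2,
#' ...). Sequences shorter than `n` are right-padded with 0; longer ones keep
#' the N-terminal `n` residues.
#'
#' @param sequence A single peptide string.
#' @param n Target length (default 50).
#' @return Integer vector of length `n`.
#' @export
#' @examples
#' encode_residues("ACD")[1:5]
encode_residues <- function(sequence, n = 50L) {
  stopifnot(length(sequence) == 1L, nzchar(sequence))
  assert_valid_sequences(sequence)
  ids <- match(strsplit(sequence, "", fixed = TRUE)[[1L]], AA_ALPHABET)
  out <- integer(n)
  keep <- seq_len(min(length(ids), n))
  out[keep] <- ids[keep]
  out
}

# Vectorized form: rows = records, columns = positions 1..n.
encode_residue_matrix <- function(sequences, n = 50L) {
  t(vapply(sequences, encode_residues, integer(n), n = n, USE.NAMES = FALSE))
}

#' Split a peptide dataset into training and test portions
#'
#' Unstratified random partition, deterministic under `seed`. The training
#' part receives `round(fraction * n)` records.
#'
#' @param records Peptide tibble.
#' @param fraction Training fraction, strictly between 0 and 1 (default 0.8).
#' @param seed Integer seed.
#' @return A list with elements `train` and `test` (disjoint tibbles).
#' @export
train_test_split <- function(records, fraction = 0.8, seed = 1L) {
  validate_peptide_tbl(records)
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records to split", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  n_train <- max(1L, min(n - 1L, as.integer(round(fraction * n))))
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = records[sort(idx), , drop = FALSE],
       test  = records[setdiff(seq_len(n), sort(idx)), , drop = FALSE])
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
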