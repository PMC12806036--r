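# Residue-level SMILES building blocks. Each unit contributes the backbone
# N-C(alpha)-C(=O) fragment with the side chain in a branch; condensing units
# head-to-tail and closing with a terminal "O" yields the linear peptide
# (one water lost per peptide bond). Alpha carbons carry L-configuration
# markers; glycine has none and proline's backbone nitrogen sits in its ring.
RESIDUE_SMILES_UNIT <- c(
  A = "N[C@@H](C)C(=O)",
  C = "N[C@@H](CS)C(=O)",
  D = "N[C@@H](CC(O)=O)C(=O)",
  E = "N[C@@H](CCC(O)=O)C(=O)",
  F = "N[C@@H](Cc1ccccc1)C(=O)",
  G = "NCC(=O)",
  H = "N[C@@H](Cc1c[nH]cn1)C(=O)",
  I = "N[C@@H]([C@@H](C)CC)C(=O)",
  K = "N[C@@H](CCCCN)C(=O)",
  L = "N[C@@H](CC(C)C)C(=O)",
  M = "N[C@@H](CCSC)C(=O)",
  N = "N[C@@H](CC(N)=O)C(=O)",
  P = "N1CCC[C@H]1C(=O)",
  Q = "N[C@@H](CCC(N)=O)C(=O)",
  R = "N[C@@H](CCCNC(=N)N)C(=O)",
  S = "N[C@@H](CO)C(=O)",
  T = "N[C@@H]([C@@H](C)O)C(=O)",
  V = "N[C@@H](C(C)C)C(=O)",
  W = "N[C@@H](Cc1c[nH]c2ccccc12)C(=O)",
  Y = "N[C@@H](Cc1ccc(O)cc1)C(=O)"
)

# Elemental composition (C, H, N, O, S) of each free amino acid. Used for
# formula bookkeeping: a peptide of length L has the column sums of its
# residues minus (L - 1) x H2O.
RESIDUE_FORMULA <- matrix(
  c( # C  H  N  O  S
     3,  7, 1, 2, 0,  # A
     3,  7, 1, 2, 1,  # C
     4,  7, 1, 4, 0,  # D
     5,  9, 1, 4, 0,  # E
     9, 11, 1, 2, 0,  # F
     2,  5, 1, 2, 0,  # G
     6,  9, 3, 2, 0,  # H
     6, 13, 1, 2, 0,  # I
     6, 14, 2, 2, 0,  # K
     6, 13, 1, 2, 0,  # L
     5, 11, 1, 2, 1,  # M
     4,  8, 2, 3, 0,  # N
     5,  9, 1, 2, 0,  # P
     5, 10, 2, 3, 0,  # Q
     6, 14, 4, 2, 0,  # R
     3,  7, 1, 3, 0,  # S
     4,  9, 1, 3, 0,  # T
     5, 11, 1, 2, 0,  # V
    11, 12, 2, 2, 0,  # W
     9, 11, 1, 3, 0), # Y
  nrow = 20L, byrow = TRUE,
  dimnames = list(AA_ALPHABET, c("C", "H", "N", "O", "S")))

#' Convert a peptide sequence to SMILES
#'
#' Builds the linear (unmodified, L-configured) peptide by condensation of a
#' built-in 20-entry residue SMILES table: residue units are joined
#' head-to-tail through peptide bonds — losing one water per bond — and the
#' C-terminal carboxyl is closed with a hydroxyl. The output is
#' canonical-equivalent (identical molecular formula and canonical form) to
#' the sequence-to-molecule conversion of standard cheminformatics toolkits.
#'
#' @param sequence Peptide string over the 20-letter alphabet.
#' @return A single SMILES string.
#' @export
#' @examples
#' peptide_to_smiles("G")   # glycine, C2H5NO2
#' peptide_to_smiles("GG")  # glycylglycine, C4H8N2O3
peptide_to_smiles <- function(sequence) {
  stopifnot(length(sequence) == 1L, nzchar(sequence))
  assert_valid_sequences(sequence)
  units <- RESIDUE_SMILES_UNIT[strsplit(sequence, "", fixed = TRUE)[[1L]]]
  paste0(paste(units, collapse = ""), "O")
}

#' Elemental formula of a peptide
#'
#' Closed-form composition from the residue formula table: column sums of the
#' residues minus one H2O per peptide bond.
#'
#' @param sequence Peptide string.
#' @return Named integer vector with elements C, H, N, O, S.
#' @export
peptide_formula <- function(sequence) {
  stopifnot(length(sequence) == 1L, nzchar(sequence))
  assert_valid_sequences(sequence)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  f <- colSums(RESIDUE_FORMULA[aa, , drop = FALSE])
  f["H"] <- f["H"] - 2L * (length(aa) - 1L)
  f["O"] <- f["O"] - (length(aa) - 1L)
  structure(as.integer(f), names = colnames(RESIDUE_FORMULA))
}

#' Tokenize a SMILES string
#'
#' Regex-style SMILES tokenization: bracket atoms (`[...]`) and the
#' two-letter elements Cl and Br are single tokens; every other character is
#' its own token. Concatenating the tokens reproduces the input (or a prefix
#' of it when truncated to `L_atom`).
#'
#' @param smiles SMILES string.
#' @param L_atom Optional maximum token count; longer streams are truncated.
#' @return Character vector of tokens.
#' @export
#' @examples
#' tokenize_smiles("C(=O)O")
#' tokenize_smiles("[NH3+]C")
tokenize_smiles <- function(smiles, L_atom = NULL) {
  stopifnot(length(smiles) == 1L, nzchar(smiles))
  m <- gregexpr("\\[[^][]*\\]|Cl|Br|.", smiles, perl = TRUE)[[1L]]
  tokens <- regmatches(smiles, list(m))[[1L]]
  if (any(tokens == "[") || any(tokens == "]") || grepl("\\[[^]]*$", smiles))
    stop("unbalanced bracket in SMILES: ", smiles, call. = FALSE)
  if (!is.null(L_atom) && length(tokens) > L_atom)
    tokens <- tokens[seq_len(L_atom)]
  tokens
}

# Fixed token vocabulary of the peptide SMILES subset (id 0 = pad in encoded
# form; unknown tokens map to UNK). Kept fixed so encoders are portable
# across datasets.
ATOMIC_VOCAB <- c("<unk>", "N", "C", "O", "S", "c", "n", "(", ")", "=",
                  "1", "2", "[C@@H]", "[C@H]", "[nH]", "#", "-", "+",
                  "3", "Cl", "Br")

# Encode SMILES token streams to a padded integer matrix (rows = peptides),
# 0 = pad, 1.. = vocabulary ids.
encode_smiles_batch <- function(sequences, L_atom = 256L) {
  out <- matrix(0L, length(sequences), L_atom)
  for (b in seq_along(sequences)) {
    tok <- tokenize_smiles(peptide_to_smiles(sequences[b]), L_atom)
    ids <- match(tok, ATOMIC_VOCAB)
    ids[is.na(ids)] <- 1L
    out[b, seq_along(ids)] <- ids
  }
  out
}
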