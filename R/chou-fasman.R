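# Package-local cache for the propensity table.
.pf_env <- new.env(parent = emptyenv())

#' Chou-Fasman propensity table
#'
#' The published per-residue conformational propensities (helix, sheet, turn,
#' scaled by 100) and the four positional bend frequencies f(i)..f(i+3).
#' Shipped as a plain CSV under `inst/extdata` so the numbers are auditable.
#'
#' @return Tibble with one row per residue.
#' @export
chou_fasman_table <- function() {
  if (is.null(.pf_env$cf)) {
    path <- system.file("extdata", "chou_fasman_propensities.csv",
                        package = "pepfusion", mustWork = TRUE)
    .pf_env$cf <- tibble::as_tibble(utils::read.csv(path,
                                                    stringsAsFactors = FALSE))
  }
  .pf_env$cf
}

#' Predict secondary structure with the Chou-Fasman heuristic
#'
#' Assigns each residue one of four states — 0 alpha-helix, 1 beta-sheet,
#' 2 beta-turn, 3 random coil — using the classical nucleation/extension
#' rules: a helix nucleates in any 6-residue window with at least 4 residues
#' of helix propensity > 100 and extends in both directions while the mean
#' helix propensity of the advancing 4-residue window stays at or above 100;
#' sheets nucleate in 5-residue windows with at least 3 residues of sheet
#' propensity > 100 and extend the same way on sheet propensity; a
#' helix/sheet overlap goes to the state with the higher mean propensity over
#' the overlapping region. A beta-turn is assigned at positions i..i+3 when
#' the bend-frequency product f(i) f(i+1) f(i+2) f(i+3) exceeds 7.5e-5, the
#' mean turn propensity over the window exceeds 100 and exceeds both the mean
#' helix and mean sheet propensities there; turn assignment fills only
#' positions not already claimed by a helix or sheet region. Everything else
#' is coil. Sequences shorter than a nucleation window simply acquire no
#' nucleus of that type.
#'
#' @param sequence Peptide string over the 20-letter alphabet.
#' @return Integer vector (same length as `sequence`) with values in 0..3.
#' @export
#' @examples
#' chou_fasman("AAAAAAAAAA")  # all helix
#' chou_fasman("VVVVVVVVVV")  # all sheet
chou_fasman <- function(sequence) {
  stopifnot(length(sequence) == 1L, nzchar(sequence))
  assert_valid_sequences(sequence)
  cf <- chou_fasman_table()
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  ix <- match(aa, cf$residue)
  pa <- cf$p_helix[ix]; pb <- cf$p_sheet[ix]; pt <- cf$p_turn[ix]
  L <- length(aa)

  # rolling window sums via cumulative sums: wsum(p, w)[t] = sum p[t..t+w-1]
  wsum <- function(p, w) {
    cs <- cumsum(c(0, p))
    cs[(w + 1L):(L + 1L)] - cs[seq_len(L - w + 1L)]
  }

  grow_regions <- function(p, win, min_hits) {
    inreg <- logical(L)
    if (L >= win) {
      hits <- wsum(as.numeric(p > 100), win)
      w4 <- if (L >= 4L) wsum(p, 4L) else numeric(0)
      for (s in which(hits >= min_hits)) {
        lo <- s; hi <- s + win - 1L
        # extend while the advancing 4-residue window keeps mean >= 100
        while (hi < L && w4[hi - 2L] >= 400) hi <- hi + 1L
        while (lo > 1L && w4[lo - 1L] >= 400) lo <- lo - 1L
        inreg[lo:hi] <- TRUE
      }
    }
    inreg
  }

  helix <- grow_regions(pa, 6L, 4L)
  sheet <- grow_regions(pb, 5L, 3L)

  # resolve helix/sheet overlaps by the higher mean propensity over each
  # contiguous overlapping stretch
  both <- helix & sheet
  if (any(both)) {
    r <- rle(both)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      span <- starts[j]:ends[j]
      if (mean(pa[span]) >= mean(pb[span])) sheet[span] <- FALSE
      else helix[span] <- FALSE
    }
  }

  turn <- logical(L)
  if (L >= 4L) {
    f1 <- cf$f_i[ix]; f2 <- cf$f_i1[ix]; f3 <- cf$f_i2[ix]; f4 <- cf$f_i3[ix]
    nw <- L - 3L
    pprod <- f1[seq_len(nw)] * f2[seq_len(nw) + 1L] *
      f3[seq_len(nw) + 2L] * f4[seq_len(nw) + 3L]
    w4t <- wsum(pt, 4L); w4a <- wsum(pa, 4L); w4b <- wsum(pb, 4L)
    for (i in which(pprod > 7.5e-5 & w4t > 400 & w4t > w4a & w4t > w4b))
      turn[i:(i + 3L)] <- TRUE
  }

  out <- rep.int(3L, L)
  out[turn] <- 2L
  out[sheet] <- 1L
  out[helix] <- 0L
  out
}

# Vectorized helper: structure classes for many sequences, padded/truncated
# to n positions with pad marker 4 (the 5th embedding index).
encode_structure_matrix <- function(sequences, n = 50L) {
  out <- matrix(4L, length(sequences), n)
  for (b in seq_along(sequences)) {
    s <- chou_fasman(sequences[b])
    keep <- seq_len(min(length(s), n))
    out[b, keep] <- s[keep]
  }
  out
}
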