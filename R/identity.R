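# Pairwise sequence identity and the scrambled-sequence homology floor.
# Global alignment with linear gap scoring replaces a multiple aligner;
# identity is matches per alignment column, so end gaps count as columns.

#' Percent identity of two sequences under global alignment
#'
#' Needleman-Wunsch with linear gap scoring (defaults: match +1, mismatch
#' -1, gap -2).  Identity = 100 x matches / alignment columns, evaluated on
#' the optimal-score alignment that maximizes matches (then minimizes
#' columns), which makes the value deterministic when the optimum is
#' degenerate.  `method = "gapless"` instead compares positions directly
#' (sequences must then have equal length).
#'
#' @param a,b DNA sequences (character scalars).
#' @param match,mismatch,gap alignment scores.
#' @param method "global" (default) or "gapless".
#' @return percent identity in [0, 100].
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = -1, gap = -2,
                              method = c("global", "gapless")) {
  method <- match.arg(method)
  stopifnot(nzchar(a), nzchar(b))
  if (method == "gapless") {
    stopifnot(nchar(a) == nchar(b))
    va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
    return(100 * mean(va == vb))
  }
  r <- nw_align_stats(a, b, match, mismatch, gap)
  100 * r$matches / r$columns
}

#' Pairwise identity matrix with a homology floor
#'
#' @param seqs named character vector of ortholog sequences.
#' @param reference name of the reference sequence used to set the floor.
#' @param n_scrambles scrambled copies of the reference (study convention: 2).
#' @param seed RNG seed for the scrambles.
#' @param ... passed to [pairwise_identity()].
#' @return an `identity_matrix`: symmetric percent-identity matrix with
#'   attributes `floor` (percent) and `raw` (unclipped copy); printing
#'   clips displayed values to [floor, 100].
#' @export
identity_matrix <- function(seqs, reference, n_scrambles = 2, seed = 1, ...) {
  stopifnot(reference %in% names(seqs))
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      v <- pairwise_identity(seqs[[i]], seqs[[j]], ...)
      m[i, j] <- m[j, i] <- v
    }
  }
  fl <- homology_floor(seqs, seqs[[reference]], n_scrambles = n_scrambles,
                       seed = seed, ...)
  structure(m, floor = fl, class = c("identity_matrix", class(m)))
}

#' @export
print.identity_matrix <- function(x, ...) {
  fl <- attr(x, "floor")
  disp <- pmax(unclass(x), fl)
  cat(sprintf("Percent identity (displayed values clipped to [%.1f, 100]):\n", fl))
  print(round(disp, 1))
  invisible(x)
}

#' Scrambled-sequence lower limit of homology
#'
#' The floor is the mean pairwise identity between each ortholog and each
#' scrambled copy of the reference sequence.  Skewed nucleotide composition
#' raises the floor above the theoretical 25% of uniform random sequences.
#'
#' @param seqs character vector of ortholog sequences.
#' @param reference_seq the reference sequence to scramble.
#' @param n_scrambles number of scrambled copies (>= 1).
#' @param seed RNG seed.
#' @param ... passed to [pairwise_identity()].
#' @return floor as percent identity.
#' @export
homology_floor <- function(seqs, reference_seq, n_scrambles = 2, seed = 1,
                           ...) {
  stopifnot(n_scrambles >= 1)
  scr <- scramble_sequence(reference_seq, n_scrambles, seed = seed)
  vals <- outer(seq_along(seqs), seq_along(scr),
                Vectorize(function(i, j)
                  pairwise_identity(seqs[[i]], scr[[j]], ...)))
  mean(vals)
}
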