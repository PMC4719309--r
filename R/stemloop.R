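# Hairpin scoring by base-pair maximization.  The target RNA structures are
# stem-loops read from genomic DNA, so G.U wobble pairs appear as G-T/T-G.
# A hairpin here has two ungapped arms of equal length around a loop; its
# score is the number of paired bases minus a penalty per internal mismatch
# (a mismatch lying strictly between the innermost and outermost paired
# positions of the stem).

# 4x4 pairing table over A,C,G,T: Watson-Crick plus G-T wobble.
PAIR_TABLE <- local({
  m <- matrix(FALSE, 4, 4, dimnames = list(DNA_LETTERS, DNA_LETTERS))
  m["A", "T"] <- m["T", "A"] <- TRUE
  m["C", "G"] <- m["G", "C"] <- TRUE
  m["G", "T"] <- m["T", "G"] <- TRUE
  m
})

# Score one explicit placement: 5' arm starting at s (0-based), arm length
# a, loop length l.  Shared by the scanner below and by tests' oracles.
stem_placement_score <- function(enc, s, a, l, mismatch_penalty = 1) {
  idx5 <- s + a - 1 - (0:(a - 1)) + 1   # innermost first (1-based)
  idx3 <- s + a + l + (0:(a - 1)) + 1
  b5 <- enc[idx5]; b3 <- enc[idx3]
  if (anyNA(b5) || anyNA(b3)) return(0)
  m <- PAIR_TABLE[cbind(b5, b3)]
  if (!any(m)) return(0)
  rng <- range(which(m))
  paired <- sum(m)
  internal_mm <- (rng[2] - rng[1] + 1) - sum(m[rng[1]:rng[2]])
  paired - mismatch_penalty * internal_mm
}

#' Score the best hairpin whose 5' arm overlaps a focus interval
#'
#' Exhaustively maximizes over arm placements, arm lengths up to `max_arm`
#' and loop lengths in [`min_loop`, `max_loop`].
#'
#' @param sequence character scalar (A/C/G/T/N; windows touching N score 0).
#' @param focus_start,focus_end 0-based half-open interval the 5' arm must
#'   overlap.
#' @param min_loop,max_loop loop length bounds (defaults 3, 50).
#' @param max_arm maximum arm length (default 20).
#' @param mismatch_penalty per internal mismatch (default 1).
#' @return list(`score`, `arm5` = c(start, end), `loop_len`,
#'   `arm3` = c(start, end)); score 0 and NULL arms when no hairpin pairs.
#' @export
score_stem_loop <- function(sequence, focus_start, focus_end,
                            min_loop = 3, max_loop = 50, max_arm = 20,
                            mismatch_penalty = 1) {
  L <- nchar(sequence)
  stopifnot(focus_start >= 0, focus_end <= L, focus_start < focus_end)
  enc <- encode_dna(sequence)
  best <- list(score = 0, arm5 = NULL, loop_len = NULL, arm3 = NULL)
  for (a in seq_len(max_arm)) {
    for (l in min_loop:max_loop) {
      span <- 2 * a + l
      if (span > L) next
      n_s <- L - span + 1
      starts <- 0:(n_s - 1)
      # 5' arm [s, s+a) must overlap [focus_start, focus_end)
      keep <- starts < focus_end & (starts + a) > focus_start
      if (!any(keep)) next
      # pair matrix: rows i = 0..a-1 (innermost first), cols = placements
      M <- matrix(FALSE, a, n_s)
      for (i in 0:(a - 1)) {
        p5 <- starts + a - 1 - i + 1
        p3 <- starts + a + l + i + 1
        b5 <- enc[p5]; b3 <- enc[p3]
        ok <- !is.na(b5) & !is.na(b3)
        v <- logical(n_s)
        v[ok] <- PAIR_TABLE[cbind(b5[ok], b3[ok])]
        M[i + 1, ] <- v
      }
      paired <- colSums(M)
      cand <- which(keep & paired > best$score)  # upper bound: score <= paired
      for (s in cand) {
        m <- M[, s]
        rng <- range(which(m))
        sc <- paired[s] - mismatch_penalty *
          ((rng[2] - rng[1] + 1) - sum(m[rng[1]:rng[2]]))
        if (sc > best$score) {
          s0 <- starts[s]
          best <- list(score = sc,
                       arm5 = c(s0, s0 + a),
                       loop_len = l,
                       arm3 = c(s0 + a + l, s0 + 2 * a + l))
        }
      }
    }
  }
  best
}
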