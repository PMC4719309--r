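# Synteny-anchor location: a desk-scale translated search that stands in
# for tBLASTn.  The genome is translated in all six frames, seeded with
# exact length-k amino-acid matches to the anchor protein, and each seed is
# extended without gaps under BLOSUM62; the maximal-scoring locus is
# returned when it clears a score threshold.

blosum62 <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      env$m <- env$BLOSUM62
    }
    env$m
  }
})

# Translate one frame of a scaffold; returns the AA string (unknown codons
# as X) so that AA position j (0-based) covers nt [offset + 3j, offset + 3j + 3).
translate_frame <- function(seq_chr, frame) {
  L <- nchar(seq_chr)
  n_codon <- (L - frame) %/% 3
  if (n_codon < 1) return("")
  sub <- substr(seq_chr, frame + 1, frame + 3 * n_codon)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

#' Locate a protein-coding anchor gene in a genome
#'
#' @param g a `genome`.
#' @param protein amino-acid sequence of the anchor.
#' @param k seed word length (exact amino-acid match, default 5).
#' @param min_extension_score minimum BLOSUM62 ungapped-extension score to
#'   report a locus (default 50).
#' @return NULL when nothing clears the threshold, else a list with
#'   `scaffold`, `start`, `end` (genomic, 0-based half-open), `strand`,
#'   `frame`, `score`, `protein_start`, `protein_end`.
#' @export
find_anchor_locus <- function(g, protein, k = 5, min_extension_score = 50) {
  stopifnot(nchar(protein) >= k)
  bl <- blosum62()
  prot <- strsplit(protein, "")[[1]]
  np <- length(prot)
  # seed index: protein k-mers -> start positions (1-based)
  kmers <- substring(protein, seq_len(np - k + 1), seq_len(np - k + 1) + k - 1)
  seed_idx <- split(seq_along(kmers), kmers)
  best <- NULL
  for (sc in names(g$scaffolds)) {
    fseq <- g$scaffolds[[sc]]
    L <- nchar(fseq)
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") fseq else revcomp(fseq)
      for (frame in 0:2) {
        aa <- translate_frame(sseq, frame)
        na <- nchar(aa)
        if (na < k) next
        aav <- strsplit(aa, "")[[1]]
        tmers <- substring(aa, seq_len(na - k + 1), seq_len(na - k + 1) + k - 1)
        hits <- which(tmers %in% names(seed_idx))
        seen <- character()
        for (tpos in hits) {
          for (ppos in seed_idx[[tmers[tpos]]]) {
            key <- sprintf("%d", tpos - ppos)  # one extension per diagonal
            if (key %in% seen) next
            seen <- c(seen, key)
            # ungapped extension around the seed on this diagonal
            score_at <- function(pi, ti) {
              a <- prot[pi]; b <- aav[ti]
              if (is.na(a) || is.na(b) ||
                  !a %in% rownames(bl) || !b %in% colnames(bl)) -4
              else bl[a, b]
            }
            seed_score <- sum(vapply(0:(k - 1), function(o)
              score_at(ppos + o, tpos + o), 0))
            # extend left
            best_l <- 0; cum <- 0; ext_l <- 0
            i <- 1
            while (ppos - i >= 1 && tpos - i >= 1) {
              cum <- cum + score_at(ppos - i, tpos - i)
              if (cum > best_l) { best_l <- cum; ext_l <- i }
              i <- i + 1
            }
            # extend right
            best_r <- 0; cum <- 0; ext_r <- 0
            i <- k
            while (ppos + i <= np && tpos + i <= na) {
              cum <- cum + score_at(ppos + i, tpos + i)
              if (cum > best_r) { best_r <- cum; ext_r <- i - k + 1 }
              i <- i + 1
            }
            tot <- seed_score + best_l + best_r
            if (is.null(best) || tot > best$score) {
              aa0 <- tpos - ext_l - 1            # 0-based AA start
              aa1 <- tpos + k - 1 + ext_r        # 0-based AA end (exclusive)
              nt0 <- frame + 3 * aa0
              nt1 <- frame + 3 * aa1
              if (strand == "+") {
                gstart <- nt0; gend <- nt1
              } else {
                gstart <- L - nt1; gend <- L - nt0
              }
              best <- list(scaffold = sc, start = gstart, end = gend,
                           strand = strand, frame = frame, score = tot,
                           protein_start = ppos - ext_l - 1,
                           protein_end = ppos + k - 1 + ext_r)
            }
          }
        }
      }
    }
  }
  if (is.null(best) || best$score < min_extension_score) return(NULL)
  best
}

#' Define the synteny window between anchor hits
#'
#' With two anchors on one scaffold within `max_span`, the window is the
#' inter-anchor interval; with a single anchor it is +/- `max_span/2` around
#' the anchor, clipped to the scaffold; anchors on different scaffolds give
#' no window and raise a syntenic-disruption flag.
#'
#' @param anchor_hits list of anchor loci as returned by
#'   [find_anchor_locus()] (NULL entries dropped).
#' @param max_span maximum span in bp for a two-anchor window.
#' @param lengths named scaffold lengths (or a `genome`).
#' @return list(`window` = list(scaffold, start, end) or NULL,
#'   `disrupted` = logical).
#' @export
define_synteny_window <- function(anchor_hits, max_span, lengths) {
  lengths <- scaffold_lengths(lengths)
  anchor_hits <- Filter(Negate(is.null), anchor_hits)
  if (!length(anchor_hits)) return(list(window = NULL, disrupted = FALSE))
  scs <- vapply(anchor_hits, `[[`, "", "scaffold")
  if (length(unique(scs)) > 1)
    return(list(window = NULL, disrupted = TRUE))
  sc <- scs[1]
  L <- lengths[[sc]]
  if (length(anchor_hits) >= 2) {
    ord <- order(vapply(anchor_hits, `[[`, 0, "start"))
    a <- anchor_hits[[ord[1]]]; b <- anchor_hits[[ord[length(ord)]]]
    if (b$start - a$end > max_span)
      return(list(window = NULL, disrupted = TRUE))
    st <- a$end; en <- b$start
    if (st >= en) { st <- max(0, a$start); en <- min(L, b$end) }
    return(list(window = list(scaffold = sc, start = st, end = en),
                disrupted = FALSE))
  }
  a <- anchor_hits[[1]]
  mid <- (a$start + a$end) / 2
  st <- max(0, floor(mid - max_span / 2))
  en <- min(L, ceiling(mid + max_span / 2))
  list(window = list(scaffold = sc, start = st, end = en), disrupted = FALSE)
}
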