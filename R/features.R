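# Genomic-feature assignment of peak summits (with double counting across
# overlapping transcripts, as in the source annotation convention) and the
# motif orientation-bias test per feature class.

FEATURE_CLASSES <- c("CDS", "intron", "five_prime_UTR", "three_prime_UTR",
                     "intergenic")

# Per-summit feature classes across all transcripts.  Returns a data.frame
# with one row per (peak, class, transcript) assignment; intergenic summits
# get a single row with transcript NA.
summit_classes <- function(p, annot) {
  introns <- transcript_introns(annot)
  rows <- list()
  feat <- annot[annot$type %in% c("CDS", "five_prime_UTR", "three_prime_UTR"), ]
  for (i in seq_len(nrow(p))) {
    s <- p$summit[i]; sc <- p$scaffold[i]
    hit_f <- feat[feat$scaffold == sc & feat$start <= s & s < feat$end, ]
    hit_i <- introns[introns$scaffold == sc & introns$start <= s &
                     s < introns$end, ]
    n <- nrow(hit_f) + nrow(hit_i)
    if (n == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        peak = p$name[i], class = "intergenic", transcript_id = NA_character_,
        gene_strand = NA_character_, stringsAsFactors = FALSE)
    } else {
      if (nrow(hit_f))
        rows[[length(rows) + 1]] <- data.frame(
          peak = p$name[i], class = hit_f$type,
          transcript_id = hit_f$transcript_id, gene_strand = hit_f$strand,
          stringsAsFactors = FALSE)
      if (nrow(hit_i))
        rows[[length(rows) + 1]] <- data.frame(
          peak = p$name[i], class = "intron",
          transcript_id = hit_i$transcript_id, gene_strand = hit_i$strand,
          stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # a summit may sit in the same class of several transcripts of one gene;
  # count each (peak, class, transcript) once
  out <- unique(out)
  rownames(out) <- NULL
  out
}

# Total genome bp covered by each feature class (transcript union per
# class); intergenic = genome minus the union of gene spans.
class_genome_fractions <- function(annot, lengths) {
  lengths <- scaffold_lengths(lengths)
  total <- sum(as.numeric(lengths))
  union_bp <- function(df) {
    if (!nrow(df)) return(0)
    bp <- 0
    for (sc in unique(df$scaffold)) {
      d <- df[df$scaffold == sc, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      cur_s <- d$start[1]; cur_e <- d$end[1]
      for (i in seq_len(nrow(d))[-1]) {
        if (d$start[i] <= cur_e) cur_e <- max(cur_e, d$end[i])
        else { bp <- bp + cur_e - cur_s; cur_s <- d$start[i]; cur_e <- d$end[i] }
      }
      bp <- bp + cur_e - cur_s
    }
    bp
  }
  introns <- transcript_introns(annot)
  fr <- c(
    CDS = union_bp(annot[annot$type == "CDS", ]),
    intron = union_bp(introns),
    five_prime_UTR = union_bp(annot[annot$type == "five_prime_UTR", ]),
    three_prime_UTR = union_bp(annot[annot$type == "three_prime_UTR", ]))
  gs <- gene_spans(annot)
  genic <- union_bp(gs)
  c(fr, intergenic = total - genic) / total
}

#' Feature-class assignment of peak summits with fold enrichment
#'
#' Every summit receives at least one class; summits inside overlapping
#' transcripts are double-counted (one assignment per transcript).  Fold
#' enrichment per class is the fraction of summit-class assignments over
#' the fraction of the genome covered by the class.
#'
#' @param p a `peaks` table.
#' @param annot an `annotation`.
#' @param lengths named scaffold lengths (or the `genome`).
#' @return list: `assignments` (peak, class, transcript_id, gene_strand),
#'   `enrichment` (class, n_assignments, assign_frac, genome_frac, fold).
#' @export
feature_assignment <- function(p, annot, lengths) {
  asn <- summit_classes(p, annot)
  tab <- table(factor(asn$class, levels = FEATURE_CLASSES))
  assign_frac <- as.numeric(tab) / sum(tab)
  genome_frac <- class_genome_fractions(annot, lengths)[FEATURE_CLASSES]
  enr <- data.frame(class = FEATURE_CLASSES, n_assignments = as.numeric(tab),
                    assign_frac = assign_frac,
                    genome_frac = as.numeric(genome_frac),
                    fold = ifelse(genome_frac > 0,
                                  assign_frac / as.numeric(genome_frac),
                                  NA_real_),
                    stringsAsFactors = FALSE)
  list(assignments = asn, enrichment = enr)
}

#' Motif orientation bias per feature class
#'
#' The best motif hit per peak (maximal log-odds over both strands, ties to
#' forward) is oriented relative to the host gene's transcription
#' direction: "+" when motif strand equals gene strand.  Intergenic peaks
#' use the genomic strand directly.  Counts per class are tested against
#' p0 = 0.5 with the two-sided (tail-doubling) binomial test.
#'
#' @param p a `peaks` table.
#' @param x the motif `pwm`.
#' @param annot an `annotation`.
#' @param g the `genome`.
#' @return list: `per_peak` (peak, class, motif_strand, orientation),
#'   `counts` (class, n_plus, n_minus, p), `n_unscorable`.
#' @export
orientation_bias <- function(p, x, annot, g) {
  classes <- summit_classes(p, annot)
  per_peak <- list()
  n_unscorable <- 0L
  for (i in seq_len(nrow(p))) {
    s <- genome_seq(g, p$scaffold[i], p$start[i], p$end[i])
    hits <- scan_pwm(s, x, p_threshold = 1)
    if (!nrow(hits)) { n_unscorable <- n_unscorable + 1L; next }
    o <- order(-hits$score, hits$strand)  # ties -> "+" before "-"
    best <- hits[o[1], ]
    cl <- classes[classes$peak == p$name[i], , drop = FALSE]
    ori <- ifelse(is.na(cl$gene_strand), best$strand,
                  ifelse(cl$gene_strand == best$strand, "+", "-"))
    per_peak[[length(per_peak) + 1]] <- data.frame(
      peak = p$name[i], class = cl$class, motif_strand = best$strand,
      orientation = ori, stringsAsFactors = FALSE)
  }
  per_peak <- if (length(per_peak)) do.call(rbind, per_peak) else
    data.frame(peak = character(), class = character(),
               motif_strand = character(), orientation = character())
  counts <- do.call(rbind, lapply(split(per_peak, per_peak$class), function(d) {
    np <- sum(d$orientation == "+"); nm <- sum(d$orientation == "-")
    data.frame(class = d$class[1], n_plus = np, n_minus = nm,
               p = binom_two_sided(np, np + nm), stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  list(per_peak = per_peak, counts = counts, n_unscorable = n_unscorable)
}
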