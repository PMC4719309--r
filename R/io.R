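# Readers and writers for the external formats the pipeline touches:
# FASTA genomes, BED-style peaks (6 columns + summit offset + enrichment),
# bedGraph signal, chain-score tables and Newick trees.

#' Construct a genome object
#'
#' A genome is a set of named scaffold sequences (uppercase A/C/G/T/N) with
#' optional Muller-element labels per scaffold.
#'
#' @param scaffolds named character vector of scaffold sequences.
#' @param me optional named character vector of Muller-element labels
#'   (values among "A".."F" or NA for unassigned), names matching scaffolds.
#' @return a `genome` object.
#' @export
genome <- function(scaffolds, me = NULL) {
  stopifnot(is.character(scaffolds), !is.null(names(scaffolds)),
            !anyDuplicated(names(scaffolds)))
  scaffolds <- toupper(scaffolds)
  bad <- grepl("[^ACGTN]", scaffolds)
  if (any(bad))
    stop("scaffold(s) contain non-ACGTN letters: ",
         paste(names(scaffolds)[bad], collapse = ", "))
  if (!is.null(me)) {
    me <- me[names(scaffolds)]
    names(me) <- names(scaffolds)
  }
  structure(list(scaffolds = scaffolds, me = me), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %d scaffold(s), %s bp total\n",
              length(x$scaffolds),
              format(sum(nchar(x$scaffolds)), big.mark = ",")))
  invisible(x)
}

#' Scaffold lengths of a genome
#' @param g a `genome`.
#' @return named integer vector of lengths.
#' @export
scaffold_lengths <- function(g) {
  if (inherits(g, "genome")) nchar(g$scaffolds) else g
}

#' Read / write genomes as FASTA
#'
#' @param file FASTA path.
#' @param me optional Muller-element labels (see [genome()]).
#' @return a `genome`.
#' @export
read_genome_fasta <- function(file, me = NULL) {
  ss <- Biostrings::readDNAStringSet(file)
  genome(stats::setNames(toupper(as.character(ss)),
                         sub("\\s.*$", "", names(ss))), me = me)
}

#' @rdname read_genome_fasta
#' @param g a `genome` to serialize.
#' @export
write_genome_fasta <- function(g, file) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(g$scaffolds), file)
  invisible(file)
}

#' Extract a scaffold subsequence (0-based, half-open)
#' @param g a `genome`.
#' @param scaffold scaffold name.
#' @param start,end 0-based half-open bounds.
#' @export
genome_seq <- function(g, scaffold, start, end) {
  L <- nchar(g$scaffolds[[scaffold]])
  stopifnot(start >= 0, end <= L, start < end)
  substr(g$scaffolds[[scaffold]], start + 1, end)
}

# ---- peaks ------------------------------------------------------------

#' Construct a peak table
#'
#' Peaks are the unit of every evolutionary analysis here (the high-affinity
#' sites of a chromatin-bound RNA).  Columns: scaffold, start, end (0-based
#' half-open), name, q_score (-log10 q-value), strand, summit (absolute
#' genomic position), enrichment (ChIRP/input); optional extra columns carry
#' per-RNA summed signal.
#'
#' @param df data.frame with the columns above.
#' @return validated `peaks` data.frame.
#' @export
peaks <- function(df) {
  stop_fields(df, c("scaffold", "start", "end", "name", "q_score",
                    "strand", "summit", "enrichment"), "peak table")
  ok <- df$start < df$end & df$summit >= df$start & df$summit < df$end &
    df$q_score >= 0 & df$enrichment >= 0
  ok[is.na(ok)] <- FALSE
  if (!all(ok)) {
    warning(sum(!ok), " invalid peak record(s) rejected")
    df <- df[ok, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("peaks", "data.frame")
  df
}

#' Read / write peaks in BED-plus format
#'
#' Native format: tab-delimited BED6 plus two columns, i.e. scaffold, start,
#' end, name, q_score, strand, summit_offset (summit relative to start),
#' enrichment.  Lines with start >= end or a summit outside the interval are
#' rejected with a warning.
#'
#' @param file path or connection; may also be a literal character vector of
#'   lines via `text =`.
#' @param text optional character scalar holding the file body.
#' @return a `peaks` data.frame (summit stored as absolute position).
#' @export
read_peaks <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n")[[1]] else readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(peaks(data.frame(scaffold = character(), start = numeric(),
                            end = numeric(), name = character(),
                            q_score = numeric(), strand = character(),
                            summit = numeric(), enrichment = numeric())))
  }
  f <- strsplit(lines, "[ \t]+")
  df <- data.frame(
    scaffold = vapply(f, `[`, "", 1),
    start = as.numeric(vapply(f, `[`, "", 2)),
    end = as.numeric(vapply(f, `[`, "", 3)),
    name = vapply(f, `[`, "", 4),
    q_score = as.numeric(vapply(f, `[`, "", 5)),
    strand = vapply(f, `[`, "", 6),
    summit_offset = as.numeric(vapply(f, `[`, "", 7)),
    enrichment = as.numeric(vapply(f, `[`, "", 8)),
    stringsAsFactors = FALSE)
  df$summit <- df$start + df$summit_offset
  df$summit_offset <- NULL
  peaks(df[, c("scaffold", "start", "end", "name", "q_score", "strand",
               "summit", "enrichment")])
}

#' @rdname read_peaks
#' @param p a `peaks` table to serialize.
#' @export
write_peaks <- function(p, file) {
  out <- data.frame(p$scaffold, p$start, p$end, p$name, p$q_score, p$strand,
                    p$summit - p$start, p$enrichment)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

# ---- signal tracks ----------------------------------------------------

#' Construct a signal track
#'
#' A track holds non-negative coverage values in fixed-size bins per
#' scaffold.
#'
#' @param values named list of numeric vectors (one per scaffold).
#' @param bin bin size in base pairs.
#' @return a `signal_track`.
#' @export
signal_track <- function(values, bin) {
  stopifnot(is.list(values), !is.null(names(values)), bin >= 1)
  if (any(vapply(values, function(v) any(v < 0), logical(1))))
    stop("signal values must be non-negative")
  structure(list(values = values, bin = as.integer(bin)),
            class = "signal_track")
}

#' Read / write signal tracks as bedGraph
#'
#' Lines are `scaffold  start  end  value` with start/end multiples of the
#' track's bin size.  On read, scaffold lengths (or the maximum end seen)
#' size the per-scaffold vectors; uncovered bins are zero.
#'
#' @param file path or connection.
#' @param bin bin size in bp.
#' @param lengths optional named scaffold lengths.
#' @return a `signal_track`.
#' @export
read_signal_track <- function(file, bin, lengths = NULL) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          col.names = c("scaffold", "start", "end", "value"))
  scs <- unique(df$scaffold)
  values <- list()
  for (sc in scs) {
    d <- df[df$scaffold == sc, ]
    L <- if (!is.null(lengths)) lengths[[sc]] else max(d$end)
    v <- numeric(ceiling(L / bin))
    for (i in seq_len(nrow(d))) {
      b0 <- d$start[i] %/% bin + 1
      b1 <- ceiling(d$end[i] / bin)
      v[b0:b1] <- d$value[i]
    }
    values[[sc]] <- v
  }
  signal_track(values, bin)
}

#' @rdname read_signal_track
#' @param track a `signal_track` to serialize (runs of equal values merged).
#' @export
write_signal_track <- function(track, file) {
  con <- if (is.character(file)) file(file, "w") else file
  if (is.character(file)) on.exit(close(con))
  for (sc in names(track$values)) {
    v <- track$values[[sc]]
    r <- rle(v)
    ends <- cumsum(r$lengths) * track$bin
    starts <- c(0, ends[-length(ends)])
    writeLines(sprintf("%s\t%d\t%d\t%g", sc, starts, ends, r$values), con)
  }
  invisible(file)
}

# Sum of track signal over a half-open genomic interval (whole bins whose
# midpoint falls inside are counted; intervals are expected to be
# bin-aligned in practice).
track_sum <- function(track, scaffold, start, end) {
  v <- track$values[[scaffold]]
  if (is.null(v)) return(NA_real_)
  b0 <- floor(start / track$bin) + 1
  b1 <- ceiling(end / track$bin)
  b1 <- min(b1, length(v))
  if (b0 > b1) return(0)
  sum(v[b0:b1])
}

# ---- chain-score tables and trees ------------------------------------

#' Read a chain-score table
#'
#' Tab-delimited rows `scaffold  ME  score`; returns a scaffold x ME matrix
#' of non-negative chain scores.
#'
#' @param file path or connection.
#' @return numeric matrix, rownames = scaffolds, colnames = Muller elements.
#' @export
read_chain_table <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          col.names = c("scaffold", "me", "score"))
  chain_table(df)
}

#' @rdname read_chain_table
#' @param df data.frame with columns scaffold, me, score.
#' @export
chain_table <- function(df) {
  stop_fields(df, c("scaffold", "me", "score"), "chain table")
  if (any(!is.finite(df$score)) || any(df$score < 0))
    stop("chain scores must be finite and non-negative")
  m <- stats::xtabs(score ~ scaffold + me, data = df)
  matrix(as.numeric(m), nrow = nrow(m),
         dimnames = list(rownames(m), colnames(m)))
}

#' @rdname read_chain_table
#' @param mat scaffold x ME score matrix to serialize.
#' @export
write_chain_table <- function(mat, file) {
  df <- data.frame(scaffold = rep(rownames(mat), ncol(mat)),
                   me = rep(colnames(mat), each = nrow(mat)),
                   score = as.vector(mat))
  df <- df[df$score > 0 | TRUE, ]
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Order species by patristic distance from a reference leaf
#'
#' @param tree an `ape::phylo` tree whose tips are species identifiers.
#' @param reference reference tip label.
#' @return character vector of the other tips, closest first; ties broken
#'   alphabetically.
#' @export
species_search_order <- function(tree, reference) {
  stopifnot(reference %in% tree$tip.label)
  d <- stats::cophenetic(tree)[reference, ]
  d <- d[names(d) != reference]
  names(d)[order(d, names(d))]
}
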