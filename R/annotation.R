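# Gene-model handling.  Annotations are held as a flat feature table
# (scaffold, type, start, end, strand, gene_id, transcript_id) with 0-based
# half-open coordinates; GFF-style input (1-based inclusive) is converted on
# read.  Introns are derived, never stored: they exactly fill the gaps
# between consecutive exons of a transcript.

ANNOT_TYPES <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")

#' Construct an annotation from a feature table
#'
#' @param features data.frame with columns `scaffold`, `type` (one of exon,
#'   CDS, five_prime_UTR, three_prime_UTR), `start`, `end` (0-based
#'   half-open), `strand` ("+"/"-"), `gene_id`, `transcript_id`.
#' @return validated `annotation` data.frame.  Records with unknown strand
#'   and transcripts with overlapping exons are rejected with a warning.
#' @export
annotation <- function(features) {
  stop_fields(features, c("scaffold", "type", "start", "end", "strand",
                          "gene_id", "transcript_id"), "annotation")
  ok <- features$strand %in% c("+", "-") & features$start < features$end &
    features$type %in% ANNOT_TYPES
  if (!all(ok)) {
    warning(sum(!ok), " malformed annotation record(s) rejected")
    features <- features[ok, , drop = FALSE]
  }
  # reject transcripts whose exons overlap
  bad_tx <- character()
  ex <- features[features$type == "exon", , drop = FALSE]
  for (tx in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) bad_tx <- c(bad_tx, tx)
  }
  if (length(bad_tx)) {
    warning("transcript(s) with overlapping exons rejected: ",
            paste(bad_tx, collapse = ", "))
    features <- features[!features$transcript_id %in% bad_tx, , drop = FALSE]
  }
  features <- features[order(features$scaffold, features$transcript_id,
                             features$start), , drop = FALSE]
  rownames(features) <- NULL
  class(features) <- c("annotation", "data.frame")
  features
}

#' Read a GFF-style annotation
#'
#' Nine tab-delimited columns as in GFF3; only exon, CDS, five_prime_UTR and
#' three_prime_UTR features are kept.  Coordinates are converted from
#' 1-based inclusive to the internal 0-based half-open convention.  The
#' attribute column must carry `gene_id` and `transcript_id` keys
#' (`key=value` or `key "value"`).
#'
#' @param file path or connection.
#' @param text optional character scalar holding the file body.
#' @return an `annotation`.
#' @export
read_annotation <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n")[[1]] else readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t")
  keep <- vapply(f, length, 0L) >= 9
  f <- f[keep]
  get_attr <- function(a, key) {
    m <- regmatches(a, regexec(paste0(key, "[= \"]+([^;\"]+)"), a))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  df <- data.frame(
    scaffold = vapply(f, `[`, "", 1),
    type = vapply(f, `[`, "", 3),
    start = as.numeric(vapply(f, `[`, "", 4)) - 1,
    end = as.numeric(vapply(f, `[`, "", 5)),
    strand = vapply(f, `[`, "", 7),
    gene_id = vapply(f, function(x) get_attr(x[9], "gene_id"), ""),
    transcript_id = vapply(f, function(x) get_attr(x[9], "transcript_id"), ""),
    stringsAsFactors = FALSE)
  annotation(df[df$type %in% ANNOT_TYPES, , drop = FALSE])
}

#' Write an annotation in the GFF-style format read by [read_annotation()]
#' @param annot an `annotation`.
#' @param file output path.
#' @export
write_annotation <- function(annot, file) {
  out <- sprintf("%s\tchirpevo\t%s\t%d\t%d\t.\t%s\t.\tgene_id=%s;transcript_id=%s",
                 annot$scaffold, annot$type, annot$start + 1, annot$end,
                 annot$strand, annot$gene_id, annot$transcript_id)
  writeLines(out, file)
  invisible(file)
}

#' Derive introns from an annotation
#'
#' One row per inter-exon gap of each transcript; the union of a
#' transcript's exons and introns tiles its genomic span exactly.
#'
#' @param annot an `annotation`.
#' @return data.frame with columns `intron_id`, `scaffold`, `start`, `end`,
#'   `strand`, `gene_id`, `transcript_id`.
#' @export
transcript_introns <- function(annot) {
  ex <- annot[annot$type == "exon", , drop = FALSE]
  res <- list()
  for (tx in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2) next
    st <- e$end[-nrow(e)]
    en <- e$start[-1]
    res[[tx]] <- data.frame(
      intron_id = sprintf("%s.i%d", tx, seq_along(st)),
      scaffold = e$scaffold[1], start = st, end = en,
      strand = e$strand[1], gene_id = e$gene_id[1], transcript_id = tx,
      stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(intron_id = character(), scaffold = character(),
                      start = numeric(), end = numeric(), strand = character(),
                      gene_id = character(), transcript_id = character()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Gene spans (transcript union) with UTR presence flags
#'
#' @param annot an `annotation`.
#' @return data.frame: `gene_id`, `scaffold`, `start`, `end`, `strand`,
#'   `has_utr5`, `has_utr3`.
#' @export
gene_spans <- function(annot) {
  sp <- split(seq_len(nrow(annot)), annot$gene_id)
  out <- lapply(names(sp), function(g) {
    a <- annot[sp[[g]], , drop = FALSE]
    data.frame(gene_id = g, scaffold = a$scaffold[1],
               start = min(a$start), end = max(a$end), strand = a$strand[1],
               has_utr5 = any(a$type == "five_prime_UTR"),
               has_utr3 = any(a$type == "three_prime_UTR"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
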