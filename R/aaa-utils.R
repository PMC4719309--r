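# Shared low-level helpers. All genomic coordinates in this package are
# 0-based, half-open [start, end); BED-style I/O is native and GFF-style
# input is converted on read.

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_LETTERS <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' @param x character vector of A/C/G/T/N sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Derive a child seed from a parent seed and a label
#'
#' Submodules of the simulator draw their own deterministic seeds so that one
#' global seed fixes every byte of output.  The derivation hashes the label
#' into the 31-bit integer range.
#'
#' @param seed integer parent seed.
#' @param label character label naming the consumer.
#' @return integer seed in [1, 2^31 - 2].
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 2147483629
  as.integer((abs(as.numeric(seed)) %% 2147483629 * 48271 + h) %% 2147483629 + 1)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a random DNA sequence
#'
#' @param n sequence length.
#' @param probs letter probabilities for A, C, G, T (default uniform).
#' @return single character string.
#' @export
random_dna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(DNA_LETTERS, n, replace = TRUE, prob = probs), collapse = "")
}

# Integer-encode a DNA string: A=1 C=2 G=3 T=4, anything else NA.
encode_dna <- function(s) {
  m <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], DNA_LETTERS)
  m
}

# Mononucleotide composition as named frequencies over A,C,G,T (N ignored).
dna_composition <- function(s) {
  v <- encode_dna(paste(s, collapse = ""))
  v <- v[!is.na(v)]
  if (!length(v)) return(stats::setNames(rep(0.25, 4), DNA_LETTERS))
  tab <- tabulate(v, nbins = 4L)
  stats::setNames(tab / sum(tab), DNA_LETTERS)
}

# Distance from a point to a half-open interval: 0 when inside, otherwise
# base-pair gap to the nearest covered base.
point_interval_distance <- function(pos, start, end) {
  d <- numeric(length(start))
  d[pos < start] <- (start - pos)[pos < start]
  d[pos >= end] <- (pos - (end - 1))[pos >= end]
  d
}

stop_fields <- function(df, fields, what) {
  miss <- setdiff(fields, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")),
         call. = FALSE)
}
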