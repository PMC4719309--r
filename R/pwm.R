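# Position-weight-matrix construction, refinement, and scanning with exact
# score-distribution p-values.  Log-odds scores are in bits and are
# rescaled to integer hundredths of a bit before the dynamic-programming
# computation of the null score distribution, bounding the table size; the
# reported score is the rescaled one, so the p-value is exact for the score
# actually reported.

PWM_SCALE <- 100L  # integer rescaling granularity: 1/100 bit

#' Construct a position weight matrix
#'
#' @param counts 4 x width numeric matrix of non-negative letter counts,
#'   rows A, C, G, T.
#' @param pseudocount added to every cell before converting to
#'   probabilities (default 0.25).
#' @param background named background letter frequencies (default uniform).
#' @param instances optional character vector of the aligned instances the
#'   counts were tabulated from; kept for later refinement.
#' @return a `pwm` object.
#' @export
pwm <- function(counts, pseudocount = 0.25, background = NULL,
                instances = NULL) {
  stopifnot(is.matrix(counts), nrow(counts) == 4, all(counts >= 0))
  rownames(counts) <- DNA_LETTERS
  background <- background %||% stats::setNames(rep(0.25, 4), DNA_LETTERS)
  background <- background[DNA_LETTERS] / sum(background)
  if (any(background <= 0)) stop("background frequencies must be positive")
  adj <- counts + pseudocount
  if (any(colSums(adj) <= 0)) stop("column count sums must be positive")
  probs <- sweep(adj, 2, colSums(adj), "/")
  structure(list(counts = counts, pseudocount = pseudocount,
                 background = background, probs = probs,
                 width = ncol(counts), instances = instances),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> width %d, pseudocount %g, consensus %s\n", x$width,
              x$pseudocount, paste(DNA_LETTERS[apply(x$probs, 2, which.max)],
                                   collapse = "")))
  invisible(x)
}

#' Build a PWM from aligned instances
#'
#' @param instances character vector of equal-length, N-free sequences.
#' @inheritParams pwm
#' @return a `pwm` whose counts are the letter counts over the instances.
#' @export
pwm_from_instances <- function(instances, pseudocount = 0.25,
                               background = NULL) {
  stopifnot(length(instances) >= 1)
  w <- nchar(instances[1])
  bad <- which(nchar(instances) != w)
  if (length(bad))
    stop("instance width mismatch: ", instances[bad[1]])
  enc <- lapply(instances, encode_dna)
  if (any(vapply(enc, anyNA, logical(1))))
    stop("instances must be N-free A/C/G/T sequences")
  counts <- matrix(0, 4, w, dimnames = list(DNA_LETTERS, NULL))
  for (e in enc) counts[cbind(e, seq_len(w))] <-
    counts[cbind(e, seq_len(w))] + 1
  pwm(counts, pseudocount = pseudocount, background = background,
      instances = instances)
}

#' Refine a PWM with newly accepted motif instances
#'
#' Counts are re-tabulated over all accepted instances (old plus new); the
#' background can be re-estimated, typically from the composition of all
#' synteny windows searched so far.
#'
#' @param x a `pwm` built from instances.
#' @param new_instances character vector of new aligned instances.
#' @param background optional new background frequencies.
#' @return the refined `pwm`.
#' @export
refine_pwm <- function(x, new_instances, background = NULL) {
  stopifnot(inherits(x, "pwm"))
  bad <- which(nchar(new_instances) != x$width)
  if (length(bad))
    stop("instance width mismatch: ", new_instances[bad[1]])
  all_inst <- c(x$instances, new_instances)
  pwm_from_instances(all_inst, pseudocount = x$pseudocount,
                     background = background %||% x$background)
}

# Integer log-odds score matrix (hundredths of a bit).
pwm_int_scores <- function(x) {
  if (any(x$probs <= 0))
    stop("zero cell probability; use a positive pseudocount to keep log-odds finite")
  lo <- log2(sweep(x$probs, 1, x$background, "/"))
  round(lo * PWM_SCALE)
}

# Exact null distribution of the integer window score under the background
# model: returns list(support offset `min`, probability vector `p` where
# p[i] = P(score == min + i - 1)).
pwm_score_distribution <- function(x) {
  s <- pwm_int_scores(x)
  lo <- sum(apply(s, 2, min)); hi <- sum(apply(s, 2, max))
  p <- numeric(hi - lo + 1)
  # column-by-column convolution
  cur <- 1; cur_min <- 0
  for (j in seq_len(ncol(s))) {
    cmin <- min(s[, j])
    width <- max(s[, j]) - cmin + 1
    nxt <- numeric(length(cur) + width - 1)
    for (l in 1:4) {
      off <- s[l, j] - cmin
      idx <- seq_along(cur) + off
      nxt[idx] <- nxt[idx] + cur * x$background[l]
    }
    cur <- nxt; cur_min <- cur_min + cmin
  }
  list(min = cur_min, p = cur)
}

# P(score >= q) lookup table: upper-tail sums of the null distribution.
pwm_tail_fun <- function(x) {
  d <- pwm_score_distribution(x)
  tail <- rev(cumsum(rev(d$p)))
  function(q) {
    i <- q - d$min + 1
    out <- numeric(length(q))
    out[i <= 1] <- 1
    inside <- i >= 1 & i <= length(tail)
    out[inside] <- tail[i[inside]]
    out[i > length(tail)] <- 0
    pmin(pmax(out, 0), 1)
  }
}

#' Scan a sequence with a PWM
#'
#' Both strands are scanned; windows containing N are unscorable and
#' skipped.  The score of a window is the sum of per-column log-odds in
#' bits (rescaled to 1/100-bit granularity) and its p-value is the exact
#' probability, under the background model, of a window score at least as
#' large.
#'
#' @param sequence character scalar (A/C/G/T/N).
#' @param x a `pwm`.
#' @param p_threshold report hits with p-value <= this (default 1e-4).
#' @return data.frame of hits sorted by position: `start`, `end` (0-based
#'   half-open on the forward sequence), `strand`, `score` (bits),
#'   `p_value`, `hit_seq` (the matched sequence read on its strand).
#' @export
scan_pwm <- function(sequence, x, p_threshold = 1e-4) {
  stopifnot(inherits(x, "pwm"))
  w <- x$width
  empty <- data.frame(start = numeric(), end = numeric(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), hit_seq = character())
  L <- nchar(sequence)
  if (L < w) return(empty)
  s <- pwm_int_scores(x)
  tailp <- pwm_tail_fun(x)
  scan_one <- function(seq_chr) {
    e <- encode_dna(seq_chr)
    n <- length(e) - w + 1
    if (n < 1) return(NULL)
    tot <- numeric(n)
    bad <- logical(n)
    for (j in seq_len(w)) {
      lj <- e[j:(j + n - 1)]
      bad <- bad | is.na(lj)
      sc <- s[, j][lj]
      sc[is.na(sc)] <- 0
      tot <- tot + sc
    }
    list(score = tot, bad = bad)
  }
  fwd <- scan_one(sequence)
  rc <- scan_one(revcomp(sequence))
  res <- list()
  if (!is.null(fwd)) {
    p <- tailp(fwd$score)
    keep <- !fwd$bad & p <= p_threshold
    if (any(keep)) {
      st <- which(keep) - 1
      res$fwd <- data.frame(start = st, end = st + w, strand = "+",
                            score = fwd$score[keep] / PWM_SCALE,
                            p_value = p[keep],
                            hit_seq = substring(sequence, st + 1, st + w),
                            stringsAsFactors = FALSE)
    }
  }
  if (!is.null(rc)) {
    p <- tailp(rc$score)
    keep <- !rc$bad & p <= p_threshold
    if (any(keep)) {
      i <- which(keep) - 1          # 0-based start on the reverse complement
      st <- L - w - i               # corresponding forward-strand start
      rcseq <- revcomp(sequence)
      res$rev <- data.frame(start = st, end = st + w, strand = "-",
                            score = rc$score[keep] / PWM_SCALE,
                            p_value = p[keep],
                            hit_seq = substring(rcseq, i + 1, i + w),
                            stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write PWMs in MEME-minimal text format
#'
#' @param file path or connection.
#' @param pseudocount pseudocount for the reconstructed `pwm`.
#' @return a `pwm` (counts reconstructed as probabilities x nsites).
#' @export
read_pwm <- function(file, pseudocount = 0.25) {
  lines <- readLines(file)
  bg <- stats::setNames(rep(0.25, 4), DNA_LETTERS)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl) && bgl[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]]
    if (length(tok) >= 8) bg <- stats::setNames(as.numeric(tok[c(2, 4, 6, 8)]),
                                                tok[c(1, 3, 5, 7)])[DNA_LETTERS]
  }
  hd <- grep("^letter-probability matrix", lines)
  if (!length(hd)) stop("no letter-probability matrix in PWM file")
  w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[hd[1]]))
  ns <- if (grepl("nsites=", lines[hd[1]]))
    as.numeric(sub(".*nsites= *([0-9.]+).*", "\\1", lines[hd[1]])) else 20
  rows <- lines[(hd[1] + 1):(hd[1] + w)]
  m <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                numeric(4)))
  counts <- t(m) * ns
  pwm(counts, pseudocount = pseudocount, background = bg)
}

#' @rdname read_pwm
#' @param x a `pwm` to serialize.
#' @param name motif name written in the MOTIF line.
#' @export
write_pwm <- function(x, file, name = "motif1") {
  ns <- max(colSums(x$counts))
  probs <- if (ns > 0) sweep(x$counts, 2, pmax(colSums(x$counts), 1e-9), "/")
  else x$probs
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "Background letter frequencies",
             sprintf("A %.5f C %.5f G %.5f T %.5f",
                     x$background["A"], x$background["C"],
                     x$background["G"], x$background["T"]),
             "", sprintf("MOTIF %s", name),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= %g",
                     x$width, max(ns, 1)),
             apply(probs, 2, function(col)
               sprintf(" %.6f %.6f %.6f %.6f", col[1], col[2], col[3], col[4])))
  writeLines(lines, file)
  invisible(file)
}
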