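# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive each quantity from first principles, not via
# the package's own code paths.

# -- PWM scanning: score every window directly from the probability matrix,
# and compute exact tail p-values by enumerating all 4^w background words.
oracle_scan_pwm <- function(sequence, x, p_threshold) {
  w <- x$width
  lo <- log2(sweep(x$probs, 1, x$background, "/"))
  lo_int <- round(lo * 100)  # same granularity the scanner documents
  words <- expand.grid(rep(list(1:4), w))
  word_scores <- as.matrix(words)
  sc <- numeric(nrow(words))
  pr <- numeric(nrow(words))
  for (j in seq_len(w)) {
    sc <- sc + lo_int[cbind(word_scores[, j], j)]
    pr <- pr + log(x$background[word_scores[, j]])
  }
  pr <- exp(pr)
  tailp <- function(s) sum(pr[sc >= s])
  score_win <- function(enc) {
    if (anyNA(enc)) return(NA_real_)
    sum(lo_int[cbind(enc, seq_len(w))])
  }
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
    enc <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    L <- length(enc)
    for (i in 0:(L - w)) {
      v <- score_win(enc[(i + 1):(i + w)])
      if (is.na(v)) next
      p <- tailp(v)
      if (p <= p_threshold) {
        st <- if (strand == "+") i else L - w - i
        res[[length(res) + 1]] <- data.frame(
          start = st, strand = strand, score = v / 100, p_value = p)
      }
    }
  }
  if (!length(res))
    return(data.frame(start = numeric(), strand = character(),
                      score = numeric(), p_value = numeric()))
  out <- do.call(rbind, res)
  out[order(out$start, out$strand), , drop = FALSE]
}

# -- densest motif-cluster window by checking every hit as a left edge.
oracle_elect <- function(starts, scores, span, min_hits) {
  best <- NULL
  o <- order(starts)
  starts <- starts[o]; scores <- scores[o]
  for (i in seq_along(starts)) {
    inside <- starts >= starts[i] & starts < starts[i] + span
    n <- sum(inside)
    if (n < min_hits) next
    ss <- sum(scores[inside])
    if (is.null(best) || n > best$n || (n == best$n && ss > best$ss + 1e-12))
      best <- list(start = starts[i], n = n, ss = ss)
  }
  best
}

# -- hairpin score by plain triple loop over (start, arm, loop).
oracle_stem <- function(sequence, f0, f1, min_loop = 3, max_loop = 50,
                        max_arm = 20, penalty = 1) {
  v <- strsplit(sequence, "")[[1]]
  pairs <- list(A = "T", C = "G", G = c("C", "T"), T = c("A", "G"))
  L <- length(v)
  best <- 0
  for (a in 1:max_arm) for (l in min_loop:max_loop) {
    span <- 2 * a + l
    if (span > L) next
    for (s in 0:(L - span)) {
      if (!(s < f1 && s + a > f0)) next
      m <- logical(a)
      for (i in 0:(a - 1)) {
        b5 <- v[s + a - i]; b3 <- v[s + a + l + i + 1]
        m[i + 1] <- b5 %in% names(pairs) && b3 %in% pairs[[b5]]
      }
      if (!any(m)) next
      r <- range(which(m))
      sc <- sum(m) - penalty * ((r[2] - r[1] + 1) - sum(m[r[1]:r[2]]))
      if (sc > best) best <- sc
    }
  }
  best
}

# -- second, independently coded global-alignment DP with the same
# lexicographic objective (score, then matches, then fewest columns).
oracle_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  S <- matrix(-Inf, n + 1, m + 1); M <- matrix(0L, n + 1, m + 1)
  C <- matrix(0L, n + 1, m + 1)
  S[1, ] <- gap * (0:m); C[1, ] <- 0:m
  S[, 1] <- gap * (0:n); C[, 1] <- 0:n
  for (i in 1:n) for (j in 1:m) {
    eq <- va[i] == vb[j]
    cand <- rbind(
      c(S[i, j] + if (eq) match else mismatch, M[i, j] + eq, C[i, j] + 1),
      c(S[i, j + 1] + gap, M[i, j + 1], C[i, j + 1] + 1),
      c(S[i + 1, j] + gap, M[i + 1, j], C[i + 1, j] + 1))
    o <- order(-cand[, 1], -cand[, 2], cand[, 3])[1]
    S[i + 1, j + 1] <- cand[o, 1]
    M[i + 1, j + 1] <- cand[o, 2]
    C[i + 1, j + 1] <- cand[o, 3]
  }
  list(score = S[n + 1, m + 1],
       identity = 100 * M[n + 1, m + 1] / C[n + 1, m + 1])
}

# -- nearest peak-edge distance by direct search over all B peaks.
oracle_turnover_distance <- function(pos, scaffold, pb) {
  on_sc <- which(pb$scaffold == scaffold)
  if (!length(on_sc)) return(NA_real_)
  d <- vapply(on_sc, function(i) {
    if (pos >= pb$start[i] && pos < pb$end[i]) 0
    else if (pos < pb$start[i]) pb$start[i] - pos
    else pos - (pb$end[i] - 1)
  }, 0)
  min(d)
}

# -- tract selection by O(L^2) substring enumeration.
oracle_select_ppt <- function(intron_seq, min_len = 9, min_pyr = 0.85) {
  v <- strsplit(intron_seq, "")[[1]]
  L <- length(v)
  best <- NULL
  for (s in 0:(L - min_len)) for (e in (s + min_len):L) {
    sub <- v[(s + 1):e]
    np <- sum(sub %in% c("C", "T")); len <- e - s
    pur <- len - np
    if (np / len < min_pyr || pur * 10 > len) next
    raw <- np - 2 * pur
    dist <- L - e
    pen <- if (dist < 40) 0 else 0.02 * (dist - 40)
    cand <- c(raw - pen, -dist, len)
    if (is.null(best) || cand[1] > best$key[1] + 1e-12 ||
        (abs(cand[1] - best$key[1]) <= 1e-12 &&
         (cand[2] > best$key[2] ||
          (cand[2] == best$key[2] && cand[3] > best$key[3])))) {
      best <- list(key = cand, start = s, end = e, raw = raw, dist = dist)
    }
  }
  best
}

# -- all-pairs nearest-neighbor distances.
oracle_nnd <- function(x) {
  vapply(seq_along(x), function(i) min(abs(x[-i] - x[i])), 0)
}

# -- exhaustive two-sample KS permutation p over all label assignments.
oracle_ks_perm_p <- function(x, y) {
  ks_stat <- function(a, b) {
    v <- sort(unique(c(a, b)))
    max(abs(vapply(v, function(t) mean(a <= t) - mean(b <= t), 0)))
  }
  D_obs <- ks_stat(x, y)
  pool <- c(x, y)
  idx <- utils::combn(length(pool), length(x))
  hits <- 0
  for (k in seq_len(ncol(idx))) {
    a <- pool[idx[, k]]; b <- pool[-idx[, k]]
    if (ks_stat(a, b) >= D_obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(idx)
}
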