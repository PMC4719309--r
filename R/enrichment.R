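# Windowed ChIRP/input signal enrichment, Muller-element assignment from
# chain scores, peak filtering and the RNA1/RNA2 occupancy bias.

#' Windowed signal enrichment (ChIRP / input)
#'
#' Enrichment per fixed window is the sum of ChIRP signal divided by the
#' sum of input signal over the same window.  Windows intersecting an
#' exclusion zone (e.g. the lncRNA loci themselves, where antisense probes
#' can recover genomic DNA directly) are dropped; windows with zero input
#' are flagged rather than divided.
#'
#' @param chirp,input `signal_track`s on the same scaffolds and bin size.
#' @param window_bp window size in bp (default 1000).
#' @param exclude optional data.frame of zones (`scaffold`, `start`, `end`).
#' @return data.frame: `scaffold`, `start`, `end`, `chirp_sum`,
#'   `input_sum`, `enrichment` (NA when input is zero), `zero_input`.
#' @export
window_enrichment <- function(chirp, input, window_bp = 1000, exclude = NULL) {
  stopifnot(chirp$bin == input$bin)
  d1 <- setdiff(names(chirp$values), names(input$values))
  d2 <- setdiff(names(input$values), names(chirp$values))
  if (length(d1) || length(d2))
    stop("scaffold sets differ between tracks: ",
         paste(c(d1, d2), collapse = ", "))
  bin <- chirp$bin
  stopifnot(window_bp %% bin == 0)
  k <- window_bp %/% bin
  out <- list()
  for (sc in names(chirp$values)) {
    cv <- chirp$values[[sc]]; iv <- input$values[[sc]]
    n <- min(length(cv), length(iv))
    nw <- n %/% k
    if (nw < 1) next
    idx <- rep(seq_len(nw), each = k)
    cs <- as.numeric(tapply(cv[seq_len(nw * k)], idx, sum))
    is <- as.numeric(tapply(iv[seq_len(nw * k)], idx, sum))
    st <- (seq_len(nw) - 1) * window_bp
    df <- data.frame(scaffold = sc, start = st, end = st + window_bp,
                     chirp_sum = cs, input_sum = is,
                     enrichment = ifelse(is > 0, cs / is, NA_real_),
                     zero_input = is == 0, stringsAsFactors = FALSE)
    out[[sc]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(exclude) && nrow(res)) {
    drop <- rep(FALSE, nrow(res))
    for (i in seq_len(nrow(exclude))) {
      drop <- drop | (res$scaffold == exclude$scaffold[i] &
                      res$start < exclude$end[i] &
                      res$end > exclude$start[i])
    }
    res <- res[!drop, , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

#' Assign scaffolds to Muller elements from chain scores
#'
#' Each scaffold's similarity score to an element is its chain score
#' divided by the scaffold's total chain score across elements; the argmax
#' element is assigned when its score reaches the cutoff, otherwise the
#' scaffold is left unassigned with all scores reported for manual review.
#' Ties at the maximum are never assigned.
#'
#' @param chains scaffold x ME chain-score matrix (see [read_chain_table()]).
#' @param cutoff assignment cutoff on the similarity score (default 0.85).
#' @return data.frame: `scaffold`, `me` (NA when unassigned), `score` (best
#'   similarity score), `assigned`, plus one `sim_<ME>` column per element.
#' @export
assign_scaffold_to_me <- function(chains, cutoff = 0.85) {
  stopifnot(is.matrix(chains))
  rs <- rowSums(chains)
  sim <- chains
  sim[rs > 0, ] <- chains[rs > 0, , drop = FALSE] / rs[rs > 0]
  sim[rs == 0, ] <- NA_real_
  me <- rep(NA_character_, nrow(chains))
  score <- rep(NA_real_, nrow(chains))
  for (i in seq_len(nrow(chains))) {
    if (rs[i] == 0) next
    v <- sim[i, ]
    score[i] <- max(v)
    top <- which(v == max(v))
    if (length(top) == 1 && v[top] >= cutoff) me[i] <- colnames(chains)[top]
  }
  out <- data.frame(scaffold = rownames(chains), me = me, score = score,
                    assigned = !is.na(me), stringsAsFactors = FALSE)
  simdf <- as.data.frame(sim)
  names(simdf) <- paste0("sim_", colnames(chains))
  cbind(out, simdf, row.names = NULL)
}

#' Filter peaks by significance and enrichment
#'
#' Keeps peaks with q_score >= `q_min` and enrichment >= `enrichment_min`
#' (both thresholds inclusive).
#'
#' @param p a `peaks` table.
#' @param q_min minimum -log10 q-value (study convention: 3000, or 8000 for
#'   the species with the largest X).
#' @param enrichment_min minimum ChIRP/input ratio (study convention: 20).
#' @return the filtered `peaks` table.
#' @export
filter_peaks <- function(p, q_min = 3000, enrichment_min = 20) {
  out <- p[p$q_score >= q_min & p$enrichment >= enrichment_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-peak RNA1/RNA2 occupancy bias
#'
#' Computes, for each peak, the summed signal of two RNA tracks over the
#' peak interval and the per-peak log2 ratio; peaks with zero signal in
#' either channel are excluded and counted.
#'
#' @param p a `peaks` table.
#' @param track1,track2 `signal_track`s for the two RNAs.
#' @return list: `per_peak` (name, s1, s2, log2_ratio), `percentiles`
#'   (p5/p25/p50/p75/p95 of the log2 ratios), `median_fraction`
#'   (median s1/s2), `n_zero` (excluded peaks).
#' @export
rox_bias <- function(p, track1, track2) {
  s1 <- mapply(function(sc, a, b) track_sum(track1, sc, a, b),
               p$scaffold, p$start, p$end)
  s2 <- mapply(function(sc, a, b) track_sum(track2, sc, a, b),
               p$scaffold, p$start, p$end)
  ok <- !is.na(s1) & !is.na(s2) & s1 > 0 & s2 > 0
  if (!any(ok)) stop("all peaks have zero signal in one channel")
  r <- log2(s1[ok] / s2[ok])
  q <- stats::quantile(r, c(.05, .25, .5, .75, .95), names = FALSE)
  list(per_peak = data.frame(name = p$name[ok], s1 = s1[ok], s2 = s2[ok],
                             log2_ratio = r, stringsAsFactors = FALSE),
       percentiles = stats::setNames(q, c("p5", "p25", "p50", "p75", "p95")),
       median_fraction = stats::median(s1[ok] / s2[ok]),
       n_zero = sum(!ok))
}
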