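# Polypyrimidine-tract (PPT) selection within introns and peak-to-PPT
# proximity statistics.  The default tract scorer is deliberately simple
# and pluggable: externally computed tract tables can be injected instead.

#' Distance penalty for PPT selection
#'
#' Zero within 40 bp of the 3' splice site, then 0.02 per base:
#' penalty(d) = 0 for d < 40, 0.02 * (d - 40) otherwise (so d = 40 itself
#' incurs no penalty; the offset convention is configurable upstream).
#'
#' @param distance bp from the candidate tract's 3' end to the intron's 3'
#'   splice site (>= 0).
#' @param free_zone penalty-free distance (default 40).
#' @param per_base penalty slope per bp beyond the free zone (default 0.02).
#' @return penalty score(s).
#' @export
ppt_penalty <- function(distance, free_zone = 40, per_base = 0.02) {
  if (any(distance < 0)) stop("distance_to_3ss must be non-negative")
  ifelse(distance < free_zone, 0, per_base * (distance - free_zone))
}

#' Default pyrimidine-tract scorer
#'
#' Enumerates all substrings of an intron sequence that qualify as tracts:
#' length >= `min_len`, pyrimidine (C/T) fraction >= `min_pyr_frac`, and at
#' most one purine per 10 nt.  Raw score = #pyrimidines - 2 x #purines.
#'
#' @param intron_seq intron sequence in transcript orientation (5'->3';
#'   the 3' splice site is at its right end).
#' @param min_len minimum tract length (default 9).
#' @param min_pyr_frac minimum C/T fraction (default 0.85).
#' @return data.frame of candidates: `start`, `end` (0-based half-open
#'   within the intron), `raw`.
#' @export
ppt_candidates <- function(intron_seq, min_len = 9, min_pyr_frac = 0.85) {
  L <- nchar(intron_seq)
  if (L < min_len)
    return(data.frame(start = numeric(), end = numeric(), raw = numeric()))
  v <- strsplit(toupper(intron_seq), "")[[1]]
  pyr <- cumsum(v %in% c("C", "T"))
  res <- list()
  for (len in min_len:L) {
    starts <- 0:(L - len)
    np <- pyr[starts + len] - c(0, pyr)[starts + 1]
    pur <- len - np
    ok <- (np / len >= min_pyr_frac) & (pur * 10 <= len)
    if (any(ok))
      res[[length(res) + 1]] <- data.frame(start = starts[ok],
                                           end = starts[ok] + len,
                                           raw = np[ok] - 2 * pur[ok])
  }
  if (!length(res))
    return(data.frame(start = numeric(), end = numeric(), raw = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Select the most likely PPT of an intron
#'
#' Candidates from `scorer` are ranked by penalized score = raw -
#' penalty(distance to the 3' splice site); ties go to the candidate
#' closest to the 3' splice site, then to the longest.
#'
#' @param intron_seq intron sequence in transcript orientation.
#' @param scorer function(intron_seq) returning a candidate table with
#'   columns `start`, `end`, `raw` (default [ppt_candidates()]).
#' @param ... penalty parameters passed to [ppt_penalty()].
#' @return NULL when no candidate exists, else a one-row data.frame:
#'   `start`, `end`, `raw`, `distance_to_3ss`, `penalized`.
#' @export
find_and_select_ppt <- function(intron_seq, scorer = ppt_candidates, ...) {
  cand <- scorer(intron_seq)
  if (!nrow(cand)) return(NULL)
  L <- nchar(intron_seq)
  cand$distance_to_3ss <- L - cand$end
  cand$penalized <- cand$raw - ppt_penalty(cand$distance_to_3ss, ...)
  o <- order(-cand$penalized, cand$distance_to_3ss,
             -(cand$end - cand$start))
  cand[o[1], , drop = FALSE]
}

#' Select PPTs for every intron of an annotation
#'
#' Extracts each intron sequence in transcript orientation, selects its
#' best tract and reports genomic coordinates.
#'
#' @param annot an `annotation`.
#' @param g the `genome`.
#' @param min_intron minimum intron length to consider (default 9).
#' @param ... passed to [find_and_select_ppt()].
#' @return data.frame: `intron_id`, `gene_id`, `scaffold`, `strand`,
#'   `start`, `end` (genomic), `midpoint`, `raw`, `distance_to_3ss`,
#'   `penalized`.
#' @export
select_ppts <- function(annot, g, min_intron = 9, ...) {
  introns <- transcript_introns(annot)
  out <- list()
  for (i in seq_len(nrow(introns))) {
    len <- introns$end[i] - introns$start[i]
    if (len < min_intron) next
    s <- genome_seq(g, introns$scaffold[i], introns$start[i], introns$end[i])
    if (introns$strand[i] == "-") s <- revcomp(s)
    sel <- find_and_select_ppt(s, ...)
    if (is.null(sel)) next
    if (introns$strand[i] == "+") {
      gstart <- introns$start[i] + sel$start
      gend <- introns$start[i] + sel$end
    } else {
      gstart <- introns$end[i] - sel$end
      gend <- introns$end[i] - sel$start
    }
    out[[length(out) + 1]] <- data.frame(
      intron_id = introns$intron_id[i], gene_id = introns$gene_id[i],
      scaffold = introns$scaffold[i], strand = introns$strand[i],
      start = gstart, end = gend, midpoint = (gstart + gend) / 2,
      raw = sel$raw, distance_to_3ss = sel$distance_to_3ss,
      penalized = sel$penalized, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(intron_id = character(), gene_id = character(),
                      scaffold = character(), strand = character(),
                      start = numeric(), end = numeric(), midpoint = numeric(),
                      raw = numeric(), distance_to_3ss = numeric(),
                      penalized = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Peak-to-PPT proximity with a permutation null
#'
#' For each peak summit, the signed distance to the nearest selected PPT
#' midpoint (positive when the summit lies 3' of the tract in the host
#' gene's orientation); summits are then permuted uniformly within their
#' chromosome and the two distance distributions are compared by a
#' two-tailed KS test.  The fraction of summits within `within` bp
#' (absolute distance) of a PPT is reported for both.
#'
#' @param p a `peaks` table.
#' @param ppts selected-tract table from [select_ppts()].
#' @param lengths named scaffold lengths (or a `genome`).
#' @param n_perm number of permutation rounds (default 100).
#' @param seed RNG seed.
#' @param within proximity window in bp (default 100).
#' @return list: `signed_distances`, `perm_distances` (pooled),
#'   `frac_within` (observed), `perm_frac_within`, `ks` (list D, p).
#' @export
peak_ppt_proximity <- function(p, ppts, lengths, n_perm = 100, seed = 1,
                               within = 100) {
  if (!nrow(ppts)) stop("no PPTs supplied")
  lengths <- scaffold_lengths(lengths)
  signed_to_nearest <- function(scaffold, pos) {
    on_sc <- ppts$scaffold == scaffold
    if (!any(on_sc)) return(NA_real_)
    d <- pos - ppts$midpoint[on_sc]
    i <- which.min(abs(d))
    if (ppts$strand[on_sc][i] == "-") -d[i] else d[i]
  }
  obs <- mapply(signed_to_nearest, p$scaffold, p$summit, USE.NAMES = FALSE)
  perm <- with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(k) {
      pos <- floor(stats::runif(nrow(p)) * as.numeric(lengths[p$scaffold]))
      mapply(signed_to_nearest, p$scaffold, pos, USE.NAMES = FALSE)
    }))
  })
  obs_ok <- obs[!is.na(obs)]; perm_ok <- perm[!is.na(perm)]
  ks <- ks_two_sample(obs_ok, perm_ok)
  list(signed_distances = obs, perm_distances = perm,
       frac_within = mean(abs(obs_ok) <= within),
       perm_frac_within = mean(abs(perm_ok) <= within),
       ks = ks)
}
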