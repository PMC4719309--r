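# The nested-homology ortholog search: elect the densest motif-cluster
# window inside a synteny block, confirm a stem-loop, then bootstrap the
# motif and anchor sets species by species along the phylogeny.

#' Elect the densest motif-cluster window
#'
#' Finds the window of width `cluster_span` containing the most hits
#' (requiring at least `min_hits`); ties broken by more hits, then higher
#' summed score, then leftmost start.
#'
#' @param hits data.frame of motif hits sorted by `start` (as returned by
#'   [scan_pwm()]).
#' @param cluster_span window width in bp (default 500).
#' @param min_hits minimum hits in the window (default 3).
#' @return NULL if no window qualifies, else list(`start`, `end` = elected
#'   window bounds, `hits` = the hit rows inside, `n_hits`, `score_sum`).
#' @export
elect_candidate_window <- function(hits, cluster_span = 500, min_hits = 3) {
  if (is.null(hits) || nrow(hits) < min_hits) return(NULL)
  hits <- hits[order(hits$start), , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(hits))) {
    w0 <- hits$start[i]
    inside <- hits$start >= w0 & hits$start < w0 + cluster_span
    n <- sum(inside)
    if (n < min_hits) next
    ssum <- sum(hits$score[inside])
    if (is.null(best) || n > best$n_hits ||
        (n == best$n_hits && ssum > best$score_sum + 1e-12)) {
      best <- list(start = w0, end = w0 + cluster_span,
                   hits = hits[inside, , drop = FALSE],
                   n_hits = n, score_sum = ssum)
    }
  }
  best
}

#' Default parameters for the bootstrap ortholog search
#'
#' @param max_span maximum synteny-window span in bp.
#' @param cluster_span motif cluster window width.
#' @param min_hits minimum clustered motif hits.
#' @param p_threshold motif hit p-value threshold.
#' @param stem_threshold minimum stem score to accept (0 disables the
#'   structure filter).
#' @param anchor_k,anchor_min_score translated-seed search parameters.
#' @return list of parameters for [run_bootstrap_search()].
#' @export
search_params <- function(max_span = 20000, cluster_span = 500, min_hits = 3,
                          p_threshold = 1e-4, stem_threshold = 6,
                          anchor_k = 5, anchor_min_score = 50) {
  list(max_span = max_span, cluster_span = cluster_span, min_hits = min_hits,
       p_threshold = p_threshold, stem_threshold = stem_threshold,
       anchor_k = anchor_k, anchor_min_score = anchor_min_score)
}

#' Iterative bootstrap ortholog search across species
#'
#' Species are processed in increasing patristic distance from the
#' reference (ties alphabetical).  For each species the anchor proteins are
#' located, the synteny window defined, motif hits clustered and the best
#' stem-loop scored; accepted candidates contribute their hit sequences to
#' a refined PWM (background re-estimated from all searched windows) before
#' the next species is attempted.  Anchor sets are ordered: if the primary
#' pair yields no window the search falls back to the next set.
#'
#' @param genomes named list of `genome` objects (reference included).
#' @param tree `ape::phylo` over the species names.
#' @param reference name of the initiating species.
#' @param anchor_sets list of anchor sets, tried in order; each set is a
#'   named character vector of anchor protein sequences.
#' @param initial_pwm starting `pwm`, built from the reference lncRNA's
#'   motif instances.
#' @param params list from [search_params()].
#' @return list with `results` (data.frame: species, status, reason,
#'   scaffold, start, end, n_hits, stem_score, window_start, window_end),
#'   `candidates` (per-species hit tables), and `state` (final `pwm`,
#'   accepted instances, searched-window composition).
#' @export
run_bootstrap_search <- function(genomes, tree, reference, anchor_sets,
                                 initial_pwm, params = search_params()) {
  stopifnot(reference %in% names(genomes))
  order_sp <- species_search_order(tree, reference)
  order_sp <- order_sp[order_sp %in% names(genomes)]
  cur_pwm <- initial_pwm
  window_seqs <- character()
  rows <- list(); cand <- list()
  for (sp in order_sp) {
    g <- genomes[[sp]]
    status <- "rejected"; reason <- NA_character_
    scf <- NA_character_; st <- NA_real_; en <- NA_real_
    nh <- 0L; stem <- NA_real_; w0 <- NA_real_; w1 <- NA_real_
    win <- NULL; disrupted <- FALSE
    for (aset in anchor_sets) {
      hits <- lapply(aset, function(p)
        find_anchor_locus(g, p, k = params$anchor_k,
                          min_extension_score = params$anchor_min_score))
      found <- Filter(Negate(is.null), hits)
      if (!length(found)) next
      sw <- define_synteny_window(found, params$max_span, g)
      if (sw$disrupted) { disrupted <- TRUE; next }
      if (!is.null(sw$window)) { win <- sw$window; break }
    }
    if (is.null(win)) {
      reason <- if (disrupted) "syntenic_disruption" else "no_assembly_window"
    } else {
      w0 <- win$start; w1 <- win$end; scf <- win$scaffold
      wseq <- genome_seq(g, win$scaffold, win$start, win$end)
      window_seqs <- c(window_seqs, wseq)
      mh <- scan_pwm(wseq, cur_pwm, p_threshold = params$p_threshold)
      el <- elect_candidate_window(mh, params$cluster_span, params$min_hits)
      if (is.null(el)) {
        reason <- "no_motif_cluster"
      } else {
        span0 <- min(el$hits$start); span1 <- max(el$hits$end)
        sl <- score_stem_loop(wseq, span0, span1)
        stem <- sl$score
        if (stem < params$stem_threshold) {
          reason <- "no_stem"
        } else {
          status <- "accepted"
          st <- win$start + span0; en <- win$start + span1
          nh <- el$n_hits
          inst <- el$hits$hit_seq[!grepl("N", el$hits$hit_seq)]
          if (length(inst)) {
            bg <- dna_composition(window_seqs)
            cur_pwm <- refine_pwm(cur_pwm, inst, background = bg)
          }
          cand[[sp]] <- el$hits
        }
      }
    }
    rows[[sp]] <- data.frame(
      species = sp, status = status, reason = reason, scaffold = scf,
      start = st, end = en, n_hits = nh, stem_score = stem,
      window_start = w0, window_end = w1, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results, candidates = cand,
       state = list(pwm = cur_pwm, instances = cur_pwm$instances,
                    background = cur_pwm$background))
}
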