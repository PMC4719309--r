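# Nearest-neighbor spacing of peak summits on a chromosome: observed
# distributions, a uniform permutation null, the perfect spacing distance
# D* = L/n, and summaries of departure toward even or clustered placement.

#' Strong / conserved / strong-and-conserved peak subsets
#'
#' Strong peaks satisfy strict inequalities (enrichment > and q_score >,
#' per the defining convention for this subset, unlike the inclusive primary
#' peak filter); conserved peaks are those shared with at least one other
#' species.
#'
#' @param p a `peaks` table.
#' @param conserved logical vector along `p` (or character vector of
#'   conserved peak names).
#' @param strong_enrichment_min,strong_q_min strict thresholds (defaults
#'   50 and 10000).
#' @return list of `peaks` tables: `strong`, `conserved`,
#'   `strong_conserved`.
#' @export
subset_peaks <- function(p, conserved, strong_enrichment_min = 50,
                         strong_q_min = 10000) {
  if (is.character(conserved)) conserved <- p$name %in% conserved
  stopifnot(length(conserved) == nrow(p))
  strong <- p$enrichment > strong_enrichment_min & p$q_score > strong_q_min
  res <- list(strong = p[strong, , drop = FALSE],
              conserved = p[conserved, , drop = FALSE],
              strong_conserved = p[strong & conserved, , drop = FALSE])
  lapply(res, function(d) { rownames(d) <- NULL; d })
}

#' Nearest-neighbor distances of summits on one chromosome
#'
#' @param summits numeric vector of summit positions (>= 2).
#' @return per-summit distance to its nearest other summit.
#' @export
nearest_neighbor_distances <- function(summits) {
  n <- length(summits)
  if (n < 2) stop("need at least 2 peaks for nearest-neighbor distances")
  o <- order(summits)
  s <- summits[o]
  gap <- diff(s)
  d <- pmin(c(Inf, gap), c(gap, Inf))
  d[order(o)]
}

#' Null nearest-neighbor distributions under uniform placement
#'
#' @param chrom_length chromosome length L.
#' @param n_peaks number of summits per permutation (>= 2).
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return numeric vector of pooled null nearest-neighbor distances.
#' @export
spacing_null <- function(chrom_length, n_peaks, n_perm = 1000, seed = 1) {
  stopifnot(n_peaks >= 2)
  with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(k)
      nearest_neighbor_distances(stats::runif(n_peaks, 0, chrom_length))))
  })
}

#' Departure of observed spacing from the random null
#'
#' Compares observed and null nearest-neighbor densities on a shared bin
#' grid.  The evenness summary is the observed-minus-null probability mass
#' within +/-25% of the perfect spacing distance D* = L/n; the clustering
#' summary is the same difference below 0.1 * D*.
#'
#' @param observed,null nearest-neighbor distance vectors.
#' @param L chromosome length.
#' @param n number of peaks defining D*.
#' @param bin_width histogram bin width (default D*/10).
#' @return list: `d_star`, `curve` (data.frame mid, observed_density,
#'   null_density, diff), `evenness` (mass difference near D*),
#'   `clustering` (mass difference near 0).
#' @export
spacing_departure <- function(observed, null, L, n, bin_width = NULL) {
  stopifnot(length(observed) > 0, length(null) > 0)
  d_star <- L / n
  bw <- bin_width %||% (d_star / 10)
  top <- max(observed, null) + bw
  breaks <- seq(0, top + bw, by = bw)
  ho <- graphics::hist(observed, breaks = breaks, plot = FALSE)
  hn <- graphics::hist(null, breaks = breaks, plot = FALSE)
  po <- ho$counts / sum(ho$counts)
  pn <- hn$counts / sum(hn$counts)
  mass <- function(v, lo, hi) mean(v >= lo & v <= hi)
  list(d_star = d_star,
       curve = data.frame(mid = ho$mids,
                          observed_density = po / bw,
                          null_density = pn / bw,
                          diff = (po - pn) / bw),
       evenness = mass(observed, 0.75 * d_star, 1.25 * d_star) -
         mass(null, 0.75 * d_star, 1.25 * d_star),
       clustering = mass(observed, 0, 0.1 * d_star) -
         mass(null, 0, 0.1 * d_star))
}
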