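# Gene-level and element-level conservation of peaks across species:
# peak-gene association within a distance rule, orthology-aware
# conservation calls, liftover-based turnover distances and their
# permutation nulls.

#' Associate peaks with nearby genes
#'
#' A gene is associated with a peak when the peak summit lies within
#' `max_distance` of the gene's transcript-union span; genes lacking
#' annotated UTRs are first extended upstream/downstream (in gene
#' orientation) by typical UTR lengths.
#'
#' @param p a `peaks` table.
#' @param annot an `annotation`.
#' @param max_distance association distance in bp (default 1000).
#' @param utr5_ext,utr3_ext extensions in bp applied only to genes lacking
#'   annotated 5'/3' UTRs (defaults 200, 500).
#' @return data.frame: `peak`, `gene_id`, `distance`.
#' @export
associate_genes <- function(p, annot, max_distance = 1000,
                            utr5_ext = 200, utr3_ext = 500) {
  gs <- gene_spans(annot)
  up <- ifelse(gs$has_utr5, 0, utr5_ext)
  dn <- ifelse(gs$has_utr3, 0, utr3_ext)
  ext_start <- ifelse(gs$strand == "+", gs$start - up, gs$start - dn)
  ext_end <- ifelse(gs$strand == "+", gs$end + dn, gs$end + up)
  ext_start <- pmax(0, ext_start)
  out <- list()
  for (i in seq_len(nrow(p))) {
    on_sc <- gs$scaffold == p$scaffold[i]
    if (!any(on_sc)) next
    d <- point_interval_distance(p$summit[i], ext_start[on_sc], ext_end[on_sc])
    hit <- which(d <= max_distance)
    if (length(hit))
      out[[length(out) + 1]] <- data.frame(
        peak = p$name[i], gene_id = gs$gene_id[on_sc][hit],
        distance = d[hit], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(peak = character(), gene_id = character(),
                      distance = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify gene-level peak conservation across species
#'
#' A peak in species A is gene-conserved with respect to species B when any
#' of its associated genes has an ortholog that is itself associated with a
#' peak in B; otherwise it is species-specific.  Genes absent from the
#' orthology table are treated as having no ortholog.
#'
#' @param assoc named list (by species) of association tables from
#'   [associate_genes()].
#' @param orthology data.frame mapping genes to ortholog groups: columns
#'   `species`, `gene_id`, `group`.
#' @return list: `calls` (species, peak, other_species, status),
#'   `shared_groups` (ortholog group, membership string, n_species),
#'   `n_all_species` (groups bound in every species), `has_in_shared`
#'   (per-species count of peaks associated with an all-species group).
#' @export
classify_gene_conservation <- function(assoc, orthology) {
  stop_fields(orthology, c("species", "gene_id", "group"), "orthology table")
  species <- names(assoc)
  grp <- function(sp, genes) {
    o <- orthology[orthology$species == sp, ]
    unique(o$group[o$gene_id %in% genes])
  }
  bound_groups <- lapply(species, function(sp)
    grp(sp, unique(assoc[[sp]]$gene_id)))
  names(bound_groups) <- species
  calls <- list()
  for (sp in species) {
    a <- assoc[[sp]]
    pk <- unique(a$peak)
    o_sp <- orthology[orthology$species == sp, ]
    for (other in setdiff(species, sp)) {
      status <- vapply(pk, function(pid) {
        genes <- a$gene_id[a$peak == pid]
        gset <- unique(o_sp$group[o_sp$gene_id %in% genes])
        if (length(intersect(gset, bound_groups[[other]])))
          "gene_conserved" else "species_specific"
      }, "")
      calls[[paste(sp, other)]] <- data.frame(
        species = sp, peak = pk, other_species = other, status = status,
        stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  all_groups <- sort(unique(unlist(bound_groups)))
  member <- vapply(all_groups, function(g)
    paste(species[vapply(species, function(sp) g %in% bound_groups[[sp]],
                         TRUE)], collapse = "+"), "")
  n_sp <- vapply(all_groups, function(g)
    sum(vapply(species, function(sp) g %in% bound_groups[[sp]], TRUE)), 0L)
  shared <- data.frame(group = all_groups, membership = member,
                       n_species = n_sp, stringsAsFactors = FALSE)
  univ <- all_groups[n_sp == length(species)]
  has_in_shared <- vapply(species, function(sp) {
    a <- assoc[[sp]]
    o_sp <- orthology[orthology$species == sp, ]
    genes_univ <- o_sp$gene_id[o_sp$group %in% univ]
    length(unique(a$peak[a$gene_id %in% genes_univ]))
  }, 0L)
  list(calls = calls, shared_groups = shared,
       n_all_species = length(univ), has_in_shared = has_in_shared)
}

#' Element-level turnover distances between two species' peaks
#'
#' Each peak summit in A is lifted through the coordinate map; the reported
#' distance is 0 when the lifted position falls inside a B peak, otherwise
#' the bp distance to the nearest B-peak edge on that scaffold.  Unmappable
#' summits (and summits landing on scaffolds without B peaks) are reported
#' separately.
#'
#' @param peaks_a,peaks_b `peaks` tables for species A and B.
#' @param map `coordinate_map` from A's assembly to B's.
#' @return data.frame: `peak`, `mapped`, `tgt_scaffold`, `tgt_pos`,
#'   `distance` (NA when unmappable or no B peak on the scaffold).
#' @export
element_turnover <- function(peaks_a, map, peaks_b) {
  lifted <- map_point(peaks_a$scaffold, peaks_a$summit, map)
  dist <- rep(NA_real_, nrow(peaks_a))
  for (i in seq_len(nrow(peaks_a))) {
    if (is.na(lifted$pos[i])) next
    on_sc <- peaks_b$scaffold == lifted$scaffold[i]
    if (!any(on_sc)) next
    dist[i] <- min(point_interval_distance(lifted$pos[i],
                                           peaks_b$start[on_sc],
                                           peaks_b$end[on_sc]))
  }
  data.frame(peak = peaks_a$name, mapped = !is.na(lifted$pos),
             tgt_scaffold = lifted$scaffold, tgt_pos = lifted$pos,
             distance = dist, stringsAsFactors = FALSE)
}

# Place peaks uniformly at random within their scaffold (lengths preserved,
# pairwise non-overlapping), shuffleBed-style; returns a relocated copy.
permute_peaks <- function(p, lengths, genome_wide = FALSE) {
  lengths <- scaffold_lengths(lengths)
  out <- p
  scs <- if (genome_wide) names(lengths) else unique(p$scaffold)
  if (genome_wide) {
    w <- as.numeric(lengths[scs]); w <- w / sum(w)
    out$scaffold <- sample(scs, nrow(p), replace = TRUE, prob = w)
  }
  for (sc in unique(out$scaffold)) {
    idx <- which(out$scaffold == sc)
    L <- lengths[[sc]]
    lens <- out$end[idx] - out$start[idx]
    if (any(lens > L)) stop("peak length exceeds scaffold ", sc)
    free <- L - sum(lens)
    if (free < 0) stop("could not place non-overlapping peaks on ", sc)
    n <- length(idx)
    # gap construction: drop n uniform points into the free space, then
    # insert the peaks (in random order) at the sorted points -- uniform
    # over non-overlapping placements, no rejection needed
    u <- sort(floor(stats::runif(n, 0, free + 1)))
    ord <- sample.int(n)
    starts_sorted <- u + c(0, cumsum(lens[ord]))[seq_len(n)]
    starts <- numeric(n)
    starts[ord] <- starts_sorted
    off <- out$summit[idx] - out$start[idx]
    out$start[idx] <- starts
    out$end[idx] <- starts + lens
    out$summit[idx] <- starts + off
  }
  out
}

#' Permutation null for element-level turnover
#'
#' Repeatedly relocates B's peaks uniformly at random (lengths preserved,
#' non-overlapping) within their own chromosome or genome-wide, recomputes
#' the turnover distances, and summarizes observed and null cumulative
#' fraction-within-distance curves and their ratio.
#'
#' @param peaks_a,peaks_b `peaks` tables; `map` as in [element_turnover()].
#' @param lengths named scaffold lengths of species B (or its `genome`).
#' @param mode "within_chromosome" or "genome_wide".
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param d_grid distances (bp) at which the cumulative curves are read.
#' @return list: `observed` (turnover table), `curve` (data.frame d,
#'   observed_frac, null_frac, ratio), `null_fracs` (n_perm x |d_grid|).
#' @export
turnover_null <- function(peaks_a, map, peaks_b, lengths,
                          mode = c("within_chromosome", "genome_wide"),
                          n_perm = 100, seed = 1,
                          d_grid = c(0, 1000, 5000, 10000, 30000)) {
  mode <- match.arg(mode)
  stopifnot(n_perm >= 1)
  obs <- element_turnover(peaks_a, map, peaks_b)
  odist <- obs$distance[!is.na(obs$distance)]
  frac_at <- function(d, v) if (length(v)) mean(v <= d) else NA_real_
  obs_frac <- vapply(d_grid, frac_at, 0, v = odist)
  nulls <- matrix(NA_real_, n_perm, length(d_grid))
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      pb <- permute_peaks(peaks_b, lengths,
                          genome_wide = mode == "genome_wide")
      et <- element_turnover(peaks_a, map, pb)
      nd <- et$distance[!is.na(et$distance)]
      nulls[k, ] <- vapply(d_grid, frac_at, 0, v = nd)
    }
  })
  null_frac <- colMeans(nulls, na.rm = TRUE)
  list(observed = obs,
       curve = data.frame(d = d_grid, observed_frac = obs_frac,
                          null_frac = null_frac,
                          ratio = obs_frac / null_frac),
       null_fracs = nulls)
}
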