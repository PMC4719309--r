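# Synthetic multi-species datasets with planted ground truth: genomes with
# Muller-element-labeled scaffolds, syntenic anchor genes, a planted lncRNA
# locus whose motif instances sit inside stem-loops, gene models whose
# introns end in polypyrimidine tracts, and ChIRP-like signal tracks with
# planted X-enriched peaks.  Everything derives from one global seed;
# submodules draw child seeds by labeled hashing, so outputs are
# byte-identical across runs.

GENCODE <- local({
  env <- new.env()
  function() {
    if (is.null(env$tab)) {
      env$tab <- Biostrings::GENETIC_CODE
      env$syn <- split(names(env$tab), env$tab)
    }
    env
  }
})

#' Default simulation configuration
#'
#' The defaults define the study conditions the rest of the package is
#' exercised under: eight species on a caterpillar phylogeny, an X-like
#' scaffold carrying two syntenic anchor genes around a planted lncRNA
#' locus (five motif instances in hairpins, clustered within ~500 bp),
#' intron-bearing genes with 3'-terminal pyrimidine tracts, and a peak plan
#' with 20% of X peaks placed within 100 bp of a tract.
#'
#' @param ... named overrides of the top-level fields.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    seed = 1,
    n_species = 8,
    reference = "sp01",
    scaffolds = data.frame(
      name = c("chrX", "chr2L", "chr3R", "scf_un"),
      length = c(150000, 80000, 50000, 6000),
      me = c("A", "B", "E", NA), stringsAsFactors = FALSE),
    anchor = list(protein_len = 60, up_start = 40000, dn_start = 43000,
                  sec_up_start = 38500, sec_dn_start = 44500),
    lncrna = list(motif_consensus = "GCTAATCG", n_instances = 5,
                  arm_extra = 2, loop_len = 6, spacer_min = 40,
                  spacer_max = 70, locus_start = 41200),
    genes = list(n_x = 30, n_2l = 10, x_first = 50000, x_pitch = 3200,
                 l2_first = 2000, l2_pitch = 6000,
                 utr5 = 60, cds1 = 240, intron = 500, cds2 = 300,
                 utr3 = 150, ppt_len = c(12, 18), ppt_pyr = 0.95,
                 ppt_end_gap = c(8, 30)),
    rates = list(background = 0.25, structure = 0.03, anchor_syn = 0.30),
    chain = list(weight = 0.92, total = 1000),
    peak_plan = list(n_x = 50, n_auto = 3, fold = 20, peak_width = 300,
                     ppt_frac = 0.20,
                     orientation_bias = c(intron = 0.2, three_prime_UTR = 0.8,
                                          CDS = 0.5, five_prime_UTR = 0.5,
                                          intergenic = 0.5),
                     spacing_regime = "random", background_mean = 10,
                     bin = 10, window_bp = 1000, rox1_ratio = 0.125,
                     frac_strong = 0.5, conserved_frac = 0.4,
                     class_quota = NULL,
                     mre_consensus = "GAGAGAGAGAGA"))
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && !is.data.frame(cfg[[nm]]) &&
                     is.list(over[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

# Schema check: errors name the offending field path.
validate_simulation_config <- function(cfg) {
  frac_fields <- list(
    c("peak_plan", "ppt_frac"), c("peak_plan", "rox1_ratio"),
    c("peak_plan", "frac_strong"), c("peak_plan", "conserved_frac"),
    c("rates", "background"), c("rates", "structure"),
    c("rates", "anchor_syn"), c("chain", "weight"),
    c("genes", "ppt_pyr"))
  for (f in frac_fields) {
    v <- cfg[[f[1]]][[f[2]]]
    if (is.null(v) || any(v < 0) || any(v > 1))
      stop(sprintf("config field %s must be a fraction in [0, 1]",
                   paste(f, collapse = ".")), call. = FALSE)
  }
  ob <- cfg$peak_plan$orientation_bias
  if (any(ob < 0 | ob > 1))
    stop("config field peak_plan.orientation_bias must be fractions in [0, 1]",
         call. = FALSE)
  if (cfg$n_species < 2) stop("config field n_species must be >= 2",
                              call. = FALSE)
  invisible(TRUE)
}

#' Uniformly scramble a sequence
#'
#' Each copy is an independent uniform permutation of the input letters,
#' so mononucleotide composition is preserved exactly.
#'
#' @param sequence character scalar.
#' @param n_copies number of scrambles.
#' @param seed RNG seed.
#' @return character vector of scrambled copies.
#' @export
scramble_sequence <- function(sequence, n_copies, seed = 1) {
  stopifnot(nzchar(sequence))
  v <- strsplit(sequence, "")[[1]]
  with_seed(seed, vapply(seq_len(n_copies), function(i)
    paste(sample(v), collapse = ""), ""))
}

#' Sample summit positions under a spacing regime
#'
#' "even": a jittered regular grid; "random": uniform; "clustered": normal
#' scatter around a few uniformly placed cluster centers.
#'
#' @param L chromosome length.
#' @param n number of summits.
#' @param regime one of "even", "random", "clustered".
#' @param seed optional RNG seed (NULL = use current stream).
#' @return sorted numeric summit positions in [0, L).
#' @export
sample_summit_positions <- function(L, n, regime = c("random", "even",
                                                     "clustered"),
                                    seed = NULL) {
  regime <- match.arg(regime)
  draw <- function() {
    pos <- switch(regime,
      random = stats::runif(n, 0, L),
      even = (seq_len(n) - 0.5) * L / n +
        stats::rnorm(n, 0, 0.08 * L / n),
      clustered = {
        k <- max(1, round(n / 8))
        centers <- stats::runif(k, 0, L)
        centers[sample.int(k, n, replace = TRUE)] +
          stats::rnorm(n, 0, 0.005 * L)
      })
    sort(pmin(pmax(pos, 0), L - 1))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Pick summits inside features of requested classes (used to plant
# orientation biases with controlled per-class sample sizes).
place_class_quota <- function(annot, quota, half, L) {
  introns <- transcript_introns(annot)
  pools <- list(
    intron = introns[introns$scaffold == "chrX", , drop = FALSE],
    three_prime_UTR = annot[annot$type == "three_prime_UTR" &
                              annot$scaffold == "chrX", , drop = FALSE],
    five_prime_UTR = annot[annot$type == "five_prime_UTR" &
                             annot$scaffold == "chrX", , drop = FALSE],
    CDS = annot[annot$type == "CDS" & annot$scaffold == "chrX", , drop = FALSE])
  out <- list()
  for (cl in names(quota)) {
    pool <- pools[[cl]]
    if (is.null(pool) || nrow(pool) < quota[[cl]])
      stop("class quota for ", cl, " exceeds available features")
    pick <- sample.int(nrow(pool), quota[[cl]])
    s <- floor((pool$start[pick] + pool$end[pick]) / 2)
    out[[cl]] <- data.frame(summit = pmin(pmax(s, half), L - half - 1))
  }
  do.call(rbind, out)
}

#' Generate coordinated ChIRP experiments for a species set
#'
#' Draws one shared set of "conserved" X summits (fraction
#' `plan$conserved_frac` of `plan$n_x`, a fraction `ppt_frac` of them near
#' tracts) that every species receives at the same coordinates -- the
#' coordinate maps of the species set are exact, so these are planted
#' conserved peaks -- plus species-specific summits for the remainder.
#'
#' @param ss a species set from [generate_species_set()].
#' @param plan peak plan (default: the set's own `peak_plan`).
#' @param seed RNG seed (default: the set's seed).
#' @return named list of per-species experiments (see
#'   [generate_chirp_experiment()]); each carries the shared-summit truth
#'   in `$shared_summits`.
#' @export
generate_chirp_set <- function(ss, plan = NULL, seed = NULL) {
  plan <- plan %||% ss$config$peak_plan
  seed <- seed %||% ss$config$seed
  ref <- ss$config$reference
  g <- ss$species[[ref]]$genome
  annot <- ss$species[[ref]]$annotation
  ppts <- select_ppts(annot, g)
  ppts_x <- ppts[ppts$scaffold == "chrX", , drop = FALSE]
  L <- nchar(g$scaffolds[["chrX"]])
  half <- plan$peak_width / 2
  n_shared <- round(plan$conserved_frac * plan$n_x)
  n_shared_ppt <- round(plan$ppt_frac * n_shared)
  shared <- with_seed(child_seed(seed, "shared_summits"), {
    rows <- if (n_shared_ppt > 0)
      sample.int(nrow(ppts_x), n_shared_ppt) else integer()
    off_pool <- c(-60:-15, 15:60)
    s_ppt <- round(ppts_x$midpoint[rows]) +
      sample(off_pool, n_shared_ppt, replace = TRUE)
    n_clear <- n_shared - n_shared_ppt
    s_clear <- round(stats::runif(n_clear, half, L - half - 1))
    for (i in seq_along(s_clear)) {
      for (try in 1:200) {
        clash <- any(abs(s_clear[i] - ppts_x$midpoint) <= 120) ||
          any(abs(s_clear[i] - s_ppt) < plan$peak_width) ||
          (i > 1 && any(abs(s_clear[i] - s_clear[seq_len(i - 1)]) <
                        plan$peak_width))
        if (!clash) break
        s_clear[i] <- round(stats::runif(1, half, L - half - 1))
      }
    }
    list(fixed = data.frame(summit = c(s_ppt, s_clear),
                            ppt_proximal = c(rep(TRUE, n_shared_ppt),
                                             rep(FALSE, n_clear))),
         rows = rows)
  })
  out <- list()
  for (sp in names(ss$species)) {
    plan_sp <- plan
    plan_sp$fixed <- shared$fixed
    plan_sp$fixed_ppt_rows <- shared$rows
    ex <- generate_chirp_experiment(ss$species[[sp]]$genome,
                                    ss$species[[sp]]$annotation, plan_sp,
                                    seed = child_seed(seed,
                                                      paste0("chirp_", sp)))
    ex$shared_summits <- shared$fixed$summit
    out[[sp]] <- ex
  }
  out
}

# ---- internal builders ------------------------------------------------

encode_protein <- function(protein) {
  gc <- GENCODE()
  paste(vapply(strsplit(protein, "")[[1]], function(aa) {
    cods <- gc$syn[[aa]]
    cods[sample.int(length(cods), 1)]
  }, ""), collapse = "")
}

random_protein <- function(n) {
  aas <- setdiff(unique(Biostrings::GENETIC_CODE), "*")
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

# Replace codons by synonymous codons at the given per-codon rate.
mutate_cds_synonymous <- function(cds, rate) {
  gc <- GENCODE()
  cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  flip <- which(stats::runif(length(cods)) < rate)
  for (i in flip) {
    aa <- gc$tab[[cods[i]]]
    alt <- setdiff(gc$syn[[aa]], cods[i])
    if (length(alt)) cods[i] <- alt[sample.int(length(alt), 1)]
  }
  paste(cods, collapse = "")
}

# Substitute bases at per-position rates (vector or scalar).
mutate_positions <- function(seq_chr, rate) {
  v <- strsplit(seq_chr, "")[[1]]
  L <- length(v)
  rate <- rep_len(rate, L)
  idx <- which(stats::runif(L) < rate & v %in% DNA_LETTERS)
  if (length(idx)) {
    cur <- match(v[idx], DNA_LETTERS)
    v[idx] <- DNA_LETTERS[(cur - 1 + sample.int(3, length(idx),
                                                replace = TRUE)) %% 4 + 1]
  }
  paste(v, collapse = "")
}

# Build one gene in transcript orientation and return its sequence plus
# feature offsets; gp = cfg$genes.
build_gene_template <- function(gp) {
  u5 <- gp$utr5; c1 <- gp$cds1; ilen <- gp$intron; c2 <- gp$cds2
  u3 <- gp$utr3
  pl <- sample(gp$ppt_len[1]:gp$ppt_len[2], 1)
  gap <- sample(gp$ppt_end_gap[1]:gp$ppt_end_gap[2], 1)
  intron_seq <- random_dna(ilen)
  ppt <- paste(sample(c("C", "T"), pl, replace = TRUE,
                      prob = c(0.5, 0.5)), collapse = "")
  # enforce pyrimidine fraction by drawing purine positions explicitly
  n_pur <- stats::rbinom(1, pl, 1 - gp$ppt_pyr)
  if (n_pur > 0) {
    pv <- strsplit(ppt, "")[[1]]
    pv[sample.int(pl, n_pur)] <- sample(c("A", "G"), n_pur, replace = TRUE)
    ppt <- paste(pv, collapse = "")
  }
  p0 <- ilen - gap - pl
  substr(intron_seq, p0 + 1, p0 + pl) <- ppt
  seqs <- c(random_dna(u5), random_dna(c1), intron_seq, random_dna(c2),
            random_dna(u3))
  tx_len <- u5 + c1 + ilen + c2 + u3
  list(seq = paste(seqs, collapse = ""), tx_len = tx_len,
       offsets = list(utr5 = c(0, u5), exon1 = c(0, u5 + c1),
                      cds1 = c(u5, u5 + c1),
                      intron = c(u5 + c1, u5 + c1 + ilen),
                      exon2 = c(u5 + c1 + ilen, tx_len),
                      cds2 = c(u5 + c1 + ilen, u5 + c1 + ilen + c2),
                      utr3 = c(tx_len - gp$utr3, tx_len)),
       ppt = c(u5 + c1 + p0, u5 + c1 + p0 + pl))
}

tx_to_genomic <- function(off, gstart, tx_len, strand) {
  if (strand == "+") c(gstart + off[1], gstart + off[2])
  else c(gstart + tx_len - off[2], gstart + tx_len - off[1])
}

# Build the lncRNA locus sequence and relative motif coordinates.
build_lnc_locus <- function(lp) {
  motif <- lp$motif_consensus
  w <- nchar(motif)
  arm_len <- w + lp$arm_extra
  parts <- character(); motifs <- list(); units <- list()
  pos <- 0
  lead <- random_dna(30); parts <- c(parts, lead); pos <- pos + 30
  for (i in seq_len(lp$n_instances)) {
    arm5 <- paste0(motif, random_dna(lp$arm_extra))
    loop <- random_dna(lp$loop_len)
    unit <- paste0(arm5, loop, revcomp(arm5))
    motifs[[length(motifs) + 1]] <- data.frame(
      rel_start = pos, rel_end = pos + w, strand = "+")
    motifs[[length(motifs) + 1]] <- data.frame(
      rel_start = pos + arm_len + lp$loop_len + lp$arm_extra,
      rel_end = pos + arm_len + lp$loop_len + lp$arm_extra + w,
      strand = "-")
    units[[length(units) + 1]] <- c(pos, pos + 2 * arm_len + lp$loop_len)
    parts <- c(parts, unit)
    pos <- pos + 2 * arm_len + lp$loop_len
    if (i < lp$n_instances) {
      sp <- sample(lp$spacer_min:lp$spacer_max, 1)
      parts <- c(parts, random_dna(sp)); pos <- pos + sp
    }
  }
  tail <- random_dna(30); parts <- c(parts, tail); pos <- pos + 30
  list(seq = paste(parts, collapse = ""), len = pos,
       motifs = do.call(rbind, motifs), units = do.call(rbind, units))
}

#' Generate a multi-species synthetic dataset
#'
#' Builds a reference genome with planted anchor genes, intron-bearing
#' genes (each intron ending in a pyrimidine tract) and a lncRNA locus of
#' clustered motif-bearing hairpins; derives every other species by
#' substituting bases at rates proportional to patristic distance
#' (structure units and tracts at a low rate, anchor coding sequence by
#' synonymous codon swaps), with one inverted scaffold in the most distant
#' species to exercise strand-aware liftover.  Coordinate maps are exact by
#' construction.
#'
#' @param cfg a `simulation_config`.
#' @return list: `config`, `tree` (`ape::phylo`), `species` (named list of
#'   `genome` + `annotation`), `maps` (species -> reference
#'   `coordinate_map`s), `chains` (chain-score matrices), `truth` (planted
#'   loci, motif instances, tract intervals, anchors, proteins).
#' @export
generate_species_set <- function(cfg = simulation_config()) {
  validate_simulation_config(cfg)
  sp_names <- sprintf("sp%02d", seq_len(cfg$n_species))
  ref <- cfg$reference
  stopifnot(ref %in% sp_names)
  # caterpillar tree, reference at the tip of the deepest split
  nwk <- sp_names[1]
  nwk <- sprintf("(%s:1,%s:1)", sp_names[1], sp_names[2])
  for (k in 3:cfg$n_species)
    nwk <- sprintf("(%s:1,%s:%d)", nwk, sp_names[k], k - 1)
  tree <- ape::read.tree(text = paste0(nwk, ";"))
  pat <- stats::cophenetic(tree)[ref, ]
  pat <- pat / max(pat)  # rates below are per unit of this scaled distance

  scf <- cfg$scaffolds
  gp <- cfg$genes; lp <- cfg$lncrna; ap <- cfg$anchor
  # the plan must fit inside its scaffolds
  gene_len <- gp$utr5 + gp$cds1 + gp$intron + gp$cds2 + gp$utr3
  lx <- scf$length[scf$name == "chrX"]
  l2 <- scf$length[scf$name == "chr2L"]
  if (gp$x_first + (gp$n_x - 1) * gp$x_pitch + gene_len > lx)
    stop("gene plan exceeds scaffold capacity on chrX", call. = FALSE)
  if (gp$l2_first + (gp$n_2l - 1) * gp$l2_pitch + gene_len > l2)
    stop("gene plan exceeds scaffold capacity on chr2L", call. = FALSE)
  if (ap$sec_dn_start + 3 * ap$protein_len > min(lx, gp$x_first))
    stop("anchor plan exceeds scaffold capacity on chrX", call. = FALSE)

  build <- with_seed(child_seed(cfg$seed, "reference"), {
    scaffolds <- stats::setNames(
      vapply(scf$length, random_dna, ""), scf$name)
    feats <- list(); ppts <- list()
    protect <- list()  # list of c(scaffold-idx free) intervals w/ class
    add_feat <- function(type, sc, iv, strand, gid, tid)
      data.frame(scaffold = sc, type = type, start = iv[1], end = iv[2],
                 strand = strand, gene_id = gid, transcript_id = tid,
                 stringsAsFactors = FALSE)
    plant_gene <- function(sc, gstart, strand, gid) {
      tpl <- build_gene_template(gp)
      gseq <- if (strand == "+") tpl$seq else revcomp(tpl$seq)
      substr(scaffolds[[sc]], gstart + 1, gstart + tpl$tx_len) <<- gseq
      g <- function(off) tx_to_genomic(off, gstart, tpl$tx_len, strand)
      tid <- paste0(gid, ".t1")
      feats[[length(feats) + 1]] <<- rbind(
        add_feat("exon", sc, g(tpl$offsets$exon1), strand, gid, tid),
        add_feat("exon", sc, g(tpl$offsets$exon2), strand, gid, tid),
        add_feat("CDS", sc, g(tpl$offsets$cds1), strand, gid, tid),
        add_feat("CDS", sc, g(tpl$offsets$cds2), strand, gid, tid),
        add_feat("five_prime_UTR", sc, g(tpl$offsets$utr5), strand, gid, tid),
        add_feat("three_prime_UTR", sc, g(tpl$offsets$utr3), strand, gid, tid))
      piv <- g(tpl$ppt)
      ppts[[length(ppts) + 1]] <<- data.frame(
        gene_id = gid, scaffold = sc, start = piv[1], end = piv[2],
        strand = strand, stringsAsFactors = FALSE)
      protect[[length(protect) + 1]] <<- data.frame(
        scaffold = sc, start = piv[1], end = piv[2], kind = "structure")
      protect[[length(protect) + 1]] <<- data.frame(
        scaffold = sc, start = gstart, end = gstart + tpl$tx_len,
        kind = "genic")
    }
    for (i in seq_len(gp$n_x))
      plant_gene("chrX", gp$x_first + (i - 1) * gp$x_pitch,
                 if (i %% 2) "+" else "-", sprintf("gx%02d", i))
    for (i in seq_len(gp$n_2l))
      plant_gene("chr2L", gp$l2_first + (i - 1) * gp$l2_pitch,
                 if (i %% 2) "+" else "-", sprintf("g2l%02d", i))
    # anchors: single-exon CDS genes (no UTRs annotated)
    prot_len <- ap$protein_len
    proteins <- list(anchor_up = random_protein(prot_len),
                     anchor_dn = random_protein(prot_len),
                     anchor_sec_up = random_protein(prot_len),
                     anchor_sec_dn = random_protein(prot_len))
    anchor_pos <- c(anchor_up = ap$up_start, anchor_dn = ap$dn_start,
                    anchor_sec_up = ap$sec_up_start,
                    anchor_sec_dn = ap$sec_dn_start)
    anchors <- list()
    for (nm in names(proteins)) {
      cds <- encode_protein(proteins[[nm]])
      st <- anchor_pos[[nm]]
      substr(scaffolds[["chrX"]], st + 1, st + nchar(cds)) <- cds
      iv <- c(st, st + nchar(cds))
      feats[[length(feats) + 1]] <- rbind(
        add_feat("exon", "chrX", iv, "+", nm, paste0(nm, ".t1")),
        add_feat("CDS", "chrX", iv, "+", nm, paste0(nm, ".t1")))
      anchors[[nm]] <- data.frame(gene_id = nm, scaffold = "chrX",
                                  start = iv[1], end = iv[2],
                                  stringsAsFactors = FALSE)
      protect[[length(protect) + 1]] <- data.frame(
        scaffold = "chrX", start = iv[1], end = iv[2], kind = "cds_anchor")
    }
    # lncRNA locus between the anchors
    locus <- build_lnc_locus(lp)
    l0 <- lp$locus_start
    stopifnot(l0 + locus$len < ap$dn_start)
    substr(scaffolds[["chrX"]], l0 + 1, l0 + locus$len) <- locus$seq
    for (i in seq_len(nrow(locus$units)))
      protect[[length(protect) + 1]] <- data.frame(
        scaffold = "chrX", start = l0 + locus$units[i, 1],
        end = l0 + locus$units[i, 2], kind = "structure")
    list(scaffolds = scaffolds, feats = do.call(rbind, feats),
         ppts = do.call(rbind, ppts), protect = do.call(rbind, protect),
         proteins = proteins, anchors = do.call(rbind, anchors),
         locus = locus, locus_start = l0)
  })

  annot <- annotation(build$feats)
  me_labels <- stats::setNames(scf$me, scf$name)
  inverted_sp <- sp_names[length(sp_names)]  # chr3R inverted here

  species <- list(); maps <- list(); chains <- list()
  truth_loci <- list(); truth_motifs <- list()
  for (sp in sp_names) {
    d <- pat[[sp]]
    scaffolds <- build$scaffolds
    if (d > 0) {
      with_seed(child_seed(cfg$seed, paste0("mutate_", sp)), {
        for (sc in names(scaffolds)) {
          L <- nchar(scaffolds[[sc]])
          rate <- rep(cfg$rates$background * d, L)
          pr <- build$protect[build$protect$scaffold == sc, , drop = FALSE]
          for (i in seq_len(nrow(pr))) {
            idx <- (pr$start[i] + 1):pr$end[i]
            rate[idx] <- switch(pr$kind[i],
              structure = cfg$rates$structure * d,
              genic = cfg$rates$background * d * 0.5,
              cds_anchor = 0)
          }
          # tract + hairpin protection wins over the genic rate
          pr2 <- pr[pr$kind == "structure", , drop = FALSE]
          for (i in seq_len(nrow(pr2)))
            rate[(pr2$start[i] + 1):pr2$end[i]] <- cfg$rates$structure * d
          scaffolds[[sc]] <- mutate_positions(scaffolds[[sc]], rate)
        }
        # synonymous drift of anchor coding sequences
        for (i in seq_len(nrow(build$anchors))) {
          a <- build$anchors[i, ]
          cds <- substr(scaffolds[[a$scaffold]], a$start + 1, a$end)
          cds <- mutate_cds_synonymous(cds, cfg$rates$anchor_syn * d)
          substr(scaffolds[[a$scaffold]], a$start + 1, a$end) <- cds
        }
      })
    }
    if (sp == inverted_sp)
      scaffolds[["chr3R"]] <- revcomp(scaffolds[["chr3R"]])
    species[[sp]] <- list(genome = genome(scaffolds, me = me_labels),
                          annotation = annot)
    blocks <- data.frame(
      src_scaffold = scf$name, src_start = 0, src_end = scf$length,
      tgt_scaffold = scf$name, tgt_start = 0, tgt_end = scf$length,
      orientation = ifelse(scf$name == "chr3R" & sp == inverted_sp,
                           "-", "+"), stringsAsFactors = FALSE)
    maps[[sp]] <- coordinate_map(blocks)
    chains[[sp]] <- with_seed(child_seed(cfg$seed, paste0("chain_", sp)), {
      mes <- c("A", "B", "C", "D", "E", "F")
      m <- matrix(0, nrow(scf), 6, dimnames = list(scf$name, mes))
      for (i in seq_len(nrow(scf))) {
        if (!is.na(scf$me[i])) {
          w <- cfg$chain$weight + stats::runif(1, 0, 0.04)
          m[i, scf$me[i]] <- w
          m[i, mes != scf$me[i]] <- (1 - w) / 5
        } else {
          m[i, c("A", "B", "E")] <- c(0.4, 0.3, 0.3)
        }
        m[i, ] <- m[i, ] * cfg$chain$total
      }
      m
    })
    truth_loci[[sp]] <- data.frame(
      species = sp, scaffold = "chrX", start = build$locus_start,
      end = build$locus_start + build$locus$len,
      cluster_start = build$locus_start + min(build$locus$motifs$rel_start),
      cluster_end = build$locus_start + max(build$locus$motifs$rel_end),
      stringsAsFactors = FALSE)
    truth_motifs[[sp]] <- data.frame(
      species = sp, scaffold = "chrX",
      start = build$locus_start + build$locus$motifs$rel_start,
      end = build$locus_start + build$locus$motifs$rel_end,
      strand = build$locus$motifs$strand, stringsAsFactors = FALSE)
  }
  list(config = cfg, tree = tree, species = species, maps = maps,
       chains = chains,
       truth = list(loci = do.call(rbind, truth_loci),
                    motifs = do.call(rbind, truth_motifs),
                    ppts = build$ppts, anchors = build$anchors,
                    proteins = build$proteins))
}

#' Generate a synthetic ChIRP experiment
#'
#' Plants X-enriched peaks on the genome per the peak plan: a configured
#' fraction of X-peak summits lands within 100 bp of a selected
#' polypyrimidine tract (the rest are kept clear of tracts so the realized
#' fraction matches the plan), each peak receives a best-motif instance
#' written into the genome with the configured per-feature-class
#' orientation bias, and ChIRP/input tracks are drawn as flat Poisson
#' background plus triangular peak bumps calibrated so the 1-kb windowed
#' enrichment at peaks matches the planned fold.
#'
#' @param g a `genome` (chrX present).
#' @param annot the matching `annotation`.
#' @param plan peak plan (see `simulation_config()$peak_plan`).
#' @param seed RNG seed.
#' @return list: `genome` (with planted motifs), `peaks` (truth table with
#'   class / ppt_proximal / mre_orientation columns), `chirp`, `chirp_rna1`,
#'   `input` (`signal_track`s), `ppts` (tract table used for placement).
#' @export
generate_chirp_experiment <- function(g, annot, plan, seed = 1) {
  ppts <- select_ppts(annot, g)
  ppts_x <- ppts[ppts$scaffold == "chrX", , drop = FALSE]
  n_ppt <- round(plan$ppt_frac * plan$n_x)
  if (plan$ppt_frac > 0 && nrow(ppts_x) == 0)
    stop("peak plan requests PPT-proximal peaks but the annotation has no introns with tracts")
  if (n_ppt > nrow(ppts_x))
    stop("peak plan requests more PPT-proximal peaks than available tracts")
  L <- nchar(g$scaffolds[["chrX"]])
  half <- plan$peak_width / 2
  with_seed(child_seed(seed, "chirp"), {
    if (!is.null(plan$class_quota)) {
      placed <- place_class_quota(annot, plan$class_quota, half, L)
      summits <- placed$summit
      is_ppt <- rep(FALSE, length(summits))
    } else {
      fixed <- plan$fixed %||%
        data.frame(summit = numeric(), ppt_proximal = logical())
      n_ppt_specific <- max(0L, n_ppt - sum(fixed$ppt_proximal))
      avail <- setdiff(seq_len(nrow(ppts_x)), plan$fixed_ppt_rows %||%
                         integer())
      sel <- if (n_ppt_specific > 0)
        sample(avail, n_ppt_specific) else integer()
      off_pool <- c(-60:-15, 15:60)
      ppt_summits <- round(ppts_x$midpoint[sel]) +
        sample(off_pool, n_ppt_specific, replace = TRUE)
      n_rest <- plan$n_x - nrow(fixed) - n_ppt_specific
      stopifnot(n_rest >= 0)
      rest <- sample_summit_positions(L, n_rest, plan$spacing_regime)
      rest <- round(pmin(pmax(rest, half), L - half - 1))
      # keep non-designated summits clear of tracts and of other summits
      taken <- c(fixed$summit, ppt_summits)
      for (i in seq_along(rest)) {
        for (try in 1:200) {
          clash <- any(abs(rest[i] - ppts_x$midpoint) <= 120) ||
            any(abs(rest[i] - taken) < plan$peak_width) ||
            (i > 1 && any(abs(rest[i] - rest[seq_len(i - 1)]) <
                          plan$peak_width))
          if (!clash) break
          rest[i] <- round(stats::runif(1, half, L - half - 1))
        }
      }
      summits <- c(fixed$summit, ppt_summits, rest)
      is_ppt <- c(fixed$ppt_proximal, rep(TRUE, n_ppt_specific),
                  rep(FALSE, n_rest))
    }
    auto_L <- nchar(g$scaffolds[["chr2L"]])
    auto_summits <- round(stats::runif(plan$n_auto, half, auto_L - half - 1))
    pk <- data.frame(
      scaffold = c(rep("chrX", length(summits)),
                   rep("chr2L", plan$n_auto)),
      summit = c(summits, auto_summits),
      ppt_proximal = c(is_ppt, rep(FALSE, plan$n_auto)),
      stringsAsFactors = FALSE)
    pk$start <- pk$summit - half
    pk$end <- pk$summit + half
    pk$name <- sprintf("peak_%03d", seq_len(nrow(pk)))
    pk$strand <- "."
    n <- nrow(pk)
    strong <- stats::runif(n) < plan$frac_strong
    pk$enrichment <- ifelse(strong, stats::runif(n, 55, 80),
                            stats::runif(n, 20, 45))
    pk$q_score <- ifelse(strong, stats::runif(n, 12000, 30000),
                         stats::runif(n, 3000, 9000))
    # feature class of each summit, then plant the best-motif instance
    pk_tbl <- peaks(pk[, c("scaffold", "start", "end", "name", "q_score",
                           "strand", "summit", "enrichment")])
    cls <- summit_classes(pk_tbl, annot)
    prio <- c("intron", "three_prime_UTR", "CDS", "five_prime_UTR",
              "intergenic")
    mre <- plan$mre_consensus
    wm <- nchar(mre)
    pk$class <- NA_character_; pk$gene_strand <- NA_character_
    pk$mre_orientation <- NA_character_; pk$mre_strand <- NA_character_
    for (i in seq_len(nrow(pk))) {
      ci <- cls[cls$peak == pk$name[i], , drop = FALSE]
      ci <- ci[order(match(ci$class, prio)), , drop = FALSE]
      cl <- ci$class[1]; gstrand <- ci$gene_strand[1]
      fw <- stats::runif(1) < plan$orientation_bias[[cl]]
      host <- if (is.na(gstrand)) "+" else gstrand
      mstrand <- if (fw) host else setdiff(c("+", "-"), host)
      ins <- if (mstrand == "+") mre else revcomp(mre)
      p0 <- pk$summit[i] - floor(wm / 2)
      substr(g$scaffolds[[pk$scaffold[i]]], p0 + 1, p0 + wm) <- ins
      pk$class[i] <- cl
      pk$gene_strand[i] <- gstrand
      pk$mre_orientation[i] <- if (fw) "+" else "-"
      pk$mre_strand[i] <- mstrand
    }
    # signal tracks
    bin <- plan$bin
    bg <- plan$background_mean
    mk_track <- function() {
      vals <- lapply(g$scaffolds, function(s)
        stats::rpois(ceiling(nchar(s) / bin), bg))
      signal_track(vals, bin)
    }
    input <- mk_track()
    chirp <- mk_track()
    chirp1 <- mk_track()
    extra_total <- (plan$fold - 1) * bg * (plan$window_bp / bin)
    for (i in seq_len(nrow(pk))) {
      sc <- pk$scaffold[i]
      b0 <- floor(pk$start[i] / bin) + 1
      b1 <- ceiling(pk$end[i] / bin)
      nb <- b1 - b0 + 1
      w <- nb %/% 2
      tri <- c(seq_len(w + 1), rev(seq_len(nb - w - 1)))
      tri <- tri / sum(tri)
      lam <- extra_total * tri
      chirp$values[[sc]][b0:b1] <- chirp$values[[sc]][b0:b1] +
        stats::rpois(nb, lam)
      chirp1$values[[sc]][b0:b1] <- chirp1$values[[sc]][b0:b1] +
        stats::rpois(nb, lam * plan$rox1_ratio)
    }
    pk <- pk[, c("scaffold", "start", "end", "name", "q_score", "strand",
                 "summit", "enrichment", "class", "gene_strand",
                 "ppt_proximal", "mre_orientation", "mre_strand")]
    list(genome = g, peaks = peaks(pk), chirp = chirp, chirp_rna1 = chirp1,
         input = input, ppts = ppts)
  })
}
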