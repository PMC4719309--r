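# Peak-gene association, cross-species conservation calls, liftover
# turnover distances and their permutation nulls.

test_that("gene association applies UTR extensions and the distance rule", {
  # gene on + strand at [1000, 2000) with no annotated UTRs
  ann <- annotation(data.frame(
    scaffold = "c", type = c("exon", "CDS"), start = 1000, end = 2000,
    strand = "+", gene_id = "g1", transcript_id = "t1"))
  # summit 500 bp downstream of the gene end: only reachable via the 3' ext
  p <- fixture_peaks(data.frame(scaffold = "c", start = 2449, end = 2549))
  a <- associate_genes(p, ann, max_distance = 0, utr5_ext = 200,
                       utr3_ext = 500)
  expect_equal(a$gene_id, "g1")
  # boundary: summit 1001 bp beyond the extended span is not associated
  p2 <- fixture_peaks(data.frame(scaffold = "c", start = 3450, end = 3551,
                                 summit = 3500))
  expect_equal(nrow(associate_genes(p2, ann, 1000, 200, 500)), 0)
  p3 <- fixture_peaks(data.frame(scaffold = "c", start = 3440, end = 3540,
                                 summit = 3499))
  expect_equal(nrow(associate_genes(p3, ann, 1000, 200, 500)), 1)
  # genes with annotated UTRs are not extended
  ann2 <- annotation(data.frame(
    scaffold = "c", type = c("exon", "CDS", "three_prime_UTR"),
    start = c(1000, 1000, 1900), end = c(2000, 1900, 2000),
    strand = "+", gene_id = "g1", transcript_id = "t1"))
  expect_equal(nrow(associate_genes(p, ann2, max_distance = 0)), 0)
})

test_that("association matches an all-pairs distance oracle", {
  set.seed(14)
  genes <- data.frame(
    scaffold = "c", type = "exon",
    start = sort(sample(seq(0, 90000, 100), 10)), strand = "+",
    stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(500:2000, 10)
  genes$gene_id <- sprintf("g%02d", 1:10)
  genes$transcript_id <- paste0(genes$gene_id, ".t")
  ann <- annotation(genes[, c("scaffold", "type", "start", "end", "strand",
                              "gene_id", "transcript_id")])
  p <- fixture_peaks(data.frame(scaffold = "c",
                                start = sample(0:99000, 30)))
  p$end <- p$start + 100
  p$summit <- p$start + 50
  p <- peaks(p)
  got <- associate_genes(p, ann, 1000, utr5_ext = 200, utr3_ext = 500)
  # oracle: extended span per gene, then brute-force distance
  want <- 0
  for (i in seq_len(nrow(p))) for (j in 1:10) {
    s0 <- genes$start[j] - 200; e0 <- genes$end[j] + 500
    s <- p$summit[i]
    d <- if (s >= s0 && s < e0) 0 else if (s < s0) s0 - s else s - (e0 - 1)
    if (d <= 1000) {
      want <- want + 1
      expect_true(any(got$peak == p$name[i] & got$gene_id == genes$gene_id[j]))
    }
  }
  expect_equal(nrow(got), want)
})

test_that("gene-level conservation distinguishes conserved from specific peaks", {
  assoc <- list(
    A = data.frame(peak = c("a1", "a2"), gene_id = c("g1", "g2"),
                   distance = 0),
    B = data.frame(peak = "b1", gene_id = "h1", distance = 0))
  orth <- data.frame(species = c("A", "A", "B", "B"),
                     gene_id = c("g1", "g2", "h1", "h2"),
                     group = c("og1", "og2", "og1", "og2"))
  res <- classify_gene_conservation(assoc, orth)
  st <- res$calls
  expect_equal(st$status[st$species == "A" & st$peak == "a1"],
               "gene_conserved")
  # ortholog exists in B but is unbound there -> species-specific
  expect_equal(st$status[st$species == "A" & st$peak == "a2"],
               "species_specific")
  expect_equal(res$n_all_species, 1)
  # genes missing from the orthology table never support conservation
  assoc2 <- list(A = data.frame(peak = "a1", gene_id = "unknown",
                                distance = 0),
                 B = assoc$B)
  res2 <- classify_gene_conservation(assoc2, orth)
  expect_true(all(res2$calls$status[res2$calls$species == "A"] ==
                  "species_specific"))
})

test_that("planted conserved peaks are recovered as universally bound genes", {
  ss <- fixture_species_set()
  exs <- fixture_chirp_set()
  sp_names <- names(ss$species)
  assoc <- lapply(sp_names, function(sp)
    associate_genes(exs[[sp]]$peaks, ss$species[[sp]]$annotation, 1000))
  names(assoc) <- sp_names
  orth <- do.call(rbind, lapply(sp_names, function(sp)
    data.frame(species = sp,
               gene_id = unique(ss$species[[sp]]$annotation$gene_id),
               group = unique(ss$species[[sp]]$annotation$gene_id))))
  res <- classify_gene_conservation(assoc, orth)
  # truth: genes within 1 kb of a shared summit are bound in every species
  shared <- exs$sp01$shared_summits
  gs <- gene_spans(ss$species$sp01$annotation)
  truth_genes <- gs$gene_id[vapply(seq_len(nrow(gs)), function(i)
    any(shared >= gs$start[i] - 1200 & shared <= gs$end[i] + 1200), TRUE)]
  # every truth gene must be recovered among the all-species groups
  expect_gt(res$n_all_species, 0)
  rec <- res$shared_groups$group[res$shared_groups$n_species ==
                                 length(sp_names)]
  # recovered all-species genes must at least contain those strictly
  # within the association distance of a shared summit in every species
  strict <- gs$gene_id[vapply(seq_len(nrow(gs)), function(i)
    any(shared >= gs$start[i] - 500 & shared <= gs$end[i] + 500), TRUE)]
  expect_true(all(strict %in% rec))
  # most recovered groups trace back to planted shared summits; a few genes
  # may be universally bound by chance coincidence of species-specific peaks
  expect_gte(mean(rec %in% truth_genes), 0.6)
})

test_that("element turnover distances follow the liftover and edge rules", {
  map <- coordinate_map(data.frame(
    src_scaffold = "c", src_start = 0, src_end = 1e6,
    tgt_scaffold = "c", tgt_start = 0, tgt_end = 1e6, orientation = "+"))
  pa <- fixture_peaks(data.frame(scaffold = "c",
                                 start = c(1000, 40000, 100000),
                                 end = c(1200, 40200, 100200)))
  pb <- fixture_peaks(data.frame(scaffold = "c", start = c(900, 45100),
                                 end = c(1300, 45300)))
  et <- element_turnover(pa, map, pb)
  expect_equal(et$distance[1], 0)        # lands inside a B peak
  expect_equal(et$distance[2], 5000)     # 45100 - 40100 = 5 kb to the edge
  expect_true(all(et$mapped))
  set.seed(77)
  pa2 <- fixture_peaks(data.frame(scaffold = "c",
                                  start = sort(sample(0:9e5, 50)) ))
  pa2$end <- pa2$start + 100; pa2$summit <- pa2$start + 50
  pa2 <- peaks(pa2)
  et2 <- element_turnover(pa2, map, pb)
  want <- vapply(pa2$summit, oracle_turnover_distance, 0, scaffold = "c",
                 pb = pb)
  expect_equal(et2$distance, want)
})

test_that("unmappable summits are reported, not counted", {
  map <- coordinate_map(data.frame(
    src_scaffold = "c", src_start = 0, src_end = 1000,
    tgt_scaffold = "c", tgt_start = 0, tgt_end = 1000, orientation = "+"))
  pa <- fixture_peaks(data.frame(scaffold = "c", start = c(100, 5000),
                                 end = c(200, 5100)))
  pb <- fixture_peaks(data.frame(scaffold = "c", start = 100, end = 300))
  et <- element_turnover(pa, map, pb)
  expect_equal(et$mapped, c(TRUE, FALSE))
  expect_true(is.na(et$distance[2]))
})

test_that("turnover permutation null preserves peaks and matches the closed form", {
  map <- coordinate_map(data.frame(
    src_scaffold = "c", src_start = 0, src_end = 1e6,
    tgt_scaffold = "c", tgt_start = 0, tgt_end = 1e6, orientation = "+"))
  # identical peak sets: observed fraction at d = 0 is 1, null below 1
  pa <- fixture_peaks(data.frame(scaffold = "c",
                                 start = seq(10000, 90000, 20000)))
  pa$end <- pa$start + 500; pa$summit <- pa$start + 250
  pa <- peaks(pa)
  tn <- turnover_null(pa, map, pa, c(c = 1e6), n_perm = 30, seed = 2)
  expect_equal(tn$curve$observed_frac[tn$curve$d == 0], 1)
  expect_lt(tn$curve$null_frac[tn$curve$d == 0], 1)
  # permutations preserve the length multiset and are reproducible
  tn2 <- turnover_null(pa, map, pa, c(c = 1e6), n_perm = 30, seed = 2)
  expect_identical(tn$null_fracs, tn2$null_fracs)
  # closed form: one B peak of length len, fixed A summit:
  # P(distance <= d) ~ (2d + len)/L
  len <- 500; d <- 1e4; L <- 1e6; n_perm <- 2000
  pb1 <- fixture_peaks(data.frame(scaffold = "c", start = 3e5,
                                  end = 3e5 + len))
  pa1 <- fixture_peaks(data.frame(scaffold = "c", start = 499900,
                                  end = 500100))
  tn3 <- turnover_null(pa1, map, pb1, c(c = L), n_perm = n_perm, seed = 5,
                       d_grid = c(0, d))
  p_hat <- tn3$curve$null_frac[tn3$curve$d == d]
  p_true <- (2 * d + len) / L
  se <- sqrt(p_true * (1 - p_true) / n_perm)
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("planted exact conservation inflates the observed/null ratio at d = 0", {
  ss <- fixture_species_set()
  exs <- fixture_chirp_set()
  tn <- turnover_null(exs$sp02$peaks, ss$maps$sp02, exs$sp01$peaks,
                      ss$species$sp01$genome, n_perm = 40, seed = 8)
  expect_gt(tn$curve$ratio[tn$curve$d == 0], 1)
})
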