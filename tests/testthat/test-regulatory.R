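# PPT penalty and selection, peak-tract proximity, KS and binomial tests,
# feature assignment and motif orientation bias.

test_that("the distance penalty is zero inside 40 bp and 0.02/bp beyond", {
  expect_equal(ppt_penalty(10), 0)
  expect_equal(ppt_penalty(40), 0)
  expect_equal(ppt_penalty(41), 0.02)
  expect_equal(ppt_penalty(90), 1.0)
  expect_error(ppt_penalty(-1), "non-negative")
  d <- 0:200
  expect_true(all(diff(ppt_penalty(d)) >= 0))  # nondecreasing
})

test_that("tract selection prefers 3'-proximal tracts and matches the oracle", {
  # a clean tract ending 2 bp from the 3' splice site: penalty-free
  intron <- paste0(strrep("A", 30), "TTTTCTTTTC", "AA")
  sel <- find_and_select_ppt(intron)
  expect_equal(sel$start, 30)
  expect_equal(sel$end, 40)
  expect_equal(sel$distance_to_3ss, 2)
  expect_equal(ppt_penalty(sel$distance_to_3ss), 0)
  # two equal tracts at distances 10 and 100: the near one wins by 1.2
  tract <- "TTTTTCTTTTT"
  intron2 <- paste0(strrep("A", 40), tract, strrep("G", 89 - 11), tract,
                    strrep("A", 10))
  sel2 <- find_and_select_ppt(intron2)
  expect_equal(sel2$distance_to_3ss, 10)
  set.seed(25)
  for (rep in 1:50) {
    # pyrimidine-enriched random introns so tracts actually occur
    s <- random_dna(sample(60:120, 1), probs = c(.12, .36, .12, .40))
    got <- find_and_select_ppt(s)
    want <- oracle_select_ppt(s)
    if (is.null(want)) expect_null(got)
    else {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$raw, want$raw)
    }
  }
})

test_that("a dominated candidate is never selected", {
  set.seed(26)
  for (rep in 1:20) {
    s <- random_dna(100, probs = c(.1, .4, .1, .4))
    sel <- find_and_select_ppt(s)
    if (is.null(sel)) next
    cand <- ppt_candidates(s)
    cand$dist <- 100 - cand$end
    dominating <- cand$raw > sel$raw & cand$dist < sel$distance_to_3ss
    expect_false(any(dominating &
                     (cand$raw - ppt_penalty(cand$dist) >
                        sel$penalized + 1e-9)))
  }
})

test_that("KS statistic and exact p-values are correct", {
  ks0 <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ks0$D, 0)
  expect_equal(ks0$p, 1)
  ks1 <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ks1$D, 1)
  set.seed(33)
  for (rep in 1:8) {
    x <- runif(4); y <- runif(4)
    got <- ks_two_sample(x, y)
    want <- oracle_ks_perm_p(x, y)
    expect_lt(abs(got$p - want) / want, 0.1)
  }
  # cross-check against the standard implementation on larger samples
  for (rep in 1:5) {
    x <- rnorm(30); y <- rnorm(25, 0.5)
    got <- ks_two_sample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y))
    expect_equal(got$D, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 0.02)
  }
})

test_that("the doubled binomial tail matches the closed form", {
  expect_equal(binom_two_sided(0, 10), 2 * 0.5^10)
  expect_equal(binom_two_sided(10, 10), 2 * 0.5^10)
  expect_equal(binom_two_sided(5, 10), 1)
  # agreement with the standard exact test away from the midpoint
  for (k in c(0, 1, 2, 15, 19, 20)) {
    expect_equal(binom_two_sided(k, 20),
                 min(1, stats::binom.test(k, 20)$p.value), tolerance = 1e-9)
  }
})

test_that("proximity statistics recover planted distances", {
  ppts <- data.frame(intron_id = "i1", gene_id = "g", scaffold = "c",
                     strand = "+", start = 995, end = 1005, midpoint = 1000,
                     raw = 10, distance_to_3ss = 5, penalized = 10)
  p <- fixture_peaks(data.frame(scaffold = "c", start = 950, end = 1050))
  res <- peak_ppt_proximity(p, ppts, c(c = 100000), n_perm = 20, seed = 3)
  expect_equal(res$signed_distances, 0)
  expect_equal(res$frac_within, 1)
  expect_error(peak_ppt_proximity(p, ppts[0, ], c(c = 1e5)), "no PPTs")
  # sign convention: summit 3' of the tract is positive in gene orientation
  p2 <- fixture_peaks(data.frame(scaffold = "c", start = 1150, end = 1250))
  res2 <- peak_ppt_proximity(p2, ppts, c(c = 1e5), n_perm = 5, seed = 1)
  expect_equal(res2$signed_distances, 200)
  ppts_m <- ppts; ppts_m$strand <- "-"
  res3 <- peak_ppt_proximity(p2, ppts_m, c(c = 1e5), n_perm = 5, seed = 1)
  expect_equal(res3$signed_distances, -200)
})

test_that("planted PPT-proximal fraction is recovered with the permuted control below it", {
  ss <- fixture_species_set()
  exs <- fixture_chirp_set()
  ex <- exs$sp01
  ppts <- select_ppts(ss$species$sp01$annotation, ex$genome)
  px <- ex$peaks[ex$peaks$scaffold == "chrX", ]
  res <- peak_ppt_proximity(px, ppts[ppts$scaffold == "chrX", ],
                            ex$genome, n_perm = 50, seed = 9)
  planted <- ss$config$peak_plan$ppt_frac
  n <- nrow(px)
  ci <- 1.96 * sqrt(planted * (1 - planted) / n)
  expect_lt(abs(res$frac_within - planted), ci + 1e-9)
  expect_lt(res$perm_frac_within, res$frac_within)
})

test_that("feature assignment double-counts overlapping transcripts and computes folds", {
  ann <- fixture_toy_annotation()
  g_len <- c(chr1 = 10000)
  # summit inside gA's only intron
  p <- fixture_peaks(data.frame(scaffold = "chr1", start = 1300, end = 1400))
  fa <- feature_assignment(p, ann, g_len)
  expect_equal(fa$assignments$class, "intron")
  # overlapping transcripts: intron of one, CDS of the other
  ann2 <- annotation(data.frame(
    scaffold = "chr1",
    type = c("exon", "exon", "exon", "CDS"),
    start = c(100, 500, 150, 150), end = c(300, 700, 450, 450),
    strand = "+", gene_id = c("gA", "gA", "gB", "gB"),
    transcript_id = c("tA", "tA", "tB", "tB"),
    stringsAsFactors = FALSE))
  p2 <- fixture_peaks(data.frame(scaffold = "chr1", start = 350, end = 450,
                                 summit = 400))
  fa2 <- feature_assignment(p2, ann2, g_len)
  expect_setequal(fa2$assignments$class, c("intron", "CDS"))
  # toy genome 50% intergenic with all summits intergenic: fold = 2
  ann3 <- annotation(data.frame(
    scaffold = "chr1", type = c("exon", "CDS"), start = 0, end = 5000,
    strand = "+", gene_id = "g", transcript_id = "t"))
  p3 <- fixture_peaks(data.frame(scaffold = "chr1",
                                 start = c(6000, 7000, 8000)))
  fa3 <- feature_assignment(p3, ann3, g_len)
  enr <- fa3$enrichment
  expect_equal(enr$fold[enr$class == "intergenic"], 2)
})

test_that("orientation bias counts and tests per feature class", {
  # 10 intronic peaks, all motifs reverse relative to transcription
  gp <- simulation_config()$genes
  set.seed(55)
  mre <- "GAGAGAGAGAGA"
  feats <- list(); seqs <- character()
  pos <- 0
  for (i in 1:10) {
    lead <- random_dna(200)
    exon1 <- random_dna(100); intron <- random_dna(300)
    exon2 <- random_dna(100)
    # plant the reverse-complement MRE mid-intron (gene on + strand)
    substr(intron, 140, 139 + nchar(mre)) <- revcomp(mre)
    gstart <- pos + 200
    feats[[i]] <- data.frame(
      scaffold = "chr", type = c("exon", "exon", "CDS", "CDS"),
      start = gstart + c(0, 400, 0, 400), end = gstart + c(100, 500, 100, 500),
      strand = "+", gene_id = sprintf("g%d", i),
      transcript_id = sprintf("g%d.t", i), stringsAsFactors = FALSE)
    seqs <- c(seqs, lead, exon1, intron, exon2)
    pos <- pos + 700
  }
  g <- genome(c(chr = paste(seqs, collapse = "")))
  ann <- annotation(do.call(rbind, feats))
  p <- fixture_peaks(data.frame(
    scaffold = "chr", start = 200 + (0:9) * 700 + 150,
    end = 200 + (0:9) * 700 + 350))
  x <- pwm_from_instances(rep(mre, 5))
  ob <- orientation_bias(p, x, ann, g)
  cnt <- ob$counts[ob$counts$class == "intron", ]
  expect_equal(cnt$n_minus, 10)
  expect_equal(cnt$n_plus, 0)
  expect_equal(cnt$p, 2 * 0.5^10)
})

test_that("planted orientation biases are recovered with class quotas", {
  cfg <- fixture_config_small(
    n_species = 2,
    scaffolds = data.frame(name = c("chrX", "chr2L", "chr3R", "scf_un"),
                           length = c(150000, 30000, 20000, 6000),
                           me = c("A", "B", "E", NA),
                           stringsAsFactors = FALSE),
    genes = list(n_x = 40, x_first = 18000, x_pitch = 3200, n_2l = 4),
    peak_plan = list(class_quota = c(intron = 30, three_prime_UTR = 30),
                     n_auto = 0,
                     orientation_bias = c(intron = 0.2,
                                          three_prime_UTR = 0.8,
                                          CDS = 0.5, five_prime_UTR = 0.5,
                                          intergenic = 0.5)))
  ss <- generate_species_set(cfg)
  ex <- generate_chirp_experiment(ss$species$sp01$genome,
                                  ss$species$sp01$annotation,
                                  cfg$peak_plan, seed = 5)
  x <- pwm_from_instances(rep(cfg$peak_plan$mre_consensus, 5))
  ob <- orientation_bias(ex$peaks, x, ss$species$sp01$annotation, ex$genome)
  ci <- ob$counts[ob$counts$class == "intron", ]
  cu <- ob$counts[ob$counts$class == "three_prime_UTR", ]
  expect_gt(ci$n_minus, ci$n_plus)
  expect_gt(cu$n_plus, cu$n_minus)
  # recovered orientations match the planted ones peak by peak
  planted <- ex$peaks[match(ob$per_peak$peak, ex$peaks$name), ]
  same_class <- ob$per_peak$class == planted$class
  expect_gt(mean(ob$per_peak$orientation[same_class] ==
                 planted$mre_orientation[same_class]), 0.95)
})
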