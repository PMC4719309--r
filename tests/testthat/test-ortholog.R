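# PWM scanning with exact p-values, cluster election, stem-loop scoring,
# anchor location and the bootstrap search.

test_that("consensus-only PWM assigns the analytic p-value to its top score", {
  cw <- pwm(matrix(c(97, 1, 1, 1), 4, 8), pseudocount = 0)
  hits <- scan_pwm(paste0("CC", strrep("A", 8), "GG"), cw, p_threshold = 1)
  top <- hits[which.max(hits$score), ]
  expect_equal(top$p_value, 0.25^8)
  expect_equal(top$start, 2)
  expect_equal(top$strand, "+")
})

test_that("an embedded consensus yields exactly one forward hit at its offset", {
  x <- pwm_from_instances(rep("GATTACAA", 4))
  s <- paste0(strrep("C", 57), "GATTACAA", strrep("C", 35))
  hits <- scan_pwm(s, x, p_threshold = 0.25^8 * 1.01)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 57)
  expect_equal(hits$strand, "+")
  expect_equal(hits$hit_seq, "GATTACAA")
})

test_that("scan_pwm matches the brute-force enumeration oracle", {
  set.seed(42)
  for (rep in 1:6) {
    inst <- replicate(4, random_dna(6))
    x <- pwm_from_instances(inst, background = c(A = .3, C = .2, G = .2, T = .3))
    s <- random_dna(200)
    got <- scan_pwm(s, x, p_threshold = 0.02)
    want <- oracle_scan_pwm(s, x, p_threshold = 0.02)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    expect_equal(got$p_value, unname(want$p_value), tolerance = 1e-12)
  }
})

test_that("scan_pwm hits are invariant under reverse complementation", {
  set.seed(5)
  x <- pwm_from_instances(replicate(5, random_dna(7)))
  s <- random_dna(300)
  h1 <- scan_pwm(s, x, p_threshold = 0.05)
  h2 <- scan_pwm(revcomp(s), x, p_threshold = 0.05)
  L <- nchar(s)
  # a hit at [st, st+w) on strand z maps to [L-w-st, ...) on the other strand
  remap <- data.frame(start = L - 7 - h2$start,
                      strand = ifelse(h2$strand == "+", "-", "+"),
                      score = h2$score)
  o1 <- order(h1$start, h1$strand); o2 <- order(remap$start, remap$strand)
  expect_equal(h1$start[o1], remap$start[o2])
  expect_equal(h1$strand[o1], remap$strand[o2])
  expect_equal(h1$score[o1], remap$score[o2])
})

test_that("all-N and too-short sequences yield no hits", {
  x <- pwm_from_instances(rep("ACGTAC", 3))
  expect_equal(nrow(scan_pwm(strrep("N", 50), x, 1)), 0)
  expect_equal(nrow(scan_pwm("ACG", x, 1)), 0)
})

test_that("cluster election follows the density/score/leftmost tie-break", {
  hits <- data.frame(start = c(10, 100, 400, 5000),
                     score = c(5, 5, 5, 9), end = NA, strand = "+",
                     p_value = 1e-5, hit_seq = "X")
  el <- elect_candidate_window(hits, cluster_span = 500, min_hits = 3)
  expect_equal(el$n_hits, 3)
  expect_equal(sort(el$hits$start), c(10, 100, 400))
  expect_null(elect_candidate_window(hits[1:2, ], 500, 3))
  set.seed(9)
  for (rep in 1:60) {
    n <- sample(5:20, 1)
    st <- sort(sample(0:3000, n))
    sc <- round(stats::runif(n, 1, 10), 3)
    h <- data.frame(start = st, score = sc)
    got <- elect_candidate_window(h, cluster_span = 400, min_hits = 3)
    want <- oracle_elect(st, sc, span = 400, min_hits = 3)
    if (is.null(want)) expect_null(got)
    else {
      expect_equal(got$n_hits, want$n)
      expect_equal(got$score_sum, want$ss)
      expect_equal(got$start, want$start)
    }
  }
})

test_that("stem-loop scoring handles perfect repeats, homopolymers, and matches the oracle", {
  # perfect 8-bp inverted repeat around a 4-nt loop
  arm <- "GATTCCGA"
  s <- paste0("TT", arm, "AAAA", revcomp(arm), "TT")
  res <- score_stem_loop(s, 2, 10, min_loop = 3, max_loop = 10, max_arm = 10)
  expect_equal(res$score, 8)
  expect_equal(res$arm5, c(2, 10))
  expect_equal(res$loop_len, 4)
  # homopolymer has no pairing partner (A-A never pairs)
  expect_equal(score_stem_loop(strrep("A", 40), 0, 40)$score, 0)
  set.seed(13)
  for (rep in 1:50) {
    s <- random_dna(40)
    got <- score_stem_loop(s, 10, 20, min_loop = 3, max_loop = 12,
                           max_arm = 8)$score
    want <- oracle_stem(s, 10, 20, min_loop = 3, max_loop = 12, max_arm = 8)
    expect_equal(got, want)
  }
})

test_that("PWM refinement re-tabulates counts and never lowers the consensus score", {
  x0 <- pwm_from_instances(c("ACGT", "ACGT"), pseudocount = 0)
  expect_equal(unname(x0$counts[, 1]), c(2, 0, 0, 0))
  expect_error(refine_pwm(x0, "ACGTA"), "ACGTA")
  x1 <- pwm_from_instances(c("ACGT", "ACCT", "AGGT"), pseudocount = 0.25)
  cons <- "ACGT"
  sc <- function(x, s) scan_pwm(paste0(s, "AAAAAA"), x, 1)[1, "score"]
  s1 <- scan_pwm(cons, x1, 1)
  x2 <- refine_pwm(x1, cons)
  s2 <- scan_pwm(cons, x2, 1)
  expect_gte(s2$score[s2$strand == "+"], s1$score[s1$strand == "+"])
  # manual tabulation over 10 instances
  set.seed(3)
  inst <- replicate(10, random_dna(5))
  xx <- pwm_from_instances(inst, pseudocount = 0)
  hand <- matrix(0, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (s in inst) {
    v <- strsplit(s, "")[[1]]
    for (j in 1:5) hand[v[j], j] <- hand[v[j], j] + 1
  }
  expect_equal(xx$counts, hand)
})

test_that("anchor search recovers planted loci and rejects absent anchors", {
  set.seed(21)
  prot <- paste(sample(setdiff(unique(Biostrings::GENETIC_CODE), "*"),
                       60, replace = TRUE), collapse = "")
  cds <- paste(vapply(strsplit(prot, "")[[1]], function(aa) {
    cods <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
    sample(cods, 1)
  }, ""), collapse = "")
  g <- genome(c(chr = paste0(random_dna(4000), cds, random_dna(4000))))
  hit <- find_anchor_locus(g, prot, k = 5, min_extension_score = 50)
  expect_equal(hit$start, 4000)
  expect_equal(hit$end, 4000 + nchar(cds))
  expect_equal(hit$strand, "+")
  # reverse-strand placement
  g2 <- genome(c(chr = paste0(random_dna(3000), revcomp(cds),
                              random_dna(3000))))
  hit2 <- find_anchor_locus(g2, prot, k = 5, min_extension_score = 50)
  expect_equal(hit2$start, 3000)
  expect_equal(hit2$strand, "-")
  # 10% amino-acid substitutions still recovered
  pv <- strsplit(prot, "")[[1]]
  idx <- sample(60, 6)
  pv[idx] <- sample(setdiff(unique(Biostrings::GENETIC_CODE), c("*", pv[idx])),
                    6, replace = TRUE)
  mut_prot <- paste(pv, collapse = "")
  hit3 <- find_anchor_locus(g, mut_prot, k = 5, min_extension_score = 50)
  expect_false(is.null(hit3))
  expect_lte(abs(hit3$start - 4000), 30)
  # random genome without the anchor: threshold calibrated from a
  # permutation of the protein must reject
  gr <- genome(c(chr = random_dna(10000)))
  perm_prot <- paste(sample(strsplit(prot, "")[[1]]), collapse = "")
  null_hit <- find_anchor_locus(gr, perm_prot, k = 4,
                                min_extension_score = 0)
  thr <- if (is.null(null_hit)) 30 else null_hit$score + 10
  expect_null(find_anchor_locus(gr, prot, k = 5, min_extension_score = thr))
})

test_that("synteny windows follow the two/one/zero-anchor rules", {
  lens <- c(chr1 = 10000, chr2 = 5000)
  a <- list(scaffold = "chr1", start = 1000, end = 2000)
  b <- list(scaffold = "chr1", start = 8000, end = 9000)
  w <- define_synteny_window(list(a, b), max_span = 20000, lens)
  expect_equal(w$window$start, 2000)
  expect_equal(w$window$end, 8000)
  expect_false(w$disrupted)
  w1 <- define_synteny_window(list(list(scaffold = "chr1", start = 4900,
                                        end = 5100)), 6000, lens)
  expect_equal(w1$window$start, 2000)
  expect_equal(w1$window$end, 8000)
  w2 <- define_synteny_window(list(a, list(scaffold = "chr2", start = 0,
                                           end = 100)), 20000, lens)
  expect_null(w2$window)
  expect_true(w2$disrupted)
})

test_that("bootstrap search recovers undiverged loci exactly and flags motifless windows", {
  cfg <- fixture_config_small(n_species = 5,
                              rates = list(background = 0, structure = 0,
                                           anchor_syn = 0))
  ss <- generate_species_set(cfg)
  genomes <- lapply(ss$species, `[[`, "genome")
  init <- pwm_from_instances(rep(cfg$lncrna$motif_consensus, 5))
  anchor_sets <- list(unlist(ss$truth$proteins[c("anchor_up", "anchor_dn")]),
                      unlist(ss$truth$proteins[c("anchor_sec_up",
                                                 "anchor_sec_dn")]))
  res <- run_bootstrap_search(genomes, ss$tree, "sp01", anchor_sets, init)
  expect_true(all(res$results$status == "accepted"))
  truth <- ss$truth$loci[ss$truth$loci$species != "sp01", ]
  got <- res$results[match(truth$species, res$results$species), ]
  expect_equal(got$start, truth$cluster_start)
  expect_equal(got$end, truth$cluster_end)
  # species with a scrambled locus is rejected for lack of a motif cluster
  decoy <- genomes
  loc <- ss$truth$loci[1, ]
  seq0 <- genome_seq(decoy$sp03, "chrX", loc$start, loc$end)
  scr <- scramble_sequence(seq0, 1, seed = 99)
  g3 <- decoy$sp03
  substr(g3$scaffolds[["chrX"]], loc$start + 1, loc$end) <- scr
  decoy$sp03 <- g3
  res2 <- run_bootstrap_search(decoy, ss$tree, "sp01", anchor_sets, init)
  r3 <- res2$results[res2$results$species == "sp03", ]
  expect_equal(r3$status, "rejected")
  expect_true(r3$reason %in% c("no_motif_cluster", "no_stem"))
})

test_that("refined PWM scores accepted instances at least as well as the initial PWM", {
  ss <- fixture_species_set()
  genomes <- lapply(ss$species, `[[`, "genome")
  cfg <- ss$config
  init <- pwm_from_instances(rep(cfg$lncrna$motif_consensus, 5))
  anchor_sets <- list(unlist(ss$truth$proteins[c("anchor_up", "anchor_dn")]))
  res <- run_bootstrap_search(genomes, ss$tree, "sp01", anchor_sets, init)
  inst <- res$state$instances
  expect_gt(length(inst), 5)
  mean_lo <- function(x, seqs) {
    s <- pwm_int_scores_test(x)
    mean(vapply(seqs, function(q) {
      e <- match(strsplit(q, "")[[1]], c("A", "C", "G", "T"))
      sum(s[cbind(e, seq_along(e))]) / 100
    }, 0))
  }
  pwm_int_scores_test <- function(x) round(log2(sweep(x$probs, 1,
                                                      x$background, "/")) * 100)
  new_inst <- setdiff(inst, init$instances)
  expect_gte(mean_lo(res$state$pwm, new_inst), mean_lo(init, new_inst) - 1e-9)
})
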