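# Shared fixtures, built in code and cached for the duration of a test run.

.fixture_env <- new.env()

# Reduced-scale simulation used by most unit tests (the default-scale set
# is reserved for the acceptance suite).
fixture_config_small <- function(...) {
  base <- list(
    n_species = 4,
    scaffolds = data.frame(
      name = c("chrX", "chr2L", "chr3R", "scf_un"),
      length = c(60000, 30000, 20000, 6000),
      me = c("A", "B", "E", NA), stringsAsFactors = FALSE),
    anchor = list(protein_len = 60, up_start = 8000, dn_start = 11000,
                  sec_up_start = 6500, sec_dn_start = 12500),
    lncrna = list(locus_start = 9200),
    genes = list(n_x = 12, x_first = 18000, x_pitch = 3200,
                 n_2l = 4, l2_first = 2000, l2_pitch = 6000),
    peak_plan = list(n_x = 20, n_auto = 2))
  do.call(simulation_config, utils::modifyList(base, list(...)))
}

fixture_species_set <- function() {
  if (is.null(.fixture_env$ss))
    .fixture_env$ss <- generate_species_set(fixture_config_small())
  .fixture_env$ss
}

fixture_chirp_set <- function() {
  if (is.null(.fixture_env$chirp))
    .fixture_env$chirp <- generate_chirp_set(fixture_species_set())
  .fixture_env$chirp
}

# A tiny two-gene annotation on one 10-kb scaffold, with one intron each.
fixture_toy_annotation <- function() {
  annotation(data.frame(
    scaffold = "chr1",
    type = c("exon", "exon", "CDS", "CDS",
             "exon", "exon", "CDS", "three_prime_UTR"),
    start = c(1000, 1500, 1000, 1500,
              4000, 4800, 4800, 4000),
    end = c(1200, 1800, 1200, 1800,
            4300, 5200, 5200, 4300),
    strand = c(rep("+", 4), rep("-", 4)),
    gene_id = c(rep("gA", 4), rep("gB", 4)),
    transcript_id = c(rep("gA.t1", 4), rep("gB.t1", 4)),
    stringsAsFactors = FALSE))
}

fixture_peaks <- function(df) {
  df$end <- df$end %||% (df$start + 100)
  df$name <- df$name %||% sprintf("p%d", seq_len(nrow(df)))
  df$q_score <- df$q_score %||% 5000
  df$strand <- df$strand %||% "."
  df$enrichment <- df$enrichment %||% 30
  df$summit <- df$summit %||% floor((df$start + df$end) / 2)
  peaks(df[, c("scaffold", "start", "end", "name", "q_score", "strand",
               "summit", "enrichment")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
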