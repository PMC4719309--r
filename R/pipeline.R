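# End-to-end orchestration: simulate a species set and ChIRP experiments,
# run the ortholog search, conservation, enrichment, turnover, tract,
# orientation and spacing analyses, and write every stage artifact plus a
# run manifest to an output directory.

#' Validate a pipeline configuration
#'
#' The pipeline configuration embeds a simulation configuration plus
#' analysis thresholds; violations are reported with their field paths.
#'
#' @param config list (or YAML file path) with fields `sim` (see
#'   [simulation_config()]) and optional `analysis` overrides.
#' @return the validated config list, invisibly a `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  sim_over <- config$sim %||% list()
  sim <- do.call(simulation_config, sim_over)
  analysis <- utils::modifyList(list(
    window_bp = 1000, me_cutoff = 0.85, q_min = 3000, enrichment_min = 20,
    gene_distance = 1000, utr5_ext = 200, utr3_ext = 500,
    ppt_free_zone = 40, ppt_per_base = 0.02, ppt_within = 100,
    cluster_span = 500, min_hits = 3, p_threshold = 1e-4,
    stem_threshold = 6, strong_enrichment_min = 50, strong_q_min = 10000,
    n_perm = 200), config$analysis %||% list())
  for (f in c("me_cutoff")) {
    if (analysis[[f]] < 0 || analysis[[f]] > 1)
      stop(sprintf("config field analysis.%s must be a fraction in [0, 1]", f),
           call. = FALSE)
  }
  structure(list(sim = sim, analysis = analysis), class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-data pipeline
#'
#' Stages: simulate -> search -> conserve -> enrich/assign-me -> evolve ->
#' ppt -> motif-bias -> spacing.  Each stage writes tab-delimited artifacts
#' under `out_dir`; a manifest records the seed, stage timings and output
#' checksums, so reruns with an identical config and seed are
#' byte-identical for the deterministic stages (all stages here are
#' seed-determined).
#'
#' @param config a `pipeline_config`, a config list, or a YAML path.
#' @param out_dir output directory (created if needed).
#' @param seed global seed overriding `config$sim$seed` when not NULL.
#' @return list of stage results (invisibly writes artifacts + manifest).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("chirpevo_run_"),
                         seed = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
  else pipeline_config(config)
  if (!is.null(seed)) cfg$sim$seed <- as.integer(seed)
  an <- cfg$analysis
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stages <- list(); timing <- list()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timing[[name]] <<- t1 - t0
    t0 <<- t1
  }

  # -- simulate
  ss <- generate_species_set(cfg$sim)
  sp_names <- names(ss$species)
  ref <- cfg$sim$reference
  experiments <- generate_chirp_set(ss)
  for (sp in sp_names)
    ss$species[[sp]]$genome <- experiments[[sp]]$genome
  write_tsv(ss$truth$loci, file.path(out_dir, "truth_loci.tsv"))
  write_peaks(experiments[[ref]]$peaks, file.path(out_dir, "peaks_ref.bed"))
  stages$species_set <- ss; stages$experiments <- experiments
  tick("simulate")

  # -- ortholog search
  genomes <- lapply(ss$species, `[[`, "genome")
  consensus <- cfg$sim$lncrna$motif_consensus
  init_pwm <- pwm_from_instances(rep(consensus, 5))
  anchor_sets <- list(
    primary = unlist(ss$truth$proteins[c("anchor_up", "anchor_dn")]),
    secondary = unlist(ss$truth$proteins[c("anchor_sec_up",
                                           "anchor_sec_dn")]))
  search <- run_bootstrap_search(
    genomes, ss$tree, ref, anchor_sets, init_pwm,
    params = search_params(cluster_span = an$cluster_span,
                           min_hits = an$min_hits,
                           p_threshold = an$p_threshold,
                           stem_threshold = an$stem_threshold))
  write_tsv(search$results, file.path(out_dir, "search_results.tsv"))
  stages$search <- search
  tick("search")

  # -- sequence conservation
  loci <- ss$truth$loci
  lnc_seqs <- vapply(sp_names, function(sp)
    genome_seq(genomes[[sp]], "chrX", loci$start[loci$species == sp],
               loci$end[loci$species == sp]), "")
  idm <- identity_matrix(lnc_seqs, reference = ref, n_scrambles = 2,
                         seed = child_seed(cfg$sim$seed, "scramble"))
  write_tsv(as.data.frame(unclass(idm)), file.path(out_dir, "identity.tsv"))
  stages$identity <- idm
  tick("conserve")

  # -- enrichment + ME assignment (reference species)
  ex <- experiments[[ref]]
  roxw <- cfg$sim$lncrna
  exclude <- data.frame(scaffold = "chrX",
                        start = max(0, loci$start[1] - 2500),
                        end = loci$end[1] + 2500)
  enr <- window_enrichment(ex$chirp, ex$input, window_bp = an$window_bp,
                           exclude = exclude)
  me <- assign_scaffold_to_me(ss$chains[[ref]], cutoff = an$me_cutoff)
  flt <- filter_peaks(ex$peaks, q_min = an$q_min,
                      enrichment_min = an$enrichment_min)
  bias <- rox_bias(flt, ex$chirp_rna1, ex$chirp)
  write_tsv(enr, file.path(out_dir, "window_enrichment.tsv"))
  write_tsv(me, file.path(out_dir, "me_assignment.tsv"))
  stages$enrichment <- enr; stages$me <- me; stages$rox_bias <- bias
  stages$filtered_peaks <- flt
  tick("enrich")

  # -- gene-level and element-level conservation (all species vs reference)
  annot_by_sp <- lapply(ss$species, `[[`, "annotation")
  assoc <- lapply(sp_names, function(sp)
    associate_genes(experiments[[sp]]$peaks, annot_by_sp[[sp]],
                    max_distance = an$gene_distance,
                    utr5_ext = an$utr5_ext, utr3_ext = an$utr3_ext))
  names(assoc) <- sp_names
  orthology <- do.call(rbind, lapply(sp_names, function(sp) {
    genes <- unique(annot_by_sp[[sp]]$gene_id)
    data.frame(species = sp, gene_id = genes, group = genes,
               stringsAsFactors = FALSE)
  }))
  cons <- classify_gene_conservation(assoc, orthology)
  sp2 <- setdiff(sp_names, ref)[1]
  to_ref <- invert_coordinate_map(ss$maps[[sp2]])  # sp2 -> ref is identity here
  turn <- turnover_null(experiments[[sp2]]$peaks, ss$maps[[sp2]],
                        experiments[[ref]]$peaks,
                        genomes[[ref]], n_perm = min(an$n_perm, 100),
                        seed = child_seed(cfg$sim$seed, "turnover"))
  write_tsv(cons$calls, file.path(out_dir, "conservation_calls.tsv"))
  write_tsv(turn$curve, file.path(out_dir, "turnover_curve.tsv"))
  stages$conservation <- cons; stages$turnover <- turn
  tick("evolve")

  # -- peak-to-PPT proximity (reference)
  ppts <- select_ppts(annot_by_sp[[ref]], genomes[[ref]],
                      free_zone = an$ppt_free_zone,
                      per_base = an$ppt_per_base)
  px <- ex$peaks[ex$peaks$scaffold == "chrX", , drop = FALSE]
  prox <- peak_ppt_proximity(px, ppts[ppts$scaffold == "chrX", ],
                             genomes[[ref]], n_perm = min(an$n_perm, 100),
                             seed = child_seed(cfg$sim$seed, "ppt_perm"),
                             within = an$ppt_within)
  write_tsv(ppts, file.path(out_dir, "selected_ppts.tsv"))
  stages$ppt <- list(ppts = ppts, proximity = prox)
  tick("ppt")

  # -- motif orientation bias (reference)
  mre_pwm <- pwm_from_instances(rep(cfg$sim$peak_plan$mre_consensus, 5))
  ob <- orientation_bias(ex$peaks, mre_pwm, annot_by_sp[[ref]],
                         genomes[[ref]])
  fa <- feature_assignment(ex$peaks, annot_by_sp[[ref]], genomes[[ref]])
  write_tsv(ob$counts, file.path(out_dir, "orientation_bias.tsv"))
  write_tsv(fa$enrichment, file.path(out_dir, "feature_enrichment.tsv"))
  stages$orientation <- ob; stages$features <- fa
  tick("motif_bias")

  # -- spacing (reference X peaks)
  conserved_names <- unique(cons$calls$peak[
    cons$calls$species == ref & cons$calls$status == "gene_conserved"])
  subs <- subset_peaks(px, conserved_names,
                       strong_enrichment_min = an$strong_enrichment_min,
                       strong_q_min = an$strong_q_min)
  Lx <- nchar(genomes[[ref]]$scaffolds[["chrX"]])
  use <- if (nrow(subs$strong_conserved) >= 2) subs$strong_conserved else px
  obs_nnd <- nearest_neighbor_distances(use$summit)
  null_nnd <- spacing_null(Lx, nrow(use), n_perm = min(an$n_perm, 200),
                           seed = child_seed(cfg$sim$seed, "spacing"))
  dep <- spacing_departure(obs_nnd, null_nnd, Lx, nrow(use))
  write_tsv(dep$curve, file.path(out_dir, "spacing_curve.tsv"))
  stages$spacing <- list(subsets = subs, departure = dep)
  tick("spacing")

  manifest <- data.frame(
    stage = names(timing), seconds = round(unlist(timing), 3),
    seed = cfg$sim$seed, stringsAsFactors = FALSE)
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest", files)]
  sums <- tools::md5sum(files)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  write_tsv(data.frame(file = basename(names(sums)), md5 = unname(sums)),
            file.path(out_dir, "checksums.tsv"))
  stages$manifest <- manifest
  stages$out_dir <- out_dir
  invisible(stages)
}
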