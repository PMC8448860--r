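# ---------------------------------------------------------------------------
# End-to-end orchestration: simulate -> partition -> blocks -> callmut ->
# callhe -> curate -> date -> bias, with a machine-readable run manifest.
# ---------------------------------------------------------------------------

#' Run the whole analysis pipeline on a simulated system
#'
#' Executes every stage in dependency order against a freshly simulated
#' allotetraploid system, writes all stage outputs under `outdir`, and
#' returns the in-memory results together with a reproducible run manifest.
#'
#' @param config a [sim_config()] (or path to a YAML config).
#' @param outdir output directory.
#' @param neutral_rate neutral substitution rate (substitutions/site/year)
#'   for dS-based dating.
#' @return list of class `pf_run`: `$sim`, per-stage results, `$manifest`.
#' @export
run_pipeline <- function(config, outdir, neutral_rate = 7.1e-9) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "pf_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  t0 <- Sys.time()
  log_stage <- function(name, outputs, params = list()) {
    manifest$stages[[name]] <<- list(outputs = outputs, params = params)
    message(sprintf("[%s] done (%.1fs)", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
  }

  ## 1. simulate ------------------------------------------------------------
  sim <- simulate_system(config)
  cfg_path <- file.path(outdir, "config.yaml")
  write_sim_config(config, cfg_path)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  genome_paths <- write_genome_fasta(sim, file.path(outdir, "genomes"))
  aln_dir <- file.path(outdir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  aln_paths <- vapply(block_ids(config), function(b)
    write_alignment(sim_alignment_block(sim, b),
                    file.path(aln_dir, paste0(b, ".afa"))), character(1))
  truth_paths <- write_truth_set(sim, file.path(outdir, "truth"))
  map <- sim_synteny_map(sim)
  map_paths <- write_synteny_map(map, outdir)
  genes_all <- rbind(
    data.frame(gene_id = paste0(sim$truth$genes$gene_id, "_A"),
               chrom = sim$truth$genes$block,
               start = sim$truth$genes$start, end = sim$truth$genes$end,
               strand = sim$truth$genes$strand, stringsAsFactors = FALSE),
    data.frame(gene_id = paste0(sim$truth$genes$gene_id, "_B"),
               chrom = sub("^A", "B", sim$truth$genes$block),
               start = sim$truth$genes$start, end = sim$truth$genes$end,
               strand = sim$truth$genes$strand, stringsAsFactors = FALSE))
  gff_path <- file.path(outdir, "genes.gff3")
  write_genes_gff3(genes_all, gff_path)
  expr_path <- file.path(outdir, "expression.tsv")
  utils::write.table(sim$expression, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dip_track <- simulate_depth(sim, "diploid")
  dip_path <- file.path(outdir, "depth_diploid.bedGraph")
  write_depth_bedgraph(dip_track, dip_path)
  sample_tracks <- lapply(sample_names(config), function(s) simulate_depth(sim, s))
  names(sample_tracks) <- sample_names(config)
  depth_paths <- vapply(sample_names(config), function(s) {
    p <- file.path(outdir, sprintf("depth_%s.bedGraph", s))
    write_depth_bedgraph(sample_tracks[[s]], p)
    p
  }, character(1))
  log_stage("simulate",
            c(genome_paths, aln_paths, truth_paths, map_paths,
              gff = gff_path, expression = expr_path,
              depth_diploid = dip_path, depth_paths),
            params = list(seed = config$seed))

  ## 2. partition -----------------------------------------------------------
  partition <- partition_depth_track(dip_track, min_run = 5L)
  part_path <- file.path(outdir, "partition_blocks.bed")
  write_partition_bed(partition, part_path)
  log_stage("partition", c(blocks = part_path),
            params = list(min_run = 5, window = config$window_size))

  ## 3. blocks --------------------------------------------------------------
  msas <- lapply(names(aln_paths), function(b) read_alignment(aln_paths[[b]], block_id = b))
  intervals <- do.call(rbind, lapply(msas, function(m)
    filter_intervals(m, segment_on_gaps(m))))
  int_path <- file.path(outdir, "conserved_intervals.tsv")
  utils::write.table(intervals, int_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log_stage("blocks", c(intervals = int_path),
            params = list(max_gap = 100, min_length = 500, min_identity = 0.8))

  ## 4. callmut -------------------------------------------------------------
  calls <- do.call(rbind, lapply(msas, function(m)
    call_mutations(m, intervals[intervals$block_id == m$block_id, , drop = FALSE])))
  calls_path <- file.path(outdir, "mutation_calls.tsv")
  utils::write.table(calls, calls_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  spectra <- lapply(LINEAGES, function(l) summarize_spectrum(calls, l))
  names(spectra) <- LINEAGES
  spec_path <- file.path(outdir, "spectrum96.tsv")
  utils::write.table(
    do.call(rbind, lapply(LINEAGES, function(l)
      cbind(lineage = l, spectrum_table(spectra[[l]])))),
    spec_path, sep = "\t", quote = FALSE, row.names = FALSE)
  comparison <- compare_lineages(calls)
  log_stage("callmut", c(calls = calls_path, spectrum = spec_path),
            params = list(flank = 5))

  ## 5. callhe --------------------------------------------------------------
  seg_calls <- do.call(rbind, lapply(sample_tracks, function(tr)
    call_segmental_he(tr, map)))
  genic_calls <- do.call(rbind, lapply(sample_tracks, function(tr)
    call_genic_he(tr, map$gene_pairs)))
  balanced_calls <- call_balanced_he(partition, map)
  nonrec_calls <- do.call(rbind, lapply(sample_tracks, function(tr)
    call_nonreciprocal_he(tr, scan_nonreciprocal_candidates(tr))))
  he_path <- file.path(outdir, "he_calls.tsv")
  he_all <- list(seg_calls, nonrec_calls)
  he_tab <- do.call(rbind, he_all[vapply(he_all, nrow, 1L) > 0])
  utils::write.table(he_tab, he_path, sep = "\t", quote = FALSE, row.names = FALSE)
  chrom_sizes <- rep(config$chrom_length,
                     2 * config$n_chromosomes)
  names(chrom_sizes) <- c(block_ids(config), sub("^A", "B", block_ids(config)))
  enrichment <- if (nrow(genic_calls)) {
    gene_ann <- data.frame(gene_id = c(map$gene_pairs$gene_a, map$gene_pairs$gene_b),
                           chrom = c(map$gene_pairs$chrom_a, map$gene_pairs$chrom_b),
                           start = c(map$gene_pairs$start_a, map$gene_pairs$start_b),
                           end = c(map$gene_pairs$end_a, map$gene_pairs$end_b),
                           stringsAsFactors = FALSE)
    telomere_enrichment(genic_calls, gene_ann, chrom_sizes,
                        window = config$telomere_window)
  } else NULL
  sharing <- sharing_summary(if (is.null(he_tab)) bind_he_calls(list()) else
    he_tab[he_tab$class == "segmental", , drop = FALSE])
  log_stage("callhe", c(calls = he_path),
            params = list(min_size = 2e4, dup_band = c(1.5, 3), del_max = 0.5))

  ## 6. curate --------------------------------------------------------------
  curation <- curate_sim_genes(sim)
  cur_path <- file.path(outdir, "curation_calls.tsv")
  utils::write.table(curation, cur_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fract <- fractionation_test(curation$status[curation$target == "PFA"],
                              curation$status[curation$target == "PFB"])
  log_stage("curate", c(calls = cur_path), params = list(deletion_threshold = 0.2))

  ## 7. date ----------------------------------------------------------------
  pairs_ab <- sim_coding_pairs(sim, c("PFA", "PFB"))
  ds_vals <- vapply(seq_len(nrow(pairs_ab)), function(i)
    ng86(pairs_ab$seq_a[i], pairs_ab$seq_b[i])$dS, numeric(1))
  ds_dist <- ds_distribution(ds_vals)
  dating <- list(ds_mode = ds_dist$mode,
                 time_years = divergence_time(ds_dist$mode, neutral_rate))
  ds_path <- file.path(outdir, "ds_pairs.tsv")
  utils::write.table(data.frame(gene_id = pairs_ab$gene_id, dS = ds_vals),
                     ds_path, sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("date", c(ds = ds_path), params = list(rate = neutral_rate))

  ## 8. bias ----------------------------------------------------------------
  bias <- summarize_bias(sim$expression)
  bias_path <- file.path(outdir, "expression_bias.tsv")
  utils::write.table(bias$ratios, bias_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log_stage("bias", c(ratios = bias_path), params = list(bin = 0.05))

  manifest$n_stages <- length(manifest$stages)
  man_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)

  structure(list(
    sim = sim, config = config,
    partition = partition, intervals = intervals, mutation_calls = calls,
    spectra = spectra, comparison = comparison,
    he_calls = list(segmental = seg_calls, genic = genic_calls,
                    balanced = balanced_calls, nonreciprocal = nonrec_calls),
    enrichment = enrichment, sharing = sharing,
    curation = curation, fractionation = fract,
    dating = dating, ds = ds_vals, bias = bias,
    manifest = manifest, outdir = outdir
  ), class = "pf_run")
}

#' @export
print.pf_run <- function(x, ...) {
  cat(sprintf("polyforge run (seed %d): %d stages -> %s\n",
              x$config$seed, x$manifest$n_stages, x$outdir))
  invisible(x)
}

reciprocal_overlap1 <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2))
  min(ov / (e1 - s1), ov / (e2 - s2))
}

#' Score pipeline outputs against the simulator truth set
#'
#' Computes recall and precision per stage: exact-position matching for
#' mutation calls, reciprocal-overlap (>= 0.5) matching for exchange calls
#' restricted to events the caller can see (detectable sizes, correct
#' class), window accuracy for the partition, and per-copy agreement for
#' gene fates.
#'
#' @param run a `pf_run` from [run_pipeline()].
#' @return data.frame stage / metric / value.
#' @export
evaluate_against_truth <- function(run) {
  sim <- run$sim
  out <- list()
  add <- function(stage, metric, value)
    out[[length(out) + 1L]] <<- data.frame(stage = stage, metric = metric,
                                           value = value, stringsAsFactors = FALSE)

  ## partition
  truth_org <- window_origins(sim)
  add("partition", "accuracy", partition_accuracy(run$partition, truth_org))

  ## mutations: exact carrier/position/derived-base match, scored on the
  ## AA-interpretable carriers (PFA, PC02).  PFB and PC99 calls additionally
  ## carry progenitor/accession divergence -- real 1:3 columns, but not de
  ## novo mutations -- so they are excluded from recovery scoring just as
  ## they are from the headline tetraploid-vs-diploid contrast.
  tm <- sim$truth$mutations
  tm <- tm[tm$lineage %in% c("PFA", "PC02"), , drop = FALSE]
  truth_key <- paste(tm$lineage, tm$block, tm$pos - 1L, tm$der)
  calls <- run$mutation_calls
  calls <- calls[calls$carrier %in% c("PFA", "PC02"), , drop = FALSE]
  call_key <- paste(calls$carrier, calls$block, calls$column, calls$der)
  add("callmut", "recall", mean(truth_key %in% call_key))
  add("callmut", "precision", mean(call_key %in% truth_key))

  ## segmental HEs
  th <- sim$truth$hes
  if (!is.null(th)) {
    seg_t <- th[th$class == "segmental" & th$detectable, , drop = FALSE]
    seg_c <- run$he_calls$segmental
    matched_t <- vapply(seq_len(nrow(seg_t)), function(i) {
      any(vapply(seq_len(nrow(seg_c)), function(j)
        seg_c$donor_chrom[j] == seg_t$donor_chrom[i] &&
          reciprocal_overlap1(seg_c$donor_start[j], seg_c$donor_end[j],
                              seg_t$donor_start[i], seg_t$donor_end[i]) >= 0.5,
        logical(1)))
    }, logical(1))
    matched_c <- vapply(seq_len(nrow(seg_c)), function(j) {
      any(vapply(seq_len(nrow(seg_t)), function(i)
        seg_c$donor_chrom[j] == seg_t$donor_chrom[i] &&
          reciprocal_overlap1(seg_c$donor_start[j], seg_c$donor_end[j],
                              seg_t$donor_start[i], seg_t$donor_end[i]) >= 0.5,
        logical(1)))
    }, logical(1))
    if (nrow(seg_t)) add("callhe", "segmental_recall", mean(matched_t))
    if (nrow(seg_c)) add("callhe", "segmental_precision", mean(matched_c))
  }

  ## gene fates
  fates <- sim$truth$gene_fates
  cur <- run$curation
  for (sub in c("A", "B")) {
    tr <- fates[fates$subgenome == sub, ]
    got <- cur[cur$target == (if (sub == "A") "PFA" else "PFB"), ]
    m <- match(tr$gene_id, got$gene_id)
    add("curate", paste0("fate_accuracy_", sub),
        mean(tr$status == got$status[m], na.rm = TRUE))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
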