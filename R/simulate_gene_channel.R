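# ---------------------------------------------------------------------------
# Gene-level sequence channel of the simulator: per-gene five-row alignments
# (an intact guide plus the four lineage copies) carrying the planted gene
# fates, used to test comparative curation and to provide coding pairs for
# dS estimation.  Coding sequences are generated independently of the
# genome-scale substitution channel (same divergence parameters) so that
# codon structure can be controlled: lineage substitutions are rejected when
# they would create a stop codon, keeping 'intact' copies truly intact.
# ---------------------------------------------------------------------------

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

# substitute CDS sites at rate q without creating stop codons or touching
# the terminal stop codon
mutate_cds <- function(nt, q) {
  n <- length(nt)
  hit <- which(stats::runif(n - 3) < q)  # spare the terminal stop codon
  for (p in hit) {
    old <- nt[p]
    new <- sample(setdiff(.base_alphabet, old), 1)
    codon_i <- (p - 1) %/% 3
    cod <- nt[codon_i * 3 + 1:3]
    cod[(p - 1) %% 3 + 1] <- new
    if (!(paste(cod, collapse = "") %in% c("TAA", "TAG", "TGA"))) nt[p] <- new
  }
  nt
}

#' Generate per-gene five-row alignments carrying the planted gene fates
#'
#' For every gene in the truth set an ancestral CDS (sense codons plus a
#' terminal stop) is evolved along the lineage tree with the configured
#' divergences and de novo rates; the planted subgenome fates are then
#' materialized on the PFA/PFB rows (premature TAA stop, 1-bp frameshift
#' deletion, whole-row deletion, or a 6-bp in-frame deletion on flagged
#' intact copies).  Rows of minus-strand genes are emitted in genome
#' orientation (reverse-complemented).
#'
#' @param sim a `pf_sim` after [plant_genes()].
#' @return list (one element per gene) of `list(model, aln)` where `aln` has
#'   rows `guide, PFA, PFB, PC02, PC99`.
#' @export
sim_gene_alignments <- function(sim) {
  config <- sim$config
  genes <- sim$truth$genes
  fates <- sim$truth$gene_fates
  if (is.null(genes)) stop("plant_genes() must run first")
  withr::with_seed(stage_seed(config, "genes") + 17L, {
    qa <- config$progenitor_divergence / 2
    lapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      n_codon <- g$length / 3
      anc <- c(unlist(strsplit(sample(SENSE_CODONS, n_codon - 1, replace = TRUE), "")),
               c("T", "A", "A"))
      aa_cds <- mutate_cds(anc, qa)
      bb_cds <- mutate_cds(anc, qa)
      rows <- list(
        guide = anc,
        PFA  = mutate_cds(aa_cds, config$tetraploid_mutation_rate),
        PFB  = mutate_cds(bb_cds, config$tetraploid_mutation_rate),
        PC02 = mutate_cds(aa_cds, config$diploid_mutation_rate),
        PC99 = mutate_cds(mutate_cds(aa_cds, config$pc99_divergence),
                          config$diploid_mutation_rate)
      )
      for (sub in c("A", "B")) {
        f <- fates[fates$gene_id == g$gene_id & fates$subgenome == sub, ]
        row_name <- if (sub == "A") "PFA" else "PFB"
        nt <- rows[[row_name]]
        if (f$status == "deleted") {
          nt[] <- "-"
        } else if (f$status == "pseudogene" && f$defect == "premature_stop") {
          k <- sample(2:(n_codon - 2), 1)
          nt[(k - 1) * 3 + 1:3] <- c("T", "A", "A")
        } else if (f$status == "pseudogene" && f$defect == "frameshift_indel") {
          p <- sample(4:(length(nt) - 6), 1)
          nt[p] <- "-"
        } else if (f$status == "intact" && identical(f$defect, "inframe_deletion")) {
          k <- sample(2:(n_codon - 3), 1)
          nt[(k - 1) * 3 + 1:6] <- "-"
        }
        rows[[row_name]] <- nt
      }
      aln <- do.call(rbind, rows)
      if (g$strand == "-") {
        aln <- aln[, ncol(aln):1, drop = FALSE]
        aln[] <- ifelse(aln == "-", "-", comp_base(aln))
      }
      rownames(aln) <- names(rows)
      model <- gene_model(g$gene_id,
                          data.frame(start = 0L, end = g$length),
                          strand = g$strand, chrom = g$block)
      list(model = model, aln = aln)
    })
  })
}

#' Run comparative curation over the simulated gene channel
#'
#' @param sim a `pf_sim`.
#' @param targets rows to classify (default PFA and PFB).
#' @return data.frame of curation calls (gene_id, target, status, defects,
#'   fraction_cds_alignable).
#' @export
curate_sim_genes <- function(sim, targets = c("PFA", "PFB")) {
  gas <- sim_gene_alignments(sim)
  rows <- list()
  for (ga in gas) {
    for (tr in targets) {
      call <- project_and_classify(ga$model, ga$aln, tr)
      rows[[length(rows) + 1L]] <- curation_table(list(call))
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Extract in-frame coding pairs for divergence estimation
#'
#' Returns plus-strand, in-frame CDS strings for the requested pair of rows,
#' restricted to genes where both copies are free of indels (NG86 operates
#' on aligned codons).
#'
#' @param sim a `pf_sim`.
#' @param rows two row names (default PFA vs PFB).
#' @return data.frame gene_id, seq_a, seq_b.
#' @export
sim_coding_pairs <- function(sim, rows = c("PFA", "PFB")) {
  gas <- sim_gene_alignments(sim)
  out <- list()
  for (ga in gas) {
    a <- ga$aln[rows[1], ]
    b <- ga$aln[rows[2], ]
    if (any(a == "-") || any(b == "-")) next
    if (ga$model$strand == "-") { a <- revcomp_chars(a); b <- revcomp_chars(b) }
    # restrict to structurally intact pairs: premature-stop pseudogenes are
    # not valid coding pairs for codon-based divergence
    has_internal_stop <- function(nt) {
      cod <- split_codons(nt)
      any(cod[-length(cod)] %in% c("TAA", "TAG", "TGA"))
    }
    if (has_internal_stop(a) || has_internal_stop(b)) next
    out[[length(out) + 1L]] <- data.frame(
      gene_id = ga$model$gene_id,
      seq_a = paste(a, collapse = ""), seq_b = paste(b, collapse = ""),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
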