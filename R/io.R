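# ---------------------------------------------------------------------------
# File-format plumbing: FASTA genomes, bedGraph depth tracks, GFF3 gene
# models, TSV synteny maps / truth sets / expression tables.
# ---------------------------------------------------------------------------

#' Write simulated genomes to FASTA
#'
#' One file per lineage; sequence names are the native chromosome names.
#'
#' @param sim a `pf_sim`.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_genome_fasta <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (lin in LINEAGES) {
    seqs <- vapply(names(sim$genomes[[lin]]), function(b)
      decode_seq(sim$genomes[[lin]][[b]]), character(1))
    names(seqs) <- native_chrom(names(sim$genomes[[lin]]), lin)
    x <- Biostrings::DNAStringSet(seqs)
    p <- file.path(dir, paste0(lin, ".fa"))
    Biostrings::writeXStringSet(x, p)
    paths[lin] <- p
  }
  invisible(paths)
}

#' Write / read a depth track as bedGraph
#'
#' Plain 4-column bedGraph (chrom, start, end, depth; 0-based half-open).
#'
#' @param track a [depth_track()].
#' @param path bedGraph file.
#' @return `path` / a [depth_track()].
#' @export
write_depth_bedgraph <- function(track, path) {
  df <- data.frame(track$chrom,
                   format(track$start, scientific = FALSE, trim = TRUE),
                   format(track$end, scientific = FALSE, trim = TRUE),
                   track$depth)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_bedgraph
#' @param sample,reference identifiers attached to the returned track.
#' @export
read_depth_bedgraph <- function(path, sample = basename(path),
                                reference = "reference") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "depth"),
                          colClasses = c("character", "numeric", "numeric", "numeric"))
  depth_track(df$chrom, df$start, df$end, df$depth,
              sample = sample, reference = reference)
}

#' Write / read gene models as GFF3
#'
#' Minimal single-CDS gene models (one `gene` feature per gene).
#'
#' @param genes data.frame with gene_id, chrom, start, end (0-based
#'   half-open), strand.
#' @param path GFF3 file.
#' @return `path` / the data.frame.
#' @export
write_genes_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- sprintf("%s\tpolyforge\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chrom, genes$start + 1L, genes$end,
                   genes$strand, genes$gene_id)
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_genes_gff3
#' @export
read_genes_gff3 <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = c("chrom", "source", "type", "start",
                                        "end", "score", "strand", "frame",
                                        "attributes"),
                          colClasses = "character")
  df <- df[df$type == "gene", , drop = FALSE]
  data.frame(
    gene_id = sub("^ID=([^;]+).*$", "\\1", df$attributes),
    chrom = df$chrom,
    start = as.numeric(df$start) - 1,
    end = as.numeric(df$end),
    strand = df$strand,
    stringsAsFactors = FALSE
  )
}

#' Write / read a synteny map as TSV
#'
#' Two files: segment pairs and gene pairs.
#'
#' @param map list with `$segments` and `$gene_pairs`.
#' @param dir directory for `synteny_segments.tsv` / `synteny_gene_pairs.tsv`.
#' @return file paths / the map list.
#' @export
write_synteny_map <- function(map, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "synteny_segments.tsv")
  p2 <- file.path(dir, "synteny_gene_pairs.tsv")
  utils::write.table(map$segments, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(map$gene_pairs))
    utils::write.table(map$gene_pairs, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(segments = p1, gene_pairs = p2))
}

#' @rdname write_synteny_map
#' @export
read_synteny_map <- function(dir) {
  p1 <- file.path(dir, "synteny_segments.tsv")
  p2 <- file.path(dir, "synteny_gene_pairs.tsv")
  list(
    segments = utils::read.table(p1, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE),
    gene_pairs = if (file.exists(p2))
      utils::read.table(p2, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    else NULL
  )
}

#' Write the simulator truth set as TSV files
#'
#' @param sim a `pf_sim`.
#' @param dir output directory.
#' @return named paths, invisibly.
#' @export
write_truth_set <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wr <- function(df, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[name] <<- p
  }
  wr(sim$truth$mutations, "truth_mutations")
  if (!is.null(sim$truth$hes)) wr(sim$truth$hes, "truth_hes")
  if (!is.null(sim$truth$genes)) wr(sim$truth$genes, "truth_genes")
  if (!is.null(sim$truth$gene_fates)) wr(sim$truth$gene_fates, "truth_gene_fates")
  wr(window_origins(sim), "truth_window_origins")
  invisible(paths)
}

#' Read truth-set TSVs back
#'
#' @param dir directory written by [write_truth_set()].
#' @return list of data.frames.
#' @export
read_truth_set <- function(dir) {
  rd <- function(name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    if (file.exists(p))
      utils::read.table(p, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                        colClasses = NA)
    else NULL
  }
  list(mutations = rd("truth_mutations"), hes = rd("truth_hes"),
       genes = rd("truth_genes"), gene_fates = rd("truth_gene_fates"),
       window_origins = rd("truth_window_origins"))
}
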