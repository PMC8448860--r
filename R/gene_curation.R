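# ---------------------------------------------------------------------------
# Comparative gene curation: project a guide coding model onto an aligned
# orthologous sequence and classify the target copy as intact, pseudogene
# (premature stop and/or frameshift indel) or deleted.
# ---------------------------------------------------------------------------

#' Build a gene model
#'
#' @param gene_id identifier.
#' @param exons data.frame with `start`/`end` CDS exon intervals (0-based
#'   half-open) in the guide row's ungapped coordinate space, ordered,
#'   non-overlapping.
#' @param strand `"+"` or `"-"` (alignment rows are in genome orientation).
#' @param chrom chromosome label.
#' @return list of class `pf_gene_model`.
#' @export
gene_model <- function(gene_id, exons, strand = "+", chrom = NA_character_) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1,
            all(exons$end > exons$start))
  o <- order(exons$start)
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("overlapping exons")
  total <- sum(exons$end - exons$start)
  if (total %% 3 != 0) stop("guide CDS length must be divisible by 3")
  structure(list(gene_id = gene_id, exons = exons, strand = strand,
                 chrom = chrom, cds_length = total),
            class = "pf_gene_model")
}

translate_cds <- function(nt) {
  # nt: character vector of A/C/G/T/N, length assumed >= 3
  n_codon <- floor(length(nt) / 3)
  if (n_codon == 0) return(character(0))
  codons <- paste0(nt[3 * seq_len(n_codon) - 2],
                   nt[3 * seq_len(n_codon) - 1],
                   nt[3 * seq_len(n_codon)])
  aa <- Biostrings::GENETIC_CODE[codons]
  ifelse(is.na(aa), "X", aa)
}

#' Project a guide coding model onto a target alignment row and classify it
#'
#' The guide CDS columns are spliced onto the target row.  If the alignable
#' CDS fraction falls below `deletion_threshold` the copy is `deleted`.
#' Otherwise the target CDS is translated in the guide frame, tolerating
#' in-frame indels (length divisible by 3): any internal stop codon yields a
#' `premature_stop` defect, any CDS indel of length not divisible by 3 a
#' `frameshift_indel`; a defect-free copy is `intact`.
#'
#' @param guide a [gene_model()].
#' @param aln character matrix of aligned rows (equal columns) containing a
#'   row named `guide_row` (the guide sequence) and `target_row`.
#' @param target_row name of the row to classify.
#' @param guide_row name of the guide row (default `"guide"`).
#' @param deletion_threshold alignable-CDS fraction below which the copy is
#'   called deleted.
#' @return list of class `pf_curation_call`: gene_id, target, status,
#'   defects, fraction_cds_alignable.
#' @export
project_and_classify <- function(guide, aln, target_row, guide_row = "guide",
                                 deletion_threshold = 0.2) {
  stopifnot(inherits(guide, "pf_gene_model"),
            guide_row %in% rownames(aln), target_row %in% rownames(aln))
  g <- toupper(aln[guide_row, ])
  t <- toupper(aln[target_row, ])
  gpos <- cumsum(g != "-")  # 1-based ungapped guide position per column
  in_cds_pos <- logical(max(gpos))
  for (i in seq_len(nrow(guide$exons)))
    in_cds_pos[(guide$exons$start[i] + 1):guide$exons$end[i]] <- TRUE
  cds_col <- which(g != "-" & in_cds_pos[gpos])
  if (!length(cds_col)) stop("guide CDS does not map into the alignment")
  span <- range(cds_col)
  # insertion columns: guide gaps strictly inside the CDS span and flanked by
  # consecutive CDS positions (guide gaps inside introns are not CDS events)
  gap_inside <- which(g == "-" & seq_along(g) > span[1] & seq_along(g) < span[2])
  n_cds <- max(gpos)
  ins_col <- gap_inside[in_cds_pos[pmax(gpos[gap_inside], 1L)] &
                          in_cds_pos[pmin(gpos[gap_inside] + 1L, n_cds)]]

  frac_alignable <- mean(t[cds_col] != "-")

  # validate the guide itself
  guide_nt <- g[cds_col]
  if (guide$strand == "-") guide_nt <- revcomp_chars(guide_nt)
  guide_aa <- translate_cds(guide_nt)
  if (any(guide_aa[-length(guide_aa)] == "*")) stop("invalid guide: internal stop codon")

  if (frac_alignable < deletion_threshold) {
    return(curation_call(guide$gene_id, target_row, "deleted", character(0),
                         frac_alignable))
  }

  defects <- character(0)
  # indel events within the CDS span: deletions are target gaps at CDS
  # columns, insertions are target bases at guide-gap columns inside the span
  event_cols <- sort(c(cds_col, ins_col))
  state <- ifelse(event_cols %in% ins_col,
                  ifelse(t[event_cols] != "-", "ins", "none"),
                  ifelse(t[event_cols] == "-", "del", "none"))
  r <- rle(state)
  if (any(r$values %in% c("ins", "del") & r$lengths %% 3 != 0))
    defects <- c(defects, "frameshift_indel")

  if (!("frameshift_indel" %in% defects)) {
    keep <- (event_cols %in% cds_col & t[event_cols] != "-") |
      (event_cols %in% ins_col & t[event_cols] != "-")
    target_nt <- t[event_cols][keep]
    if (guide$strand == "-") target_nt <- revcomp_chars(target_nt)
    aa <- translate_cds(target_nt)
    if (length(aa) > 1 && any(aa[-length(aa)] == "*"))
      defects <- c(defects, "premature_stop")
  }

  status <- if (length(defects)) "pseudogene" else "intact"
  curation_call(guide$gene_id, target_row, status, defects, frac_alignable)
}

curation_call <- function(gene_id, target, status, defects, frac) {
  structure(list(gene_id = gene_id, target = target, status = status,
                 defects = defects, fraction_cds_alignable = frac),
            class = "pf_curation_call")
}

#' @export
print.pf_curation_call <- function(x, ...) {
  cat(sprintf("%s [%s]: %s%s (alignable %.2f)\n", x$gene_id, x$target,
              x$status,
              if (length(x$defects)) paste0(" {", paste(x$defects, collapse = ", "), "}") else "",
              x$fraction_cds_alignable))
  invisible(x)
}

#' Curation calls as a data frame
#'
#' @param calls list of `pf_curation_call`.
#' @return data.frame: gene_id, target, status, defects (comma-joined),
#'   fraction_cds_alignable.
#' @export
curation_table <- function(calls) {
  do.call(rbind, lapply(calls, function(x) data.frame(
    gene_id = x$gene_id, target = x$target, status = x$status,
    defects = paste(x$defects, collapse = ","),
    fraction_cds_alignable = x$fraction_cds_alignable,
    stringsAsFactors = FALSE
  )))
}

#' Test subgenome fractionation asymmetry
#'
#' Builds the 2x2 table of lost (pseudogene + deleted) versus retained gene
#' copies per subgenome over the shared ancestral models and applies the
#' Pearson chi-squared test.
#'
#' @param status_a,status_b character vectors of statuses (`intact`,
#'   `pseudogene`, `deleted`) for subgenomes A and B over the same ancestral
#'   model set.
#' @return list of class `pf_fractionation`: per-subgenome loss counts and
#'   the [test_result()].
#' @export
fractionation_test <- function(status_a, status_b) {
  if (!length(status_a) || !length(status_b)) stop("empty call set")
  lost_a <- sum(status_a != "intact"); kept_a <- sum(status_a == "intact")
  lost_b <- sum(status_b != "intact"); kept_b <- sum(status_b == "intact")
  structure(list(
    counts = matrix(c(lost_a, kept_a, lost_b, kept_b), nrow = 2, byrow = TRUE,
                    dimnames = list(c("A", "B"), c("lost", "retained"))),
    test = chi_squared_2x2(lost_a, kept_a, lost_b, kept_b)
  ), class = "pf_fractionation")
}

#' @export
print.pf_fractionation <- function(x, ...) {
  print(x$counts)
  print(x$test)
  invisible(x)
}
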