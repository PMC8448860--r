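# ---------------------------------------------------------------------------
# De novo mutation calling on conserved four-way intervals: a column is a
# mutation iff exactly one row deviates from three identical rows (1:3
# genotype), all four bases are A/C/G/T, and the five columns on either side
# are gap-free and identical across all four rows.  Calls are classified into
# the 96 pyrimidine-centred trinucleotide classes.
# ---------------------------------------------------------------------------

#' Call de novo mutations on a conserved interval
#'
#' Implements the 1:3 ancestral-genotype rule with the five-identical-flank
#' filter.  A column yields a call iff (a) all four rows carry A/C/G/T, (b)
#' exactly one row differs from the other three, which are identical, and
#' (c) the `flank` columns on each side are gap-free and identical across all
#' four rows (and lie within the interval).  The carrier is the deviant row;
#' the ancestral base is the base of the three agreeing rows, whose consensus
#' also supplies the 5'/3' context bases.
#'
#' @param msa a `pf_msa`.
#' @param intervals data.frame of conserved intervals (aligned-column
#'   `start`/`end`, 0-based half-open), e.g. from [filter_intervals()];
#'   `NULL` scans the whole block as one interval.
#' @param flank number of identical flanking columns required per side.
#' @return data.frame of calls: block, column (0-based), carrier, anc, der,
#'   ctx5, ctx3, class6, class96, is_transition, chrom, pos (0-based source
#'   coordinate on the carrier row).
#' @export
call_mutations <- function(msa, intervals = NULL, flank = 5L) {
  stopifnot(inherits(msa, "pf_msa"))
  L <- ncol(msa$rows)
  if (is.null(intervals))
    intervals <- data.frame(block_id = msa$block_id, start = 0L, end = L)
  m <- matrix(match(msa$rows, c("A", "C", "G", "T")), nrow = 4L)
  valid <- colSums(!is.na(m)) == 4L
  m0 <- m; m0[is.na(m0)] <- 0L
  r1 <- m0[1, ]; r2 <- m0[2, ]; r3 <- m0[3, ]; r4 <- m0[4, ]
  conserved <- valid & r1 == r2 & r2 == r3 & r3 == r4
  carrier <- integer(L)
  carrier[valid & r2 == r3 & r3 == r4 & r1 != r2] <- 1L
  carrier[valid & r1 == r3 & r3 == r4 & r2 != r1] <- 2L
  carrier[valid & r1 == r2 & r2 == r4 & r3 != r1] <- 3L
  carrier[valid & r1 == r2 & r2 == r3 & r4 != r1] <- 4L
  cs0 <- c(0, cumsum(conserved))  # padded: sum over (a..b) = cs0[b+1]-cs0[a]
  # per-row ungapped-position cumsums for fast column -> source mapping
  ung <- lapply(seq_len(4L), function(r) cumsum(msa$rows[r, ] != "-"))
  starts <- msa$meta$start[match(rownames(msa$rows), msa$meta$role)]
  out <- list()
  for (i in seq_len(nrow(intervals))) {
    lo <- intervals$start[i] + 1L  # first column, 1-based
    hi <- intervals$end[i]
    if (hi - lo + 1L < 2L * flank + 1L) next
    cols <- (lo + flank):(hi - flank)
    cand <- cols[carrier[cols] > 0L]
    if (!length(cand)) next
    left_ok  <- (cs0[cand] - cs0[cand - flank]) == flank
    right_ok <- (cs0[cand + flank + 1L] - cs0[cand + 1L]) == flank
    cand <- cand[left_ok & right_ok]
    if (!length(cand)) next
    car <- carrier[cand]
    anc_row <- ifelse(car == 1L, 2L, 1L)
    anc <- msa$rows[cbind(anc_row, cand)]
    der <- msa$rows[cbind(car, cand)]
    ctx5 <- msa$rows[cbind(anc_row, cand - 1L)]
    ctx3 <- msa$rows[cbind(anc_row, cand + 1L)]
    carrier_role <- rownames(msa$rows)[car]
    pos <- integer(length(cand))
    for (r in 1:4) {
      sel <- car == r
      if (any(sel)) pos[sel] <- starts[r] + ung[[r]][cand[sel]] - 1L
    }
    out[[length(out) + 1L]] <- data.frame(
      block = msa$block_id, column = cand - 1L,
      carrier = carrier_role, anc = anc, der = der,
      ctx5 = ctx5, ctx3 = ctx3,
      chrom = msa$meta$chrom[match(carrier_role, msa$meta$role)],
      pos = pos, stringsAsFactors = FALSE
    )
  }
  calls <- if (length(out)) do.call(rbind, out) else data.frame(
    block = character(0), column = integer(0), carrier = character(0),
    anc = character(0), der = character(0), ctx5 = character(0),
    ctx3 = character(0), chrom = character(0), pos = integer(0),
    stringsAsFactors = FALSE)
  cls <- classify_mutation(calls$anc, calls$der, calls$ctx5, calls$ctx3)
  cbind(calls, cls)
}

#' Classify substitutions into six-class and 96-context labels
#'
#' Substitutions are strand-collapsed so the mutated base is a pyrimidine:
#' when the ancestral base is a purine the `(5', anc>der, 3')` triple is
#' reverse-complemented.  The 96-class label is `5'[anc>der]3'` over the 16
#' flanking contexts per class.  A context containing `N` yields `class96 =
#' NA` (the call is retained but excluded from 96-spectra).
#'
#' @param anc,der ancestral and derived bases (A/C/G/T), vectorized.
#' @param ctx5,ctx3 5' and 3' context bases on the reference strand.
#' @return data.frame with class6, class96, is_transition.
#' @export
classify_mutation <- function(anc, der, ctx5, ctx3) {
  stopifnot(length(anc) == length(der))
  if (!length(anc))
    return(data.frame(class6 = character(0), class96 = character(0),
                      is_transition = logical(0), stringsAsFactors = FALSE))
  if (any(anc == der)) stop("ancestral and derived base must differ")
  purine <- anc %in% c("A", "G")
  a <- ifelse(purine, comp_base(anc), anc)
  d <- ifelse(purine, comp_base(der), der)
  c5 <- ifelse(purine, comp_base(ctx3), ctx5)
  c3 <- ifelse(purine, comp_base(ctx5), ctx3)
  class6 <- paste0(a, ">", d)
  stopifnot(all(class6 %in% CLASS6))
  ok_ctx <- c5 %in% .base_alphabet & c3 %in% .base_alphabet
  class96 <- ifelse(ok_ctx, paste0(c5, "[", class6, "]", c3), NA_character_)
  data.frame(class6 = class6, class96 = class96,
             is_transition = class6 %in% c("C>T", "T>C"),
             stringsAsFactors = FALSE)
}

#' All 96 context-class labels in canonical display order
#'
#' Ordered by substitution class (`C>A` ... `T>G`) and alphabetically by
#' context within each class (`A[.]A` ... `T[.]T`), the usual signature-plot
#' layout.
#' @return character vector of length 96.
#' @export
class96_levels <- function() {
  ctx <- expand.grid(c3 = .base_alphabet, c5 = .base_alphabet,
                     stringsAsFactors = FALSE)
  ctx <- ctx[order(ctx$c5, ctx$c3), ]
  unlist(lapply(CLASS6, function(cl) paste0(ctx$c5, "[", cl, "]", ctx$c3)),
         use.names = FALSE)
}

#' Summarize a call set into a mutational spectrum
#'
#' @param calls data.frame from [call_mutations()].
#' @param lineage optional carrier lineage to restrict to.
#' @return list of class `pf_spectrum`: per-class96 and per-class6 counts,
#'   total, transition/transversion ratio (`NA` when no transversions or no
#'   calls) and the G:C -> A:T fraction (class `C>T`).
#' @export
summarize_spectrum <- function(calls, lineage = NULL) {
  if (!is.null(lineage)) calls <- calls[calls$carrier == lineage, , drop = FALSE]
  counts96 <- table(factor(calls$class96, levels = class96_levels()))
  counts6 <- table(factor(calls$class6, levels = CLASS6))
  total <- nrow(calls)
  ts <- sum(calls$is_transition)
  tv <- total - ts
  structure(list(
    lineage = if (is.null(lineage)) "all" else lineage,
    counts96 = counts96, counts6 = counts6, total = total,
    n_context_na = sum(is.na(calls$class96)),
    tstv = if (total == 0 || tv == 0) NA_real_ else ts / tv,
    gc_to_at = if (total == 0) NA_real_ else unname(counts6["C>T"]) / total
  ), class = "pf_spectrum")
}

#' @export
print.pf_spectrum <- function(x, ...) {
  cat(sprintf("mutation spectrum [%s]: %d calls, Ts/Tv = %s, G:C->A:T = %s\n",
              x$lineage, x$total,
              format(x$tstv, digits = 3), format(x$gc_to_at, digits = 3)))
  print(x$counts6)
  invisible(x)
}

#' Spectrum as a 96-row table (signature-plot layout)
#'
#' @param spectrum a `pf_spectrum`.
#' @return data.frame with class96, class6, context, count, fraction.
#' @export
spectrum_table <- function(spectrum) {
  lev <- class96_levels()
  data.frame(
    class96 = lev,
    class6 = sub("^.\\[(.>.)\\].$", "\\1", lev),
    context = sub("^(.)\\[.>.\\](.)$", "\\1N\\2", lev),
    count = as.integer(spectrum$counts96[lev]),
    fraction = if (spectrum$total > 0)
      as.numeric(spectrum$counts96[lev]) / sum(spectrum$counts96) else 0,
    stringsAsFactors = FALSE
  )
}

#' Contrast mutation burden between two carrier lineages
#'
#' Pairs per-unit (chromosome or block) counts for the two lineages, reports
#' the percent excess of lineage `a` over lineage `b` from the totals, and a
#' one-sided paired t test of the per-unit counts.  The headline contrast is
#' PFA (tetraploid AA) versus PC02 (diploid AA); PFB/PC99 tallies are not
#' interpretable as subgenome-specific because the BB diploid is unsampled.
#'
#' @param calls data.frame from [call_mutations()] (multi-block).
#' @param unit pairing unit: `"chrom"` or `"block"`.
#' @param lineage_a,lineage_b carrier lineages to contrast.
#' @return list of class `pf_lineage_comparison`.
#' @export
compare_lineages <- function(calls, unit = c("chrom", "block"),
                             lineage_a = "PFA", lineage_b = "PC02") {
  unit <- match.arg(unit)
  key <- if (unit == "chrom") calls$chrom else calls$block
  # chromosome names differ between lineages (A vs B subgenome); pair on the
  # orthologous block instead when carriers live on different chromosomes
  if (unit == "chrom" && "block" %in% names(calls)) key <- calls$block
  units <- sort(unique(key))
  na <- vapply(units, function(u) sum(key == u & calls$carrier == lineage_a), numeric(1))
  nb <- vapply(units, function(u) sum(key == u & calls$carrier == lineage_b), numeric(1))
  excess <- 100 * (sum(na) - sum(nb)) / sum(nb)
  test <- tryCatch(paired_t_one_sided(na, nb), error = function(e) NULL)
  structure(list(
    unit = unit, units = units,
    counts = data.frame(unit = units, n_a = na, n_b = nb),
    lineage_a = lineage_a, lineage_b = lineage_b,
    excess_percent = excess, test = test
  ), class = "pf_lineage_comparison")
}

#' @export
print.pf_lineage_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s over %d %ss: totals %d vs %d, excess %.1f%%\n",
              x$lineage_a, x$lineage_b, length(x$units), x$unit,
              sum(x$counts$n_a), sum(x$counts$n_b), x$excess_percent))
  if (!is.null(x$test)) print(x$test) else cat("  paired test: NA (degenerate differences)\n")
  invisible(x)
}
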