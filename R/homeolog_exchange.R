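# ---------------------------------------------------------------------------
# Homeologous-exchange detection from depth dichotomy: candidate duplications
# at 1.5-3x of the sample mean whose homeologous interval sits below 0.5x,
# with a 20-kb minimal size at the segmental level, gene-pair resolution
# below it, balanced (2:2) exchanges from the diploid-coverage partition, and
# 3:1 nonreciprocal events from intermediate dosage bands.
# ---------------------------------------------------------------------------

# depth ratios in units of the sample genome-wide mean
depth_ratio <- function(track) track$depth / mean(track$depth)

# map an interval through the segment-pair synteny map; returns a one-row
# data.frame or NULL when the interval has no homeologous mapping
map_homeolog_interval <- function(map, chrom, start, end) {
  seg <- map$segments
  hitA <- which(seg$chrom_a == chrom & seg$start_a < end & seg$end_a > start)
  hitB <- which(seg$chrom_b == chrom & seg$start_b < end & seg$end_b > start)
  if (length(hitA)) {
    s <- seg[hitA[1], ]
    scale <- (s$end_b - s$start_b) / (s$end_a - s$start_a)
    data.frame(chrom = s$chrom_b,
               start = s$start_b + (max(start, s$start_a) - s$start_a) * scale,
               end = s$start_b + (min(end, s$end_a) - s$start_a) * scale)
  } else if (length(hitB)) {
    s <- seg[hitB[1], ]
    scale <- (s$end_a - s$start_a) / (s$end_b - s$start_b)
    data.frame(chrom = s$chrom_a,
               start = s$start_a + (max(start, s$start_b) - s$start_b) * scale,
               end = s$start_a + (min(end, s$end_b) - s$start_b) * scale)
  } else NULL
}

# mean depth ratio over windows overlapping [start, end) on chrom
interval_mean_ratio <- function(track, ratio, chrom, start, end) {
  sel <- track$chrom == chrom & track$start < end & track$end > start
  if (!any(sel)) return(NA_real_)
  w <- pmin(track$end[sel], end) - pmax(track$start[sel], start)
  sum(ratio[sel] * w) / sum(w)
}

# maximal candidate runs of in-band windows, with single-window gap filling
# when the gap window still exceeds gap_min_ratio (robustness to Poisson
# jitter at moderate depth)
candidate_runs <- function(track, ratio, band, gap_fill = 1L,
                           gap_min_ratio = 1.2) {
  out <- list()
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    seed <- ratio[idx] > band[1] & ratio[idx] < band[2]
    if (gap_fill > 0 && length(idx) > 2) {
      r <- rle(seed)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      fill <- which(!r$values & r$lengths <= gap_fill &
                      seq_along(r$values) > 1 &
                      seq_along(r$values) < length(r$values))
      for (i in fill) {
        gap_idx <- starts[i]:ends[i]
        if (all(ratio[idx[gap_idx]] > gap_min_ratio)) seed[gap_idx] <- TRUE
      }
    }
    r <- rle(seed)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = track$start[idx[starts[i]]],
        end = track$end[idx[ends[i]]],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
}

#' Call segmental (4:0) homeologous exchanges from a depth track
#'
#' Maximal runs of windows with depth ratio inside the open duplication band
#' form candidate duplications; a candidate becomes a call iff its
#' homeologous interval (via the synteny map) has mean ratio below
#' `del_max`, and either interval spans at least `min_size` bp.  Candidates
#' without a homeologous mapping are reported with class `"unresolved"`.
#'
#' @param track a [depth_track()] for one tetraploid sample.
#' @param map synteny map (list with `$segments`), e.g. [sim_synteny_map()].
#' @param min_size minimal event size in bp.
#' @param dup_band open interval of duplication depth ratios.
#' @param del_max strict upper bound of the deletion depth ratio.
#' @return data.frame of HE calls (class, sample, donor/recipient intervals,
#'   size, mean ratios, direction).
#' @export
call_segmental_he <- function(track, map, min_size = 2e4,
                              dup_band = c(1.5, 3), del_max = 0.5) {
  ratio <- depth_ratio(track)
  cands <- candidate_runs(track, ratio, dup_band)
  out <- list()
  for (i in seq_len(nrow(cands))) {
    ca <- cands[i, ]
    dup_ratio <- interval_mean_ratio(track, ratio, ca$chrom, ca$start, ca$end)
    if (!(dup_ratio > dup_band[1] && dup_ratio < dup_band[2])) next
    hom <- map_homeolog_interval(map, ca$chrom, ca$start, ca$end)
    if (is.null(hom)) {
      out[[length(out) + 1L]] <- he_call_row("unresolved", track, ca$chrom,
                                             ca$start, ca$end, NA, NA, NA,
                                             dup_ratio, NA)
      next
    }
    rec_ratio <- interval_mean_ratio(track, ratio, hom$chrom, hom$start, hom$end)
    if (is.na(rec_ratio) || rec_ratio >= del_max) next
    size <- max(ca$end - ca$start, hom$end - hom$start)
    if (size < min_size) next
    out[[length(out) + 1L]] <- he_call_row("segmental", track, ca$chrom,
                                           ca$start, ca$end, hom$chrom,
                                           hom$start, hom$end, dup_ratio,
                                           rec_ratio)
  }
  bind_he_calls(out)
}

he_call_row <- function(class, track, dchrom, dstart, dend, rchrom, rstart,
                        rend, dratio, rratio) {
  sub_of <- function(ch) if (is.na(ch)) NA_character_ else substr(ch, 1, 1)
  data.frame(
    class = class, sample = attr(track, "sample"),
    donor_chrom = dchrom, donor_start = dstart, donor_end = dend,
    recip_chrom = rchrom, recip_start = rstart, recip_end = rend,
    size = max(dend - dstart, if (is.na(rstart)) 0 else rend - rstart),
    donor_ratio = dratio, recip_ratio = rratio,
    direction = if (is.na(rchrom)) NA_character_ else
      paste0(sub_of(dchrom), "->", sub_of(rchrom)),
    stringsAsFactors = FALSE
  )
}

bind_he_calls <- function(rows) {
  if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame(class = character(0), sample = character(0),
               donor_chrom = character(0), donor_start = numeric(0),
               donor_end = numeric(0), recip_chrom = character(0),
               recip_start = numeric(0), recip_end = numeric(0),
               size = numeric(0), donor_ratio = numeric(0),
               recip_ratio = numeric(0), direction = character(0),
               stringsAsFactors = FALSE)
}

#' Call genic homeologous exchanges (gene conversions)
#'
#' Applies the segmental depth bands at gene-pair resolution: a homeologous
#' gene pair where one copy sits in the duplication band and its partner
#' below the deletion bound is a genic HE.  Gene depth is the base-weighted
#' mean ratio over overlapping windows.
#'
#' @param track a [depth_track()] for one sample.
#' @param gene_pairs data.frame with gene_a/chrom_a/start_a/end_a and the
#'   `_b` counterparts (see [sim_synteny_map()]).
#' @inheritParams call_segmental_he
#' @return data.frame of genic HE calls with gene ids.
#' @export
call_genic_he <- function(track, gene_pairs, dup_band = c(1.5, 3),
                          del_max = 0.5) {
  ratio <- depth_ratio(track)
  ra <- vapply(seq_len(nrow(gene_pairs)), function(i)
    interval_mean_ratio(track, ratio, gene_pairs$chrom_a[i],
                        gene_pairs$start_a[i], gene_pairs$end_a[i]), numeric(1))
  rb <- vapply(seq_len(nrow(gene_pairs)), function(i)
    interval_mean_ratio(track, ratio, gene_pairs$chrom_b[i],
                        gene_pairs$start_b[i], gene_pairs$end_b[i]), numeric(1))
  a_dup <- !is.na(ra) & !is.na(rb) & ra > dup_band[1] & ra < dup_band[2] & rb < del_max
  b_dup <- !is.na(ra) & !is.na(rb) & rb > dup_band[1] & rb < dup_band[2] & ra < del_max
  rows <- list()
  add <- function(i, donor_is_a) {
    d <- if (donor_is_a) "a" else "b"; r <- if (donor_is_a) "b" else "a"
    g <- gene_pairs[i, ]
    data.frame(
      class = "genic", sample = attr(track, "sample"),
      donor_gene = g[[paste0("gene_", d)]], recip_gene = g[[paste0("gene_", r)]],
      donor_chrom = g[[paste0("chrom_", d)]],
      donor_start = g[[paste0("start_", d)]], donor_end = g[[paste0("end_", d)]],
      recip_chrom = g[[paste0("chrom_", r)]],
      recip_start = g[[paste0("start_", r)]], recip_end = g[[paste0("end_", r)]],
      donor_ratio = if (donor_is_a) ra[i] else rb[i],
      recip_ratio = if (donor_is_a) rb[i] else ra[i],
      direction = if (donor_is_a) "A->B" else "B->A",
      stringsAsFactors = FALSE
    )
  }
  for (i in which(a_dup)) rows[[length(rows) + 1L]] <- add(i, TRUE)
  for (i in which(b_dup)) rows[[length(rows) + 1L]] <- add(i, FALSE)
  if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame(class = character(0), sample = character(0),
               donor_gene = character(0), recip_gene = character(0),
               donor_chrom = character(0), donor_start = numeric(0),
               donor_end = numeric(0), recip_chrom = character(0),
               recip_start = numeric(0), recip_end = numeric(0),
               donor_ratio = numeric(0), recip_ratio = numeric(0),
               direction = character(0), stringsAsFactors = FALSE)
}

#' Call balanced (2:2) homeologous exchanges from a diploid-coverage partition
#'
#' A balanced exchange is dosage-neutral and invisible in the tetraploid's
#' own depth; it shows as an origin island in the diploid-onto-tetraploid
#' partition: an AA-origin island embedded in BB context whose homeologous
#' interval is a reciprocal BB-origin island in AA context.  Islands must be
#' flanked on both sides by at least `min_flank` windows of the surrounding
#' origin.  Islands whose partner does not switch are reported `"one_sided"`.
#'
#' @param partition a `pf_partition` of the diploid-onto-tetraploid track.
#' @param map synteny map.
#' @param min_flank minimal flanking tract length in windows.
#' @return data.frame of balanced calls and one-sided records.
#' @export
call_balanced_he <- function(partition, map, min_flank = 10L) {
  b <- partition$blocks
  rows <- list()
  seen <- character(0)
  for (ch in unique(b$chrom)) {
    cb <- b[b$chrom == ch, , drop = FALSE]
    if (nrow(cb) < 3) next
    bp <- tapply(cb$end - cb$start, cb$origin, sum)
    dominant <- names(bp)[which.max(bp)]
    for (i in 2:(nrow(cb) - 1)) {
      if (cb$origin[i] == dominant) next
      if (cb$origin[i - 1] != dominant || cb$origin[i + 1] != dominant) next
      if (cb$n_windows[i - 1] < min_flank || cb$n_windows[i + 1] < min_flank) next
      hom <- map_homeolog_interval(map, ch, cb$start[i], cb$end[i])
      if (is.null(hom)) next
      # fraction of the partner interval that switched origin (i.e. carries
      # the island origin's opposite on a chromosome of opposite dominance)
      wo <- partition$window_origins
      sel <- wo$chrom == hom$chrom & wo$start < hom$end & wo$end > hom$start
      if (!any(sel)) next
      switched <- mean(wo$origin[sel] == dominant)
      key <- paste(sort(c(paste(ch, cb$start[i]), paste(hom$chrom, round(hom$start)))),
                   collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <- data.frame(
        class = if (switched >= 0.5) "balanced" else "one_sided",
        donor_chrom = ch, donor_start = cb$start[i], donor_end = cb$end[i],
        recip_chrom = hom$chrom, recip_start = hom$start, recip_end = hom$end,
        size = cb$end[i] - cb$start[i],
        island_origin = cb$origin[i], switched_fraction = switched,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame(class = character(0), donor_chrom = character(0),
               donor_start = numeric(0), donor_end = numeric(0),
               recip_chrom = character(0), recip_start = numeric(0),
               recip_end = numeric(0), size = numeric(0),
               island_origin = character(0), switched_fraction = numeric(0),
               stringsAsFactors = FALSE)
}

#' Call nonreciprocal (3:1) exchanges on candidate interval pairs
#'
#' The gene-conversion-like dosage signature: three copies of one interval
#' and one of its (non-homeologous) partner, i.e. depth ratios near 1.5 and
#' 0.5.  Ratios falling in the segmental 4:0 bands instead are left to the
#' segmental caller.
#'
#' @param track a [depth_track()].
#' @param candidates data.frame with chrom_a/start_a/end_a (putative
#'   triplicated) and chrom_b/start_b/end_b (putative single-copy) pairs.
#' @param dup_band,del_band open acceptance bands for the 3- and 1-copy sides.
#' @return data.frame of nonreciprocal calls.
#' @export
call_nonreciprocal_he <- function(track, candidates,
                                  dup_band = c(1.25, 1.75),
                                  del_band = c(0.25, 0.75)) {
  ratio <- depth_ratio(track)
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    ca <- candidates[i, ]
    r3 <- interval_mean_ratio(track, ratio, ca$chrom_a, ca$start_a, ca$end_a)
    r1 <- interval_mean_ratio(track, ratio, ca$chrom_b, ca$start_b, ca$end_b)
    if (is.na(r3) || is.na(r1)) next
    if (r3 > dup_band[1] && r3 < dup_band[2] && r1 > del_band[1] && r1 < del_band[2]) {
      rows[[length(rows) + 1L]] <- data.frame(
        class = "nonreciprocal", sample = attr(track, "sample"),
        donor_chrom = ca$chrom_a, donor_start = ca$start_a, donor_end = ca$end_a,
        recip_chrom = ca$chrom_b, recip_start = ca$start_b, recip_end = ca$end_b,
        size = ca$end_a - ca$start_a,
        donor_ratio = r3, recip_ratio = r1, direction = NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    bind_he_calls(list())
}

#' Scan a track for intermediate-dosage runs (3:1 candidates)
#'
#' Helper that pairs runs in the 3-copy band with equal-scale runs in the
#' 1-copy band (closest size first) to feed [call_nonreciprocal_he()].
#'
#' @param track a [depth_track()].
#' @param min_size minimal run span in bp.
#' @inheritParams call_nonreciprocal_he
#' @return candidate data.frame (possibly empty).
#' @export
scan_nonreciprocal_candidates <- function(track, min_size = 2e4,
                                          dup_band = c(1.25, 1.75),
                                          del_band = c(0.25, 0.75)) {
  ratio <- depth_ratio(track)
  up <- candidate_runs(track, ratio, dup_band, gap_fill = 1L, gap_min_ratio = 1.1)
  dn <- candidate_runs(track, ratio, del_band, gap_fill = 1L, gap_min_ratio = 0.1)
  up <- up[up$end - up$start >= min_size, , drop = FALSE]
  dn <- dn[dn$end - dn$start >= min_size, , drop = FALSE]
  rows <- list()
  used <- logical(nrow(dn))
  for (i in seq_len(nrow(up))) {
    if (!nrow(dn)) break
    sz <- up$end[i] - up$start[i]
    j <- order(abs((dn$end - dn$start) - sz))
    j <- j[!used[j]][1]
    if (is.na(j)) next
    used[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      chrom_a = up$chrom[i], start_a = up$start[i], end_a = up$end[i],
      chrom_b = dn$chrom[j], start_b = dn$start[j], end_b = dn$end[j],
      stringsAsFactors = FALSE
    )
  }
  if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame(chrom_a = character(0), start_a = numeric(0), end_a = numeric(0),
               chrom_b = character(0), start_b = numeric(0), end_b = numeric(0),
               stringsAsFactors = FALSE)
}

#' Telomere enrichment of genic exchanges
#'
#' Observed: genic-HE genes overlapping the first or last `window` bp of
#' their chromosome.  Expected proportion: the fraction of all annotated
#' genes in those regions.  One-sided exact binomial test.
#'
#' @param genic_calls data.frame from [call_genic_he()] (any sample union).
#' @param genes annotation data.frame: gene_id, chrom, start, end.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param window telomeric span at each end (bp).
#' @return list of class `pf_enrichment`: observed, total, expected
#'   proportion and the [test_result()].
#' @export
telomere_enrichment <- function(genic_calls, genes, chrom_sizes, window = 2e6) {
  if (window >= min(chrom_sizes) / 2) stop("degenerate window: telomere window covers the chromosome")
  near_telomere <- function(chrom, start, end) {
    len <- chrom_sizes[chrom]
    (start < window) | (end > len - window)
  }
  gene_near <- near_telomere(genes$chrom, genes$start, genes$end)
  p0 <- mean(gene_near)
  he_genes <- unique(c(genic_calls$donor_gene, genic_calls$recip_gene))
  he_genes <- he_genes[!is.na(he_genes)]
  # evaluate positions of the HE genes via the annotation
  idx <- match(he_genes, genes$gene_id)
  idx <- idx[!is.na(idx)]
  observed <- sum(near_telomere(genes$chrom[idx], genes$start[idx], genes$end[idx]))
  total <- length(idx)
  structure(list(
    observed = observed, total = total, expected_proportion = p0,
    test = exact_binomial(observed, total, p0, "one_sided_greater")
  ), class = "pf_enrichment")
}

#' @export
print.pf_enrichment <- function(x, ...) {
  cat(sprintf("telomere enrichment: %d/%d genic-HE genes near telomeres (expected %.1f%%)\n",
              x$observed, x$total, 100 * x$expected_proportion))
  print(x$test)
  invisible(x)
}

#' Cross-sample sharing of exchange events
#'
#' Groups calls across samples into events (genic calls by gene pair;
#' interval calls by reciprocal overlap of at least `min_overlap` on both
#' the donor and recipient intervals), counts per-event occurrences and
#' direction totals, and reports a goodness-of-fit chi-squared on the two
#' direction totals.  The direction test's table construction is flagged as
#' ambiguous: occurrence totals conflate event counts with sharing.
#'
#' @param calls data.frame of HE calls pooled over samples.
#' @param min_overlap reciprocal-overlap threshold for event identity.
#' @return list of class `pf_sharing`: `$events` (per-event occurrence
#'   counts), `$direction_totals`, `$direction_test`, `$note`.
#' @export
sharing_summary <- function(calls, min_overlap = 0.8) {
  if (!nrow(calls)) {
    return(structure(list(events = data.frame(), direction_totals = c(),
                          direction_test = NULL,
                          note = "no calls"), class = "pf_sharing"))
  }
  reciprocal_overlap <- function(s1, e1, s2, e2) {
    ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
    pmin(ov / (e1 - s1), ov / (e2 - s2))
  }
  n <- nrow(calls)
  event_id <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    assigned <- FALSE
    if ("donor_gene" %in% names(calls) && !is.na(calls$donor_gene[i])) {
      prev <- which(event_id[seq_len(i - 1)] > 0 &
                      calls$donor_gene[seq_len(i - 1)] == calls$donor_gene[i])
      if (length(prev)) { event_id[i] <- event_id[prev[1]]; assigned <- TRUE }
    } else {
      for (j in seq_len(i - 1)) {
        if (event_id[j] == 0) next
        if (is.na(calls$recip_chrom[i]) || is.na(calls$recip_chrom[j])) next
        if (calls$donor_chrom[j] != calls$donor_chrom[i] ||
            calls$recip_chrom[j] != calls$recip_chrom[i]) next
        od <- reciprocal_overlap(calls$donor_start[i], calls$donor_end[i],
                                 calls$donor_start[j], calls$donor_end[j])
        orr <- reciprocal_overlap(calls$recip_start[i], calls$recip_end[i],
                                  calls$recip_start[j], calls$recip_end[j])
        if (od >= min_overlap && orr >= min_overlap) {
          event_id[i] <- event_id[j]; assigned <- TRUE; break
        }
      }
    }
    if (!assigned) { next_id <- next_id + 1L; event_id[i] <- next_id }
  }
  events <- do.call(rbind, lapply(split(seq_len(n), event_id), function(ix) {
    data.frame(
      event = event_id[ix[1]],
      donor_chrom = calls$donor_chrom[ix[1]],
      donor_start = calls$donor_start[ix[1]], donor_end = calls$donor_end[ix[1]],
      direction = calls$direction[ix[1]],
      occurrences = length(unique(calls$sample[ix])),
      stringsAsFactors = FALSE
    )
  }))
  dirs <- calls$direction[!is.na(calls$direction)]
  totals <- table(factor(dirs, levels = c("A->B", "B->A")))
  test <- if (sum(totals) > 0) {
    stat <- sum((totals - sum(totals) / 2)^2 / (sum(totals) / 2))
    log_p <- stats::pchisq(stat, df = 1, lower.tail = FALSE, log.p = TRUE)
    test_result(stat, exp(log_p), log_p, "two_sided",
                "chi-squared goodness of fit on direction occurrence totals")
  } else NULL
  structure(list(
    events = events, direction_totals = totals, direction_test = test,
    note = paste("direction test construction ambiguous: occurrence totals",
                 "mix event multiplicity with cross-sample sharing")
  ), class = "pf_sharing")
}

#' @export
print.pf_sharing <- function(x, ...) {
  cat(sprintf("exchange sharing: %d event(s)\n",
              if (is.data.frame(x$events)) nrow(x$events) else 0L))
  if (length(x$direction_totals)) print(x$direction_totals)
  if (!is.null(x$direction_test)) print(x$direction_test)
  cat("note:", x$note, "\n")
  invisible(x)
}
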