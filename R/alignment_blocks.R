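# ---------------------------------------------------------------------------
# Four-way orthologous alignment blocks and the conserved-interval filters
# applied before mutation calling: split on long gap runs, then keep
# intervals that are long enough and sufficiently identical across all four
# rows.
# ---------------------------------------------------------------------------

MSA_ROLES <- c("PFA", "PFB", "PC02", "PC99")

new_msa <- function(block_id, rows, meta) {
  stopifnot(is.matrix(rows), nrow(rows) == 4L,
            setequal(rownames(rows), MSA_ROLES))
  rows <- rows[MSA_ROLES, , drop = FALSE]
  meta <- meta[match(MSA_ROLES, meta$role), , drop = FALSE]
  structure(list(block_id = block_id, rows = rows, meta = meta),
            class = "pf_msa")
}

#' @export
print.pf_msa <- function(x, ...) {
  cat(sprintf("4-way alignment block '%s': %d columns\n",
              x$block_id, ncol(x$rows)))
  invisible(x)
}

#' Read a four-way orthologous alignment from aligned FASTA
#'
#' The file must contain exactly four records whose identifiers start with
#' the role names `PFA`, `PFB`, `PC02`, `PC99` (an optional
#' `role|chrom|start|strand` form carries source coordinates).  Lowercase is
#' normalized to uppercase; rows must have equal aligned lengths.
#'
#' @param path aligned FASTA file.
#' @param block_id block identifier; defaults to the file name.
#' @return a `pf_msa`: a 4 x L character matrix over `A,C,G,T,N,-` with
#'   per-row source coordinates.
#' @export
read_alignment <- function(path, block_id = basename(path)) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) stop("empty file: no alignment records")
  if (length(recs) != 4) stop("missing role: need exactly four records (PFA, PFB, PC02, PC99)")
  ids <- names(recs)
  parts <- strsplit(ids, "|", fixed = TRUE)
  roles <- vapply(parts, `[`, character(1), 1L)
  roles <- sub("[[:space:]].*$", "", roles)
  if (!setequal(roles, MSA_ROLES)) stop("unknown ids: cannot map records to the four roles")
  lens <- Biostrings::width(recs)
  if (length(unique(lens)) != 1) stop("ragged alignment: rows have unequal lengths")
  chrom  <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, character(1))
  start  <- vapply(parts, function(p) if (length(p) >= 3) as.integer(p[3]) else 0L, integer(1))
  strand <- vapply(parts, function(p) if (length(p) >= 4) p[4] else "+", character(1))
  m <- do.call(rbind, lapply(seq_along(recs), function(i)
    strsplit(toupper(as.character(recs[[i]])), "")[[1]]))
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) stop("alignment contains unsupported characters: ",
                        paste(bad, collapse = ", "))
  rownames(m) <- roles
  meta <- data.frame(role = roles, chrom = ifelse(is.na(chrom), roles, chrom),
                     start = start, strand = strand, stringsAsFactors = FALSE)
  if (any(colSums(m == "-") == 4L)) stop("alignment contains all-gap columns")
  new_msa(block_id, m, meta)
}

#' Write a `pf_msa` to aligned FASTA
#'
#' @param msa a `pf_msa`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path) {
  seqs <- apply(msa$rows, 1, paste, collapse = "")
  ids <- sprintf("%s|%s|%d|%s", msa$meta$role, msa$meta$chrom,
                 msa$meta$start, msa$meta$strand)
  x <- Biostrings::BStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Split an alignment block at long gap runs
#'
#' Any run of at least `max_gap` consecutive gap characters in any single row
#' splits the block at that run; the gap run itself is excluded from both
#' resulting intervals.  Overlapping qualifying runs in different rows split
#' once at their union.
#'
#' @param msa a `pf_msa`.
#' @param max_gap minimal gap-run length (bp) that forces a split.
#' @return data.frame of aligned-column intervals (`start`, `end`, 0-based
#'   half-open) with the parent `block_id`.
#' @export
segment_on_gaps <- function(msa, max_gap = 100L) {
  L <- ncol(msa$rows)
  cut_mask <- logical(L)
  for (r in seq_len(nrow(msa$rows))) {
    g <- msa$rows[r, ] == "-"
    runs <- rle(g)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    long <- which(runs$values & runs$lengths >= max_gap)
    for (i in long) cut_mask[starts[i]:ends[i]] <- TRUE
  }
  runs <- rle(!cut_mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  data.frame(block_id = msa$block_id,
             start = starts[keep] - 1L, end = ends[keep],
             stringsAsFactors = FALSE)
}

# per-interval summary used by the filter and by downstream coordinate maps
interval_stats <- function(msa, start, end) {
  cols <- (start + 1L):end
  sub <- msa$rows[, cols, drop = FALSE]
  ungapped <- rowSums(sub != "-")
  gap_free <- colSums(sub == "-") == 0L
  has_n <- colSums(sub == "N") > 0L
  agree <- gap_free & !has_n &
    sub[1, ] == sub[2, ] & sub[2, ] == sub[3, ] & sub[3, ] == sub[4, ]
  identity <- if (any(gap_free)) sum(agree) / sum(gap_free) else 0
  list(ungapped = ungapped, identity = identity)
}

#' Filter segmented intervals by length and four-way identity
#'
#' Keeps intervals whose shortest ungapped row exceeds `min_length` bp and
#' whose overall identity is at least `min_identity`.  Identity is defined as
#' the fraction of gap-free columns in which all four rows carry the same
#' base; columns containing `N` are gap-free but never count as agreement.
#'
#' @param msa the parent `pf_msa`.
#' @param intervals data.frame from [segment_on_gaps()].
#' @param min_length minimal ungapped row length in bp (strict `>`).
#' @param min_identity minimal identity fraction (inclusive `>=`).
#' @return data.frame of conserved intervals with per-row ungapped lengths
#'   (`len_PFA` ...) and `identity`.
#' @export
filter_intervals <- function(msa, intervals, min_length = 500L, min_identity = 0.80) {
  if (!nrow(intervals)) return(cbind(intervals, identity = numeric(0)))
  stats <- lapply(seq_len(nrow(intervals)), function(i)
    interval_stats(msa, intervals$start[i], intervals$end[i]))
  lens <- do.call(rbind, lapply(stats, `[[`, "ungapped"))
  colnames(lens) <- paste0("len_", MSA_ROLES)
  identity <- vapply(stats, `[[`, numeric(1), "identity")
  out <- cbind(intervals, lens, identity = identity)
  out[apply(lens, 1, min) > min_length & identity >= min_identity, , drop = FALSE]
}

#' Map aligned columns to source coordinates for one row
#'
#' @param msa a `pf_msa`.
#' @param role row name.
#' @param columns aligned column indices (1-based).
#' @return integer source positions (0-based); `NA` at gap columns.
#' @export
column_to_source <- function(msa, role, columns) {
  row <- msa$rows[role, ]
  ungapped <- cumsum(row != "-")
  meta <- msa$meta[msa$meta$role == role, ]
  pos <- ifelse(row[columns] == "-", NA_integer_,
                meta$start + ungapped[columns] - 1L)
  as.integer(pos)
}
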