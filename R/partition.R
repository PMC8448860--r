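# ---------------------------------------------------------------------------
# Subgenome partition from diploid-onto-tetraploid coverage depth: windows
# above half of the genome peak depth are AA-derived, runs shorter than five
# windows are flipped to the surrounding origin.
# ---------------------------------------------------------------------------

#' Build a depth track
#'
#' @param chrom,start,end,depth per-window vectors; `start`/`end` 0-based
#'   half-open, windows sorted and non-overlapping within chromosomes.
#' @param sample,reference identifiers carried along for reporting.
#' @return data.frame of class `pf_depth_track`.
#' @export
depth_track <- function(chrom, start, end, depth, sample = "sample",
                        reference = "reference") {
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            length(end) == length(depth), all(end > start), all(depth >= 0))
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), depth = as.numeric(depth),
                   stringsAsFactors = FALSE)
  o <- order(df$chrom, df$start)
  df <- df[o, ]
  for (ch in unique(df$chrom)) {
    w <- df[df$chrom == ch, ]
    if (nrow(w) > 1 && any(w$start[-1] < w$end[-nrow(w)]))
      stop("overlapping windows on ", ch)
  }
  attr(df, "sample") <- sample
  attr(df, "reference") <- reference
  class(df) <- c("pf_depth_track", "data.frame")
  df
}

#' Estimate the genome peak depth
#'
#' Mode of the integer-binned depth histogram over windows with positive
#' depth; ties are broken toward the larger depth.  On a diploid-onto-
#' tetraploid track (where roughly half the windows have no coverage) this
#' recovers the covered-mode depth whose half sets the origin threshold.
#'
#' @param track a [depth_track()].
#' @return integer peak depth.
#' @export
estimate_peak_depth <- function(track) {
  d <- round(track$depth[track$depth > 0])
  d <- d[d > 0]
  if (!length(d)) stop("no coverage: all windows have zero depth")
  tab <- table(d)
  best <- max(tab)
  as.integer(max(as.integer(names(tab)[tab == best])))
}

#' Classify windows by the half-peak rule
#'
#' A window is AA-derived iff its depth is strictly greater than half the
#' peak depth (boundary windows at exactly half-peak go BB).
#'
#' @param track a [depth_track()].
#' @param peak peak depth, e.g. from [estimate_peak_depth()].
#' @return character vector of provisional origins (`"AA"`/`"BB"`).
#' @export
classify_windows <- function(track, peak) {
  stopifnot(peak > 0)
  ifelse(track$depth > 0.5 * peak, "AA", "BB")
}

# iterative fixed-point flipping of sub-minimum runs, left-to-right: the
# leftmost run shorter than min_run is flipped to the opposite origin and
# merged, until every run reaches min_run (or one run remains)
flip_short_runs <- function(labels, min_run) {
  n <- length(labels)
  if (n < min_run) {
    maj <- names(sort(table(labels), decreasing = TRUE))[1]
    if (sum(labels == "AA") == sum(labels == "BB")) maj <- labels[1]
    return(rep(maj, n))
  }
  repeat {
    r <- rle(labels)
    if (length(r$lengths) == 1L || all(r$lengths >= min_run)) break
    i <- which(r$lengths < min_run)[1]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    labels[starts[i]:ends[i]] <- setdiff(c("AA", "BB"), r$values[i])
  }
  labels
}

#' Merge provisional origins into confident blocks
#'
#' Runs shorter than `min_run` windows are iteratively reassigned to the
#' opposite origin (left-to-right, to a fixed point), then adjacent
#' same-origin windows are merged into blocks.  A chromosome with fewer than
#' `min_run` windows collapses to a single block of its majority label.
#'
#' @param track a [depth_track()].
#' @param origins provisional per-window origins from [classify_windows()].
#' @param min_run minimal number of contiguous same-origin windows.
#' @param peak,threshold echoed into the result (optional).
#' @return object of class `pf_partition` with `$blocks` (chrom, start, end,
#'   origin, n_windows; 0-based half-open), `$window_origins`, `$peak`,
#'   `$threshold`.
#' @export
merge_blocks <- function(track, origins, min_run = 5L, peak = NA_real_,
                         threshold = NA_real_) {
  stopifnot(length(origins) == nrow(track), all(origins %in% c("AA", "BB")))
  blocks <- list()
  final <- character(nrow(track))
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    lab <- flip_short_runs(origins[idx], min_run)
    final[idx] <- lab
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    blocks[[ch]] <- data.frame(
      chrom = ch,
      start = track$start[idx[starts]],
      end = track$end[idx[ends]],
      origin = r$values,
      n_windows = r$lengths,
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    blocks = do.call(rbind, c(blocks, make.row.names = FALSE)),
    window_origins = data.frame(chrom = track$chrom, start = track$start,
                                end = track$end, origin = final,
                                stringsAsFactors = FALSE),
    peak = peak, threshold = threshold,
    parameters = list(min_run = min_run)
  ), class = "pf_partition")
}

#' @export
print.pf_partition <- function(x, ...) {
  bp <- tapply(x$blocks$end - x$blocks$start, x$blocks$origin, sum)
  cat(sprintf("subgenome partition: %d blocks (peak %s, threshold %s)\n",
              nrow(x$blocks), format(x$peak), format(x$threshold)))
  for (o in names(bp)) cat(sprintf("  %s: %s bp\n", o, format(bp[[o]], big.mark = ",")))
  invisible(x)
}

#' Partition a depth track end to end
#'
#' Convenience wrapper: peak estimation, half-peak window classification and
#' five-window block merging.
#'
#' @param track a [depth_track()].
#' @param min_run minimal confident run length in windows.
#' @return a `pf_partition`.
#' @export
partition_depth_track <- function(track, min_run = 5L) {
  peak <- estimate_peak_depth(track)
  origins <- classify_windows(track, peak)
  merge_blocks(track, origins, min_run = min_run, peak = peak,
               threshold = 0.5 * peak)
}

#' Fraction of windows labeled correctly against a truth origin grid
#'
#' @param partition a `pf_partition`.
#' @param truth data.frame with chrom, start, end, origin over the same
#'   window grid.
#' @return fraction in `[0, 1]`.
#' @export
partition_accuracy <- function(partition, truth) {
  got <- partition$window_origins
  key_a <- paste(got$chrom, got$start, got$end)
  key_b <- paste(truth$chrom, truth$start, truth$end)
  if (length(key_a) != length(key_b) || !all(sort(key_a) == sort(key_b)))
    stop("window grid mismatch between partition and truth")
  m <- match(key_b, key_a)
  mean(got$origin[m] == truth$origin)
}

#' Write origin blocks as BED6
#'
#' @param partition a `pf_partition`.
#' @param path output BED file (0-based half-open; name column AA/BB).
#' @return `path`, invisibly.
#' @export
write_partition_bed <- function(partition, path) {
  b <- partition$blocks
  bed <- data.frame(b$chrom, format(b$start, scientific = FALSE, trim = TRUE),
                    format(b$end, scientific = FALSE, trim = TRUE),
                    b$origin, b$n_windows, "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
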