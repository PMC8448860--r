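# ---------------------------------------------------------------------------
# Homeolog expression bias: log2(TPM_A / TPM_B) per syntenic gene pair with
# the pseudo-count rule (when either TPM of the pair is below 1, add 1 to
# both before taking the ratio), and histogram-based dominance-peak
# detection.
# ---------------------------------------------------------------------------

#' log2 homeolog expression bias with the pseudo-count rule
#'
#' When the smaller of the paired TPM values is below 1, a pseudo-count of 1
#' is added to both values before the log2 ratio; the result is therefore
#' finite for every non-negative input and exactly antisymmetric under
#' swapping the pair.
#'
#' @param tpm_a,tpm_b non-negative TPM vectors (pairwise).
#' @return numeric vector of log2(A/B) ratios.
#' @examples
#' log2_bias(4, 2)      # 1
#' log2_bias(0.5, 0.5)  # 0 (both shifted to 1.5)
#' @export
log2_bias <- function(tpm_a, tpm_b) {
  if (any(tpm_a < 0) || any(tpm_b < 0)) stop("TPM values must be non-negative")
  shift <- as.numeric(pmin(tpm_a, tpm_b) < 1)
  log2((tpm_a + shift) / (tpm_b + shift))
}

#' Summarize homeolog expression bias over gene pairs
#'
#' Replicate TPMs are averaged per gene before the pseudo-count rule
#' (set `per_replicate = TRUE` to compute per-replicate ratios and average
#' those instead).  The histogram of per-pair ratios is scanned for local
#' maxima; the highest local maximum other than the global mode is reported
#' as the secondary (dominance) peak.
#'
#' @param pairs data.frame with gene_a, gene_b, tpm_a, tpm_b and optionally
#'   replicate.
#' @param bin histogram bin width (log2 units).
#' @param per_replicate see above.
#' @return list of class `pf_bias`: per-pair ratios, mean, median,
#'   histogram, `secondary_peak` (bin centre or `NA`).
#' @export
summarize_bias <- function(pairs, bin = 0.05, per_replicate = FALSE) {
  stopifnot(all(c("gene_a", "tpm_a", "tpm_b") %in% names(pairs)))
  if (per_replicate) {
    ratio_all <- log2_bias(pairs$tpm_a, pairs$tpm_b)
    ratios <- tapply(ratio_all, pairs$gene_a, mean)
    genes <- names(ratios)
    ratios <- as.numeric(ratios)
  } else {
    ta <- tapply(pairs$tpm_a, pairs$gene_a, mean)
    tb <- tapply(pairs$tpm_b, pairs$gene_a, mean)
    genes <- names(ta)
    ratios <- log2_bias(as.numeric(ta), as.numeric(tb))
  }
  lo <- floor(min(ratios) / bin) * bin
  hi <- ceiling(max(ratios) / bin) * bin
  if (hi <= lo) hi <- lo + bin
  h <- graphics::hist(ratios, breaks = seq(lo, hi + bin / 2, by = bin), plot = FALSE)
  counts <- h$counts
  k <- length(counts)
  global_mode <- which.max(counts)
  local_max <- which(counts > c(-Inf, counts[-k]) & counts > c(counts[-1], -Inf))
  local_max <- setdiff(local_max, global_mode)
  secondary <- if (length(local_max)) {
    local_max[which.max(counts[local_max])]
  } else NA_integer_
  structure(list(
    ratios = data.frame(gene = genes, log2_ratio = ratios,
                        stringsAsFactors = FALSE),
    mean = mean(ratios), median = stats::median(ratios),
    histogram = data.frame(mid = h$mids, count = counts),
    secondary_peak = if (is.na(secondary)) NA_real_ else h$mids[secondary]
  ), class = "pf_bias")
}

#' @export
print.pf_bias <- function(x, ...) {
  cat(sprintf("homeolog expression bias over %d pairs: mean %.3f, median %.3f\n",
              nrow(x$ratios), x$mean, x$median))
  cat(sprintf("  secondary peak: %s\n",
              if (is.na(x$secondary_peak)) "none detected"
              else sprintf("%.3f (TPM ratio %.3f)", x$secondary_peak,
                           2^x$secondary_peak)))
  invisible(x)
}
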