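# ---------------------------------------------------------------------------
# Pairwise synonymous/nonsynonymous divergence by the Nei-Gojobori (1986)
# counting method with Jukes-Cantor correction, and the dS -> time
# conversion t = dS / 2r.
# ---------------------------------------------------------------------------

# environment caches: per-codon synonymous site fractions and per-codon-pair
# path-averaged difference counts
.ng_cache <- new.env(parent = emptyenv())

codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  ifelse(is.na(aa), "X", aa)
}

is_stop <- function(codon) codon_aa(codon) == "*"

# synonymous site count of one codon: at each position, the fraction of the
# three possible substitutions that are synonymous (changes to stop codons
# count as nonsynonymous), summed over positions
codon_syn_sites <- function(codon) {
  key <- paste0("S_", codon)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  aa0 <- codon_aa(codon)
  nt <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(.base_alphabet, nt[p])) {
      alt <- nt; alt[p] <- b
      alt <- paste(alt, collapse = "")
      if (!is_stop(alt) && codon_aa(alt) == aa0) s <- s + 1 / 3
    }
  }
  .ng_cache[[key]] <- s
  s
}

# path-averaged (syn, nonsyn) difference counts between two codons: all
# orderings of the differing positions are enumerated with equal weights;
# paths passing through a stop codon are excluded (all paths are kept when
# every path is blocked)
codon_pair_diffs <- function(c1, c2) {
  key <- paste0("D_", c1, "_", c2)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  n1 <- strsplit(c1, "")[[1]]
  n2 <- strsplit(c2, "")[[1]]
  pos <- which(n1 != n2)
  k <- length(pos)
  if (k == 0) {
    res <- c(syn = 0, nonsyn = 0)
  } else {
    perms <- if (k == 1) list(pos) else {
      # all orderings of the differing positions
      perm_idx <- function(v) {
        if (length(v) == 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
          for (rest in perm_idx(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
        out
      }
      perm_idx(pos)
    }
    path_counts <- function(order_pos) {
      cur <- n1
      syn <- 0; nonsyn <- 0
      for (p in order_pos) {
        nxt <- cur; nxt[p] <- n2[p]
        c_from <- paste(cur, collapse = ""); c_to <- paste(nxt, collapse = "")
        if (is_stop(c_to)) return(NULL)  # blocked path
        if (codon_aa(c_from) == codon_aa(c_to)) syn <- syn + 1 else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      c(syn = syn, nonsyn = nonsyn)
    }
    counts <- Filter(Negate(is.null), lapply(perms, path_counts))
    if (!length(counts)) {
      # every path runs through a stop; fall back to unfiltered averaging
      path_counts_any <- function(order_pos) {
        cur <- n1; syn <- 0; nonsyn <- 0
        for (p in order_pos) {
          nxt <- cur; nxt[p] <- n2[p]
          if (codon_aa(paste(cur, collapse = "")) == codon_aa(paste(nxt, collapse = "")))
            syn <- syn + 1 else nonsyn <- nonsyn + 1
          cur <- nxt
        }
        c(syn = syn, nonsyn = nonsyn)
      }
      counts <- lapply(perms, path_counts_any)
    }
    res <- colMeans(do.call(rbind, counts))
  }
  .ng_cache[[key]] <- res
  res
}

split_codons <- function(seq) {
  if (length(seq) == 1 && nchar(seq[1]) > 1) seq <- strsplit(toupper(seq), "")[[1]]
  else seq <- toupper(seq)
  if (length(seq) %% 3 != 0) stop("sequence length must be divisible by 3")
  n <- length(seq) / 3
  paste0(seq[3 * seq_len(n) - 2], seq[3 * seq_len(n) - 1], seq[3 * seq_len(n)])
}

#' Nei-Gojobori (1986) synonymous and nonsynonymous divergence
#'
#' Per-codon synonymous site fractions are averaged over both sequences;
#' multi-difference codons are averaged over all minimal mutational paths
#' with equal weights (paths through stop codons excluded); proportions are
#' Jukes-Cantor corrected, `d = -(3/4) ln(1 - (4/3) p)`, with saturation
#' flagged at `p >= 3/4`.  Codons containing gaps or `N` in either sequence
#' are removed before counting; a shared terminal stop codon is dropped.
#'
#' @param seq_a,seq_b in-frame CDS strings (or character vectors) of equal
#'   length.
#' @return list of class `pf_ds`: dS, dN, S, N, Sd, Nd, pS, pN, saturated,
#'   n_codons.
#' @export
ng86 <- function(seq_a, seq_b) {
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  if (length(ca) != length(cb)) stop("sequences must have equal codon counts")
  if (!length(ca)) stop("zero codons")
  drop <- grepl("[^ACGT]", ca) | grepl("[^ACGT]", cb)
  ca <- ca[!drop]; cb <- cb[!drop]
  if (!length(ca)) stop("zero codons after removing gapped/ambiguous codons")
  if (length(ca) && is_stop(ca[length(ca)]) && is_stop(cb[length(cb)])) {
    ca <- ca[-length(ca)]; cb <- cb[-length(cb)]
  }
  if (!length(ca)) stop("zero codons")
  if (any(is_stop(ca)) || any(is_stop(cb))) stop("internal stop codon")
  S <- (sum(vapply(ca, codon_syn_sites, numeric(1))) +
          sum(vapply(cb, codon_syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  d <- vapply(seq_along(ca), function(i) codon_pair_diffs(ca[i], cb[i]), numeric(2))
  Sd <- sum(d["syn", ]); Nd <- sum(d["nonsyn", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  structure(list(
    dS = jc(pS), dN = jc(pN), S = S, N = N, Sd = Sd, Nd = Nd,
    pS = pS, pN = pN, saturated = (pS >= 0.75 || pN >= 0.75),
    n_codons = length(ca)
  ), class = "pf_ds")
}

#' @export
print.pf_ds <- function(x, ...) {
  cat(sprintf("NG86: dS = %s, dN = %s (S = %.2f, N = %.2f, Sd = %.2f, Nd = %.2f%s)\n",
              format(x$dS, digits = 4), format(x$dN, digits = 4),
              x$S, x$N, x$Sd, x$Nd,
              if (x$saturated) ", SATURATED" else ""))
  invisible(x)
}

#' Convert synonymous divergence to time
#'
#' `t = dS / (2 r)` with `r` the neutral substitution rate per site per
#' year: both lineages accumulate substitutions independently.
#'
#' @param dS synonymous substitutions per site (`>= 0`).
#' @param r neutral substitution rate, substitutions/site/year (`> 0`).
#' @return divergence time in years.
#' @examples
#' divergence_time(0.034, 7.1e-9) / 1e6  # ~2.4 My
#' @export
divergence_time <- function(dS, r) {
  if (any(r <= 0)) stop("substitution rate r must be positive")
  if (any(dS < 0)) stop("dS must be non-negative")
  dS / (2 * r)
}

#' Distribution of pairwise dS values
#'
#' Bins positive dS values (zero-dS mass is reported separately, since a
#' very young polyploid puts a large point mass at exactly zero) and
#' reports the densest-bin centre as the mode.
#'
#' @param ds numeric vector of dS values (NAs from saturated pairs dropped).
#' @param bin bin width.
#' @return list of class `pf_ds_dist`: histogram data.frame, `mode`,
#'   `zero_fraction`, `n`.
#' @export
ds_distribution <- function(ds, bin = 0.005) {
  ds <- ds[!is.na(ds)]
  if (!length(ds)) stop("no dS values")
  zero_fraction <- mean(ds == 0)
  pos <- ds[ds > 0]
  if (length(pos)) {
    breaks <- seq(0, max(pos) + bin, by = bin)
    h <- graphics::hist(pos, breaks = breaks, plot = FALSE)
    mode <- h$mids[which.max(h$counts)]
    hist_df <- data.frame(mid = h$mids, count = h$counts)
  } else {
    mode <- 0
    hist_df <- data.frame(mid = numeric(0), count = integer(0))
  }
  structure(list(histogram = hist_df, mode = mode,
                 zero_fraction = zero_fraction, n = length(ds)),
            class = "pf_ds_dist")
}

#' @export
print.pf_ds_dist <- function(x, ...) {
  cat(sprintf("dS distribution: n = %d, mode = %.3f, zero-dS fraction = %.3f\n",
              x$n, x$mode, x$zero_fraction))
  invisible(x)
}
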