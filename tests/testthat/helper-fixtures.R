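# shared fixture builders and independent oracles

# build a pf_msa from four row strings (named PFA/PFB/PC02/PC99) by writing
# an aligned FASTA and reading it back through the package reader
make_msa <- function(pfa, pfb, pc02, pc99, block_id = "blk",
                     chroms = c("A01", "B01", "A01", "A01"), starts = c(0, 0, 0, 0)) {
  path <- tempfile(fileext = ".afa")
  ids <- sprintf("%s|%s|%d|+", c("PFA", "PFB", "PC02", "PC99"), chroms, starts)
  writeLines(c(rbind(paste0(">", ids), c(pfa, pfb, pc02, pc99))), path)
  read_alignment(path, block_id = block_id)
}

rand_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

collapse <- function(x) paste(x, collapse = "")

# independent brute-force 1:3 + flank scanner: direct re-check of every
# 11-column window, no cumsums, no vectorized shortcuts
brute_force_calls <- function(msa, flank = 5L) {
  m <- msa$rows
  L <- ncol(m)
  hits <- list()
  for (j in seq_len(L)) {
    col <- m[, j]
    if (!all(col %in% c("A", "C", "G", "T"))) next
    tab <- table(col)
    if (!(length(tab) == 2 && any(tab == 3))) next
    anc <- names(tab)[tab == 3]
    carrier <- which(col != anc)
    if (j - flank < 1 || j + flank > L) next
    ok <- TRUE
    for (k in c((j - flank):(j - 1), (j + 1):(j + flank))) {
      w <- m[, k]
      if (!all(w %in% c("A", "C", "G", "T")) || length(unique(w)) != 1) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    hits[[length(hits) + 1L]] <- data.frame(
      column = j - 1L, carrier = rownames(m)[carrier],
      anc = anc, der = col[carrier], stringsAsFactors = FALSE)
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(column = integer(0), carrier = character(0),
               anc = character(0), der = character(0))
}

# independent NG86 oracle for one codon pair: explicit permutation walk,
# recursion-free structure distinct from the package implementation
oracle_pair_diffs <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  aa <- function(cod) unname(gc[cod])
  stops <- c("TAA", "TAG", "TGA")
  n1 <- strsplit(c1, "")[[1]]
  n2 <- strsplit(c2, "")[[1]]
  pos <- which(n1 != n2)
  k <- length(pos)
  if (k == 0) return(c(0, 0))
  orders <- switch(as.character(k),
                   "1" = matrix(pos, ncol = 1),
                   "2" = rbind(pos, rev(pos)),
                   "3" = {
                     p <- pos
                     rbind(c(p[1], p[2], p[3]), c(p[1], p[3], p[2]),
                           c(p[2], p[1], p[3]), c(p[2], p[3], p[1]),
                           c(p[3], p[1], p[2]), c(p[3], p[2], p[1]))
                   })
  res <- list()
  for (r in seq_len(nrow(orders))) {
    cur <- n1
    syn <- 0; nonsyn <- 0
    blocked <- FALSE
    for (p in orders[r, ]) {
      nxt <- cur
      nxt[p] <- n2[p]
      to <- paste(nxt, collapse = "")
      if (to %in% stops) { blocked <- TRUE; break }
      if (aa(paste(cur, collapse = "")) == aa(to)) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    if (!blocked) res[[length(res) + 1L]] <- c(syn, nonsyn)
  }
  if (!length(res)) {
    # unfiltered fallback mirrors the documented degenerate-case contract
    for (r in seq_len(nrow(orders))) {
      cur <- n1; syn <- 0; nonsyn <- 0
      for (p in orders[r, ]) {
        nxt <- cur; nxt[p] <- n2[p]
        if (aa(paste(cur, collapse = "")) == aa(paste(nxt, collapse = "")))
          syn <- syn + 1 else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      res[[length(res) + 1L]] <- c(syn, nonsyn)
    }
  }
  colMeans(do.call(rbind, res))
}

all_sense_codons <- function() {
  all <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           c("A", "C", "G", "T")), 1, paste, collapse = "")
  setdiff(all, c("TAA", "TAG", "TGA"))
}

# small fast config for sim-based tests
tiny_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_chromosomes = 2L, chrom_length = 3e5,
                   gene_count = 30L, he_size_range = c(1e4, 4e4),
                   window_size = 2000L, telomere_window = 6e4)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
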