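# ---------------------------------------------------------------------------
# Synthetic allotetraploid system: progenitor genomes and de novo mutations.
#
# Lineage model (all coordinates shared across rows because the substitution
# channel is indel-free):
#
#   ancestor --+-- AA branch (divergence/2) --> AA  --> PFA, PC02 (unchanged),
#              |                                        PC99 (+ pc99 branch)
#              +-- BB branch (divergence/2) --> BB  --> PFB
#
# De novo mutations are then planted on the four terminal branches: PFA/PFB at
# the tetraploid rate, PC02/PC99 at the diploid rate.  PC02 carries no
# divergence of its own, so it retains the ancestral AA state at every
# non-mutated position -- the configuration the 1:3 ancestral-genotype caller
# is designed around.
# ---------------------------------------------------------------------------

LINEAGES <- c("PFA", "PFB", "PC02", "PC99")

block_ids <- function(config) sprintf("A%02d", seq_len(config$n_chromosomes))

# native chromosome name of a lineage row within an orthologous block
# (vectorized over either argument)
native_chrom <- function(block, lineage) {
  n <- max(length(block), length(lineage))
  ifelse(rep_len(lineage, n) == "PFB", sub("^A", "B", rep_len(block, n)),
         rep_len(block, n))
}

# substitute each site independently with probability q, uniformly to one of
# the three other bases (Jukes-Cantor-style); returns new seq + positions hit
substitute_sites <- function(seq, q) {
  if (q <= 0) return(list(seq = seq, positions = integer(0)))
  hit <- which(stats::runif(length(seq)) < q)
  if (length(hit)) {
    seq[hit] <- ((seq[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
  }
  list(seq = seq, positions = hit)
}

#' Simulate the diploid progenitor genomes
#'
#' Draws a random ancestral genome and derives the AA and BB progenitors by
#' independent substitution at `progenitor_divergence / 2` per lineage, then
#' derives the four terminal lineage genomes (PFA, PFB, PC02, PC99) with the
#' extra PC99 branch divergence.  All substituted positions are registered in
#' the truth set; they are the sites the mutation planter must stay clear of.
#'
#' @param config a [sim_config()].
#' @return an object of class `pf_sim` holding genomes and the truth registry.
#' @export
simulate_progenitors <- function(config) {
  stopifnot(inherits(config, "pf_config"))
  if (config$chrom_length < 1) stop("zero-length chromosomes")
  withr::with_seed(stage_seed(config, "progenitors"), {
    blocks <- block_ids(config)
    ancestor <- lapply(blocks, function(b) sample.int(4L, config$chrom_length, replace = TRUE))
    names(ancestor) <- blocks
    qa <- config$progenitor_divergence / 2
    genomes <- list(PFA = list(), PFB = list(), PC02 = list(), PC99 = list())
    variant_sites <- list()
    for (b in blocks) {
      aa <- substitute_sites(ancestor[[b]], qa)
      bb <- substitute_sites(ancestor[[b]], qa)
      p99 <- substitute_sites(aa$seq, config$pc99_divergence)
      genomes$PFA[[b]]  <- aa$seq
      genomes$PC02[[b]] <- aa$seq
      genomes$PC99[[b]] <- p99$seq
      genomes$PFB[[b]]  <- bb$seq
      variant_sites[[b]] <- sort(unique(c(aa$positions, bb$positions, p99$positions)))
    }
    structure(
      list(
        config = config,
        ancestor = ancestor,
        genomes = genomes,
        truth = list(
          variant_sites = variant_sites,
          mutations = empty_mutation_truth(),
          hes = NULL, genes = NULL, gene_fates = NULL
        )
      ),
      class = "pf_sim"
    )
  })
}

empty_mutation_truth <- function() {
  data.frame(lineage = character(0), block = character(0), chrom = character(0),
             pos = integer(0), anc = character(0), der = character(0),
             class6 = character(0), stringsAsFactors = FALSE)
}

#' @export
print.pf_sim <- function(x, ...) {
  cat("synthetic allotetraploid system\n")
  cat(sprintf("  %d orthologous block(s) x %s bp\n",
              length(x$ancestor), format(x$config$chrom_length, big.mark = ",")))
  cat(sprintf("  planted mutations: %d; planted HEs: %d; genes: %d\n",
              nrow(x$truth$mutations),
              if (is.null(x$truth$hes)) 0L else nrow(x$truth$hes),
              if (is.null(x$truth$genes)) 0L else nrow(x$truth$genes)))
  invisible(x)
}

CLASS6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# batch placement of mutation sites honouring the spacing rule.  `classes`
# are indices into CLASS6; returns data.frame(pos, class) or errors when the
# requested density cannot be placed.
place_mutation_sites <- function(base_seq, blocked, classes, spacing,
                                 context_modifiers = NULL) {
  L <- length(base_seq)
  is_c_strand <- base_seq == 2L | base_seq == 3L  # site base C or G
  placed_pos <- integer(0)
  placed_cls <- integer(0)
  pending <- classes
  ctx_code <- NULL
  if (!is.null(context_modifiers)) ctx_code <- context_codes(base_seq)
  for (iter in 1:200) {
    if (!length(pending)) break
    need_c <- pending[pending <= 3L]
    need_t <- pending[pending > 3L]
    cand_pos <- integer(0)
    cand_cls <- integer(0)
    for (grp in list(list(cls = need_c, mask = is_c_strand),
                     list(cls = need_t, mask = !is_c_strand))) {
      if (!length(grp$cls)) next
      pool <- which(grp$mask & !blocked)
      if (length(pool) < length(grp$cls))
        stop("unplaceable mutations: requested density too high for spacing rule")
      if (is.null(context_modifiers)) {
        pos <- pool[sample.int(length(pool), length(grp$cls))]
      } else {
        # per-class context weighting; sample class-by-class
        pos <- integer(length(grp$cls))
        for (k in seq_along(grp$cls)) {
          w <- context_modifiers[[grp$cls[k]]][ctx_code[pool]]
          pos[k] <- pool[sample.int(length(pool), 1L, prob = w)]
        }
      }
      cand_pos <- c(cand_pos, pos)
      cand_cls <- c(cand_cls, grp$cls)
    }
    # resolve spacing conflicts among candidates and against placed sites
    ord <- order(cand_pos)
    cand_pos <- cand_pos[ord]; cand_cls <- cand_cls[ord]
    keep <- !logical(length(cand_pos))
    last_kept <- -Inf
    for (i in seq_along(cand_pos)) {
      p <- cand_pos[i]
      if (p - last_kept <= spacing) { keep[i] <- FALSE; next }
      last_kept <- p
    }
    # duplicates with identical positions resolved by the loop above
    ok_pos <- cand_pos[keep]; ok_cls <- cand_cls[keep]
    placed_pos <- c(placed_pos, ok_pos)
    placed_cls <- c(placed_cls, ok_cls)
    blocked <- block_around(blocked, ok_pos, spacing)
    pending <- cand_cls[!keep]
  }
  if (length(pending))
    stop("unplaceable mutations: requested density too high for spacing rule")
  data.frame(pos = placed_pos, class = placed_cls)
}

# mark positions within `spacing` of each site as blocked (and the sites)
block_around <- function(blocked, positions, spacing) {
  if (!length(positions)) return(blocked)
  idx <- rep(positions, each = 2L * spacing + 1L) +
    rep.int(seq.int(-spacing, spacing), length(positions))
  idx <- idx[idx >= 1L & idx <= length(blocked)]
  blocked[idx] <- TRUE
  blocked
}

# pyrimidine-strand context code 1..16 ((5' - 1) * 4 + 3') for every position
context_codes <- function(base_seq) {
  L <- length(base_seq)
  left  <- c(0L, base_seq[-L])
  right <- c(base_seq[-1L], 0L)
  pyr <- base_seq == 2L | base_seq == 4L  # C or T: read forward strand
  c5 <- ifelse(pyr, left, comp_int(right))
  c3 <- ifelse(pyr, right, comp_int(left))
  code <- (c5 - 1L) * 4L + c3
  code[c5 < 1L | c5 > 4L | c3 < 1L | c3 > 4L] <- 1L  # edges: arbitrary, blocked anyway
  code
}

#' Plant de novo mutations on the four terminal lineages
#'
#' Mutation counts per lineage and chromosome are Poisson with mean
#' `rate x length`; the tetraploid lineages (PFA, PFB) use
#' `diploid_mutation_rate x tetraploid_excess`.  Substitution classes are
#' drawn from the six-class spectrum (optionally reweighted per trinucleotide
#' context); sites are chosen so the ancestral base matches the class and,
#' when `enforce_spacing` is on, so that no two variant sites fall within
#' `mutation_spacing` bp of each other or of a divergence site -- every
#' planted mutation is then callable under the five-identical-flank rule.
#'
#' @param sim a `pf_sim` from [simulate_progenitors()].
#' @return the updated `pf_sim` with mutated genomes and mutation truth.
#' @export
plant_mutations <- function(sim) {
  stopifnot(inherits(sim, "pf_sim"))
  config <- sim$config
  withr::with_seed(stage_seed(config, "mutations"), {
    rates <- c(PFA = config$tetraploid_mutation_rate,
               PFB = config$tetraploid_mutation_rate,
               PC02 = config$diploid_mutation_rate,
               PC99 = config$diploid_mutation_rate)
    spacing <- if (config$enforce_spacing) as.integer(config$mutation_spacing) else 0L
    spectrum <- config$spectrum6 / sum(config$spectrum6)
    rows <- list()
    for (b in block_ids(config)) {
      L <- config$chrom_length
      blocked <- logical(L)
      if (spacing > 0) {
        blocked <- block_around(blocked, sim$truth$variant_sites[[b]], spacing)
        blocked[seq_len(min(spacing, L))] <- TRUE
        blocked[seq.int(max(1L, L - spacing + 1L), L)] <- TRUE
      }
      base_seq <- sim$genomes$PC02[[b]]  # ancestral AA state outside variants
      for (lin in LINEAGES) {
        n <- stats::rpois(1, rates[[lin]] * L)
        if (n == 0) next
        classes <- sample.int(6L, n, replace = TRUE, prob = spectrum)
        # the ancestral base at a candidate site is the lineage's own base,
        # which outside blocked sites equals the shared state; under
        # spacing-off we still avoid existing variant sites themselves
        lineage_seq <- sim$genomes[[lin]][[b]]
        blk <- blocked
        if (spacing == 0L) {
          blk[sim$truth$variant_sites[[b]]] <- TRUE
          if (nrow(sim$truth$mutations)) {
            prev <- sim$truth$mutations
            blk[prev$pos[prev$block == b]] <- TRUE
          }
        }
        sites <- place_mutation_sites(lineage_seq, blk, classes, max(spacing, 0L),
                                      config$context_modifiers)
        anc_int <- lineage_seq[sites$pos]
        der_int <- derived_base_int(anc_int, sites$class)
        sim$genomes[[lin]][[b]][sites$pos] <- der_int
        if (spacing > 0) {
          blocked <- block_around(blocked, sites$pos, spacing)
        }
        sim$truth$variant_sites[[b]] <- sort(unique(c(sim$truth$variant_sites[[b]], sites$pos)))
        rows[[length(rows) + 1L]] <- data.frame(
          lineage = lin, block = b, chrom = native_chrom(b, lin),
          pos = sites$pos,
          anc = .base_alphabet[anc_int], der = .base_alphabet[der_int],
          class6 = CLASS6[sites$class], stringsAsFactors = FALSE
        )
      }
    }
    sim$truth$mutations <- if (length(rows)) do.call(rbind, rows) else empty_mutation_truth()
    sim
  })
}

# derived base (integer code) for an ancestral base and a CLASS6 index.
# classes are pyrimidine-collapsed: when the site carries the purine partner
# (G for C-classes, A for T-classes) the derived base is complemented.
derived_base_int <- function(anc_int, class_idx) {
  # pyrimidine-strand derived base per class: C>A, C>G, C>T, T>A, T>C, T>G
  der_py <- c(1L, 3L, 4L, 1L, 2L, 3L)[class_idx]
  purine <- anc_int == 1L | anc_int == 3L  # A or G: site is on the purine strand
  ifelse(purine, comp_int(der_py), der_py)
}

#' Extract one four-way orthologous alignment block from the simulator
#'
#' The substitution channel is indel-free, so the alignment is the columnwise
#' stack of the four lineage chromosomes.
#'
#' @param sim a `pf_sim` after [plant_mutations()].
#' @param block block id (e.g. `"A01"`).
#' @return a `pf_msa` as produced by [read_alignment()].
#' @export
sim_alignment_block <- function(sim, block) {
  stopifnot(inherits(sim, "pf_sim"), block %in% block_ids(sim$config))
  rows <- vapply(LINEAGES, function(lin) .base_alphabet[sim$genomes[[lin]][[block]]],
                 character(sim$config$chrom_length))
  m <- t(rows)
  rownames(m) <- LINEAGES
  new_msa(block_id = block, rows = m,
          meta = data.frame(role = LINEAGES,
                            chrom = native_chrom(block, LINEAGES),
                            start = 0L, strand = "+",
                            stringsAsFactors = FALSE))
}
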