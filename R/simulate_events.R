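# ---------------------------------------------------------------------------
# Structural channels of the synthetic allotetraploid: homeologous exchanges
# of the three dosage classes, gene models and fates, depth tracks, and
# homeolog expression.  Homeology in the simulated system is the identity
# map: chromosome A0i pairs with B0i over identical coordinates (the
# substitution channel is indel-free).
# ---------------------------------------------------------------------------

sample_names <- function(config) sprintf("S%02d", seq_len(config$n_samples))

# draw a non-overlapping interval on [0, L) of given size, telomere-biased
draw_interval <- function(L, size, telomere_bias, telomere_window, occupied) {
  for (attempt in 1:500) {
    biased <- stats::runif(1) < telomere_bias
    if (biased) {
      left <- stats::runif(1) < 0.5
      lo <- if (left) 0 else max(0, L - telomere_window)
      hi <- if (left) min(telomere_window, L) - size else L - size
      if (hi <= lo) biased <- FALSE  # event larger than the window: uniform
      else start <- floor(stats::runif(1, lo, hi))
    }
    if (!biased) start <- floor(stats::runif(1, 0, L - size))
    end <- start + size
    clash <- any(occupied$start < end & occupied$end > start)
    if (!clash) return(c(start, end))
  }
  stop("overlapping planted events: could not place exchange interval")
}

#' Plant homeologous exchanges of all three dosage classes
#'
#' Segmental (4:0) exchanges replace a recipient interval with its homeolog
#' in a random subset of samples; balanced (2:2) exchanges swap reciprocal
#' homeologous intervals in every sample; nonreciprocal (3:1) exchanges copy
#' a non-homeologous interval over a recipient in one sample.  Event
#' midpoints are telomere-biased.  When at least two segmental events are
#' planted and the configured size range straddles `he_min_size`, one event
#' is forced below the minimum as a negative control for the caller's size
#' filter; truth rows carry a `detectable` flag.
#'
#' @param sim a `pf_sim` after [plant_mutations()].
#' @return the updated `pf_sim` with `$truth$hes`.
#' @export
plant_homeologous_exchanges <- function(sim) {
  config <- sim$config
  withr::with_seed(stage_seed(config, "hes"), {
    L <- config$chrom_length
    tw <- config$telomere_window
    samples <- sample_names(config)
    occupied <- lapply(block_ids(config), function(b)
      data.frame(start = numeric(0), end = numeric(0)))
    names(occupied) <- block_ids(config)
    rows <- list()
    he_id <- 0L

    draw_size <- function() {
      round(stats::runif(1, config$he_size_range[1], config$he_size_range[2]))
    }
    sizes_seg <- replicate(config$n_segmental_he, draw_size())
    rng <- config$he_size_range
    # negative control: keep one event clearly below the caller minimum
    # (one window below, so window-grid rounding cannot lift it over)
    neg_cap <- config$he_min_size - config$window_size
    if (config$n_segmental_he >= 2 && rng[1] < neg_cap &&
        rng[2] >= config$he_min_size) {
      if (all(sizes_seg >= neg_cap))
        sizes_seg[1] <- round(stats::runif(1, rng[1], neg_cap - 1))
      if (all(sizes_seg < config$he_min_size))
        sizes_seg[2] <- round(stats::runif(1, config$he_min_size, rng[2]))
      sizes_seg[sizes_seg >= neg_cap & sizes_seg < config$he_min_size] <-
        config$he_min_size
    }

    add_event <- function(class, donor_block, donor_sub, size, recip_block,
                          carriers) {
      he_id <<- he_id + 1L
      iv <- draw_interval(L, size, config$telomere_bias, tw, occupied[[donor_block]])
      occupied[[donor_block]] <<- rbind(occupied[[donor_block]],
                                        data.frame(start = iv[1], end = iv[2]))
      if (class == "nonreciprocal" || recip_block != donor_block) {
        # non-homeologous recipient interval of the same size
        iv2 <- draw_interval(L, size, config$telomere_bias, tw, occupied[[recip_block]])
        occupied[[recip_block]] <<- rbind(occupied[[recip_block]],
                                          data.frame(start = iv2[1], end = iv2[2]))
      } else {
        iv2 <- iv  # homeologous partner: identical coordinates, other subgenome
        occupied[[recip_block]] <<- rbind(occupied[[recip_block]],
                                          data.frame(start = iv2[1], end = iv2[2]))
      }
      recip_sub <- if (class == "nonreciprocal") donor_sub else setdiff(c("A", "B"), donor_sub)
      donor_chrom <- sub("^A", donor_sub, donor_block)
      recip_chrom <- sub("^A", recip_sub, recip_block)
      data.frame(
        he_id = sprintf("HE%03d", he_id), class = class,
        donor_chrom = donor_chrom, donor_start = iv[1], donor_end = iv[2],
        recip_chrom = recip_chrom, recip_start = iv2[1], recip_end = iv2[2],
        size = size,
        direction = paste0(donor_sub, "->", recip_sub),
        samples = paste(carriers, collapse = ","),
        detectable = size >= config$he_min_size,
        stringsAsFactors = FALSE
      )
    }

    for (i in seq_len(config$n_segmental_he)) {
      b <- sample(block_ids(config), 1)
      donor_sub <- sample(c("A", "B"), 1)
      n_car <- sample.int(config$n_samples, 1)
      carriers <- sort(sample(samples, n_car))
      rows[[length(rows) + 1L]] <-
        add_event("segmental", b, donor_sub, sizes_seg[i], b, carriers)
    }
    for (i in seq_len(config$n_balanced_he)) {
      b <- sample(block_ids(config), 1)
      size <- round(stats::runif(1, max(3e4, rng[1]), max(3e4, rng[2])))
      rows[[length(rows) + 1L]] <-
        add_event("balanced", b, sample(c("A", "B"), 1), size, b, samples)
    }
    for (i in seq_len(config$n_nonreciprocal_he)) {
      bs <- block_ids(config)
      donor_b <- sample(bs, 1)
      recip_b <- if (length(bs) > 1) sample(setdiff(bs, donor_b), 1) else donor_b
      donor_sub <- sample(c("A", "B"), 1)
      carriers <- sample(samples, 1)
      rows[[length(rows) + 1L]] <-
        add_event("nonreciprocal", donor_b, donor_sub,
                  round(stats::runif(1, max(2.5e4, rng[1]), max(2.5e4, rng[2]))),
                  recip_b, carriers)
    }
    sim$truth$hes <- if (length(rows)) do.call(rbind, rows) else NULL
    sim
  })
}

#' The simulated homeology/synteny map
#'
#' Whole-chromosome segment pairs (A0i paired with B0i over identical
#' coordinates) plus the homeologous gene pairs.
#'
#' @param sim a `pf_sim`.
#' @return list with `$segments` and `$gene_pairs` data.frames (the format
#'   consumed by the exchange callers).
#' @export
sim_synteny_map <- function(sim) {
  config <- sim$config
  blocks <- block_ids(config)
  segments <- data.frame(
    chrom_a = blocks, start_a = 0, end_a = config$chrom_length,
    chrom_b = sub("^A", "B", blocks), start_b = 0, end_b = config$chrom_length,
    orientation = "+", stringsAsFactors = FALSE
  )
  gene_pairs <- NULL
  if (!is.null(sim$truth$genes)) {
    g <- sim$truth$genes
    gene_pairs <- data.frame(
      gene_a = paste0(g$gene_id, "_A"), chrom_a = g$block,
      start_a = g$start, end_a = g$end,
      gene_b = paste0(g$gene_id, "_B"), chrom_b = sub("^A", "B", g$block),
      start_b = g$start, end_b = g$end,
      stringsAsFactors = FALSE
    )
  }
  list(segments = segments, gene_pairs = gene_pairs)
}

#' Place gene models and draw gene fates
#'
#' Genes are single-CDS models placed one per equal-width slot along each
#' chromosome (uniform within the slot), identical coordinates on the two
#' homeologs.  Fates are drawn independently per subgenome from the
#' configured pseudogene/deletion fractions; pseudogene defects are a
#' premature stop or a 1-bp frameshift deletion with equal probability, and
#' a small fraction (2%) of intact copies carry a 6-bp in-frame deletion.
#'
#' @param sim a `pf_sim`.
#' @return updated `pf_sim` with `$truth$genes` and `$truth$gene_fates`.
#' @export
plant_genes <- function(sim) {
  config <- sim$config
  withr::with_seed(stage_seed(config, "genes"), {
    L <- config$chrom_length
    n <- config$gene_count
    if (n == 0) return(sim)
    slot <- floor(L / n)
    max_len <- 3 * floor(config$gene_length_range[2] / 3)
    if (slot < max_len + 10)
      stop("too many genes for chromosome length")
    rows <- list()
    for (b in block_ids(config)) {
      len <- 3 * floor(stats::runif(n, config$gene_length_range[1],
                                    config$gene_length_range[2]) / 3)
      start <- (seq_len(n) - 1L) * slot +
        floor(stats::runif(n, 0, slot - len - 1))
      rows[[b]] <- data.frame(
        gene_id = sprintf("g%s_%04d", sub("^A", "", b), seq_len(n)),
        block = b, start = start, end = start + len, length = len,
        strand = sample(c("+", "-"), n, replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
    genes <- do.call(rbind, c(rows, make.row.names = FALSE))
    draw_fate <- function(p_pseudo, p_del, k) {
      u <- stats::runif(k)
      ifelse(u < p_del, "deleted",
             ifelse(u < p_del + p_pseudo, "pseudogene", "intact"))
    }
    fates <- rbind(
      data.frame(gene_id = genes$gene_id, subgenome = "A",
                 status = draw_fate(config$pseudogene_fraction_A,
                                    config$deletion_fraction_A, nrow(genes)),
                 stringsAsFactors = FALSE),
      data.frame(gene_id = genes$gene_id, subgenome = "B",
                 status = draw_fate(config$pseudogene_fraction_B,
                                    config$deletion_fraction_B, nrow(genes)),
                 stringsAsFactors = FALSE)
    )
    fates$defect <- NA_character_
    ps <- fates$status == "pseudogene"
    fates$defect[ps] <- sample(c("premature_stop", "frameshift_indel"),
                               sum(ps), replace = TRUE)
    intact <- which(fates$status == "intact")
    inframe <- intact[stats::runif(length(intact)) < 0.02]
    fates$defect[inframe] <- "inframe_deletion"
    sim$truth$genes <- genes
    sim$truth$gene_fates <- fates
    sim
  })
}

#' Truth origin of every depth window
#'
#' A-subgenome chromosomes are AA-derived and B-subgenome chromosomes
#' BB-derived, except inside balanced exchanges, where both reciprocal
#' intervals switch origin.  Windows are labeled by their midpoint.
#'
#' @param sim a `pf_sim`.
#' @param window_size window width (bp), default from the config.
#' @return data.frame chrom, start, end, origin.
#' @export
window_origins <- function(sim, window_size = sim$config$window_size) {
  config <- sim$config
  chroms <- c(block_ids(config), sub("^A", "B", block_ids(config)))
  out <- list()
  for (ch in chroms) {
    starts <- seq(0, config$chrom_length - 1, by = window_size)
    ends <- pmin(starts + window_size, config$chrom_length)
    origin <- rep(if (startsWith(ch, "A")) "AA" else "BB", length(starts))
    hes <- sim$truth$hes
    if (!is.null(hes)) {
      bal <- hes[hes$class == "balanced", , drop = FALSE]
      mid <- (starts + ends) / 2
      for (i in seq_len(nrow(bal))) {
        for (side in c("donor", "recip")) {
          if (bal[[paste0(side, "_chrom")]][i] == ch) {
            inside <- mid >= bal[[paste0(side, "_start")]][i] &
              mid < bal[[paste0(side, "_end")]][i]
            if (any(inside))
              origin[inside] <- setdiff(c("AA", "BB"), origin[inside][1])
          }
        }
      }
    }
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            origin = origin, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# per-window copy number for a tetraploid sample (baseline 2 per homeolog)
window_copy_number <- function(sim, sample, window_size) {
  config <- sim$config
  chroms <- c(block_ids(config), sub("^A", "B", block_ids(config)))
  out <- list()
  hes <- sim$truth$hes
  for (ch in chroms) {
    starts <- seq(0, config$chrom_length - 1, by = window_size)
    ends <- pmin(starts + window_size, config$chrom_length)
    cn <- rep(2, length(starts))
    if (!is.null(hes)) {
      mid <- (starts + ends) / 2
      for (i in seq_len(nrow(hes))) {
        carriers <- strsplit(hes$samples[i], ",")[[1]]
        if (!(sample %in% carriers)) next
        cls <- hes$class[i]
        if (cls == "balanced") next  # dosage-neutral
        dup_cn <- if (cls == "segmental") 4 else 3
        del_cn <- if (cls == "segmental") 0 else 1
        if (hes$donor_chrom[i] == ch)
          cn[mid >= hes$donor_start[i] & mid < hes$donor_end[i]] <- dup_cn
        if (hes$recip_chrom[i] == ch)
          cn[mid >= hes$recip_start[i] & mid < hes$recip_end[i]] <- del_cn
      }
    }
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends, cn = cn,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Simulate a per-window depth track
#'
#' Tetraploid samples: window depth is Poisson with mean
#' `depth_mean x copy_number / 2`, copy numbers taken from the planted-event
#' truth (0/4 for segmental donors/recipients, 1/3 for nonreciprocal, 2
#' elsewhere).  The special sample `"diploid"` models the AA diploid mapped
#' onto the tetraploid reference: AA-origin windows at `depth_mean`, BB
#' windows at zero.  Negative-binomial overdispersion is available through
#' the config; `noise = FALSE` returns the exact expectation (useful as a
#' noise-free control).
#'
#' @param sim a `pf_sim`.
#' @param sample one of the tetraploid sample names or `"diploid"`.
#' @param window_size window width (bp).
#' @param noise logical; `FALSE` gives the deterministic expectation.
#' @return a [depth_track()].
#' @export
simulate_depth <- function(sim, sample = "diploid",
                           window_size = sim$config$window_size,
                           noise = TRUE) {
  config <- sim$config
  if (window_size <= 0) stop("window size must be positive")
  seed <- stage_seed(config, "depth") +
    131L * match(sample, c("diploid", sample_names(config)), nomatch = 99L)
  withr::with_seed(seed, {
    if (identical(sample, "diploid")) {
      org <- window_origins(sim, window_size)
      lambda <- config$depth_mean * (org$origin == "AA")
      grid <- org
    } else {
      if (!sample %in% sample_names(config)) stop("unknown sample: ", sample)
      cnw <- window_copy_number(sim, sample, window_size)
      lambda <- config$depth_mean * cnw$cn / 2
      grid <- cnw
    }
    depth <- if (!noise) lambda
    else if (is.finite(config$depth_overdispersion))
      stats::rnbinom(length(lambda), mu = lambda, size = config$depth_overdispersion)
    else stats::rpois(length(lambda), lambda)
    depth_track(grid$chrom, grid$start, grid$end, depth,
                sample = sample, reference = "PF_synthetic")
  })
}

#' Simulate homeolog expression with a dominance shift
#'
#' Per gene pair the log2(A/B) ratio is drawn from a three-component mixture:
#' a narrow conserved component at 0 (weight 0.55, sd 0.05), a broad
#' divergent background at 0 (sd 0.6), and a dominance component at
#' `expression_dominance_shift` (weight `expression_dominance_weight`,
#' sd 0.04).  TPM pairs are built around a log-normal baseline with small
#' replicate noise; pseudogene/deleted copies get TPM near zero.
#'
#' @param sim a `pf_sim` after [plant_genes()].
#' @return data.frame: gene_a, gene_b, replicate, tpm_a, tpm_b.
#' @export
simulate_expression <- function(sim) {
  config <- sim$config
  genes <- sim$truth$genes
  if (is.null(genes)) stop("plant_genes() must run before simulate_expression()")
  withr::with_seed(stage_seed(config, "expression"), {
    n <- nrow(genes)
    w_dom <- config$expression_dominance_weight
    comp <- sample.int(3L, n, replace = TRUE,
                       prob = c(0.55, 1 - 0.55 - w_dom, w_dom))
    ratio <- c(stats::rnorm(n, 0, 0.03),
               stats::rnorm(n, 0, 0.6),
               stats::rnorm(n, config$expression_dominance_shift, 0.03))[
                 (comp - 1L) * n + seq_len(n)]
    base <- stats::rnorm(n, 4, 1.5)
    fates <- sim$truth$gene_fates
    fate_a <- fates$status[fates$subgenome == "A"][match(genes$gene_id,
                fates$gene_id[fates$subgenome == "A"])]
    fate_b <- fates$status[fates$subgenome == "B"][match(genes$gene_id,
                fates$gene_id[fates$subgenome == "B"])]
    out <- list()
    for (rep_i in seq_len(config$expression_replicates)) {
      eps_a <- stats::rnorm(n, 0, 0.02)
      eps_b <- stats::rnorm(n, 0, 0.02)
      tpm_a <- 2^(base + ratio / 2 + eps_a)
      tpm_b <- 2^(base - ratio / 2 + eps_b)
      tpm_a[fate_a == "pseudogene"] <- stats::runif(sum(fate_a == "pseudogene"), 0, 0.5)
      tpm_b[fate_b == "pseudogene"] <- stats::runif(sum(fate_b == "pseudogene"), 0, 0.5)
      tpm_a[fate_a == "deleted"] <- 0
      tpm_b[fate_b == "deleted"] <- 0
      out[[rep_i]] <- data.frame(
        gene_a = paste0(genes$gene_id, "_A"), gene_b = paste0(genes$gene_id, "_B"),
        replicate = rep_i, tpm_a = tpm_a, tpm_b = tpm_b,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, c(out, make.row.names = FALSE))
  })
}

#' Materialize one sample's tetraploid chromosome after planted exchanges
#'
#' Applies the sequence-replacement side of the planted events carried by
#' `sample` (segmental and nonreciprocal replace recipient content with donor
#' content; balanced swaps exchange the reciprocal contents in every sample).
#'
#' @param sim a `pf_sim`.
#' @param sample sample name.
#' @param chrom chromosome (e.g. `"A01"` or `"B01"`).
#' @return integer-encoded sequence vector.
#' @export
sample_sequence <- function(sim, sample, chrom) {
  block <- sub("^B", "A", chrom)
  lin <- if (startsWith(chrom, "A")) "PFA" else "PFB"
  seq <- sim$genomes[[lin]][[block]]
  hes <- sim$truth$hes
  if (is.null(hes)) return(seq)
  lineage_of <- function(ch) if (startsWith(ch, "A")) "PFA" else "PFB"
  for (i in seq_len(nrow(hes))) {
    carriers <- strsplit(hes$samples[i], ",")[[1]]
    if (!(sample %in% carriers)) next
    if (hes$class[i] == "balanced") {
      # reciprocal swap: both intervals exchange content
      if (hes$donor_chrom[i] == chrom) {
        src <- sim$genomes[[lineage_of(hes$recip_chrom[i])]][[sub("^B", "A", hes$recip_chrom[i])]]
        seq[(hes$donor_start[i] + 1):hes$donor_end[i]] <-
          src[(hes$recip_start[i] + 1):hes$recip_end[i]]
      }
      if (hes$recip_chrom[i] == chrom) {
        src <- sim$genomes[[lineage_of(hes$donor_chrom[i])]][[sub("^B", "A", hes$donor_chrom[i])]]
        seq[(hes$recip_start[i] + 1):hes$recip_end[i]] <-
          src[(hes$donor_start[i] + 1):hes$donor_end[i]]
      }
    } else if (hes$recip_chrom[i] == chrom) {
      src <- sim$genomes[[lineage_of(hes$donor_chrom[i])]][[sub("^B", "A", hes$donor_chrom[i])]]
      seq[(hes$recip_start[i] + 1):hes$recip_end[i]] <-
        src[(hes$donor_start[i] + 1):hes$donor_end[i]]
    }
  }
  seq
}

#' Run the full simulator
#'
#' Progenitors, de novo mutations, gene models and fates, homeologous
#' exchanges, and expression -- everything except the depth tracks, which
#' are drawn on demand by [simulate_depth()].
#'
#' @param config a [sim_config()].
#' @return a complete `pf_sim` (with `$expression` attached).
#' @export
simulate_system <- function(config) {
  sim <- simulate_progenitors(config)
  sim <- plant_mutations(sim)
  sim <- plant_genes(sim)
  sim <- plant_homeologous_exchanges(sim)
  sim$expression <- simulate_expression(sim)
  sim
}
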