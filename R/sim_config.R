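#' Default six-class substitution spectrum
#'
#' Relative frequencies over the pyrimidine-collapsed classes
#' `C>A, C>G, C>T, T>A, T>C, T>G`.  The default places 40% of all mutations
#' in the C>T class (the G:C -> A:T transition pair) and fixes the overall
#' transition/transversion ratio at 1.8, the regime typical of spontaneous
#' plant mutation dominated by deamination of methylated cytosines.
#'
#' @param gc_to_at fraction of mutations in the C>T class.
#' @param tstv transition/transversion ratio.
#' @return named numeric vector of six frequencies summing to 1.
#' @export
default_spectrum6 <- function(gc_to_at = 0.40, tstv = 1.8) {
  ts_total <- tstv / (1 + tstv)
  if (gc_to_at > ts_total)
    stop("gc_to_at cannot exceed the total transition mass implied by tstv")
  tc <- ts_total - gc_to_at
  tv_each <- (1 - ts_total) / 4
  s <- c("C>A" = tv_each, "C>G" = tv_each, "C>T" = gc_to_at,
         "T>A" = tv_each, "T>C" = tc, "T>G" = tv_each)
  s / sum(s)
}

#' Simulator configuration
#'
#' Builds and validates the configuration for the synthetic allotetraploid
#' system.  The defaults describe the study conditions the package is built
#' around: two diploid progenitors at a synonymous-scale divergence of 0.034,
#' a tetraploid mutation excess of 10% over the diploid, a 40% G:C -> A:T /
#' Ts:Tv 1.8 mutation spectrum, telomere-biased homeologous exchanges of all
#' three dosage classes, asymmetric gene loss between subgenomes, Poisson
#' depth noise at 28x, and a small (+0.2 log2) expression-dominance shift.
#'
#' @param seed integer seed; every simulator stage derives its RNG state
#'   deterministically from it.
#' @param n_chromosomes chromosomes per subgenome.
#' @param chrom_length chromosome length in bp.
#' @param progenitor_divergence expected substitutions/site between the AA and
#'   BB progenitors (sum over both lineages).
#' @param pc99_divergence substitutions/site separating the second AA diploid
#'   accession (PC99) from the reference AA lineage; modelled entirely on the
#'   PC99 branch so the reference diploid retains the ancestral state.
#' @param diploid_mutation_rate de novo mutations per bp on each diploid
#'   lineage since polyploidization.
#' @param tetraploid_excess multiplicative excess of the tetraploid rate over
#'   the diploid rate (1.10 = +10%).
#' @param spectrum6 six-class substitution spectrum, see [default_spectrum6()].
#' @param context_modifiers optional list of six numeric vectors of length 16
#'   (5' x 3' context weights, contexts ordered `AA, AC, ..., TT`) skewing the
#'   trinucleotide context of planted mutations within each class.
#' @param mutation_spacing minimal distance (bp) between any two variant
#'   sites so that every planted mutation is callable under the flank rule;
#'   set `enforce_spacing = FALSE` to disable (for testing the flank filter).
#' @param enforce_spacing logical, see `mutation_spacing`.
#' @param n_segmental_he,n_balanced_he,n_nonreciprocal_he planted event counts.
#' @param n_samples tetraploid resequencing samples carrying population HEs.
#' @param he_size_range segmental/nonreciprocal event size range (bp).  When
#'   two or more segmental events are planted and the range straddles
#'   `he_min_size`, at least one event is forced below it as a built-in
#'   negative control for the caller's size filter.
#' @param he_min_size caller minimal size the truth set annotates
#'   detectability against (bp).
#' @param telomere_bias probability that a planted exchange falls within the
#'   telomere window.
#' @param telomere_window telomeric span at each chromosome end (bp); 2 Mb,
#'   shrunk proportionally (0.4 x length) for chromosomes under 5 Mb.
#' @param gene_count genes per chromosome (each has a homeologous partner).
#' @param gene_length_range CDS length range in bp (rounded to codons).
#' @param pseudogene_fraction_A,deletion_fraction_A,pseudogene_fraction_B,deletion_fraction_B
#'   per-subgenome gene-fate fractions (defaults reflect strong AA dominance).
#' @param depth_mean mean per-window read depth at diploid dosage (2 copies).
#' @param window_size depth/partition window (bp).
#' @param depth_overdispersion negative-binomial size parameter; `Inf`
#'   (default) gives pure Poisson noise.
#' @param expression_dominance_shift log2 shift of the dominance component.
#' @param expression_dominance_weight mixture weight of that component.
#' @param expression_replicates expression replicates per gene pair.
#' @return validated list of class `pf_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 5e6,
                       progenitor_divergence = 0.034,
                       pc99_divergence = 0.011,
                       diploid_mutation_rate = 1.5e-3,
                       tetraploid_excess = 1.10,
                       spectrum6 = default_spectrum6(),
                       context_modifiers = NULL,
                       mutation_spacing = 5L,
                       enforce_spacing = TRUE,
                       n_segmental_he = 3L,
                       n_balanced_he = 1L,
                       n_nonreciprocal_he = 1L,
                       n_samples = 4L,
                       he_size_range = c(1e4, 8e4),
                       he_min_size = 2e4,
                       telomere_bias = 0.6,
                       telomere_window = 2e6,
                       gene_count = 200L,
                       gene_length_range = c(300, 900),
                       pseudogene_fraction_A = 0.029,
                       deletion_fraction_A = 0.031,
                       pseudogene_fraction_B = 0.066,
                       deletion_fraction_B = 0.196,
                       depth_mean = 28,
                       window_size = 5000L,
                       depth_overdispersion = Inf,
                       expression_dominance_shift = 0.2,
                       expression_dominance_weight = 0.08,
                       expression_replicates = 3L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(
      seed == round(seed), n_chromosomes >= 1, chrom_length >= 1000,
      progenitor_divergence >= 0, pc99_divergence >= 0,
      diploid_mutation_rate >= 0, tetraploid_excess > 0,
      length(spectrum6) == 6, all(spectrum6 >= 0),
      mutation_spacing >= 1,
      n_segmental_he >= 0, n_balanced_he >= 0, n_nonreciprocal_he >= 0,
      n_samples >= 1, length(he_size_range) == 2, he_size_range[1] > 0,
      he_size_range[1] <= he_size_range[2],
      telomere_bias >= 0, telomere_bias <= 1,
      gene_count >= 0, depth_mean > 0, window_size >= 1,
      expression_replicates >= 1
    )
  })
  if (abs(sum(cfg$spectrum6) - 1) > 1e-3)
    stop("spectrum6 must sum to 1")
  cfg$spectrum6 <- cfg$spectrum6 / sum(cfg$spectrum6)  # absorb rounding
  if (!is.null(cfg$context_modifiers)) {
    ok <- is.list(cfg$context_modifiers) && length(cfg$context_modifiers) == 6 &&
      all(vapply(cfg$context_modifiers, length, 1L) == 16)
    if (!ok) stop("context_modifiers must be a list of six length-16 weight vectors")
  }
  # telomere window scales down on short chromosomes (0.4 x length, the same
  # proportion 2 Mb takes of a 5 Mb chromosome)
  cfg$telomere_window <- min(cfg$telomere_window, 0.4 * cfg$chrom_length)
  cfg$tetraploid_mutation_rate <- cfg$diploid_mutation_rate * cfg$tetraploid_excess
  structure(cfg, class = "pf_config")
}

#' @export
print.pf_config <- function(x, ...) {
  cat("polyforge simulator config\n")
  cat(sprintf("  genome: %d chromosome(s)/subgenome x %s bp\n",
              x$n_chromosomes, format(x$chrom_length, big.mark = ",")))
  cat(sprintf("  progenitor divergence %.4g; diploid rate %.3g/bp; tetraploid excess x%.2f\n",
              x$progenitor_divergence, x$diploid_mutation_rate, x$tetraploid_excess))
  cat(sprintf("  HEs: %d segmental, %d balanced, %d nonreciprocal over %d samples\n",
              x$n_segmental_he, x$n_balanced_he, x$n_nonreciprocal_he, x$n_samples))
  cat(sprintf("  depth %gx in %g-bp windows; %d genes/chromosome\n",
              x$depth_mean, x$window_size, x$gene_count))
  invisible(x)
}

#' Read / write a simulator configuration as YAML
#'
#' @param path YAML file path.
#' @return [sim_config()] object (`read_sim_config`) or `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$spectrum6)) raw$spectrum6 <- unlist(raw$spectrum6)
  if (!is.null(raw$he_size_range)) raw$he_size_range <- unlist(raw$he_size_range)
  if (!is.null(raw$gene_length_range)) raw$gene_length_range <- unlist(raw$gene_length_range)
  raw$tetraploid_mutation_rate <- NULL
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config a `pf_config`.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$spectrum6 <- as.list(x$spectrum6)
  yaml::write_yaml(x, path)
  invisible(path)
}

# deterministic per-stage RNG seeding: stage offsets keep streams independent
# while remaining reproducible from the single user seed
stage_seed <- function(config, stage) {
  offsets <- c(progenitors = 101L, mutations = 211L, hes = 307L,
               genes = 401L, depth = 503L, expression = 601L, misc = 701L)
  s <- (as.integer(config$seed) + offsets[[stage]]) %% .Machine$integer.max
  as.integer(s)
}
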