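test_that("the simulator is deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 5)
  a <- simulate_system(cfg)
  b <- simulate_system(cfg)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$truth, b$truth)
  expect_identical(a$expression, b$expression)
  d1 <- simulate_depth(a, "S01")
  d2 <- simulate_depth(b, "S01")
  expect_identical(d1$depth, d2$depth)
})

test_that("zero divergence and zero mutation rate leave sequences unchanged", {
  cfg <- tiny_config(seed = 2, progenitor_divergence = 0, pc99_divergence = 0,
                     diploid_mutation_rate = 0, tetraploid_excess = 1)
  sim <- plant_mutations(simulate_progenitors(cfg))
  expect_identical(sim$genomes$PFA, sim$ancestor)
  expect_identical(sim$genomes$PFB, sim$ancestor)
  expect_identical(sim$genomes$PC99, sim$ancestor)
  expect_equal(nrow(sim$truth$mutations), 0)
})

test_that("progenitor divergence matches the substitution-model expectation", {
  cfg <- sim_config(seed = 3, n_chromosomes = 1, chrom_length = 1e6,
                    progenitor_divergence = 0.034, gene_count = 0)
  sim <- simulate_progenitors(cfg)
  diff_frac <- mean(sim$genomes$PFA$A01 != sim$genomes$PFB$A01)
  # closed form for two branches at q = d/2 with uniform substitution:
  # P(differ) = 2q(1-q) + q^2 * (2/3)
  q <- 0.034 / 2
  expected <- 2 * q * (1 - q) + q^2 * (2 / 3)
  se <- sqrt(expected * (1 - expected) / 1e6)
  expect_lt(abs(diff_frac - expected), 3 * se)
})

test_that("planted mutation classes follow the configured spectrum", {
  cfg <- sim_config(seed = 9, n_chromosomes = 2, chrom_length = 4e5,
                    diploid_mutation_rate = 3e-3, tetraploid_excess = 1,
                    spectrum6 = rep(1 / 6, 6), gene_count = 0)
  sim <- plant_mutations(simulate_progenitors(cfg))
  tm <- sim$truth$mutations
  expect_gt(nrow(tm), 8000)
  frac <- table(tm$class6) / nrow(tm)
  se <- sqrt((1 / 6) * (5 / 6) / nrow(tm))
  expect_true(all(abs(frac - 1 / 6) < 3 * se))
})

test_that("tetraploid lineages carry the configured mutation excess", {
  cfg <- sim_config(seed = 13, n_chromosomes = 2, chrom_length = 5e5,
                    diploid_mutation_rate = 5e-3, tetraploid_excess = 1.10,
                    gene_count = 0)
  sim <- plant_mutations(simulate_progenitors(cfg))
  tm <- sim$truth$mutations
  n_t <- sum(tm$lineage %in% c("PFA", "PFB"))
  n_d <- sum(tm$lineage %in% c("PC02", "PC99"))
  ratio <- n_t / n_d
  se <- 1.10 * sqrt(1 / n_t + 1 / n_d)
  expect_lt(abs(ratio - 1.10), 3 * se)
})

test_that("planted variant sites honour the spacing rule", {
  cfg <- tiny_config(seed = 21)
  sim <- plant_mutations(simulate_progenitors(cfg))
  tm <- sim$truth$mutations
  for (b in unique(tm$block)) {
    muts <- sort(tm$pos[tm$block == b])
    others <- setdiff(sim$truth$variant_sites[[b]], muts)
    expect_true(all(diff(muts) > cfg$mutation_spacing))
    if (length(others)) {
      nearest <- vapply(muts, function(p) min(abs(others - p)), numeric(1))
      expect_true(all(nearest > cfg$mutation_spacing))
    }
    expect_true(all(muts > cfg$mutation_spacing &
                      muts <= cfg$chrom_length - cfg$mutation_spacing))
  }
})

test_that("over-dense mutation requests fail loudly", {
  cfg <- sim_config(seed = 2, n_chromosomes = 1, chrom_length = 2000,
                    diploid_mutation_rate = 0.4, gene_count = 0)
  sim <- simulate_progenitors(cfg)
  expect_error(plant_mutations(sim), "unplaceable")
})

test_that("exchange planting respects counts, bias and dosage semantics", {
  cfg0 <- tiny_config(seed = 4, n_segmental_he = 0, n_balanced_he = 0,
                      n_nonreciprocal_he = 0)
  sim0 <- plant_homeologous_exchanges(plant_genes(plant_mutations(simulate_progenitors(cfg0))))
  expect_null(sim0$truth$hes)
  expect_identical(sample_sequence(sim0, "S01", "A01"), sim0$genomes$PFA$A01)

  cfg <- tiny_config(seed = 4, telomere_bias = 1, he_size_range = c(8e3, 2.5e4))
  sim <- plant_homeologous_exchanges(plant_genes(plant_mutations(simulate_progenitors(cfg))))
  hes <- sim$truth$hes
  expect_equal(nrow(hes), cfg$n_segmental_he + cfg$n_balanced_he +
                 cfg$n_nonreciprocal_he)
  # degenerate bias: every donor interval inside a telomere window
  tw <- cfg$telomere_window
  L <- cfg$chrom_length
  expect_true(all(hes$donor_end <= tw | hes$donor_start >= L - tw))
  # built-in negative control below the caller minimum
  expect_true(any(!hes$detectable) && any(hes$detectable))

  # 4:0 semantics: carrier recipient content identical to donor content
  seg <- hes[hes$class == "segmental", ][1, ]
  carrier <- strsplit(seg$samples, ",")[[1]][1]
  rec_seq <- sample_sequence(sim, carrier, seg$recip_chrom)
  donor_lineage <- if (startsWith(seg$donor_chrom, "A")) "PFA" else "PFB"
  donor_seq <- sim$genomes[[donor_lineage]][[sub("^B", "A", seg$donor_chrom)]]
  expect_identical(rec_seq[(seg$recip_start + 1):seg$recip_end],
                   donor_seq[(seg$donor_start + 1):seg$donor_end])
  # non-carrier keeps its own content
  non_carrier <- setdiff(sprintf("S%02d", 1:cfg$n_samples),
                         strsplit(seg$samples, ",")[[1]])
  if (length(non_carrier)) {
    rec_lineage <- if (startsWith(seg$recip_chrom, "A")) "PFA" else "PFB"
    own <- sim$genomes[[rec_lineage]][[sub("^B", "A", seg$recip_chrom)]]
    iv <- (seg$recip_start + 1):seg$recip_end
    expect_identical(sample_sequence(sim, non_carrier[1], seg$recip_chrom)[iv],
                     own[iv])
  }
})

test_that("depth tracks follow the copy-number expectations", {
  cfg <- tiny_config(seed = 6, n_segmental_he = 0, n_balanced_he = 0,
                     n_nonreciprocal_he = 0, depth_mean = 28)
  sim <- plant_homeologous_exchanges(plant_genes(plant_mutations(simulate_progenitors(cfg))))
  tr <- simulate_depth(sim, "S01")
  n <- nrow(tr)
  expect_lt(abs(mean(tr$depth) - 28), 3 * sqrt(28 / n))

  cfg2 <- tiny_config(seed = 8, n_segmental_he = 2, n_balanced_he = 0,
                      n_nonreciprocal_he = 0, depth_mean = 20,
                      he_size_range = c(3e4, 5e4))
  sim2 <- plant_homeologous_exchanges(plant_genes(plant_mutations(simulate_progenitors(cfg2))))
  seg <- sim2$truth$hes[sim2$truth$hes$class == "segmental", ][1, ]
  carrier <- strsplit(seg$samples, ",")[[1]][1]
  exact <- simulate_depth(sim2, carrier, noise = FALSE)
  dup <- exact$chrom == seg$donor_chrom & exact$start >= seg$donor_start &
    exact$end <= seg$donor_end
  del <- exact$chrom == seg$recip_chrom & exact$start >= seg$recip_start &
    exact$end <= seg$recip_end
  expect_true(all(exact$depth[dup] == 40))  # 4 copies at depth_mean 20
  expect_true(all(exact$depth[del] == 0))   # deleted windows: Poisson(0)
  noisy <- simulate_depth(sim2, carrier)
  expect_true(all(noisy$depth[del] == 0))
  expect_error(simulate_depth(sim2, carrier, window_size = 0), "window size")
})

test_that("the diploid track covers only AA-origin windows", {
  cfg <- tiny_config(seed = 10)
  sim <- simulate_system(cfg)
  tr <- simulate_depth(sim, "diploid", noise = FALSE)
  org <- window_origins(sim)
  expect_identical(paste(tr$chrom, tr$start), paste(org$chrom, org$start))
  expect_true(all(tr$depth[org$origin == "BB"] == 0))
  expect_true(all(tr$depth[org$origin == "AA"] == cfg$depth_mean))
})

test_that("expression ratios centre at zero without a dominance shift", {
  cfg <- tiny_config(seed = 12, expression_dominance_shift = 0,
                     pseudogene_fraction_A = 0, deletion_fraction_A = 0,
                     pseudogene_fraction_B = 0, deletion_fraction_B = 0,
                     gene_count = 400, chrom_length = 4e5)
  sim <- plant_genes(plant_mutations(simulate_progenitors(cfg)))
  expr <- simulate_expression(sim)
  r <- log2_bias(expr$tpm_a, expr$tpm_b)
  expect_lt(abs(mean(r)), 3 * sd(r) / sqrt(length(r)))
})

test_that("deleted homeologs drive strongly one-sided expression", {
  cfg <- tiny_config(seed = 14, deletion_fraction_B = 1,
                     pseudogene_fraction_B = 0)
  sim <- plant_genes(plant_mutations(simulate_progenitors(cfg)))
  expr <- simulate_expression(sim)
  expect_true(all(expr$tpm_b == 0))
  expect_true(mean(log2_bias(expr$tpm_a, expr$tpm_b)) > 2)
})

test_that("truth sets round-trip through the TSV writers", {
  cfg <- tiny_config(seed = 16)
  sim <- simulate_system(cfg)
  dir <- tempfile()
  write_truth_set(sim, dir)
  back <- read_truth_set(dir)
  expect_equal(back$mutations, sim$truth$mutations)
  expect_equal(back$hes, sim$truth$hes)
  expect_equal(back$genes, sim$truth$genes)
  expect_equal(back$window_origins, window_origins(sim))
})

test_that("configs round-trip through YAML", {
  cfg <- tiny_config(seed = 23, depth_mean = 17)
  p <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, p)
  back <- read_sim_config(p)
  expect_equal(back$depth_mean, 17)
  expect_equal(back$spectrum6, cfg$spectrum6, tolerance = 1e-6)
  expect_equal(back$seed, cfg$seed)
})
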