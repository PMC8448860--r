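depth_ratio_of <- function(tr) tr$depth / mean(tr$depth)

# hand-built two-chromosome system: A01 homeologous to B01, window 5 kb
he_fixture_track <- function(a_depth, b_depth, sample = "S1", width = 5000) {
  n <- length(a_depth)
  m <- length(b_depth)
  depth_track(c(rep("A01", n), rep("B01", m)),
              c((0:(n - 1)) * width, (0:(m - 1)) * width),
              c((1:n) * width, (1:m) * width),
              c(a_depth, b_depth), sample = sample)
}

he_fixture_map <- function(n = 40, width = 5000) {
  list(segments = data.frame(chrom_a = "A01", start_a = 0, end_a = n * width,
                             chrom_b = "B01", start_b = 0, end_b = n * width,
                             orientation = "+"),
       gene_pairs = NULL)
}

test_that("segmental calls require the dup band, the deleted homeolog and the size", {
  flat <- he_fixture_track(rep(28, 40), rep(28, 40))
  expect_equal(nrow(call_segmental_he(flat, he_fixture_map())), 0)

  # 60-kb duplication at 2x with the homeologous interval at zero
  a <- rep(28, 40); a[11:22] <- 56
  b <- rep(28, 40); b[11:22] <- 0
  tr <- he_fixture_track(a, b)
  calls <- call_segmental_he(tr, he_fixture_map())
  expect_equal(nrow(calls), 1)
  expect_identical(calls$class, "segmental")
  expect_identical(calls$donor_chrom, "A01")
  expect_identical(calls$direction, "A->B")
  expect_equal(calls$donor_start, 50000)
  expect_equal(calls$donor_end, 110000)
  expect_lt(calls$recip_ratio, 0.5)

  # 15-kb event: below the minimal size
  a2 <- rep(28, 40); a2[11:13] <- 56
  b2 <- rep(28, 40); b2[11:13] <- 0
  expect_equal(nrow(call_segmental_he(he_fixture_track(a2, b2), he_fixture_map())), 0)

  # ratio above the upper bound is not a candidate duplication (long track so
  # the event barely moves the genome mean the ratios are expressed in)
  a3 <- rep(28, 200); a3[11:22] <- 28 * 3.5
  b3 <- rep(28, 200); b3[11:22] <- 0
  tr3 <- he_fixture_track(a3, b3)
  expect_gt(min(depth_ratio_of(tr3)[11:22]), 3)
  expect_equal(nrow(call_segmental_he(tr3, he_fixture_map(200))), 0)

  # duplication whose partner is not deleted is not an exchange
  b4 <- rep(28, 40)
  expect_equal(nrow(call_segmental_he(he_fixture_track(a, b4), he_fixture_map())), 0)
})

test_that("candidates without a homeolog mapping are reported unresolved", {
  a <- rep(28, 40); a[11:22] <- 56
  tr <- he_fixture_track(a, rep(28, 40))
  no_map <- list(segments = data.frame(chrom_a = character(0), start_a = numeric(0),
                                       end_a = numeric(0), chrom_b = character(0),
                                       start_b = numeric(0), end_b = numeric(0),
                                       orientation = character(0)))
  calls <- call_segmental_he(tr, no_map)
  expect_equal(nrow(calls), 1)
  expect_identical(calls$class, "unresolved")
})

test_that("genic exchanges follow the same bands at gene resolution", {
  gene_pairs <- data.frame(
    gene_a = c("g1_A", "g2_A"), chrom_a = "A01",
    start_a = c(10000, 60000), end_a = c(12000, 62000),
    gene_b = c("g1_B", "g2_B"), chrom_b = "B01",
    start_b = c(10000, 60000), end_b = c(12000, 62000))
  a <- rep(28, 40); a[3] <- 56       # g1_A duplicated
  b <- rep(28, 40); b[3] <- 2        # g1_B deleted
  tr <- he_fixture_track(a, b)
  calls <- call_genic_he(tr, gene_pairs)
  expect_equal(nrow(calls), 1)
  expect_identical(calls$donor_gene, "g1_A")
  expect_identical(calls$direction, "A->B")

  flat <- he_fixture_track(rep(28, 40), rep(28, 40))
  expect_equal(nrow(call_genic_he(flat, gene_pairs)), 0)

  # opposite direction in a second sample: bi-directional catalog
  a2 <- rep(28, 40); a2[3] <- 2
  b2 <- rep(28, 40); b2[3] <- 56
  tr2 <- he_fixture_track(a2, b2, sample = "S2")
  both <- rbind(calls, call_genic_he(tr2, gene_pairs))
  expect_setequal(both$direction, c("A->B", "B->A"))
  sh <- sharing_summary(both)
  expect_equal(as.integer(sh$direction_totals), c(1L, 1L))
  expect_equal(sh$direction_test$p_value, 1)
})

test_that("balanced exchanges appear as reciprocal origin islands", {
  # diploid-onto-tetraploid: A01 covered except a swapped island, B01 empty
  # except the reciprocal island
  a <- rep(28, 60); a[25:36] <- 0
  b <- rep(0, 60); b[25:36] <- 28
  part <- partition_depth_track(he_fixture_track(a, b))
  map <- he_fixture_map(60)
  calls <- call_balanced_he(part, map)
  expect_equal(nrow(calls), 1)
  expect_identical(calls$class, "balanced")
  expect_equal(calls$donor_start, 120000)
  expect_equal(calls$donor_end, 180000)
  expect_equal(calls$switched_fraction, 1)

  # island without a reciprocal partner: one-sided
  part2 <- partition_depth_track(he_fixture_track(a, rep(0, 60)))
  calls2 <- call_balanced_he(part2, map)
  expect_equal(nrow(calls2), 1)
  expect_identical(calls2$class, "one_sided")

  flat <- partition_depth_track(he_fixture_track(rep(28, 60), rep(0, 60)))
  expect_equal(nrow(call_balanced_he(flat, map)), 0)

  # flanks shorter than min_flank suppress the island
  short <- partition_depth_track(he_fixture_track(c(rep(28, 6), rep(0, 12), rep(28, 42)),
                                                  rep(0, 60)))
  expect_equal(nrow(call_balanced_he(short, map, min_flank = 10)), 0)
})

test_that("nonreciprocal 3:1 calls use the intermediate dosage bands", {
  cands <- data.frame(chrom_a = "A01", start_a = 50000, end_a = 110000,
                      chrom_b = "B01", start_b = 0, end_b = 60000)
  a <- rep(28, 40); a[11:22] <- 42   # 1.5x
  b <- rep(28, 40); b[1:12] <- 14    # 0.5x
  tr <- he_fixture_track(a, b)
  calls <- call_nonreciprocal_he(tr, cands)
  expect_equal(nrow(calls), 1)
  expect_identical(calls$class, "nonreciprocal")

  flat <- he_fixture_track(rep(28, 40), rep(28, 40))
  expect_equal(nrow(call_nonreciprocal_he(flat, cands)), 0)

  # a 2.0x / 0x pair belongs to the segmental logic, not 3:1
  a2 <- rep(28, 40); a2[11:22] <- 56
  b2 <- rep(28, 40); b2[1:12] <- 0
  expect_equal(nrow(call_nonreciprocal_he(he_fixture_track(a2, b2), cands)), 0)

  scanned <- scan_nonreciprocal_candidates(tr, min_size = 3e4)
  expect_equal(nrow(call_nonreciprocal_he(tr, scanned)), 1)
})

test_that("telomere enrichment counts HE genes in terminal windows", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:100), chrom = "A01",
                      start = seq(0, 990000, by = 10000),
                      end = seq(0, 990000, by = 10000) + 2000)
  sizes <- c(A01 = 1e6)
  calls <- data.frame(donor_gene = c("g001", "g002"),
                      recip_gene = c(NA, NA))
  enr <- telomere_enrichment(calls, genes, sizes, window = 1e5)
  expect_equal(enr$observed, 2)
  expect_equal(enr$total, 2)
  expect_equal(enr$expected_proportion, 0.2)
  expect_error(telomere_enrichment(calls, genes, sizes, window = 6e5),
               "degenerate window")
})

test_that("telomere enrichment is calibrated under uniform placement", {
  set.seed(61)
  genes <- data.frame(gene_id = sprintf("g%04d", 1:800), chrom = "A01",
                      start = 0, end = 0)
  genes$start <- floor(runif(800, 0, 4.9e6))
  genes$end <- genes$start + 1500
  sizes <- c(A01 = 5e6)
  hits <- 0L
  for (i in 1:200) {
    chosen <- sample(genes$gene_id, 40)
    calls <- data.frame(donor_gene = chosen, recip_gene = NA_character_)
    enr <- telomere_enrichment(calls, genes, sizes, window = 1e6)
    if (enr$test$p_value < 1e-3) hits <- hits + 1L
  }
  expect_lte(hits, 2)  # type-I at most nominal-ish over 200 null draws
})

test_that("sharing summary groups events by reciprocal overlap", {
  mk <- function(sample, ds, de, rs, re, dir = "A->B")
    data.frame(class = "segmental", sample = sample, donor_chrom = "A01",
               donor_start = ds, donor_end = de, recip_chrom = "B01",
               recip_start = rs, recip_end = re, size = de - ds,
               donor_ratio = 2, recip_ratio = 0.1, direction = dir)
  calls <- rbind(mk("S1", 100000, 160000, 100000, 160000),
                 mk("S2", 100000, 155000, 100000, 155000),
                 mk("S3", 102000, 160000, 102000, 160000),
                 mk("S1", 400000, 460000, 400000, 460000, dir = "B->A"))
  sh <- sharing_summary(calls)
  expect_equal(nrow(sh$events), 2)
  expect_setequal(sh$events$occurrences, c(3L, 1L))
  expect_match(sh$note, "ambiguous")
})

test_that("planted exchanges are recovered exactly without noise and nearly at 16x", {
  cfg <- sim_config(seed = 71, n_chromosomes = 2, chrom_length = 5e5,
                    gene_count = 0, n_segmental_he = 3, n_balanced_he = 1,
                    n_nonreciprocal_he = 1, he_size_range = c(1e4, 6e4),
                    window_size = 5000, depth_mean = 28, n_samples = 3)
  sim <- plant_homeologous_exchanges(plant_genes(plant_mutations(simulate_progenitors(cfg))))
  map <- sim_synteny_map(sim)
  th <- sim$truth$hes
  seg_t <- th[th$class == "segmental" & th$detectable, ]
  neg_t <- th[th$class == "segmental" & !th$detectable, ]
  overlap_ok <- function(call, truth) {
    ov <- max(0, min(call$donor_end, truth$donor_end) -
                max(call$donor_start, truth$donor_start))
    min(ov / (call$donor_end - call$donor_start),
        ov / (truth$donor_end - truth$donor_start)) >= 0.5
  }
  for (s in sprintf("S%02d", 1:3)) {
    tr <- simulate_depth(sim, s, noise = FALSE)
    calls <- call_segmental_he(tr, map)
    carried <- seg_t[vapply(strsplit(seg_t$samples, ","),
                            function(x) s %in% x, logical(1)), ]
    expect_equal(nrow(calls), nrow(carried))
    for (i in seq_len(nrow(carried)))
      expect_true(any(vapply(seq_len(nrow(calls)), function(j)
        calls$donor_chrom[j] == carried$donor_chrom[i] &&
          overlap_ok(calls[j, ], carried[i, ]), logical(1))))
    # the sub-minimum planted event is never called segmentally
    for (i in seq_len(nrow(neg_t)))
      expect_false(any(vapply(seq_len(nrow(calls)), function(j)
        calls$donor_chrom[j] == neg_t$donor_chrom[i] &&
          overlap_ok(calls[j, ], neg_t[i, ]), logical(1))))
  }

  # balanced recovery from the noise-free diploid partition
  part <- partition_depth_track(simulate_depth(sim, "diploid", noise = FALSE))
  bal <- call_balanced_he(part, map)
  bal <- bal[bal$class == "balanced", ]
  expect_equal(nrow(bal), 1)
})
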