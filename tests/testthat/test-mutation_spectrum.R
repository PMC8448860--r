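test_that("the 1:3 + flank rule calls exactly the right columns", {
  base <- rand_bases(21)
  base[11] <- "A"
  mut <- base; mut[11] <- "G"
  msa <- make_msa(collapse(mut), collapse(base), collapse(base), collapse(base))
  calls <- call_mutations(msa)
  expect_equal(nrow(calls), 1)
  expect_identical(calls$carrier, "PFA")
  expect_identical(calls$anc, "A")
  expect_identical(calls$der, "G")
  expect_equal(calls$column, 10)  # 0-based
  expect_equal(calls$pos, 10)

  # four identical rows: silence
  quiet <- make_msa(collapse(base), collapse(base), collapse(base), collapse(base))
  expect_equal(nrow(call_mutations(quiet)), 0)

  # mismatch 3 columns from the interval edge fails the flank rule
  edge <- base; edge[4] <- setdiff(c("A", "C", "G", "T"), base[4])[1]
  expect_equal(nrow(call_mutations(make_msa(collapse(edge), collapse(base),
                                            collapse(base), collapse(base)))), 0)

  # 2:2 columns are progenitor-divergence sites, not mutations
  b2 <- base
  b2[11] <- "A"
  m2 <- base; m2[11] <- "G"
  msa22 <- make_msa(collapse(m2), collapse(m2), collapse(b2), collapse(b2))
  expect_equal(nrow(call_mutations(msa22)), 0)

  # intervals shorter than 2*flank+1 yield no calls, silently
  tiny <- make_msa("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC")
  expect_equal(nrow(call_mutations(tiny)), 0)
})

test_that("two 1:3 columns within the flank window reject each other", {
  base <- rand_bases(30)
  m <- base
  m[14] <- setdiff(c("A", "C", "G", "T"), base[14])[1]
  m[17] <- setdiff(c("A", "C", "G", "T"), base[17])[1]  # 3 bp apart
  msa <- make_msa(collapse(m), collapse(base), collapse(base), collapse(base))
  expect_equal(nrow(call_mutations(msa)), 0)

  # at distance 6 both survive
  m2 <- base
  m2[12] <- setdiff(c("A", "C", "G", "T"), base[12])[1]
  m2[18] <- setdiff(c("A", "C", "G", "T"), base[18])[1]
  msa2 <- make_msa(collapse(m2), collapse(base), collapse(base), collapse(base))
  expect_equal(nrow(call_mutations(msa2)), 2)
})

test_that("gaps and N in the focal or flank columns suppress calls", {
  base <- rand_bases(21)
  m <- base; m[11] <- setdiff(c("A", "C", "G", "T"), base[11])[1]
  g <- base; g[8] <- "-"
  expect_equal(nrow(call_mutations(make_msa(collapse(m), collapse(g),
                                            collapse(base), collapse(base)))), 0)
  n <- base; n[13] <- "N"
  expect_equal(nrow(call_mutations(make_msa(collapse(m), collapse(n),
                                            collapse(base), collapse(base)))), 0)
})

test_that("classification collapses strands onto pyrimidine-centred classes", {
  a <- classify_mutation("C", "T", "A", "G")
  expect_identical(a$class6, "C>T")
  expect_identical(a$class96, "A[C>T]G")
  expect_true(a$is_transition)

  # purine ancestral: reverse-complement the whole triple
  b <- classify_mutation("G", "A", "C", "T")
  expect_identical(b$class96, "A[C>T]G")

  d <- classify_mutation("T", "G", "T", "T")
  expect_identical(d$class96, "T[T>G]T")
  expect_false(d$is_transition)

  expect_identical(classify_mutation("C", "T", "N", "G")$class96, NA_character_)
  expect_error(classify_mutation("C", "C", "A", "G"), "must differ")
})

test_that("strand collapse is an involution", {
  set.seed(23)
  for (i in 1:50) {
    anc <- sample(c("A", "C", "G", "T"), 1)
    der <- sample(setdiff(c("A", "C", "G", "T"), anc), 1)
    ctx <- sample(c("A", "C", "G", "T"), 2, replace = TRUE)
    fwd <- classify_mutation(anc, der, ctx[1], ctx[2])
    comp1 <- function(b) chartr("ACGT", "TGCA", b)
    rev <- classify_mutation(comp1(anc), comp1(der), comp1(ctx[2]), comp1(ctx[1]))
    expect_identical(fwd$class96, rev$class96)
    expect_identical(fwd$class6, rev$class6)
  }
})

test_that("spectrum summaries count classes, Ts/Tv and the G:C->A:T share", {
  lev <- class96_levels()
  expect_length(lev, 96)
  expect_identical(lev[1], "A[C>A]A")
  expect_identical(lev[96], "T[T>G]T")

  calls <- data.frame(
    carrier = "PFA",
    class6 = c(rep("C>T", 6), rep("T>C", 3), rep("C>A", 5)),
    class96 = c(rep("A[C>T]G", 6), rep("T[T>C]T", 3), rep("C[C>A]C", 5)),
    is_transition = c(rep(TRUE, 9), rep(FALSE, 5))
  )
  sp <- summarize_spectrum(calls)
  expect_equal(sp$total, 14)
  expect_equal(sp$tstv, 1.8)
  expect_equal(sum(sp$counts96), 14)
  expect_equal(sum(sp$counts6), 14)

  pure <- summarize_spectrum(calls[calls$class6 == "C>T", ])
  expect_equal(pure$gc_to_at, 1.0)

  empty <- summarize_spectrum(calls[0, ])
  expect_true(is.na(empty$tstv))
  expect_equal(empty$total, 0)

  tab <- spectrum_table(sp)
  expect_equal(nrow(tab), 96)
  expect_equal(sum(tab$count), 14)
})

test_that("the caller agrees with a brute-force window scanner", {
  set.seed(29)
  for (rep_i in 1:200) {
    L <- sample(40:80, 1)
    base <- rand_bases(L)
    rows <- list(base, base, base, base)
    # plant a few deviant columns, occasional gaps and Ns
    for (k in seq_len(sample(0:6, 1))) {
      j <- sample(L, 1)
      r <- sample(4, 1)
      rows[[r]][j] <- sample(c(setdiff(c("A", "C", "G", "T"), rows[[r]][j]),
                               "-", "N"), 1)
    }
    msa <- make_msa(collapse(rows[[1]]), collapse(rows[[2]]),
                    collapse(rows[[3]]), collapse(rows[[4]]))
    got <- call_mutations(msa)
    oracle <- brute_force_calls(msa)
    expect_equal(nrow(got), nrow(oracle))
    if (nrow(got)) {
      o <- order(got$column)
      expect_identical(got$column[o], oracle$column)
      expect_identical(got$carrier[o], oracle$carrier)
      expect_identical(got$der[o], oracle$der)
    }
  }
})

test_that("spacing-off simulation loses mutations only to flank violations", {
  cfg <- tiny_config(seed = 33, enforce_spacing = FALSE,
                     diploid_mutation_rate = 4e-3, n_chromosomes = 1)
  sim <- plant_mutations(simulate_progenitors(cfg))
  msa <- sim_alignment_block(sim, "A01")
  calls <- call_mutations(msa, filter_intervals(msa, segment_on_gaps(msa)))
  tm <- sim$truth$mutations
  tm <- tm[tm$lineage %in% c("PFA", "PC02"), ]
  called <- paste(calls$carrier, calls$column)
  missed <- tm[!(paste(tm$lineage, tm$pos - 1L) %in% called), ]
  expect_gt(nrow(missed), 0)  # spacing off: some rejections must occur
  variants <- sim$truth$variant_sites$A01
  for (i in seq_len(nrow(missed))) {
    near <- abs(variants - missed$pos[i])
    viol <- sum(near <= 5) > 1 ||  # another variant inside the flank window
      missed$pos[i] <= 5 || missed$pos[i] > cfg$chrom_length - 5
    expect_true(viol)
  }
})

test_that("lineage comparison recovers the configured tetraploid excess", {
  cfg <- sim_config(seed = 37, n_chromosomes = 4, chrom_length = 3e5,
                    diploid_mutation_rate = 4e-3, tetraploid_excess = 1.10,
                    gene_count = 0)
  sim <- plant_mutations(simulate_progenitors(cfg))
  calls <- do.call(rbind, lapply(sprintf("A%02d", 1:4), function(b) {
    m <- sim_alignment_block(sim, b)
    call_mutations(m, filter_intervals(m, segment_on_gaps(m)))
  }))
  cmp <- compare_lineages(calls, lineage_a = "PFA", lineage_b = "PC02")
  n_b <- sum(cmp$counts$n_b)
  se <- 110 * sqrt(2 / n_b)  # percent scale
  expect_lt(abs(cmp$excess_percent - 10), 3 * se)
  expect_false(is.null(cmp$test))

  same <- data.frame(carrier = rep(c("PFA", "PC02"), each = 4),
                     block = rep(c("A01", "A01", "A02", "A02"), 2),
                     chrom = rep(c("A01", "A01", "A02", "A02"), 2))
  cmp2 <- compare_lineages(same)
  expect_equal(cmp2$excess_percent, 0)
  expect_null(cmp2$test)
})
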