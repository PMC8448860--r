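test_that("aligned FASTA reading validates structure", {
  s <- collapse(rand_bases(100))
  msa <- make_msa(s, s, s, s)
  expect_s3_class(msa, "pf_msa")
  expect_equal(ncol(msa$rows), 100)

  p <- tempfile(fileext = ".afa")
  writeLines(c(">PFA", "ACGT", ">PFB", "ACGT", ">PC02", "ACGT"), p)
  expect_error(read_alignment(p), "missing role")

  writeLines(c(">PFA", "ACGT", ">PFB", "ACG", ">PC02", "ACGT", ">PC99", "ACGT"), p)
  expect_error(read_alignment(p), "ragged")

  writeLines(character(0), p)
  expect_error(read_alignment(p), "empty")

  writeLines(c(">PFA", "ACGT", ">PFB", "ACGT", ">PC02", "ACGT", ">foo", "ACGT"), p)
  expect_error(read_alignment(p), "unknown ids")

  # lowercase is normalized
  writeLines(c(">PFA", "acgt", ">PFB", "ACGT", ">PC02", "ACGT", ">PC99", "ACGT"), p)
  expect_identical(read_alignment(p)$rows["PFA", ], c("A", "C", "G", "T"))
})

test_that("alignments survive a write/read round trip", {
  set.seed(5)
  rows <- replicate(4, collapse(rand_bases(80)))
  msa <- make_msa(rows[1], rows[2], rows[3], rows[4], starts = c(10, 20, 30, 40))
  p <- tempfile(fileext = ".afa")
  write_alignment(msa, p)
  back <- read_alignment(p, block_id = msa$block_id)
  expect_identical(back$rows, msa$rows)
  expect_identical(back$meta$start, msa$meta$start)
})

test_that("gap runs of at least max_gap split blocks at the run union", {
  base <- rand_bases(500)
  s <- collapse(base)
  no_gap <- make_msa(s, s, s, s)
  iv <- segment_on_gaps(no_gap)
  expect_equal(nrow(iv), 1)
  expect_equal(c(iv$start, iv$end), c(0, 500))

  gapped <- base
  gapped[201:300] <- "-"
  one_gap <- make_msa(s, s, s, collapse(gapped))
  iv2 <- segment_on_gaps(one_gap, max_gap = 100)
  expect_equal(iv2$start, c(0, 300))
  expect_equal(iv2$end, c(200, 500))

  short_gap <- base
  short_gap[201:299] <- "-"  # 99 columns: below the threshold
  iv3 <- segment_on_gaps(make_msa(s, s, s, collapse(short_gap)), max_gap = 100)
  expect_equal(nrow(iv3), 1)

  # overlapping runs in two rows split once at their union
  g1 <- base; g1[151:260] <- "-"
  g2 <- base; g2[201:310] <- "-"
  iv4 <- segment_on_gaps(make_msa(collapse(g1), collapse(g2), s, s), max_gap = 100)
  expect_equal(iv4$start, c(0, 310))
  expect_equal(iv4$end, c(150, 500))
})

test_that("segmentation is idempotent", {
  set.seed(9)
  base <- rand_bases(700)
  g <- base
  g[101:220] <- "-"
  g[501:640] <- "-"
  msa <- make_msa(collapse(base), collapse(g), collapse(base), collapse(base))
  iv <- segment_on_gaps(msa)
  expect_lte(sum(iv$end - iv$start), ncol(msa$rows))
  for (i in seq_len(nrow(iv))) {
    cols <- (iv$start[i] + 1):iv$end[i]
    sub <- make_msa(collapse(msa$rows["PFA", cols]), collapse(msa$rows["PFB", cols]),
                    collapse(msa$rows["PC02", cols]), collapse(msa$rows["PC99", cols]))
    iv_i <- segment_on_gaps(sub)
    expect_equal(nrow(iv_i), 1)
    expect_equal(iv_i$end - iv_i$start, length(cols))
  }
})

test_that("interval filtering applies length and four-way identity rules", {
  s600 <- collapse(rand_bases(600))
  msa <- make_msa(s600, s600, s600, s600)
  kept <- filter_intervals(msa, segment_on_gaps(msa))
  expect_equal(nrow(kept), 1)
  expect_equal(kept$identity, 1.0)

  s400 <- collapse(rand_bases(400))
  short <- make_msa(s400, s400, s400, s400)
  expect_equal(nrow(filter_intervals(short, segment_on_gaps(short))), 0)

  # 1000 gap-free columns, 250 with one deviant row: identity 0.75
  base <- rand_bases(1000)
  dev <- base
  dev[1:250] <- vapply(dev[1:250], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  low <- make_msa(collapse(base), collapse(dev), collapse(base), collapse(base))
  iv <- segment_on_gaps(low)
  got <- filter_intervals(low, iv)
  expect_equal(nrow(got), 0)
  all_stats <- filter_intervals(low, iv, min_identity = 0)
  expect_equal(all_stats$identity, 0.75)

  # N columns are gap-free but never agree
  n_base <- base
  n_base[1:100] <- "N"
  with_n <- make_msa(collapse(n_base), collapse(n_base), collapse(n_base),
                     collapse(n_base))
  st <- filter_intervals(with_n, segment_on_gaps(with_n), min_identity = 0)
  expect_equal(st$identity, 0.9)
})

test_that("column to source coordinates round-trip on every row", {
  set.seed(17)
  base <- rand_bases(200)
  rows <- lapply(1:4, function(i) {
    x <- base
    x[sample(200, 20)] <- "-"
    x
  })
  msa <- make_msa(collapse(rows[[1]]), collapse(rows[[2]]),
                  collapse(rows[[3]]), collapse(rows[[4]]),
                  starts = c(100, 200, 300, 400))
  for (r in seq_along(rows)) {
    role <- c("PFA", "PFB", "PC02", "PC99")[r]
    non_gap <- which(rows[[r]] != "-")
    pos <- column_to_source(msa, role, non_gap)
    expect_identical(pos, as.integer(c(100, 200, 300, 400)[r] +
                                       seq_along(non_gap) - 1L))
    expect_true(all(is.na(column_to_source(msa, role, setdiff(1:200, non_gap)))))
  }
})
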