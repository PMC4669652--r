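test_that("Fisher tail matches exact enumeration and closed forms", {
  # a=5,b=0,c=0,d=95: only one table in the tail, p = 1/choose(100,5)
  expect_equal(fisher_tail_p(5, 0, 0, 95), 1 / choose(100, 5),
               tolerance = 1e-12)
  # a = 0: the whole support is in the tail
  expect_equal(fisher_tail_p(0, 10, 10, 80), 1)
  # fully concordant diagonal table vs the enumeration oracle
  expect_equal(fisher_tail_p(5, 0, 0, 5), oracle_fisher_tail(5, 0, 0, 5),
               tolerance = 1e-12)

  withr::with_seed(31, {
    for (i in 1:200) {
      tot <- sample(4:60, 1)
      cells <- as.vector(stats::rmultinom(1, tot, prob = runif(4, 0.05, 1)))
      p <- fisher_tail_p(cells[1], cells[2], cells[3], cells[4])
      o <- oracle_fisher_tail(cells[1], cells[2], cells[3], cells[4])
      expect_equal(p, o, tolerance = 1e-9)
    }
  })
})

test_that("Fisher p decreases monotonically in the both-positive cell", {
  # margins fixed: row1 = 20, col1 = 15, total = 100
  a <- 5:15
  p <- fisher_tail_p(a, 20 - a, 15 - a, 100 - 20 - 15 + a)
  expect_true(all(diff(p) < 0))
})

test_that("binned Fisher co-localization builds the right contingency table", {
  cs <- c(c1 = 1000L)
  A <- peak_set(data.frame(chrom = "c1", start = c(0L, 500L), end = c(50L, 550L)),
                genome_id = "g")
  B <- peak_set(data.frame(chrom = "c1", start = c(10L, 700L), end = c(60L, 750L)),
                genome_id = "g")
  f <- fisher_colocalization(A, B, cs, bin_width = 100L)
  expect_equal(f$n_bins, 10L)
  expect_equal(unname(f$table), c(1L, 1L, 1L, 7L))  # bin0 both, bin5 A, bin7 B
  expect_error(fisher_colocalization(A, B, integer(0)),
               class = "chipcoloc_usage_error")
})

test_that("permutation test handles degenerate inputs and planted overlap", {
  cs <- c(c1 = 300000L, c2 = 200000L)
  withr::with_seed(8, {
    A <- peak_set(random_peak_df(40, cs, max_w = 200L, min_w = 100L), genome_id = "g")
  })
  B_empty <- peak_set(data.frame(chrom = character(), start = integer(),
                                 end = integer()), genome_id = "g")
  r <- permutation_overlap_test(A, B_empty, cs, n_perm = 10L, seed = 1L)
  expect_equal(r$observed_shared, 0L)
  expect_equal(r$p_emp, 1)

  expect_error(permutation_overlap_test(A, A, cs, n_perm = 0L),
               class = "chipcoloc_usage_error")
  expect_error(permutation_overlap_test(
    peak_set(data.frame(chrom = "c1", start = 0L, end = 400000L)), A, cs),
    class = "chipcoloc_usage_error")

  pp <- generate_peak_pair(300, 200, 0.42, cs, seed = 4)
  r2 <- permutation_overlap_test(pp$A, pp$B, cs, n_perm = 999L, seed = 2L)
  expect_lte(r2$p_emp, 0.001)
})

test_that("permutation p-values are calibrated under the null", {
  # A placed uniformly, B fixed: p_emp should be uniform on its support
  cs <- c(c1 = 100000L)
  withr::with_seed(55, {
    B <- peak_set(random_peak_df(15, cs, max_w = 400L, min_w = 200L), genome_id = "g")
    ps <- vapply(1:200, function(r) {
      A <- peak_set(random_peak_df(10, cs, max_w = 400L, min_w = 200L),
                    genome_id = "g")
      permutation_overlap_test(A, B, cs, n_perm = 39L, seed = 1000L + r)$p_emp
    }, numeric(1L))
  })
  # the statistic is discrete, so p_emp is super-uniform (valid but
  # conservative where ties occur): check the one-sided Kolmogorov
  # distance in the anti-conservative direction, and that the p-values
  # are not degenerate
  grid <- seq(0.025, 1, by = 0.025)
  d_plus <- max(vapply(grid, function(t) mean(ps <= t) - t, 0))
  expect_lt(d_plus, 0.1)
  expect_lt(mean(ps), 0.8)
  expect_gt(stats::sd(ps), 0.15)
})

test_that("heat-map matrices match the rasterization oracle", {
  # one anchor, one signal peak covering the whole window -> flat row of 1s
  anchors <- peak_set(data.frame(chrom = "c1", start = 4900L, end = 5100L))
  signal <- peak_set(data.frame(chrom = "c1", start = 3000L, end = 7000L))
  hm <- heatmap_matrix(anchors, signal, flank = 500L, n_bins = 10L)
  expect_equal(unname(hm$matrix[1, ]), rep(1, 10))

  # disjoint signal -> zero matrix
  far <- peak_set(data.frame(chrom = "c1", start = 20000L, end = 21000L))
  hm0 <- heatmap_matrix(anchors, far, flank = 500L, n_bins = 10L)
  expect_true(all(hm0$matrix == 0))

  cs <- c(c1 = 20000L)
  withr::with_seed(99, {
    anc <- peak_set(random_peak_df(8, cs, max_w = 100L, min_w = 50L))
    anc <- anc[anc$anchor > 600 & anc$anchor < 19400, , drop = FALSE]
    sig <- random_peak_df(60, cs, max_w = 150L)
  })
  hm2 <- heatmap_matrix(anc, sig, flank = 500L, n_bins = 20L)
  for (r in seq_len(nrow(anc))) {
    i <- hm2$row_order[r]
    expect_equal(unname(hm2$matrix[r, ]),
                 oracle_heatmap_row(anc$anchor[i], anc$chrom[i], sig, 500L, 20L),
                 tolerance = 1e-12)
  }
  # row sums are a permutation-invariant of the anchor set
  expect_equal(sort(rowSums(hm2$matrix)),
               sort(rowSums(heatmap_matrix(anc[sample(nrow(anc)), ], sig,
                                           flank = 500L, n_bins = 20L)$matrix)))
  expect_true(all(diff(rowSums(hm2$matrix)) <= 0))
})

test_that("the combined overlap report is internally consistent", {
  cs <- c(c1 = 200000L, c2 = 200000L)
  pp <- generate_peak_pair(100, 80, 0.5, cs, seed = 21)
  rep_ <- overlap_report(pp$A, pp$B, cs, n_perm = 99L, seed = 3L)
  expect_equal(rep_$pct_B_shared, 100 * rep_$venn$B_shared / rep_$venn$n_B)
  expect_equal(rep_$venn$B_shared, 40L)
  expect_gte(rep_$jaccard, 0)
  expect_lte(rep_$jaccard, 1)
  expect_lt(rep_$p_fisher, 0.01)
  expect_lte(rep_$p_permutation, 0.01)
})
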