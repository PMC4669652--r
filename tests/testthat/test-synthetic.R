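test_that("genome generation hits its GC targets deterministically", {
  cs <- c(c1 = 100000L)
  g <- generate_genome(cs, data.frame(chrom = "c1", start = 0L,
                                      end = 100000L, gc = 0.5), seed = 101)
  freq <- Biostrings::alphabetFrequency(g$genome)[1, c("A", "C", "G", "T")]
  gc <- sum(freq[c("C", "G")]) / sum(freq)
  expect_equal(gc, 0.5, tolerance = 0.01 / 0.5)

  g2 <- generate_genome(cs, data.frame(chrom = "c1", start = 0L,
                                       end = 100000L, gc = 0.5), seed = 101)
  expect_identical(as.character(g$genome), as.character(g2$genome))

  prof <- data.frame(chrom = "c1", start = c(0L, 50000L),
                     end = c(50000L, 100000L), gc = c(0.3, 0.7))
  g3 <- generate_genome(cs, prof, seed = 102)
  s <- as.character(g3$genome[[1]])
  gc_of <- function(x) {
    f <- table(strsplit(x, "")[[1]])
    sum(f[c("C", "G")]) / sum(f)
  }
  expect_lt(gc_of(substr(s, 1, 50000)), gc_of(substr(s, 50001, 100000)))

  expect_error(generate_genome(cs, data.frame(chrom = "c1", start = 0L,
                                              end = 100000L, gc = 1.2)),
               class = "chipcoloc_usage_error")
  expect_error(generate_genome(c(c1 = 500L)), class = "chipcoloc_usage_error")
})

test_that("peak pairs carry their planted overlap counts exactly", {
  cs <- c(c1 = 2000000L, c2 = 2000000L)
  p0 <- generate_peak_pair(300, 200, 0, cs, seed = 111)
  expect_equal(venn_counts(p0$A, p0$B)$common_clusters, 0L)

  p1 <- generate_peak_pair(300, 200, 1, cs, seed = 112)
  expect_equal(venn_counts(p1$A, p1$B)$B_shared, 200L)

  p42 <- generate_peak_pair(1500, 1000, 0.42, cs, seed = 113)
  v <- venn_counts(p42$A, p42$B)
  expect_equal(v$B_shared, 420L)
  expect_equal(p42$truth$n_overlapping, 420L)

  expect_error(generate_peak_pair(5000, 100, 0.5, c(c1 = 50000L)),
               class = "chipcoloc_generation_error")
})

test_that("motif planting drives hit rates as instructed", {
  cs <- c(c1 = 400000L)
  lib <- read_jaspar(motif_library_path())
  genome <- generate_genome(cs, seed = 121)
  pp <- generate_peak_pair(80, 1, 0, cs, seed = 122,
                           width_sampler = function(n) rep(300L, n))
  pwm <- build_pwm(lib$SYN01)
  t <- score_threshold(pwm, 1e-4)

  planted <- plant_motifs(genome, pp$A, lib$SYN01, rate_peak = 1,
                          rate_bg = 0, seed = 123)
  hits <- vapply(seq_len(nrow(pp$A)), function(i) {
    seqs <- Biostrings::subseq(planted$genome[[pp$A$chrom[i]]],
                               pp$A$anchor[i] - 100L + 1L,
                               pp$A$anchor[i] + 101L)
    window_has_hit(as.character(seqs), pwm, t)
  }, logical(1L))
  expect_gte(mean(hits), 0.99)

  # no planting anywhere: hit rate equals the scan's false-positive rate,
  # about p_target per scanned position (two strands)
  bare <- plant_motifs(genome, pp$A, lib$SYN01, rate_peak = 0,
                       rate_bg = 0, seed = 124)
  hits0 <- vapply(seq_len(nrow(pp$A)), function(i) {
    seqs <- Biostrings::subseq(bare$genome[[pp$A$chrom[i]]],
                               pp$A$anchor[i] - 100L + 1L,
                               pp$A$anchor[i] + 101L)
    window_has_hit(as.character(seqs), pwm, t)
  }, logical(1L))
  expected_fpr <- 1 - (1 - attr(t, "tail_prob"))^(2 * (201 - pwm$width + 1))
  expect_lt(mean(hits0), expected_fpr + 3 * sqrt(expected_fpr / length(hits0)) + 0.05)
})

test_that("tag generation respects its truth parameters", {
  cs <- c(c1 = 1000000L)
  pp <- generate_peak_pair(60, 1, 0, cs, seed = 131)
  tg <- generate_tags(pp$A, cs, n_tags = 30000L, signal_frac = 0.3,
                      frag_len = 200L, read_len = 36L, dup_rate = 0, seed = 132)
  expect_equal(pbc(tg$tags), 1)
  expect_equal(tg$truth$n_signal, 9000L)

  tg2 <- generate_tags(pp$A, cs, n_tags = 30000L, signal_frac = 0.3,
                       frag_len = 200L, read_len = 36L, dup_rate = 0, seed = 132)
  expect_identical(tg$tags, tg2$tags)

  expect_error(generate_tags(pp$A, cs, n_tags = 100L, signal_frac = 0.3,
                             frag_len = 100L, read_len = 200L),
               class = "chipcoloc_usage_error")
  expect_error(generate_tags(pp$A, c(c1 = 10000L), frag_len = 20000L,
                             read_len = 36L),
               class = "chipcoloc_generation_error")
})

test_that("gene generation plants the requested TSS-proximal share", {
  cs <- c(c1 = 2000000L, c2 = 2000000L)
  pp <- generate_peak_pair(200, 1, 0, cs, seed = 141)

  all_prox <- generate_genes(100, cs, pp$A, tss_proximal_frac = 1, seed = 142)
  expect_equal(promoter_fraction(all_prox$peaks, all_prox$genes), 100)

  part <- generate_genes(100, cs, pp$A, tss_proximal_frac = 0.7, seed = 143)
  expect_equal(promoter_fraction(part$peaks, part$genes), 70, tolerance = 3 / 70)
  expect_equal(part$truth$n_proximal, 140L)

  # random strands: the distance histogram is roughly symmetric
  h <- tss_histogram(part$peaks, part$genes)
  inner_neg <- h$count[h$bin == "[-1000,0)"]
  inner_pos <- h$count[h$bin == "[0,1000)"]
  expect_gt(inner_neg, 0)
  expect_gt(inner_pos, 0)
  expect_lt(abs(inner_neg - inner_pos) / (inner_neg + inner_pos), 0.35)
})
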