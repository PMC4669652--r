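test_that("log-odds PWM construction matches the closed-form scores", {
  pfm <- parse_jaspar_pfm(c(">T1 toy", "A [ 4 1 ]", "C [ 0 1 ]",
                            "G [ 0 1 ]", "T [ 0 1 ]"))
  # pseudocount -> 0 limit: column (4,0,0,0) under uniform background gives
  # score -> log2(4) for A
  pwm_small <- build_pwm(pfm, pseudocount = 1e-9)
  expect_equal(unname(pwm_small$scores["A", 1]), log2(4), tolerance = 1e-6)
  # equal-count column scores 0 for every base under uniform background
  expect_equal(unname(pwm_small$scores[, 2]), rep(0, 4), tolerance = 1e-6)

  withr::with_seed(14, {
    for (rep in 1:3) {
      counts <- matrix(sample(0:20, 12, replace = TRUE), nrow = 4)
      counts[1, colSums(counts) == 0] <- 1
      rownames(counts) <- c("A", "C", "G", "T")
      pfm2 <- list(motif_id = "R", name = "R", counts = counts)
      class(pfm2) <- "pfm"
      bg <- c(0.2, 0.3, 0.3, 0.2)
      pc <- 0.8
      pwm <- build_pwm(pfm2, background = bg, pseudocount = pc)
      hand <- log2(((counts + pc * bg) %*% diag(1 / (colSums(counts) + pc))) / bg)
      expect_equal(unname(pwm$scores), unname(hand), tolerance = 1e-12)
    }
  })
  expect_error(build_pwm(pfm, background = c(0.5, 0.5, 0, 0)),
               class = "chipcoloc_usage_error")
})

test_that("threshold DP equals exhaustive enumeration and is monotone", {
  lib <- read_jaspar(motif_library_path())
  small <- Filter(function(m) ncol(m$counts) <= 8, lib)
  expect_gte(length(small), 5L)
  for (m in small[1:3]) {
    pwm <- build_pwm(m)
    for (pt in c(1e-3, 1e-4)) {
      t <- score_threshold(pwm, pt)
      w <- pwm$width
      words <- as.matrix(expand.grid(rep(list(1:4), w)))
      sc <- matrix(pwm$scores_int[cbind(as.vector(words),
                                        rep(seq_len(w), each = nrow(words)))],
                   nrow = nrow(words))
      totals <- rowSums(sc)
      probs <- apply(words, 1, function(cd) prod(pwm$background[cd]))
      enum_tail <- sum(probs[totals >= attr(t, "t_int")])
      expect_equal(attr(t, "tail_prob"), enum_tail, tolerance = 1e-12)
      expect_lte(enum_tail, pt)
    }
    expect_gte(score_threshold(pwm, 1e-5), score_threshold(pwm, 1e-3))
    # p_target = 1 admits everything: the minimum attainable score
    tmin <- score_threshold(pwm, 1)
    expect_equal(attr(tmin, "t_int"), sum(apply(pwm$scores_int, 2, min)))
  }
  expect_error(score_threshold(build_pwm(lib[[1]]), 0),
               class = "chipcoloc_usage_error")
})

test_that("window scanning finds hits on both strands and rejects bad bases", {
  lib <- read_jaspar(motif_library_path())
  pwm <- build_pwm(lib$SYN01)
  t <- score_threshold(pwm, 1e-4)
  cons <- pfm_consensus(lib$SYN01)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(cons, "")[[1]]), collapse = ""))
  flankseq <- strrep("A", 20)
  expect_true(window_has_hit(paste0(flankseq, cons, flankseq), pwm, t))
  expect_true(window_has_hit(paste0(flankseq, rc, flankseq), pwm, t))
  expect_false(window_has_hit(strrep("N", 60), pwm, t))
  expect_false(window_has_hit("ACG", pwm, t))  # shorter than the motif
  expect_error(window_has_hit("ACGTXACGT", pwm, t),
               class = "chipcoloc_format_error")
})

test_that("GC-matched background sampling matches the peak GC distribution", {
  cs <- c(c1 = 200000L, c2 = 200000L)
  # homogeneous genome: acceptance is immediate and GC matches trivially
  flat <- generate_genome(cs, seed = 41)
  bg1 <- sample_gc_matched_background(flat$genome, 100, width = 201,
                                      peak_gc = rep(0.5, 100), seed = 5)
  expect_equal(nrow(bg1), 100L)
  expect_lt(abs(mean(bg1$gc) - 0.5), 0.02)

  # GC-gradient genome, target 0.6: matched background mean within 0.01
  grad <- generate_genome(cs, gc_gradient_profile(cs, 0.3, 0.7), seed = 42)
  withr::with_seed(77, {
    target_gc <- pmin(pmax(stats::rnorm(400, 0.6, 0.015), 0.55), 0.65)
  })
  bg2 <- sample_gc_matched_background(grad$genome, 400, width = 201,
                                      peak_gc = target_gc, seed = 6)
  expect_lt(abs(mean(bg2$gc) - 0.6), 0.01)

  # determinism under the seed
  bg3 <- sample_gc_matched_background(grad$genome, 400, width = 201,
                                      peak_gc = target_gc, seed = 6)
  expect_identical(bg2, bg3)

  # an unobtainable GC bin raises a sampling error naming the bin
  expect_error(
    sample_gc_matched_background(flat$genome, 50, width = 201,
                                 peak_gc = rep(0.95, 50), seed = 1,
                                 max_draws_per_window = 20L),
    class = "chipcoloc_sampling_error")
})

test_that("binomial enrichment matches closed forms and the summation oracle", {
  # k=n=10 at p0 = 0.5 (from k_bg=499, n_bg=998): p = 2^-10
  r <- binomial_enrichment(10, 10, 499, 998)
  expect_equal(r$p0, 0.5)
  expect_equal(r$p, 2^-10, tolerance = 1e-12)
  # observed rate equal to p0: no enrichment signal
  r2 <- binomial_enrichment(50, 100, 499, 998)
  expect_gte(r2$p, 0.5)
  expect_error(binomial_enrichment(1, 0, 1, 10), class = "chipcoloc_usage_error")

  withr::with_seed(23, {
    for (i in 1:200) {
      n <- sample(5:500, 1)
      k <- sample(0:n, 1)
      n_bg <- sample(10:2000, 1)
      k_bg <- sample(0:n_bg, 1)
      got <- binomial_enrichment(k, n, k_bg, n_bg)
      p0 <- (k_bg + 1) / (n_bg + 2)
      expect_equal(got$p, oracle_binom_tail(k, n, p0), tolerance = 1e-9)
    }
  })
})

test_that("star tiers follow the p-value thresholds", {
  expect_equal(star_annotation(1e-12), "***")
  expect_equal(star_annotation(1e-3), "**")
  expect_equal(star_annotation(0.05), "*")
  expect_equal(star_annotation(0.5), "")
})

test_that("motif-set enrichment is ordered, reproducible and handles edge cases", {
  cs <- c(c1 = 300000L)
  world <- generate_genome(cs, seed = 61)
  pp <- generate_peak_pair(60, 1, 0, cs, seed = 62,
                           width_sampler = function(n) rep(300L, n))
  lib <- read_jaspar(motif_library_path())
  planted <- plant_motifs(world, pp$A, lib$SYN01, rate_peak = 0.8,
                          rate_bg = 0, seed = 63)

  # empty library -> empty table
  e0 <- enrich_motif_set(pp$A, planted$genome, list())
  expect_equal(nrow(e0), 0L)

  tab <- enrich_motif_set(pp$A, planted$genome, lib[c("SYN01", "SYND01")],
                          bg_multiple = 5L, seed = 64)
  expect_equal(tab$motif_id[1], "SYN01")
  expect_equal(tab$stars[1], "***")
  expect_true(all(diff(tab$p_binomial) >= 0))
  expect_equal(tab$q_bh, p.adjust(tab$p_binomial, "BH"))

  # identical motifs give identical records in stable motif_id order
  twin <- lib$SYND01
  twin$motif_id <- "SYND01b"
  tab2 <- enrich_motif_set(pp$A, planted$genome,
                           list(SYND01 = lib$SYND01, SYND01b = twin),
                           bg_multiple = 5L, seed = 64)
  expect_equal(tab2$k_peak[1], tab2$k_peak[2])
  expect_equal(tab2$p_binomial[1], tab2$p_binomial[2])
  expect_equal(tab2$motif_id, c("SYND01", "SYND01b"))

  # invariant to peak order (same background seed)
  shuf <- peak_set(as.data.frame(pp$A)[sample(nrow(pp$A)), ],
                   genome_id = "synthetic")
  tab3 <- enrich_motif_set(shuf, planted$genome, lib[c("SYN01", "SYND01")],
                           bg_multiple = 5L, seed = 64)
  expect_equal(tab3$k_peak, tab$k_peak)
  expect_equal(tab3$p_binomial, tab$p_binomial)
})
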