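test_that("SPOT counts 5'-ends in peaks and recovers the signal fraction", {
  peaks <- peak_set(data.frame(chrom = "c1", start = 100L, end = 200L))
  inside <- tag_table(data.frame(chrom = "c1", start = c(120L, 150L),
                                 end = c(156L, 186L), strand = c("+", "+")))
  expect_equal(spot(inside, peaks), 1)
  none <- peak_set(data.frame(chrom = character(), start = integer(),
                              end = integer()))
  expect_equal(spot(inside, none), 0)
  expect_error(spot(inside[0, ], peaks), class = "chipcoloc_usage_error")

  # sparse peaks (<1 % of the genome), wide enough that fragment-end tags
  # stay inside: SPOT ~ signal_frac
  cs <- c(c1 = 3000000L, c2 = 2000000L)
  pp <- generate_peak_pair(80, 1, 0, cs, seed = 7,
                           width_sampler = function(n) rep(400L, n))
  tg <- generate_tags(pp$A, cs, n_tags = 50000L, signal_frac = 0.3,
                      frag_len = 200L, read_len = 36L, dup_rate = 0, seed = 8)
  expect_equal(spot(tg$tags, pp$A), 0.30, tolerance = 0.02 / 0.30)
})

test_that("PBC is exact for clean and fully duplicated libraries", {
  clean <- tag_table(data.frame(chrom = "c1", start = c(10L, 20L, 30L),
                                end = c(46L, 56L, 66L), strand = "+"))
  expect_equal(pbc(clean), 1)
  doubled <- clean[rep(1:3, each = 2), ]
  expect_equal(pbc(doubled), 0)
  expect_error(pbc(clean[0, ]), class = "chipcoloc_usage_error")
})

test_that("PBC tracks the generator's duplication model", {
  cs <- c(c1 = 1000000L)
  pp <- generate_peak_pair(50, 1, 0, cs, seed = 3)
  vals <- vapply(c(0, 0.2, 0.5), function(d) {
    tg <- generate_tags(pp$A, cs, n_tags = 20000L, signal_frac = 0.2,
                        frag_len = 200L, read_len = 36L, dup_rate = d, seed = 5)
    pbc(tg$tags)
  }, numeric(1L))
  expect_equal(vals[1], 1)
  expect_true(all(diff(vals) < 0))
  # independent oracle: under the model every pre-duplication position is
  # unique, so Nd = n and N1 = n - #duplicated, giving E[PBC] = 1 - d
  expect_equal(vals[2], 1 - 0.2, tolerance = 0.02 / 0.8)
  expect_equal(vals[3], 1 - 0.5, tolerance = 0.02 / 0.5)
})

test_that("strand cross-correlation peaks at the planted offset", {
  # construction: + tags mirrored on the - strand at exactly +150
  cs <- c(c1 = 100000L)
  withr::with_seed(17, {
    pos <- sort(sample(1000:90000, 400))
  })
  plus <- data.frame(chrom = "c1", start = pos, end = pos + 36L, strand = "+")
  minus <- data.frame(chrom = "c1", start = pos + 150L - 35L,
                      end = pos + 150L + 1L, strand = "-")
  tags <- tag_table(rbind(plus, minus))
  prof <- cross_correlation(tags, max_shift = 300L, chrom_sizes = cs)
  expect_equal(prof$argmax_shift, 150L)
  expect_equal(prof$cc_max, 1, tolerance = 0.02)

  # strand-symmetric uniform noise: flat profile near zero
  withr::with_seed(18, {
    n <- 4000
    st <- sample(40:99900, n, replace = FALSE)
    noise <- tag_table(data.frame(
      chrom = "c1", start = st, end = st + 36L,
      strand = sample(c("+", "-"), n, replace = TRUE)))
  })
  prof2 <- cross_correlation(noise, max_shift = 200L, chrom_sizes = cs)
  expect_lt(max(abs(prof2$cc)), 0.05)
})

test_that("cross-correlation matches a brute-force shifted-vector oracle", {
  cs <- c(c1 = 2000L, c2 = 1500L)
  withr::with_seed(29, {
    n <- 300
    ch <- sample(names(cs), n, replace = TRUE)
    st <- floor(runif(n, 36, cs[ch] - 40))
    tg <- tag_table(data.frame(chrom = ch, start = as.integer(st),
                               end = as.integer(st + 36L),
                               strand = sample(c("+", "-"), n, TRUE)))
  })
  prof <- cross_correlation(tg, max_shift = 50L, chrom_sizes = cs)
  for (d in c(0L, 13L, 50L)) {
    xs <- NULL; ys <- NULL
    for (chn in names(cs)) {
      L <- cs[[chn]]
      p <- tabulate(tg$five_prime[tg$chrom == chn & tg$strand == "+"] + 1L, L)
      m <- tabulate(tg$five_prime[tg$chrom == chn & tg$strand == "-"] + 1L, L)
      xs <- c(xs, p[1:(L - d)]); ys <- c(ys, m[(1 + d):L])
    }
    expect_equal(prof$cc[prof$shift == d], cor(xs, ys), tolerance = 1e-12)
  }
})

test_that("NSC/RSC follow their definitions including degenerate profiles", {
  flat <- structure(list(shift = 0:100, cc = rep(0.2, 101),
                         argmax_shift = 0L, cc_max = 0.2, cc_min = 0.2),
                    class = "cc_profile")
  r <- suppressWarnings(nsc_rsc(flat, 36L))
  expect_equal(r$nsc, 1)
  expect_true(is.na(r$rsc))
  expect_warning(nsc_rsc(flat, 36L), "RSC undefined")
  expect_error(nsc_rsc(flat, 999L), class = "chipcoloc_usage_error")

  peaked <- structure(list(shift = 0:300,
                           cc = 0.05 + 0.3 * stats::dnorm(0:300, 200, 20) /
                             stats::dnorm(200, 200, 20) +
                             0.05 * stats::dnorm(0:300, 36, 5) /
                             stats::dnorm(36, 36, 5)),
                      class = "cc_profile")
  peaked$argmax_shift <- peaked$shift[which.max(peaked$cc)]
  peaked$cc_max <- max(peaked$cc)
  peaked$cc_min <- min(peaked$cc)
  r2 <- nsc_rsc(peaked, 36L)
  expect_gt(r2$nsc, 1)
  expect_gt(r2$rsc, 1)
})

test_that("saturation curves end at exactly 1 and reject bad fractions", {
  cs <- c(c1 = 500000L)
  pp <- generate_peak_pair(40, 1, 0, cs, seed = 51)
  tg <- generate_tags(pp$A, cs, n_tags = 20000L, signal_frac = 0.3,
                      frag_len = 200L, read_len = 36L, dup_rate = 0.1, seed = 52)
  sat <- saturation_curve(tg$tags, cs, seed = 53)
  expect_equal(sat$pearson_r[sat$fraction == 1], 1)
  expect_true(all(sat$pearson_r > 0))
  expect_error(saturation_curve(tg$tags, cs, fractions = c(0, 0.5)),
               class = "chipcoloc_usage_error")
  expect_error(saturation_curve(tg$tags, cs, fractions = c(0.5, 1.2)),
               class = "chipcoloc_usage_error")
})

test_that("spot and pbc are invariant under tag order permutation", {
  cs <- c(c1 = 400000L)
  pp <- generate_peak_pair(30, 1, 0, cs, seed = 71)
  tg <- generate_tags(pp$A, cs, n_tags = 5000L, signal_frac = 0.4,
                      frag_len = 200L, read_len = 36L, dup_rate = 0.2, seed = 72)
  withr::with_seed(73, {
    shuf <- tg$tags[sample(nrow(tg$tags)), ]
  })
  expect_equal(spot(shuf, pp$A), spot(tg$tags, pp$A))
  expect_equal(pbc(shuf), pbc(tg$tags))
})
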