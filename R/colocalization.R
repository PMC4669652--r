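#' Co-localization statistics for two peak sets
#'
#' The genome is tiled into non-overlapping bins (last bin truncated); a bin
#' is positive for a set iff it shares >= 1 bp with any peak of the set. The
#' 2x2 table over bins (both / A only / B only / neither) is tested with a
#' one-sided (greater) Fisher's exact test, computed from the hypergeometric
#' tail in log space. A permutation test that re-places one set uniformly
#' per chromosome, preserving peak lengths, provides a model-free companion
#' null.
#'
#' @name colocalization
NULL

# bin indices (0-based) covered by an interval under bin width `bw`
bins_hit <- function(starts, ends, bw) {
  unlist(mapply(function(s, e) seq.int(s %/% bw, (e - 1L) %/% bw),
                starts, ends, SIMPLIFY = FALSE), use.names = FALSE)
}

#' Fisher's exact test of peak-set co-localization over genome bins
#'
#' @param A,B `peak_set`s.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param bin_width bin width in bp; default is the median peak length of
#'   the combined sets (the analysis unit matches the feature scale).
#' @return list with `table` (`a`, `b`, `c`, `d`: both / A only / B only /
#'   neither), `n_bins`, `bin_width`, `p` (one-sided greater), `log10_p`.
#' @export
fisher_colocalization <- function(A, B, chrom_sizes, bin_width = NULL) {
  if (!length(chrom_sizes) || any(chrom_sizes <= 0)) {
    usage_error("chrom_sizes must be a non-empty vector of positive lengths")
  }
  if (is.null(bin_width)) {
    lens <- c(A$end - A$start, B$end - B$start)
    if (!length(lens)) usage_error("both peak sets empty and no bin_width given")
    bin_width <- as.integer(stats::median(lens))
  }
  if (bin_width < 1L) usage_error("bin_width must be >= 1")
  n_bins_chr <- ceiling(chrom_sizes / bin_width)
  offsets <- cumsum(c(0, head(n_bins_chr, -1L)))
  names(offsets) <- names(chrom_sizes)
  n_bins <- sum(n_bins_chr)

  hit_bins <- function(P) {
    P <- P[P$chrom %in% names(chrom_sizes), , drop = FALSE]
    if (!nrow(P)) return(integer())
    ids <- unlist(lapply(split(P, P$chrom), function(p) {
      ch <- p$chrom[1L]
      offsets[[ch]] + bins_hit(p$start, pmin(p$end, chrom_sizes[[ch]]), bin_width)
    }), use.names = FALSE)
    unique(ids)
  }
  ha <- hit_bins(A)
  hb <- hit_bins(B)
  a <- length(intersect(ha, hb))
  b <- length(setdiff(ha, hb))
  cc <- length(setdiff(hb, ha))
  d <- n_bins - a - b - cc
  p <- fisher_greater_p(a, b, cc, d)
  list(table = c(a = a, b = b, c = cc, d = d), n_bins = n_bins,
       bin_width = bin_width, p = p,
       log10_p = fisher_greater_logp(a, b, cc, d) / log(10))
}

#' One-sided (greater) Fisher's exact p for 2x2 tables
#'
#' `P(X >= a)` with `X ~ Hypergeometric(m = a + b, n = c + d, k = a + c)`,
#' i.e. the upper tail at the observed "both-positive" cell with all
#' margins fixed; evaluated in log space. Vectorized over tables.
#'
#' @param a,b,c,d cell counts (both / A only / B only / neither).
#' @param log10 return log10 p instead of p.
#' @return p-values (or log10 p-values) of the same length as `a`.
#' @export
fisher_tail_p <- function(a, b, c, d, log10 = FALSE) {
  if (min(a, b, c, d) < 0) usage_error("negative cell count")
  log_p <- phyper(a - 1, m = a + b, n = c + d, k = a + c,
                  lower.tail = FALSE, log.p = TRUE)
  log_p[a == 0] <- 0  # the tail spans the whole support
  log_p <- pmin(log_p, 0)
  if (log10) log_p / log(10) else exp(log_p)
}

fisher_greater_logp <- function(a, b, c, d) {
  fisher_tail_p(a, b, c, d, log10 = TRUE) * log(10)
}

fisher_greater_p <- function(a, b, c, d) {
  fisher_tail_p(a, b, c, d)
}

#' Permutation test of peak-set overlap
#'
#' Peaks of `A` are re-placed uniformly at random within their own
#' chromosome, preserving per-chromosome peak counts and lengths (no
#' mappability masking). The statistic is the number of `B` peaks
#' overlapping >= 1 re-placed `A` peak; the empirical p uses the
#' add-one rule `p = (1 + #[null >= obs]) / (1 + n_perm)`.
#'
#' @param A,B `peak_set`s.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @return list: `observed_shared`, `null_mean`, `null_sd`, `p_emp`,
#'   `n_perm`, `seed`.
#' @export
permutation_overlap_test <- function(A, B, chrom_sizes, n_perm = 1000L, seed = 1L) {
  if (!is_count(n_perm) || n_perm < 1) usage_error("n_perm must be >= 1")
  widths <- A$end - A$start
  lens <- chrom_sizes[A$chrom]
  if (any(is.na(lens))) usage_error("A contains chromosomes absent from chrom_sizes")
  if (any(widths > lens)) usage_error("peak longer than its chromosome")
  shared_count <- function(Adf) {
    if (!nrow(Adf) || !nrow(B)) return(0L)
    hits <- GenomicRanges::findOverlaps(as_granges0(B), as_granges0(Adf))
    length(unique(S4Vectors::queryHits(hits)))
  }
  observed <- shared_count(A)
  null_stats <- with_rng(seed, {
    vapply(seq_len(n_perm), function(i) {
      new_start <- floor(runif(nrow(A), min = 0, max = lens - widths + 1))
      shuf <- data.frame(chrom = A$chrom, start = as.integer(new_start),
                         end = as.integer(new_start + widths))
      shared_count(shuf)
    }, integer(1L))
  })
  list(observed_shared = observed,
       null_mean = mean(null_stats),
       null_sd = stats::sd(null_stats),
       p_emp = (1 + sum(null_stats >= observed)) / (1 + n_perm),
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Anchor-centered signal heat-map matrix
#'
#' For each anchor peak, per-base coverage by the signal intervals is
#' averaged in `n_bins` equal bins across `[anchor - flank, anchor + flank)`
#' (windows clipped at chromosome boundaries contribute zero coverage
#' outside the genome). Rows are ordered by descending row sum, the
#' conventional presentation for occupancy heat maps.
#'
#' @param anchors `peak_set`; each peak contributes one row, centered on its
#'   summit when known, midpoint otherwise.
#' @param signal `peak_set` or tag table supplying the coverage intervals.
#' @param flank half-window in bp (> 0).
#' @param n_bins number of bins per window (>= 1); `2 * flank` must be a
#'   multiple of `n_bins`.
#' @return list: `matrix` (rows = anchors in sorted order, re-ordered by
#'   row sum), `row_order` (original row indices), `anchor_names`.
#' @export
heatmap_matrix <- function(anchors, signal, flank = 1000L, n_bins = 40L) {
  if (flank <= 0) usage_error("flank must be > 0")
  if (!is_count(n_bins) || n_bins < 1) usage_error("n_bins must be >= 1")
  win <- 2L * as.integer(flank)
  if (win %% n_bins != 0L) usage_error("2*flank must be a multiple of n_bins")
  bw <- win %/% n_bins
  n <- nrow(anchors)
  mat <- matrix(0, nrow = n, ncol = n_bins)
  if (n && nrow(signal)) {
    cov_by_chr <- lapply(split(signal, signal$chrom), function(s) {
      IRanges::coverage(IRanges::IRanges(s$start + 1L, s$end))
    })
    for (i in seq_len(n)) {
      cv <- cov_by_chr[[anchors$chrom[i]]]
      if (is.null(cv)) next
      w0 <- anchors$anchor[i] - flank  # 0-based window start
      pos <- (w0 + 1L):(w0 + win)     # 1-based genome positions
      vals <- numeric(win)
      ok <- pos >= 1L & pos <= length(cv)
      if (any(ok)) vals[ok] <- as.numeric(cv[pos[ok]])
      mat[i, ] <- colMeans(matrix(vals, nrow = bw))
    }
  }
  ord <- order(rowSums(mat), decreasing = TRUE)
  list(matrix = mat[ord, , drop = FALSE], row_order = ord,
       anchor_names = anchors$name[ord])
}

#' Full co-localization report for two peak sets
#'
#' Combines the Venn counts, shared-peak percentages, base-pair Jaccard,
#' the binned Fisher's exact test, and the permutation test into one
#' record.
#'
#' @inheritParams permutation_overlap_test
#' @param bin_width Fisher bin width (default: median combined peak length).
#' @return an `overlap_report` list.
#' @export
overlap_report <- function(A, B, chrom_sizes, bin_width = NULL,
                           n_perm = 1000L, seed = 1L) {
  venn <- venn_counts(A, B)
  fish <- fisher_colocalization(A, B, chrom_sizes, bin_width)
  perm <- permutation_overlap_test(A, B, chrom_sizes, n_perm, seed)
  out <- list(
    label_A = set_label(A), label_B = set_label(B),
    venn = venn,
    pct_A_shared = if (venn$n_A) 100 * venn$A_shared / venn$n_A else 0,
    pct_B_shared = if (venn$n_B) 100 * venn$B_shared / venn$n_B else 0,
    jaccard = jaccard_bp(A, B),
    table = fish$table, bin_width = fish$bin_width, n_bins = fish$n_bins,
    p_fisher = fish$p, log10_p_fisher = fish$log10_p,
    p_permutation = perm$p_emp, n_permutations = perm$n_perm,
    null_mean = perm$null_mean, null_sd = perm$null_sd,
    seed = perm$seed
  )
  class(out) <- "overlap_report"
  out
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Co-localization of '%s' (n=%d) and '%s' (n=%d)\n",
              x$label_A, x$venn$n_A, x$label_B, x$venn$n_B))
  cat(sprintf("  shared: %.1f%% of A, %.1f%% of B; %d common clusters; Jaccard %.3f\n",
              x$pct_A_shared, x$pct_B_shared, x$venn$common_clusters, x$jaccard))
  cat(sprintf("  Fisher (bins of %d bp): table a=%d b=%d c=%d d=%d, log10 p = %.2f\n",
              x$bin_width, x$table[["a"]], x$table[["b"]], x$table[["c"]],
              x$table[["d"]], x$log10_p_fisher))
  cat(sprintf("  permutation (n=%d): p = %.4g\n", x$n_permutations, x$p_permutation))
  invisible(x)
}
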