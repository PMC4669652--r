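#' Known-motif enrichment in summit windows vs GC-matched background
#'
#' Each motif's PFM is converted to a log2-odds PWM; a per-motif score
#' threshold is calibrated exactly, by dynamic programming over the
#' discretized score distribution of random background w-mers, so that the
#' false-positive rate per scanned position is at most `p_target`. A window
#' is a hit when any position on either strand reaches the threshold
#' (presence/absence, i.e. regions with the motif, not site counts).
#' Enrichment compares the hit fraction in peak windows (summit +/- 100 bp)
#' against GC-matched random background windows with a one-sided binomial
#' test.
#'
#' @name motif_enrichment
NULL

#' Build a log2-odds PWM from a PFM
#'
#' `score(j, base) = log2(((count + pseudocount * bg_base) /
#' (colsum + pseudocount)) / bg_base)`.
#'
#' @param pfm a `pfm` (see [parse_jaspar_pfm()]).
#' @param background length-4 base probabilities (A, C, G, T), positive,
#'   summing to 1.
#' @param pseudocount total pseudocount mass per column (> 0), split across
#'   bases in background proportions.
#' @return a `pwm`: list with `motif_id`, `name`, `scores` (4 x w), the
#'   `background` and `pseudocount` used, and an integer-discretized score
#'   matrix (`scores_int`, granularity `granularity`) shared by the
#'   threshold DP and the scanner so threshold calibration is exact.
#' @param granularity score discretization step (default 1e-3).
#' @export
build_pwm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.8,
                      granularity = 1e-3) {
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8) {
    usage_error("background must be 4 positive probabilities summing to 1")
  }
  if (pseudocount <= 0) usage_error("pseudocount must be > 0")
  counts <- pfm$counts
  w <- ncol(counts)
  colsum <- colSums(counts)
  prob <- sweep(counts + outer(background, rep(pseudocount, w)), 2L,
                colsum + pseudocount, "/")
  scores <- log2(prob / background)
  scores_int <- round(scores / granularity)
  storage.mode(scores_int) <- "integer"
  structure(list(motif_id = pfm$motif_id, name = pfm$name, scores = scores,
                 scores_int = scores_int, granularity = granularity,
                 background = background, pseudocount = pseudocount,
                 width = w),
            class = "pwm")
}

#' Exact score threshold for a target per-position false-positive rate
#'
#' Computes, by dynamic programming over the exact distribution of the
#' discretized PWM score of a random background w-mer, the smallest
#' threshold `t` such that `P(score >= t) <= p_target`. Because both the DP
#' and the scanner operate on the same integer-discretized scores, the tail
#' probability at the returned threshold is exact, not approximate.
#'
#' @param pwm a `pwm`.
#' @param p_target target tail probability in (0, 1).
#' @return the threshold on the original score scale, with attributes
#'   `t_int` (integer threshold) and `tail_prob` (exact attained tail).
#' @export
score_threshold <- function(pwm, p_target = 1e-4) {
  if (!is.numeric(p_target) || length(p_target) != 1L ||
      p_target <= 0 || p_target > 1) {
    usage_error("p_target must be in (0, 1]")
  }
  dist <- score_int_distribution(pwm)
  tail <- rev(cumsum(rev(dist$prob)))
  ok <- which(tail <= p_target)
  if (!length(ok)) {
    # only possible for p_target < min prob mass; take the max score + 1
    t_int <- dist$score[length(dist$score)] + 1L
    attained <- 0
  } else {
    t_int <- dist$score[ok[1L]]
    attained <- tail[ok[1L]]
  }
  if (p_target == 1) {  # everything is a hit: minimum attainable score
    t_int <- dist$score[1L]
    attained <- 1
  }
  structure(t_int * pwm$granularity, t_int = t_int, tail_prob = attained)
}

# Exact distribution of the integer score of a random background w-mer:
# convolution column by column over the integer score support.
score_int_distribution <- function(pwm) {
  S <- pwm$scores_int
  bg <- pwm$background
  cur <- 1  # P(sum over zero columns = 0) = 1, support {0}
  support_lo <- 0L
  for (j in seq_len(pwm$width)) {
    col <- S[, j]
    new_lo <- support_lo + min(col)
    new_hi <- support_lo + length(cur) - 1L + max(col)
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      shift <- support_lo + col[b] - new_lo
      idx <- seq_along(cur) + shift
      new[idx] <- new[idx] + cur * bg[b]
    }
    cur <- new
    support_lo <- new_lo
  }
  keep <- cur > 0
  list(score = support_lo + which(keep) - 1L, prob = cur[keep])
}

#' Does a window contain a motif hit on either strand?
#'
#' @param seq nucleotide string (IUPAC; ambiguous bases score -Inf at their
#'   position).
#' @param pwm a `pwm`.
#' @param t score threshold (as returned by [score_threshold()]).
#' @return `TRUE`/`FALSE`; windows shorter than the motif return `FALSE`.
#' @export
window_has_hit <- function(seq, pwm, t) {
  if (!grepl("^[ACGTRYSWKMBDHVNacgtryswkmbdhvn]*$", seq)) {
    format_error("non-IUPAC character in sequence")
  }
  codes <- encode_dna(seq)
  if (length(codes) < pwm$width) return(FALSE)
  t_int <- attr(t, "t_int")
  if (is.null(t_int)) t_int <- as.integer(ceiling(t / pwm$granularity - 1e-9))
  any(scan_codes(codes, pwm, t_int)) ||
    any(scan_codes(revcomp_codes(codes), pwm, t_int))
}

# integer-score scan of one coded sequence; returns logical per position
scan_codes <- function(codes, pwm, t_int) {
  w <- pwm$width
  L <- length(codes)
  if (L < w) return(logical(0))
  NEG <- -10000000L  # ambiguous base sentinel; forces a miss
  S5 <- rbind(pwm$scores_int, rep(NEG, w))
  npos <- L - w + 1L
  total <- numeric(npos)
  for (j in seq_len(w)) {
    total <- total + S5[cbind(codes[j:(j + npos - 1L)], j)]
  }
  total >= t_int
}

# Vectorized scan of many equal-length windows given as a code matrix
# (rows = windows). Returns logical hit per window (either strand).
scan_window_matrix <- function(code_mat, pwm, t_int) {
  w <- pwm$width
  L <- ncol(code_mat)
  n <- nrow(code_mat)
  if (L < w || n == 0L) return(logical(n))
  NEG <- -10000000L
  S5 <- rbind(pwm$scores_int, rep(NEG, w))
  hit <- logical(n)
  comp <- c(4L, 3L, 2L, 1L, 5L)
  rc_mat <- matrix(comp[code_mat[, L:1, drop = FALSE]], nrow = n)
  for (mat in list(code_mat, rc_mat)) {
    for (p in seq_len(L - w + 1L)) {
      total <- numeric(n)
      for (j in seq_len(w)) {
        total <- total + S5[cbind(mat[, p + j - 1L], j)]
      }
      hit <- hit | (total >= t_int)
      if (all(hit)) return(hit)
    }
  }
  hit
}

#' Extract fixed-width windows from a genome
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param windows data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); windows extending past a chromosome edge are clipped and
#'   padded with N (reported via a message).
#' @return character vector of sequences.
#' @keywords internal
extract_windows <- function(genome, windows) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  n_clip <- 0L
  out <- character(nrow(windows))
  for (ch in unique(windows$chrom)) {
    if (!ch %in% names(genome)) usage_error(sprintf("chromosome '%s' not in genome", ch))
    idx <- which(windows$chrom == ch)
    s <- windows$start[idx]; e <- windows$end[idx]
    cs <- pmax(s, 0L); ce <- pmin(e, lens[[ch]])
    clipped <- cs != s | ce != e
    n_clip <- n_clip + sum(clipped)
    seqs <- as.character(Biostrings::subseq(rep(genome[ch], length(idx)),
                                            start = cs + 1L, end = ce))
    pad_l <- cs - s; pad_r <- e - ce
    seqs <- paste0(strrep("N", pad_l), seqs, strrep("N", pad_r))
    out[idx] <- seqs
  }
  if (n_clip > 0L) message(sprintf("%d window(s) clipped at chromosome edges", n_clip))
  out
}

window_codes <- function(seqs) {
  n <- length(seqs)
  if (!n) return(matrix(integer(), 0, 0))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) usage_error("windows must have equal width")
  flat <- match(strsplit(paste(toupper(seqs), collapse = ""), "")[[1L]], DNA_BASES4)
  flat[is.na(flat)] <- 5L
  matrix(flat, nrow = n, ncol = L, byrow = TRUE)
}

gc_fraction <- function(seqs) {
  up <- toupper(seqs)
  gc <- nchar(gsub("[^GC]", "", up))
  at <- nchar(gsub("[^AT]", "", up))
  ifelse(gc + at == 0, NA_real_, gc / (gc + at))
}

#' Sample background windows GC-matched to a set of peak windows
#'
#' Windows are drawn uniformly from the genome and accepted or rejected so
#' the sampled GC-fraction histogram (bins of `gc_bin`) matches the peak
#' windows' histogram proportions. Deterministic under `seed`.
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param n_bg number of background windows (>= 1).
#' @param width window width in bp (default 201 = summit +/- 100).
#' @param peak_gc numeric vector of GC fractions of the peak windows (the
#'   matching target).
#' @param seed RNG seed.
#' @param gc_bin GC histogram bin width (default 0.05).
#' @param max_draws_per_window rejection-sampling budget; a GC bin that
#'   cannot be filled within `max_draws_per_window * n_bg` draws raises a
#'   sampling error naming the bin.
#' @param exclude optional data.frame of intervals (`chrom`,`start`,`end`)
#'   that sampled windows must not overlap (e.g. the peaks themselves).
#' @return data.frame with `chrom`, `start`, `end`, `gc` of the sampled
#'   windows.
#' @export
sample_gc_matched_background <- function(genome, n_bg, width = 201L, peak_gc,
                                         seed = 1L, gc_bin = 0.05,
                                         max_draws_per_window = 10000L,
                                         exclude = NULL) {
  if (!is_count(n_bg) || n_bg < 1) usage_error("n_bg must be >= 1")
  peak_gc <- peak_gc[!is.na(peak_gc)]
  if (!length(peak_gc)) usage_error("no usable peak GC values")
  breaks <- seq(0, 1 + gc_bin, by = gc_bin)
  bin_of <- function(gc) pmin(findInterval(gc, breaks, rightmost.closed = TRUE),
                              length(breaks) - 1L)
  peak_bins <- tabulate(bin_of(peak_gc), nbins = length(breaks) - 1L)
  # largest-remainder apportionment of n_bg across occupied bins
  quota_raw <- n_bg * peak_bins / sum(peak_bins)
  quota <- floor(quota_raw)
  rem <- n_bg - sum(quota)
  if (rem > 0) {
    extra <- order(quota_raw - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  }
  lens <- Biostrings::width(genome)
  chroms <- names(genome)
  usable <- lens >= width
  if (!any(usable)) usage_error("no chromosome long enough for the window width")
  wts <- (lens - width + 1) * usable
  excl_gr <- if (!is.null(exclude) && nrow(exclude)) as_granges0(exclude) else NULL

  with_rng(seed, {
    got <- vector("list", 0L)
    need <- quota
    draws <- 0L
    budget <- max_draws_per_window * n_bg
    batch <- max(256L, 4L * n_bg)
    while (sum(need) > 0L) {
      if (draws >= budget) {
        miss <- which(need > 0L)[1L]
        sampling_error(sprintf(
          "could not fill GC bin [%.2f,%.2f) after %d draws",
          breaks[miss], breaks[miss + 1L], draws))
      }
      k <- min(batch, budget - draws)
      draws <- draws + k
      ci <- sample.int(length(chroms), k, replace = TRUE, prob = wts)
      st <- floor(runif(k, 0, lens[ci] - width + 1))
      cand <- data.frame(chrom = chroms[ci], start = as.integer(st),
                         end = as.integer(st + width), stringsAsFactors = FALSE)
      if (!is.null(excl_gr)) {
        ov <- GenomicRanges::countOverlaps(as_granges0(cand), excl_gr) > 0L
        cand <- cand[!ov, , drop = FALSE]
        if (!nrow(cand)) next
      }
      cand$gc <- gc_fraction(extract_windows(genome, cand))
      cand <- cand[!is.na(cand$gc), , drop = FALSE]
      cand$bin <- bin_of(cand$gc)
      for (i in seq_len(nrow(cand))) {
        b <- cand$bin[i]
        if (need[b] > 0L) {
          need[b] <- need[b] - 1L
          got[[length(got) + 1L]] <- cand[i, c("chrom", "start", "end", "gc")]
        }
      }
    }
    out <- do.call(rbind, got)
    rownames(out) <- NULL
    out
  })
}

#' One-sided binomial enrichment test
#'
#' Upper-tail binomial p of `k_peak` hit windows among `n_peak` at the
#' Laplace-smoothed background rate `p0 = (k_bg + 1) / (n_bg + 2)`;
#' computed in log space.
#'
#' @param k_peak,n_peak hit and total counts in peak windows.
#' @param k_bg,n_bg hit and total counts in background windows.
#' @return list: `p`, `log10_p`, `p0`, `rate_peak`, `rate_bg`.
#' @export
binomial_enrichment <- function(k_peak, n_peak, k_bg, n_bg) {
  if (!is_count(n_peak) || n_peak < 1) usage_error("n_peak must be >= 1")
  if (!is_count(k_peak) || k_peak > n_peak) usage_error("k_peak must be in [0, n_peak]")
  if (!is_count(n_bg) || !is_count(k_bg) || k_bg > n_bg) {
    usage_error("invalid background counts")
  }
  p0 <- (k_bg + 1) / (n_bg + 2)
  log_p <- pbinom(k_peak - 1, n_peak, p0, lower.tail = FALSE, log.p = TRUE)
  if (k_peak == 0) log_p <- 0
  list(p = min(1, exp(log_p)), log10_p = log_p / log(10), p0 = p0,
       rate_peak = k_peak / n_peak, rate_bg = if (n_bg) k_bg / n_bg else NA_real_)
}

#' Significance stars for an enrichment p-value
#'
#' Tiers: `***` p < 1e-10, `**` p < 0.01, `*` p < 0.1, otherwise `""`.
#'
#' @param p p-value in `[0, 1]`.
#' @export
star_annotation <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p < 1e-10) "***" else if (p < 0.01) "**" else if (p < 0.1) "*" else ""
}

#' Enrichment of a motif library in peak summit windows
#'
#' For each motif, counts peak windows (anchor +/- `flank`) and GC-matched
#' background windows containing >= 1 hit at the motif's calibrated
#' threshold, and tests enrichment with the one-sided binomial test.
#' Records are ordered by ascending p (ties by `motif_id`); a
#' Benjamini-Hochberg q-value is reported alongside the raw p, and stars
#' follow the raw p.
#'
#' @param peaks `peak_set` with resolvable anchors.
#' @param genome [Biostrings::DNAStringSet] covering the peaks.
#' @param motifs list of `pfm` objects (e.g. from [read_jaspar()]).
#' @param flank half-window around the anchor (default 100 bp).
#' @param p_target per-position false-positive target for the threshold
#'   (default 1e-4).
#' @param bg_multiple background windows per peak window (default 10).
#' @param background length-4 base composition for the PWM log-odds
#'   (default uniform).
#' @param pseudocount PWM pseudocount (default 0.8).
#' @param seed RNG seed for background sampling.
#' @param bg_windows optional explicit background windows (data.frame with
#'   `chrom`, `start`, `end`); when given, GC-matched sampling is skipped.
#' @return data.frame, one row per motif: `motif_id`, `name`, `n_peak`,
#'   `k_peak`, `n_bg`, `k_bg`, `pct_peak`, `pct_bg`, `p0`, `p_binomial`,
#'   `q_bh`, `stars`, `threshold`.
#' @export
enrich_motif_set <- function(peaks, genome, motifs, flank = 100L,
                             p_target = 1e-4, bg_multiple = 10L,
                             background = rep(0.25, 4), pseudocount = 0.8,
                             seed = 1L, bg_windows = NULL) {
  if (!length(motifs)) {
    return(data.frame(motif_id = character(), name = character(),
                      n_peak = integer(), k_peak = integer(),
                      n_bg = integer(), k_bg = integer(),
                      pct_peak = numeric(), pct_bg = numeric(),
                      p0 = numeric(), p_binomial = numeric(),
                      q_bh = numeric(), stars = character(),
                      threshold = numeric(), stringsAsFactors = FALSE))
  }
  if (!nrow(peaks)) usage_error("empty peak set")
  width <- 2L * as.integer(flank) + 1L
  pw <- data.frame(chrom = peaks$chrom,
                   start = peaks$anchor - as.integer(flank),
                   end = peaks$anchor + as.integer(flank) + 1L)
  peak_seqs <- extract_windows(genome, pw)
  peak_codes <- window_codes(peak_seqs)
  if (is.null(bg_windows)) {
    peak_gc <- gc_fraction(peak_seqs)
    bg_windows <- sample_gc_matched_background(
      genome, n_bg = bg_multiple * nrow(peaks), width = width,
      peak_gc = peak_gc, seed = seed, exclude = peaks)
  }
  bg_seqs <- extract_windows(genome, bg_windows)
  bg_codes <- window_codes(bg_seqs)

  rows <- lapply(motifs, function(m) {
    pwm <- build_pwm(m, background = background, pseudocount = pseudocount)
    t <- score_threshold(pwm, p_target)
    t_int <- attr(t, "t_int")
    k_peak <- sum(scan_window_matrix(peak_codes, pwm, t_int))
    k_bg <- sum(scan_window_matrix(bg_codes, pwm, t_int))
    res <- binomial_enrichment(k_peak, nrow(peak_codes), k_bg, nrow(bg_codes))
    data.frame(motif_id = m$motif_id, name = m$name,
               n_peak = nrow(peak_codes), k_peak = k_peak,
               n_bg = nrow(bg_codes), k_bg = k_bg,
               pct_peak = 100 * k_peak / nrow(peak_codes),
               pct_bg = 100 * k_bg / nrow(bg_codes),
               p0 = res$p0, p_binomial = res$p,
               threshold = as.numeric(t), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$q_bh <- p.adjust(tab$p_binomial, method = "BH")
  tab$stars <- vapply(tab$p_binomial, star_annotation, "")
  tab[order(tab$p_binomial, tab$motif_id), , drop = FALSE]
}
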