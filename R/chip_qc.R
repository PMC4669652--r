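#' ENCODE-style ChIP-seq quality metrics
#'
#' SPOT (signal portion of tags), PBC (PCR bottleneck coefficient, variant
#' PBC1 = N1/Nd), strand cross-correlation with NSC/RSC, and the saturation
#' test (Pearson correlation of binned coverage between a sub-sample and the
#' full library).
#'
#' @name chip_qc
NULL

#' Signal portion of tags
#'
#' Fraction of tags whose 5' end lies within any peak interval. Peak regions
#' are caller-supplied (any enriched-region set), not tied to a particular
#' peak-calling program.
#'
#' @param tags tag table (see [read_tagalign()]).
#' @param peaks `peak_set`.
#' @return fraction in `[0, 1]`.
#' @export
spot <- function(tags, peaks) {
  if (!nrow(tags)) usage_error("spot of an empty tag set")
  if (!nrow(peaks)) return(0)
  tgr <- GenomicRanges::GRanges(tags$chrom,
                                IRanges::IRanges(tags$five_prime + 1L, width = 1L))
  sum(GenomicRanges::countOverlaps(tgr, as_granges0(peaks)) > 0L) / nrow(tags)
}

#' PCR bottleneck coefficient (PBC1)
#'
#' `N1 / Nd`, where `Nd` is the number of distinct (chrom, strand, 5' end)
#' positions and `N1` the number of positions covered by exactly one tag.
#'
#' @param tags tag table.
#' @return fraction in `[0, 1]`; 1 means a duplicate-free library.
#' @export
pbc <- function(tags) {
  if (!nrow(tags)) usage_error("pbc of an empty tag set")
  key <- paste(tags$chrom, tags$strand, tags$five_prime, sep = "\r")
  cnt <- table(key)
  sum(cnt == 1L) / length(cnt)
}

#' Strand cross-correlation profile
#'
#' For each shift d in 0..`max_shift`, the Pearson correlation between
#' per-base + strand 5'-end counts and - strand counts shifted left by d.
#' Per-chromosome count vectors are trimmed by the shift and concatenated,
#' so shifts never cross chromosome boundaries. Correlation is computed on
#' raw counts (not binarized).
#'
#' @param tags tag table.
#' @param max_shift largest shift in bp.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param bin base-pair bin for the count vectors (default 1).
#' @return a `cc_profile` list: `shift`, `cc`, `argmax_shift`, `cc_max`,
#'   `cc_min`.
#' @export
cross_correlation <- function(tags, max_shift = 400L, chrom_sizes, bin = 1L) {
  if (!nrow(tags)) usage_error("cross_correlation of an empty tag set")
  if (bin < 1L) usage_error("bin must be >= 1")
  chroms <- names(chrom_sizes)[names(chrom_sizes) %in% unique(tags$chrom)]
  if (!length(chroms)) usage_error("no tags on known chromosomes")
  vecs <- lapply(chroms, function(ch) {
    L <- as.integer(ceiling(chrom_sizes[[ch]] / bin))
    tt <- tags[tags$chrom == ch, , drop = FALSE]
    pos <- pmin(tt$five_prime %/% bin + 1L, L)
    list(plus = tabulate(pos[tt$strand == "+"], nbins = L),
         minus = tabulate(pos[tt$strand == "-"], nbins = L))
  })
  shifts <- 0:as.integer(max_shift %/% bin)
  cc <- vapply(shifts, function(d) {
    xs <- unlist(lapply(vecs, function(v) {
      L <- length(v$plus)
      if (d >= L) numeric(0) else v$plus[seq_len(L - d)]
    }))
    ys <- unlist(lapply(vecs, function(v) {
      L <- length(v$minus)
      if (d >= L) numeric(0) else v$minus[(d + 1L):L]
    }))
    if (length(xs) < 2L || stats::sd(xs) == 0 || stats::sd(ys) == 0) {
      warning("zero-variance count vector at shift ", d * bin,
              "; correlation recorded as 0")
      return(0)
    }
    cor(xs, ys)
  }, numeric(1L))
  shift_bp <- shifts * bin
  k <- which.max(cc)
  structure(list(shift = shift_bp, cc = cc,
                 argmax_shift = shift_bp[k], cc_max = cc[k],
                 cc_min = min(cc)),
            class = "cc_profile")
}

#' NSC and RSC from a cross-correlation profile
#'
#' `NSC = cc(argmax) / cc_min`; `RSC = (cc(argmax) - cc_min) /
#' (cc(read_len) - cc_min)`, where `cc(read_len)` is the "phantom peak" at
#' the read length. Values above 1 indicate acceptable enrichment.
#'
#' @param profile a `cc_profile` from [cross_correlation()].
#' @param read_len read length in bp; must be within the profile's shifts.
#' @return list: `nsc`, `rsc` (NA when the phantom-peak denominator is 0,
#'   reported with a warning).
#' @export
nsc_rsc <- function(profile, read_len) {
  idx <- match(read_len, profile$shift)
  if (is.na(idx)) usage_error("read_len outside the profile's shift range")
  cc_read <- profile$cc[idx]
  nsc <- profile$cc_max / profile$cc_min
  denom <- cc_read - profile$cc_min
  rsc <- if (denom == 0) {
    warning("cc(read_len) equals cc_min; RSC undefined, reported as NA")
    NA_real_
  } else {
    (profile$cc_max - profile$cc_min) / denom
  }
  list(nsc = nsc, rsc = rsc)
}

#' Saturation analysis by read sub-sampling
#'
#' Sub-samples the tags without replacement at each fraction and reports the
#' Pearson correlation between the binned 5'-end coverage of the sub-sample
#' and of the full library (bins of `bin_width` bp, default 10 kb, across
#' the genome).
#'
#' @param tags tag table.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param fractions sampling fractions in (0, 1] (default 0.05 .. 1.00 in
#'   steps of 0.05).
#' @param bin_width coverage bin width in bp (default 10000).
#' @param seed RNG seed.
#' @return data.frame with `fraction`, `pearson_r`; the fraction-1.0 row is
#'   exactly 1.
#' @export
saturation_curve <- function(tags, chrom_sizes, fractions = seq(0.05, 1, by = 0.05),
                             bin_width = 10000L, seed = 1L) {
  if (!nrow(tags)) usage_error("saturation_curve of an empty tag set")
  if (any(fractions <= 0 | fractions > 1)) {
    usage_error("fractions must lie in (0, 1]")
  }
  n_bins_chr <- as.integer(ceiling(chrom_sizes / bin_width))
  offsets <- setNames(cumsum(c(0L, head(n_bins_chr, -1L))), names(chrom_sizes))
  n_bins <- sum(n_bins_chr)
  bin_id <- offsets[tags$chrom] + pmin(tags$five_prime %/% bin_width,
                                       n_bins_chr[match(tags$chrom, names(chrom_sizes))] - 1L) + 1L
  if (anyNA(bin_id)) usage_error("tags on chromosomes absent from chrom_sizes")
  full <- tabulate(bin_id, nbins = n_bins)
  n <- nrow(tags)
  with_rng(seed, {
    res <- vapply(fractions, function(f) {
      if (f == 1) return(1)
      keep <- sample.int(n, size = round(f * n), replace = FALSE)
      sub <- tabulate(bin_id[keep], nbins = n_bins)
      if (stats::sd(sub) == 0 || stats::sd(full) == 0) return(0)
      cor(sub, full)
    }, numeric(1L))
    data.frame(fraction = fractions, pearson_r = res)
  })
}

#' Full QC report
#'
#' @param tags tag table.
#' @param peaks `peak_set` used as the SPOT signal regions.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param read_len read length in bp.
#' @param max_shift cross-correlation maximum shift (default
#'   `max(400, 2 * read_len)`).
#' @param fractions saturation fractions.
#' @param bin_width saturation bin width.
#' @param seed RNG seed.
#' @return a `qc_report` list: `n_tags`, `spot`, `pbc`, `nsc`, `rsc`,
#'   `argmax_shift`, `saturation` (data.frame).
#' @export
qc_report <- function(tags, peaks, chrom_sizes, read_len,
                      max_shift = max(400L, 2L * read_len),
                      fractions = seq(0.05, 1, by = 0.05),
                      bin_width = 10000L, seed = 1L) {
  prof <- cross_correlation(tags, max_shift = max_shift, chrom_sizes = chrom_sizes)
  nr <- nsc_rsc(prof, read_len)
  out <- list(n_tags = nrow(tags),
              spot = spot(tags, peaks),
              pbc = pbc(tags),
              nsc = nr$nsc, rsc = nr$rsc,
              argmax_shift = prof$argmax_shift,
              cc_profile = data.frame(shift = prof$shift, cc = prof$cc),
              saturation = saturation_curve(tags, chrom_sizes,
                                            fractions = fractions,
                                            bin_width = bin_width, seed = seed))
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d tags | SPOT %.3f | PBC %.3f | NSC %.2f | RSC %s | frag-len est %d bp\n",
              x$n_tags, x$spot, x$pbc, x$nsc,
              ifelse(is.na(x$rsc), "NA", sprintf("%.2f", x$rsc)),
              x$argmax_shift))
  r95 <- x$saturation$fraction[which(x$saturation$pearson_r >= 0.95)[1L]]
  if (!is.na(r95)) cat(sprintf("  saturation: r >= 0.95 reached at fraction %.2f\n", r95))
  invisible(x)
}

#' Binned 5'-end coverage (for bedGraph export)
#'
#' @param tags tag table.
#' @param chrom_sizes named integer vector.
#' @param bin_width bin width in bp.
#' @return data.frame `chrom`, `start`, `end`, `value` (tag 5' ends per bin).
#' @export
binned_coverage <- function(tags, chrom_sizes, bin_width = 10000L) {
  out <- lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    nb <- as.integer(ceiling(L / bin_width))
    tt <- tags[tags$chrom == ch, , drop = FALSE]
    cnt <- tabulate(pmin(tt$five_prime %/% bin_width, nb - 1L) + 1L, nbins = nb)
    starts <- (seq_len(nb) - 1L) * bin_width
    data.frame(chrom = ch, start = starts, end = pmin(starts + bin_width, L),
               value = cnt, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
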