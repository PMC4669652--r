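#' Core interval arithmetic under the >=1 bp overlap rule
#'
#' Two intervals co-localize iff they share at least one base pair; with
#' 0-based half-open coordinates that is `a.start < b.end && b.start < a.end`
#' on the same chromosome. Touching intervals share zero bases and never
#' overlap or merge.
#'
#' @name interval_core
NULL

#' Construct a normalized peak set
#'
#' Normalization sorts peaks by (chrom, start, end) and rejects zero-length
#' members. The anchor of a peak is its summit (`start + summit_offset`)
#' when known, otherwise the midpoint `floor((start + end) / 2)`.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`, `summit_offset`.
#' @param label text label for the set.
#' @param genome_id genome identifier; operations on two sets require equal
#'   genome ids.
#' @return a `peak_set` data.frame with an `anchor` column.
#' @export
peak_set <- function(peaks, label = "peaks", genome_id = "unspecified") {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  if (!nrow(peaks)) {
    peaks <- data.frame(chrom = character(), start = integer(), end = integer(),
                        name = character(), score = numeric(), strand = character(),
                        summit_offset = integer(), anchor = integer(),
                        stringsAsFactors = FALSE)
    attr(peaks, "label") <- label
    attr(peaks, "genome_id") <- genome_id
    class(peaks) <- c("peak_set", "data.frame")
    return(peaks)
  }
  if (any(peaks$start >= peaks$end)) usage_error("zero- or negative-length peak")
  if (any(peaks$start < 0)) usage_error("negative peak start")
  if (is.null(peaks$name)) peaks$name <- sprintf("%s_%d", label, seq_len(nrow(peaks)))
  if (is.null(peaks$score)) peaks$score <- 0
  if (is.null(peaks$strand)) peaks$strand <- "."
  if (is.null(peaks$summit_offset)) peaks$summit_offset <- -1L
  bad <- peaks$summit_offset >= (peaks$end - peaks$start)
  if (any(bad)) usage_error("summit offset outside peak")
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks$anchor <- ifelse(peaks$summit_offset >= 0L,
                         peaks$start + peaks$summit_offset,
                         (peaks$start + peaks$end) %/% 2L)
  attr(peaks, "label") <- label
  attr(peaks, "genome_id") <- genome_id
  class(peaks) <- c("peak_set", "data.frame")
  peaks
}

set_label <- function(x) attr(x, "label") %||% "peaks"
set_genome <- function(x) attr(x, "genome_id") %||% "unspecified"
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Do two intervals share at least one base pair?
#'
#' @param a,b lists/one-row data.frames with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return `TRUE` iff same chromosome and `a$start < b$end && b$start < a$end`.
#' @export
overlaps <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

#' Venn counts of two peak sets under the >=1 bp rule
#'
#' A peak is "shared" if it overlaps at least one peak of the other set by
#' >= 1 bp. Because overlap is many-to-many, the symmetric figure-style
#' count is `common_clusters`: connected components of the overlap graph
#' that contain members of both sets.
#'
#' @param A,B `peak_set`s with equal `genome_id`.
#' @return a `venn_counts` list: `n_A`, `n_B`, `A_shared`, `B_shared`,
#'   `only_A`, `only_B`, `common_clusters`.
#' @export
venn_counts <- function(A, B) {
  if (set_genome(A) != set_genome(B)) {
    usage_error(sprintf("genome_id mismatch: '%s' vs '%s'",
                        set_genome(A), set_genome(B)))
  }
  n_A <- nrow(A); n_B <- nrow(B)
  if (n_A == 0L || n_B == 0L) {
    out <- list(n_A = n_A, n_B = n_B, A_shared = 0L, B_shared = 0L,
                only_A = n_A, only_B = n_B, common_clusters = 0L)
    class(out) <- "venn_counts"
    return(out)
  }
  gra <- as_granges0(A)
  grb <- as_granges0(B)
  hits <- GenomicRanges::findOverlaps(gra, grb, minoverlap = 1L)
  A_shared <- length(unique(S4Vectors::queryHits(hits)))
  B_shared <- length(unique(S4Vectors::subjectHits(hits)))
  # connected components of the overlap graph == runs of overlapping
  # intervals == reduce() with zero gap tolerance over the pooled sets
  pooled <- c(gra, grb)
  merged <- GenomicRanges::reduce(pooled, min.gapwidth = 0L)
  comp_a <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(gra, merged))
  comp_b <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(grb, merged))
  common_clusters <- length(intersect(unique(comp_a), unique(comp_b)))
  out <- list(n_A = n_A, n_B = n_B,
              A_shared = A_shared, B_shared = B_shared,
              only_A = n_A - A_shared, only_B = n_B - B_shared,
              common_clusters = common_clusters)
  class(out) <- "venn_counts"
  out
}

#' @export
print.venn_counts <- function(x, ...) {
  cat(sprintf("Venn (>=1 bp overlap): only A %d | common clusters %d | only B %d\n",
              x$only_A, x$common_clusters, x$only_B))
  cat(sprintf("  A: %d shared of %d; B: %d shared of %d\n",
              x$A_shared, x$n_A, x$B_shared, x$n_B))
  invisible(x)
}

#' Merge overlapping intervals
#'
#' Returns the maximal disjoint intervals covering the input. Touching but
#' non-overlapping intervals (0 shared bp) stay separate, consistent with
#' the >=1 bp overlap rule.
#'
#' @param peaks `peak_set` or data.frame with `chrom`, `start`, `end`.
#' @return data.frame of merged intervals, sorted.
#' @export
merge_peaks <- function(peaks) {
  if (!nrow(peaks)) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  m <- GenomicRanges::reduce(as_granges0(peaks), min.gapwidth = 0L)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(m)),
                    start = GenomicRanges::start(m) - 1L,
                    end = GenomicRanges::end(m),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Signed distance from a peak center to a gene's TSS
#'
#' Positive means downstream of the TSS in the gene's orientation, negative
#' upstream; on the - strand the raw genomic difference is negated.
#'
#' @param peak_mid integer vector of peak anchor positions.
#' @param tss integer vector of TSS positions (recycled against `peak_mid`).
#' @param strand gene strand vector (`"+"`/`"-"`).
#' @return signed integer distances.
#' @export
tss_distance <- function(peak_mid, tss, strand) {
  d <- peak_mid - tss
  ifelse(strand == "-", -d, d)
}

# For each peak anchor, the signed distance to the nearest TSS (by |d|);
# ties broken by smaller gene start, then gene_id, for determinism.
nearest_tss <- function(anchors, chroms, genes) {
  n <- length(anchors)
  out_d <- rep(NA_integer_, n)
  out_g <- rep(NA_character_, n)
  ord <- order(genes$start, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  for (ch in unique(chroms)) {
    gi <- which(genes$chrom == ch)
    pi <- which(chroms == ch)
    if (!length(gi) || !length(pi)) next
    g <- genes[gi, , drop = FALSE]
    # tie rule: among equal |signed distance|, the gene listed first in
    # (start, gene_id) order wins; stable which.min over that order
    for (j in pi) {
      d <- tss_distance(anchors[j], g$tss, g$strand)
      k <- which.min(abs(d))
      out_d[j] <- d[k]
      out_g[j] <- g$gene_id[k]
    }
  }
  data.frame(gene_id = out_g, distance = out_d, stringsAsFactors = FALSE)
}

#' Classify peaks as promoter / gene body / intergenic
#'
#' A peak is `promoter` when its anchor lies within `promoter_window` bp of
#' the nearest TSS (by absolute signed distance); otherwise `gene_body` when
#' the anchor falls inside any gene span; otherwise `intergenic`. The
#' three-way scheme is a deliberately simplified stand-in for feature-level
#' annotation tools and is flagged as such in reports.
#'
#' @param peaks `peak_set`.
#' @param genes gene table (see [gene_table()]).
#' @param promoter_window half-width of the promoter window in bp (default
#'   1000, i.e. "within 1 kb of the TSS").
#' @return factor of levels promoter/gene_body/intergenic, one per peak.
#' @export
classify_feature <- function(peaks, genes, promoter_window = 1000L) {
  n <- nrow(peaks)
  if (!n) return(factor(character(), levels = c("promoter", "gene_body", "intergenic")))
  cls <- rep("intergenic", n)
  if (nrow(genes)) {
    nt <- nearest_tss(peaks$anchor, peaks$chrom, genes)
    in_prom <- !is.na(nt$distance) & abs(nt$distance) <= promoter_window
    # anchor inside any gene span?
    ggr <- as_granges0(genes)
    pgr <- GenomicRanges::GRanges(peaks$chrom,
                                  IRanges::IRanges(peaks$anchor + 1L, width = 1L))
    in_body <- GenomicRanges::countOverlaps(pgr, ggr) > 0L
    cls[in_body] <- "gene_body"
    cls[in_prom] <- "promoter"
  }
  factor(cls, levels = c("promoter", "gene_body", "intergenic"))
}

#' Base-pair Jaccard index of two peak sets
#'
#' Shared base pairs of the merged sets divided by base pairs of their union.
#'
#' @param A,B `peak_set`s.
#' @return a real in `[0, 1]` (0 when both sets are empty).
#' @export
jaccard_bp <- function(A, B) {
  if (!nrow(A) && !nrow(B)) return(0)
  if (!nrow(A) || !nrow(B)) return(0)
  ga <- GenomicRanges::reduce(as_granges0(A))
  gb <- GenomicRanges::reduce(as_granges0(B))
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(ga, gb)))
  inter / uni
}
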