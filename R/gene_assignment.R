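#' Single-nearest-gene association and TSS statistics
#'
#' Peaks are associated to the gene whose TSS is nearest to the peak anchor
#' (absolute signed distance), with a maximum extension of 50 kb: peaks with
#' no TSS within the extension remain unassigned. Distances are signed in
#' gene orientation (negative = upstream).
#'
#' @name gene_assignment
NULL

#' Assign each peak its single nearest gene within a maximum extension
#'
#' @param peaks `peak_set`.
#' @param genes gene table.
#' @param max_extension maximum |distance| in bp for an assignment
#'   (default 50000).
#' @param anchor `"midpoint"` (default; the peak center) or `"summit"`
#'   (uses the summit where known, midpoint otherwise).
#' @return data.frame: `peak`, `gene_id` (NA if none within the extension),
#'   `distance` (signed, NA if unassigned), `within_50kb` logical.
#' @export
assign_nearest_gene <- function(peaks, genes, max_extension = 50000L,
                                anchor = c("midpoint", "summit")) {
  anchor <- match.arg(anchor)
  anchors <- peak_anchor(peaks, anchor)
  nt <- if (nrow(genes)) nearest_tss(anchors, peaks$chrom, genes) else
    data.frame(gene_id = rep(NA_character_, nrow(peaks)),
               distance = rep(NA_integer_, nrow(peaks)))
  too_far <- is.na(nt$distance) | abs(nt$distance) > max_extension
  data.frame(peak = peaks$name,
             gene_id = ifelse(too_far, NA_character_, nt$gene_id),
             distance = ifelse(too_far, NA_integer_, nt$distance),
             within_50kb = !too_far,
             stringsAsFactors = FALSE)
}

peak_anchor <- function(peaks, anchor = c("midpoint", "summit")) {
  anchor <- match.arg(anchor)
  if (anchor == "summit") {
    peaks$anchor
  } else {
    (peaks$start + peaks$end) %/% 2L
  }
}

#' Percentage of peaks whose anchor lies within a window of any TSS
#'
#' @inheritParams assign_nearest_gene
#' @param window half-width in bp (default 1000, "within 1 kb").
#' @return percentage in `[0, 100]`.
#' @export
promoter_fraction <- function(peaks, genes, window = 1000L,
                              anchor = c("midpoint", "summit")) {
  if (!nrow(peaks)) usage_error("promoter_fraction of an empty peak set")
  if (!nrow(genes)) return(0)
  anchors <- peak_anchor(peaks, anchor)
  nt <- nearest_tss(anchors, peaks$chrom, genes)
  100 * sum(!is.na(nt$distance) & abs(nt$distance) <= window) / nrow(peaks)
}

#' Histogram of signed nearest-TSS distances
#'
#' Bin edges partition the real line: counts below the first edge go to the
#' open left end bin and counts at or above the last edge to the open right
#' end bin, so counts always sum to the number of peaks. The default edges
#' mirror the +/- 0/1 kb/5 kb/10 kb/50 kb scheme of TSS-distance profiles.
#'
#' @inheritParams assign_nearest_gene
#' @param bin_edges strictly increasing numeric vector of interior edges.
#' @return data.frame with `bin` labels and `count`.
#' @export
tss_histogram <- function(peaks, genes,
                          bin_edges = c(-50000, -10000, -5000, -1000, 0,
                                        1000, 5000, 10000, 50000),
                          anchor = c("midpoint", "summit")) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    usage_error("bin_edges must be strictly increasing")
  }
  anchors <- peak_anchor(peaks, anchor)
  nt <- if (nrow(genes)) nearest_tss(anchors, peaks$chrom, genes) else
    data.frame(distance = rep(NA_real_, nrow(peaks)))
  d <- nt$distance
  edges <- c(-Inf, bin_edges, Inf)
  labels <- sprintf("[%s,%s)", head(edges, -1L), edges[-1L])
  counts <- integer(length(labels))
  ok <- !is.na(d)
  if (any(ok)) {
    idx <- findInterval(d[ok], edges, left.open = FALSE, rightmost.closed = FALSE)
    tab <- tabulate(idx, nbins = length(labels))
    counts <- counts + tab
  }
  # peaks on chromosomes with no genes land in the open right end bin? No:
  # they have no defined distance; report them separately as NA bin
  n_na <- sum(!ok)
  out <- data.frame(bin = labels, count = counts, stringsAsFactors = FALSE)
  if (n_na > 0L) {
    out <- rbind(out, data.frame(bin = "no_tss_on_chrom", count = n_na))
  }
  out
}

#' @importFrom utils head
NULL
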