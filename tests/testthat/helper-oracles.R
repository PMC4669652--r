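# Independent brute-force oracles. These deliberately avoid the package's
# interval machinery: all-pairs scans, per-base rasterization, and direct
# log-factorial tail sums, so agreement with the fast paths is meaningful.

ov1 <- function(c1, s1, e1, c2, s2, e2) c1 == c2 & s1 < e2 & s2 < e1

# all-pairs Venn counting plus connected components by label propagation
oracle_venn <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B)
  hitA <- logical(nA); hitB <- logical(nB)
  adj <- matrix(FALSE, nA + nB, nA + nB)
  for (i in seq_len(nA)) {
    for (j in seq_len(nB)) {
      if (ov1(A$chrom[i], A$start[i], A$end[i], B$chrom[j], B$start[j], B$end[j])) {
        hitA[i] <- TRUE; hitB[j] <- TRUE
        adj[i, nA + j] <- adj[nA + j, i] <- TRUE
      }
    }
  }
  # same-set overlaps also connect components
  both <- rbind(A[, c("chrom", "start", "end")], B[, c("chrom", "start", "end")])
  n <- nA + nB
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && ov1(both$chrom[i], both$start[i], both$end[i],
                        both$chrom[j], both$start[j], both$end[j])) {
        adj[i, j] <- TRUE
      }
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      if (length(nb) && min(comp[nb]) < comp[i]) {
        comp[i] <- min(comp[nb]); changed <- TRUE
      }
    }
    if (!changed) break
  }
  common <- length(intersect(unique(comp[seq_len(nA)]),
                             unique(comp[nA + seq_len(nB)])))
  list(A_shared = sum(hitA), B_shared = sum(hitB), common_clusters = common)
}

# rasterize onto a doubled-resolution array (odd cells = base interiors,
# even cells = integer boundary points, which an interval covers only when
# strictly inside it) so that touching intervals leave a one-cell gap and
# stay separate, per the >=1 bp rule
oracle_merge <- function(df) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    d <- df[df$chrom == ch, , drop = FALSE]
    L <- 2L * max(d$end) + 2L
    covered <- logical(L)
    for (i in seq_len(nrow(d))) {
      covered[(2L * d$start[i] + 1L):(2L * d$end[i] - 1L)] <- TRUE
    }
    r <- rle(covered)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    keep <- r$values
    if (any(keep)) {
      out[[ch]] <- data.frame(chrom = ch,
                              start = (starts_i[keep] - 1L) %/% 2L,
                              end = (ends_i[keep] + 1L) %/% 2L,
                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

oracle_heatmap_row <- function(anchor_pos, chrom, signal, flank, n_bins) {
  win <- 2L * flank
  bw <- win %/% n_bins
  depth <- numeric(win)
  for (i in seq_len(nrow(signal))) {
    if (signal$chrom[i] != chrom) next
    for (p in seq_len(win)) {
      g <- anchor_pos - flank + p - 1L  # 0-based genome position
      if (g >= signal$start[i] && g < signal$end[i]) depth[p] <- depth[p] + 1
    }
  }
  colMeans(matrix(depth, nrow = bw))
}

# all-genes scan for the nearest TSS with the deterministic tie rule
oracle_nearest_gene <- function(anchor, chrom, genes, max_ext = 50000L) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return(list(gene_id = NA_character_, distance = NA_integer_))
  g <- g[order(g$start, g$gene_id), , drop = FALSE]
  d <- ifelse(g$strand == "-", -(anchor - g$tss), anchor - g$tss)
  k <- which.min(abs(d))
  if (abs(d[k]) > max_ext) return(list(gene_id = NA_character_, distance = NA_integer_))
  list(gene_id = g$gene_id[k], distance = d[k])
}

# exact hypergeometric upper tail by direct enumeration (log factorials)
oracle_fisher_tail <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (a == 0) return(1)
  xs <- a:min(m, k)
  sum(exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)))
}

# exact binomial upper tail by direct summation
oracle_binom_tail <- function(k, n, p0) {
  if (k == 0) return(1)
  xs <- k:n
  sum(exp(lchoose(n, xs) + xs * log(p0) + (n - xs) * log1p(-p0)))
}

# random normalized peak data.frame on a toy genome
random_peak_df <- function(n, chrom_sizes, max_w = 50L, min_w = 1L) {
  ch <- sample(names(chrom_sizes), n, replace = TRUE)
  w <- sample(min_w:max_w, n, replace = TRUE)
  s <- floor(runif(n, 0, chrom_sizes[ch] - w))
  data.frame(chrom = ch, start = as.integer(s), end = as.integer(s + w),
             stringsAsFactors = FALSE)
}

toy_genes <- function(n, chrom_sizes) {
  ch <- sample(names(chrom_sizes), n, replace = TRUE)
  len <- sample(500:5000, n, replace = TRUE)
  s <- floor(runif(n, 0, pmax(1, chrom_sizes[ch] - len)))
  gene_table(data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = ch,
                        strand = sample(c("+", "-"), n, replace = TRUE),
                        start = as.integer(s), end = as.integer(s + len),
                        stringsAsFactors = FALSE))
}

motif_library_path <- function() {
  system.file("extdata", "motifs_synthetic.jaspar", package = "chipcoloc")
}
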