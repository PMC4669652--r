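#' Synthetic ChIP-seq worlds with recorded ground truth
#'
#' Generates every input the analyses consume — genome FASTA with
#' controlled GC structure, paired peak sets with an exact planted overlap
#' fraction, motif plantings at controlled rates, tag libraries with known
#' fragment length, signal fraction and duplication rate, and gene
#' annotation with a controlled TSS-proximal peak share. Every generator is
#' a pure function of its seed; the returned `truth` records are sufficient
#' to compute each downstream expectation without re-deriving it from the
#' outputs.
#'
#' @name synthetic_data
NULL

#' A blockwise GC-gradient profile across each chromosome
#'
#' @param chrom_sizes named integer vector.
#' @param from,to GC fractions at the chromosome ends.
#' @param block block size in bp.
#' @return data.frame `chrom`, `start`, `end`, `gc`.
#' @export
gc_gradient_profile <- function(chrom_sizes, from = 0.35, to = 0.65,
                                block = 10000L) {
  out <- lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    starts <- seq(0L, L - 1L, by = block)
    ends <- pmin(starts + block, L)
    mid <- (starts + ends) / 2
    data.frame(chrom = ch, start = starts, end = ends,
               gc = from + (to - from) * mid / L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate a genome of i.i.d. bases with region-specific GC targets
#'
#' @param chrom_sizes named integer vector; each chromosome >= 10 kb.
#' @param gc_profile data.frame `chrom`, `start`, `end`, `gc` of region GC
#'   targets in (0, 1); `NULL` for flat 0.5 everywhere.
#' @param seed RNG seed.
#' @return list: `genome` ([Biostrings::DNAStringSet]), `chrom_sizes`,
#'   `gc_profile`.
#' @export
generate_genome <- function(chrom_sizes, gc_profile = NULL, seed = 1L) {
  if (any(chrom_sizes < 10000L)) usage_error("each chromosome must be >= 10 kb")
  if (is.null(gc_profile)) {
    gc_profile <- data.frame(chrom = names(chrom_sizes), start = 0L,
                             end = as.integer(chrom_sizes), gc = 0.5,
                             stringsAsFactors = FALSE)
  }
  if (any(gc_profile$gc <= 0 | gc_profile$gc >= 1)) {
    usage_error("GC targets must lie strictly in (0, 1)")
  }
  base_utf8 <- utf8ToInt("ACGT")
  seqs <- with_rng(seed, {
    vapply(names(chrom_sizes), function(ch) {
      L <- chrom_sizes[[ch]]
      codes <- integer(L)
      prof <- gc_profile[gc_profile$chrom == ch, , drop = FALSE]
      if (!nrow(prof)) prof <- data.frame(chrom = ch, start = 0L, end = L, gc = 0.5)
      for (i in seq_len(nrow(prof))) {
        n <- prof$end[i] - prof$start[i]
        g <- prof$gc[i]
        p <- c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)  # A C G T
        codes[(prof$start[i] + 1L):prof$end[i]] <-
          sample.int(4L, n, replace = TRUE, prob = p)
      }
      intToUtf8(base_utf8[codes])
    }, "")
  })
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- names(chrom_sizes)
  list(genome = genome, chrom_sizes = chrom_sizes, gc_profile = gc_profile)
}

#' Generate a pair of peak sets with an exact planted overlap fraction
#'
#' `round(overlap_frac * n_B)` B-peaks are placed to overlap a distinct
#' A-peak by >= 1 bp; all remaining peaks of both sets are placed in
#' non-overlapping slots, so the realized Venn counts are exact by
#' construction: `B_shared = A_shared = common_clusters =
#' round(overlap_frac * n_B)`.
#'
#' @param n_A,n_B numbers of peaks.
#' @param overlap_frac fraction of B peaks planted to overlap A (in [0,1];
#'   requires `round(overlap_frac * n_B) <= n_A`).
#' @param chrom_sizes named integer vector.
#' @param width_sampler function(n) returning n peak widths (default:
#'   uniform 200-400 bp).
#' @param seed RNG seed.
#' @param genome_id genome identifier stamped on both sets.
#' @return list: `A`, `B` (`peak_set`s), `truth` (planted counts and pair
#'   assignments).
#' @export
generate_peak_pair <- function(n_A, n_B, overlap_frac, chrom_sizes,
                               width_sampler = NULL, seed = 1L,
                               genome_id = "synthetic") {
  if (overlap_frac < 0 || overlap_frac > 1) usage_error("overlap_frac must be in [0, 1]")
  if (is.null(width_sampler)) {
    width_sampler <- function(n) sample(200:400, n, replace = TRUE)
  }
  k <- round(overlap_frac * n_B)
  if (k > n_A) generation_error("round(overlap_frac * n_B) exceeds n_A")
  with_rng(seed, {
    w_A <- as.integer(width_sampler(n_A))
    w_B <- as.integer(width_sampler(n_B))
    max_w <- max(w_A, w_B, 1L)
    slot <- 3L * max_w
    slots_per_chr <- pmax(chrom_sizes %/% slot, 0L)
    n_slots <- sum(slots_per_chr)
    need <- n_A + (n_B - k)
    if (need > n_slots) {
      generation_error(sprintf(
        "insufficient genome space: need %d slots of %d bp, have %d",
        need, slot, n_slots))
    }
    chr_of <- rep(names(chrom_sizes), slots_per_chr)
    slot_start <- unlist(lapply(slots_per_chr,
                                function(m) (seq_len(m) - 1L) * slot),
                         use.names = FALSE)
    pick <- sample.int(n_slots, need)
    a_slots <- pick[seq_len(n_A)]
    b_free_slots <- pick[n_A + seq_len(n_B - k)]
    # A peaks in the middle third of their slots
    a_off <- floor(runif(n_A, max_w, 2L * max_w - w_A + 1))
    A <- data.frame(chrom = chr_of[a_slots],
                    start = as.integer(slot_start[a_slots] + a_off),
                    stringsAsFactors = FALSE)
    A$end <- A$start + w_A
    # overlapping B peaks: each picks a distinct A partner and is placed to
    # share >= 1 bp with it, staying inside the partner's slot
    partners <- if (k > 0L) sample.int(n_A, k) else integer(0)
    B <- data.frame(chrom = character(n_B), start = integer(n_B),
                    end = integer(n_B), stringsAsFactors = FALSE)
    if (k > 0L) {
      wb <- w_B[seq_len(k)]
      lo <- A$start[partners] - wb + 1L
      hi <- A$end[partners] - 1L
      st <- as.integer(floor(runif(k, lo, hi + 1)))
      B$chrom[seq_len(k)] <- A$chrom[partners]
      B$start[seq_len(k)] <- st
      B$end[seq_len(k)] <- st + wb
    }
    if (n_B > k) {
      idx <- (k + 1L):n_B
      wb <- w_B[idx]
      off <- floor(runif(length(idx), max_w, 2L * max_w - wb + 1))
      B$chrom[idx] <- chr_of[b_free_slots]
      B$start[idx] <- as.integer(slot_start[b_free_slots] + off)
      B$end[idx] <- B$start[idx] + wb
    }
    A$name <- sprintf("A_%04d", seq_len(n_A))
    B$name <- sprintf("B_%04d", seq_len(n_B))
    truth <- list(seed = as.integer(seed), n_A = n_A, n_B = n_B,
                  overlap_frac = overlap_frac, n_overlapping = k,
                  partner_of_B = c(partners, rep(NA_integer_, n_B - k)))
    list(A = peak_set(A, label = "setA", genome_id = genome_id),
         B = peak_set(B, label = "setB", genome_id = genome_id),
         truth = truth)
  })
}

# Place a comparison peak set against a FIXED peak set A: the first k
# widths are placed to overlap a distinct random A peak by >= 1 bp, the
# rest by rejection sampling so they overlap no A peak. Guarantees
# B_shared == k regardless of A's geometry (A may itself be clustered).
place_comparison_set <- function(A, widths, k, chrom_sizes, seed = 1L,
                                 genome_id = "synthetic") {
  n_B <- length(widths)
  if (k > nrow(A)) generation_error("k exceeds the number of anchor peaks")
  with_rng(seed, {
    B <- data.frame(chrom = character(n_B), start = integer(n_B),
                    end = integer(n_B), stringsAsFactors = FALSE)
    if (k > 0L) {
      partners <- sample.int(nrow(A), k)
      wb <- widths[seq_len(k)]
      lo <- pmax(0L, A$start[partners] - wb + 1L)
      hi <- A$end[partners] - 1L
      st <- as.integer(floor(runif(k, lo, hi + 1)))
      Lp <- as.integer(chrom_sizes[A$chrom[partners]])
      st <- pmax(0L, pmin(st, Lp - wb))
      B$chrom[seq_len(k)] <- A$chrom[partners]
      B$start[seq_len(k)] <- st
      B$end[seq_len(k)] <- st + wb
    }
    if (n_B > k) {
      a_gr <- as_granges0(A)
      todo <- (k + 1L):n_B
      tries <- 0L
      while (length(todo)) {
        tries <- tries + 1L
        if (tries > 1000L) generation_error("could not place disjoint comparison peaks")
        wb <- widths[todo]
        ci <- sample(names(chrom_sizes), length(todo), replace = TRUE,
                     prob = as.numeric(chrom_sizes))
        st <- as.integer(floor(runif(length(todo), 0, chrom_sizes[ci] - wb + 1)))
        cand <- data.frame(chrom = ci, start = st, end = st + wb,
                           stringsAsFactors = FALSE)
        ok <- GenomicRanges::countOverlaps(as_granges0(cand), a_gr) == 0L
        B$chrom[todo[ok]] <- cand$chrom[ok]
        B$start[todo[ok]] <- cand$start[ok]
        B$end[todo[ok]] <- cand$end[ok]
        todo <- todo[!ok]
      }
    }
    B$name <- sprintf("B_%04d", seq_len(n_B))
    peak_set(B, label = "setB", genome_id = genome_id)
  })
}

# sample one motif site from the PFM's per-column base frequencies
sample_site <- function(pfm) {
  probs <- sweep(pfm$counts, 2L, colSums(pfm$counts), "/")
  paste(vapply(seq_len(ncol(probs)),
               function(j) sample(DNA_BASES4, 1L, prob = probs[, j]), ""),
        collapse = "")
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

#' Plant motif sites into peak windows and background windows
#'
#' Each peak window (anchor +/- `flank`) receives, with probability
#' `rate_peak`, one site sampled from the PFM's column base frequencies,
#' written at a uniform offset on a uniform strand. Background plantings at
#' `rate_bg` go into `n_bg_windows` windows sampled uniformly from the
#' non-peak genome; those windows are returned so a null comparison can use
#' exactly them.
#'
#' @param genome_obj list with `genome` and `chrom_sizes` (as returned by
#'   [generate_genome()]).
#' @param peaks `peak_set`.
#' @param pfm a `pfm`.
#' @param rate_peak,rate_bg planting probabilities in [0, 1].
#' @param seed RNG seed.
#' @param flank half-window (default 100).
#' @param n_bg_windows number of background windows (default: one per peak).
#' @return list: `genome` (modified [Biostrings::DNAStringSet]), `truth`
#'   (`planted_peak` logical, `planted_bg` logical, `bg_windows`,
#'   `sites` data.frame of written positions).
#' @export
plant_motifs <- function(genome_obj, peaks, pfm, rate_peak, rate_bg, seed = 1L,
                         flank = 100L, n_bg_windows = NULL) {
  w <- ncol(pfm$counts)
  width <- 2L * flank + 1L
  if (w >= width) usage_error("motif width must be smaller than the window width")
  if (is.null(n_bg_windows)) n_bg_windows <- nrow(peaks)
  genome <- genome_obj$genome
  chrom_sizes <- genome_obj$chrom_sizes
  seqs <- setNames(as.character(genome), names(genome))
  with_rng(seed, {
    # background windows: uniform, non-peak, mutually non-overlapping so a
    # planted site contributes to exactly one window (as for the
    # slot-disjoint peak windows), and fully inside the genome
    pk_gr <- as_granges0(peaks)
    bg <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
    tries <- 0L
    wts <- pmax(chrom_sizes - width, 0)
    while (nrow(bg) < n_bg_windows) {
      tries <- tries + 1L
      if (tries > 1000L) generation_error("could not place non-peak background windows")
      m <- n_bg_windows - nrow(bg)
      ci <- sample(names(chrom_sizes), m, replace = TRUE, prob = wts)
      st <- as.integer(floor(runif(m, 0, chrom_sizes[ci] - width + 1)))
      cand <- data.frame(chrom = ci, start = st, end = st + width,
                         stringsAsFactors = FALSE)
      taken_gr <- if (nrow(bg)) c(pk_gr, as_granges0(bg)) else pk_gr
      cgr <- as_granges0(cand)
      ok <- GenomicRanges::countOverlaps(cgr, taken_gr) == 0L
      # also drop within-batch collisions (keep the first of each pair)
      self <- GenomicRanges::findOverlaps(cgr, cgr)
      dup <- unique(S4Vectors::queryHits(self)[S4Vectors::queryHits(self) >
                                                 S4Vectors::subjectHits(self)])
      ok[dup] <- FALSE
      bg <- rbind(bg, cand[ok, , drop = FALSE])
    }
    rownames(bg) <- NULL

    # plan all plantings first, then mutate each chromosome once
    taken <- lapply(names(chrom_sizes), function(ch) matrix(integer(), 0, 2))
    names(taken) <- names(chrom_sizes)
    plan <- list()
    plan_site <- function(kind, index, chrom, win_start) {
      site <- sample_site(pfm)
      if (runif(1) < 0.5) site <- revcomp_chr(site)
      for (try in 1:10) {  # retry offsets that collide with earlier plantings
        off <- sample.int(width - w + 1L, 1L) - 1L
        pos <- win_start + off  # 0-based
        tk <- taken[[chrom]]
        if (!nrow(tk) || all(pos + w <= tk[, 1L] | pos >= tk[, 2L])) {
          taken[[chrom]] <<- rbind(tk, c(pos, pos + w))
          plan[[length(plan) + 1L]] <<- data.frame(
            kind = kind, index = index, chrom = chrom, pos = pos,
            site = site, stringsAsFactors = FALSE)
          return(invisible(TRUE))
        }
      }
      warning("dropped one motif planting after 10 collisions")
      invisible(FALSE)
    }

    planted_peak <- runif(nrow(peaks)) < rate_peak
    for (i in which(planted_peak)) {
      ws <- peaks$anchor[i] - flank
      ws <- max(0L, min(ws, chrom_sizes[[peaks$chrom[i]]] - width))
      plan_site("peak", i, peaks$chrom[i], ws)
    }
    planted_bg <- runif(nrow(bg)) < rate_bg
    for (i in which(planted_bg)) {
      plan_site("bg", i, bg$chrom[i], bg$start[i])
    }
    sites <- if (length(plan)) do.call(rbind, plan) else NULL
    if (!is.null(sites)) {
      for (ch in unique(sites$chrom)) {
        chars <- utf8ToInt(seqs[[ch]])
        ss <- sites[sites$chrom == ch, , drop = FALSE]
        for (i in seq_len(nrow(ss))) {
          chars[(ss$pos[i] + 1L):(ss$pos[i] + w)] <- utf8ToInt(ss$site[i])
        }
        seqs[[ch]] <- intToUtf8(chars)
      }
    }
    new_genome <- Biostrings::DNAStringSet(seqs)
    names(new_genome) <- names(genome)
    list(genome = new_genome,
         truth = list(seed = as.integer(seed), rate_peak = rate_peak,
                      rate_bg = rate_bg, planted_peak = planted_peak,
                      planted_bg = planted_bg, bg_windows = bg,
                      sites = sites))
  })
}

#' Generate a tag library around peak anchors
#'
#' A `signal_frac` share of tags are fragment ends around random peak
#' anchors: + strand 5' ends at `anchor - frag_len/2`, - strand at
#' `anchor + frag_len/2`, each jittered by rounded Normal(0, `jitter_sd`)
#' noise. The remaining tags are background whose local rate varies in
#' 1 kb blocks (Gamma-distributed multipliers shared by both strands),
#' emulating the accessibility/mappability coverage biases that give real
#' libraries their positive strand cross-correlation baseline. Tags are
#' re-jittered until all pre-duplication (chrom, strand, 5' end) positions
#' are distinct, so deliberate duplication is the only source of duplicate
#' positions; every emitted tag is then duplicated with probability
#' `dup_rate` (hence `dup_rate = 0` gives PBC exactly 1).
#'
#' @param peaks `peak_set` providing the signal anchors.
#' @param chrom_sizes named integer vector.
#' @param n_tags number of (pre-duplication) tags.
#' @param signal_frac fraction of tags from peaks, in [0, 1].
#' @param frag_len fragment length (>= `read_len`).
#' @param read_len read length in bp.
#' @param dup_rate per-tag duplication probability in [0, 1].
#' @param jitter_sd standard deviation of the positional jitter (default 10).
#' @param seed RNG seed.
#' @return list: `tags` (tag table), `truth` (parameters and the realized
#'   signal-tag count).
#' @export
generate_tags <- function(peaks, chrom_sizes, n_tags = 200000L,
                          signal_frac = 0.3, frag_len = 200L, read_len = 36L,
                          dup_rate = 0.1, jitter_sd = 10, seed = 1L) {
  if (frag_len < read_len) usage_error("frag_len must be >= read_len")
  if (any(chrom_sizes <= frag_len)) generation_error("frag_len exceeds a chromosome")
  if (signal_frac < 0 || signal_frac > 1 || dup_rate < 0 || dup_rate > 1) {
    usage_error("signal_frac and dup_rate must lie in [0, 1]")
  }
  if (signal_frac > 0 && !nrow(peaks)) usage_error("signal_frac > 0 needs peaks")
  n_signal <- round(signal_frac * n_tags)
  n_bg <- n_tags - n_signal
  half <- frag_len %/% 2L
  with_rng(seed, {
    # clamp a 5' end so the full read fits on the chromosome and the
    # (start, end, strand) -> five_prime mapping stays exact
    clamp5 <- function(chrom, five, strand) {
      L <- as.integer(chrom_sizes[chrom])
      lo <- ifelse(strand == "+", 0L, read_len - 1L)
      hi <- ifelse(strand == "+", L - read_len, L - 1L)
      pmax(lo, pmin(as.integer(five), hi))
    }
    chrom <- character(0); five <- integer(0); strand <- character(0)
    if (n_signal > 0L) {
      pk <- sample.int(nrow(peaks), n_signal, replace = TRUE)
      s_str <- sample(c("+", "-"), n_signal, replace = TRUE)
      jit <- round(stats::rnorm(n_signal, 0, jitter_sd))
      f <- ifelse(s_str == "+",
                  peaks$anchor[pk] - half + jit,
                  peaks$anchor[pk] + half + jit)
      chrom <- c(chrom, peaks$chrom[pk])
      five <- c(five, clamp5(peaks$chrom[pk], f, s_str))
      strand <- c(strand, s_str)
    }
    if (n_bg > 0L) {
      # blockwise background rates shared by both strands: the
      # high-variance coverage bias (accessibility/mappability) that gives
      # real libraries their positive strand cross-correlation baseline
      block <- 1000L
      rates <- lapply(names(chrom_sizes), function(ch) {
        stats::rgamma(ceiling(chrom_sizes[[ch]] / block),
                      shape = 0.3, rate = 0.3) + 0.05
      })
      names(rates) <- names(chrom_sizes)
      chr_w <- vapply(names(chrom_sizes),
                      function(ch) sum(rates[[ch]]) * block, 0)
      ci <- sample(names(chrom_sizes), n_bg, replace = TRUE, prob = chr_w)
      f <- integer(n_bg)
      for (ch in unique(ci)) {
        idx <- which(ci == ch)
        blk <- sample.int(length(rates[[ch]]), length(idx), replace = TRUE,
                          prob = rates[[ch]])
        f[idx] <- as.integer((blk - 1L) * block +
                               floor(runif(length(idx), 0, block)))
      }
      b_str <- sample(c("+", "-"), n_bg, replace = TRUE)
      chrom <- c(chrom, ci)
      five <- c(five, clamp5(ci, f, b_str))
      strand <- c(strand, b_str)
    }
    # deliberate duplication must be the only source of duplicate
    # positions: re-jitter colliding tags (widening spread if stuck)
    sd_now <- max(jitter_sd, 1)
    for (round in 1:100) {
      key <- paste(chrom, strand, five, sep = "\r")
      dup_i <- which(duplicated(key))
      if (!length(dup_i)) break
      if (round == 100L) {
        generation_error("could not make tag 5' positions unique")
      }
      if (round %% 10L == 0L) sd_now <- sd_now * 2
      five[dup_i] <- clamp5(chrom[dup_i],
                            five[dup_i] + round(stats::rnorm(length(dup_i),
                                                             0, sd_now)),
                            strand[dup_i])
    }
    start <- ifelse(strand == "+", five, pmax(0L, five - read_len + 1L))
    start <- pmax(0L, pmin(as.integer(start),
                           as.integer(chrom_sizes[chrom]) - read_len))
    tags <- data.frame(chrom = chrom, start = as.integer(start),
                       end = as.integer(start + read_len), strand = strand,
                       stringsAsFactors = FALSE)
    dup <- runif(nrow(tags)) < dup_rate
    tags <- rbind(tags, tags[dup, , drop = FALSE])
    rownames(tags) <- NULL
    list(tags = tag_table(tags),
         truth = list(seed = as.integer(seed), n_tags = n_tags,
                      n_signal = n_signal, signal_frac = signal_frac,
                      frag_len = frag_len, read_len = read_len,
                      dup_rate = dup_rate, n_duplicated = sum(dup)))
  })
}

#' Generate gene annotation and re-anchor peaks to a TSS-proximal share
#'
#' Genes get uniform TSS positions and random strands. A
#' `tss_proximal_frac` share of the supplied peaks is re-centered within
#' +/- 500 bp of a random TSS; the remaining peaks are re-placed away from
#' every promoter (no TSS within 1.5 kb of their midpoint), so the realized
#' TSS-proximal share equals the requested one exactly.
#'
#' @param n_genes number of genes (>= 1).
#' @param chrom_sizes named integer vector.
#' @param peaks `peak_set` whose geometry is re-anchored.
#' @param tss_proximal_frac requested TSS-proximal peak share in [0, 1].
#' @param seed RNG seed.
#' @param gene_len_range gene length range in bp (default 5000-50000).
#' @return list: `genes` (gene table), `peaks` (re-anchored `peak_set`),
#'   `truth` (`proximal` logical per peak).
#' @export
generate_genes <- function(n_genes, chrom_sizes, peaks, tss_proximal_frac,
                           seed = 1L, gene_len_range = c(5000L, 50000L)) {
  if (!is_count(n_genes) || n_genes < 1) usage_error("n_genes must be >= 1")
  if (tss_proximal_frac < 0 || tss_proximal_frac > 1) {
    usage_error("tss_proximal_frac must be in [0, 1]")
  }
  with_rng(seed, {
    ci <- sample(names(chrom_sizes), n_genes, replace = TRUE,
                 prob = as.numeric(chrom_sizes))
    glen <- sample(gene_len_range[1L]:gene_len_range[2L], n_genes, replace = TRUE)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    tss <- floor(runif(n_genes, 0, chrom_sizes[ci]))
    start <- ifelse(strand == "+", tss, tss - glen + 1L)
    start <- pmax(0L, as.integer(start))
    end <- pmin(as.integer(start + glen), as.integer(chrom_sizes[ci]))
    genes <- gene_table(data.frame(
      gene_id = sprintf("gene_%03d", seq_len(n_genes)),
      chrom = ci, strand = strand, start = start, end = end,
      stringsAsFactors = FALSE))
    # NOTE: for - strand genes tss = end - 1 which may differ from the drawn
    # tss after clamping; use the realized table's tss below.
    n <- nrow(peaks)
    k <- round(tss_proximal_frac * n)
    prox <- rep(FALSE, n)
    prox[if (k > 0L) sample.int(n, k) else integer(0)] <- TRUE
    widths <- peaks$end - peaks$start
    new <- as.data.frame(peaks)
    for (i in seq_len(n)) {
      w <- widths[i]
      if (prox[i]) {
        g <- sample.int(n_genes, 1L)
        mid <- genes$tss[g] + sample(-500:500, 1L)
        ch <- genes$chrom[g]
        L <- chrom_sizes[[ch]]
        mid <- max(w %/% 2L, min(mid, L - (w - w %/% 2L)))
      } else {
        repeat {
          ch <- sample(names(chrom_sizes), 1L, prob = as.numeric(chrom_sizes))
          L <- chrom_sizes[[ch]]
          mid <- floor(runif(1, w %/% 2, L - (w - w %/% 2L)))
          tss_here <- genes$tss[genes$chrom == ch]
          if (!length(tss_here) || min(abs(tss_here - mid)) > 1500L) break
        }
      }
      new$chrom[i] <- ch
      new$start[i] <- as.integer(mid - w %/% 2L)
      new$end[i] <- new$start[i] + w
      new$summit_offset[i] <- -1L
    }
    list(genes = genes,
         peaks = peak_set(new[, c("chrom", "start", "end", "name", "score",
                                  "strand", "summit_offset")],
                          label = set_label(peaks),
                          genome_id = set_genome(peaks)),
         truth = list(seed = as.integer(seed), n_genes = n_genes,
                      tss_proximal_frac = tss_proximal_frac,
                      n_proximal = k, proximal = prox))
  })
}

#' Generate a complete desk-scale synthetic world on disk
#'
#' The default world: 3 chromosomes of 2 Mb with a GC gradient, a 1500-peak
#' "primary" set and a 1000-peak "comparison" set with 42 % of the
#' comparison peaks overlapping the primary set, 300 genes with 70 % of the
#' primary peaks TSS-proximal, one strong motif planted in 60 % of primary
#' peak windows (none in background), and a 200k-tag library with fragment
#' length 200, signal fraction 0.3 and duplication rate 0.1. All files are
#' written in the package's standard formats plus a `truth.json`.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG master seed; stage seeds are derived as small fixed
#'   offsets.
#' @param n_A,n_B,overlap_frac,n_genes,tss_proximal_frac,n_tags,frag_len,read_len,signal_frac,dup_rate,rate_peak,rate_bg
#'   world parameters (see the generator functions).
#' @param chrom_sizes named integer vector (default 3 x 2 Mb).
#' @param motif_library path to a JASPAR PFM library; the first motif is
#'   the planted one (default: the library shipped with the package).
#' @return invisibly, a list of the file paths and the truth record.
#' @export
synthetic_world <- function(dir, seed = 1L,
                            chrom_sizes = c(chr1 = 2000000L, chr2 = 2000000L,
                                            chr3 = 2000000L),
                            n_A = 1500L, n_B = 1000L, overlap_frac = 0.42,
                            n_genes = 300L, tss_proximal_frac = 0.70,
                            n_tags = 200000L, frag_len = 200L, read_len = 36L,
                            signal_frac = 0.3, dup_rate = 0.1,
                            rate_peak = 0.6, rate_bg = 0,
                            motif_library = system.file("extdata",
                                                        "motifs_synthetic.jaspar",
                                                        package = "chipcoloc")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  gen <- generate_genome(chrom_sizes, gc_gradient_profile(chrom_sizes),
                         seed = seed)
  pp <- generate_peak_pair(n_A, n_B, overlap_frac, chrom_sizes, seed = seed + 1L)
  gg <- generate_genes(n_genes, chrom_sizes, pp$A, tss_proximal_frac,
                       seed = seed + 2L)
  A <- gg$peaks
  # gene placement re-anchored A, so the comparison set is re-placed
  # relative to the final A geometry: the planted B_shared count is exact
  # by construction, and the full realized overlap structure is recorded
  # in the truth at generation time
  B <- place_comparison_set(A, pp$B$end - pp$B$start,
                            k = pp$truth$n_overlapping,
                            chrom_sizes = chrom_sizes, seed = seed + 5L,
                            genome_id = set_genome(A))
  realized_venn <- venn_counts(A, B)
  motifs <- read_jaspar(motif_library)
  pm <- plant_motifs(gen, A, motifs[[1L]], rate_peak = rate_peak,
                     rate_bg = rate_bg, seed = seed + 3L)
  tg <- generate_tags(A, chrom_sizes, n_tags = n_tags,
                      signal_frac = signal_frac, frag_len = frag_len,
                      read_len = read_len, dup_rate = dup_rate,
                      seed = seed + 4L)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    chrom_sizes = file.path(dir, "genome.chrom.sizes"),
    peaks_A = file.path(dir, "peaks_primary.narrowPeak"),
    peaks_B = file.path(dir, "peaks_comparison.narrowPeak"),
    genes = file.path(dir, "genes.bed"),
    tags = file.path(dir, "tags.tagAlign"),
    motifs = file.path(dir, "motifs.jaspar"),
    truth = file.path(dir, "truth.json"))
  write_genome_fasta(pm$genome, paths$genome)
  write_chrom_sizes(chrom_sizes, paths$chrom_sizes)
  write_peaks(A, paths$peaks_A)
  write_peaks(B, paths$peaks_B)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", gg$genes$chrom, gg$genes$start,
                     gg$genes$end, gg$genes$gene_id, gg$genes$strand),
             paths$genes)
  write_tagalign(tg$tags, paths$tags)
  file.copy(motif_library, paths$motifs, overwrite = TRUE)
  truth <- list(seed = seed, chrom_sizes = as.list(chrom_sizes),
                peak_pair = pp$truth[c("n_A", "n_B", "overlap_frac",
                                       "n_overlapping")],
                venn = unclass(realized_venn),
                genes = gg$truth[c("n_genes", "tss_proximal_frac", "n_proximal")],
                motifs = list(planted_id = motifs[[1L]]$motif_id,
                              rate_peak = rate_peak, rate_bg = rate_bg,
                              n_planted = sum(pm$truth$planted_peak)),
                tags = tg$truth[c("n_tags", "n_signal", "signal_frac",
                                  "frag_len", "read_len", "dup_rate")])
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(paths = paths, truth = truth,
                 objects = list(A = A, B = B, genes = gg$genes,
                                genome = pm$genome, tags = tg$tags,
                                gene_truth = gg$truth,
                                motif_truth = pm$truth,
                                tag_truth = tg$truth)))
}
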