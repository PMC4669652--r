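#' File formats: BED/narrowPeak peaks, gene BED, JASPAR PFM, tagAlign, FASTA
#'
#' All coordinates inside the package are 0-based half-open (BED native).
#' Gene annotation is accepted as stranded BED6 ("gene BED"): the TSS is
#' `start` on the + strand and `end - 1` on the - strand. Parsers validate
#' strictly and name the offending line; nothing is silently coerced.
#'
#' @name formats
NULL

.BED_NCOLS <- c(bed3 = 3L, bed6 = 6L, narrowPeak = 10L)

#' Parse one BED/narrowPeak line into a peak record
#'
#' @param line a single tab-separated text line.
#' @param dialect one of `"bed3"`, `"bed6"`, `"narrowPeak"`.
#' @param line_number line number used in error messages.
#' @return a one-row data.frame with columns `chrom`, `start`, `end`,
#'   `name`, `score`, `strand`, `summit_offset` (`-1` = summit unknown,
#'   also used for dialects that carry no summit).
#' @export
parse_bed_line <- function(line, dialect = c("narrowPeak", "bed6", "bed3"),
                           line_number = 1L) {
  dialect <- match.arg(dialect)
  fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  need <- .BED_NCOLS[[dialect]]
  if (length(fields) < need) {
    format_error(sprintf("expected >= %d tab-separated columns for %s, got %d",
                         need, dialect, length(fields)), line_number)
  }
  start <- suppressWarnings(as.integer(fields[2L]))
  end <- suppressWarnings(as.integer(fields[3L]))
  if (is.na(start) || is.na(end)) {
    format_error("non-integer coordinates", line_number)
  }
  if (start < 0) format_error("negative start coordinate", line_number)
  if (start >= end) {
    format_error(sprintf("start (%d) must be < end (%d)", start, end), line_number)
  }
  name <- if (length(fields) >= 4L) fields[4L] else sprintf("peak_%d", line_number)
  score <- if (length(fields) >= 5L) suppressWarnings(as.numeric(fields[5L])) else 0
  if (is.na(score)) format_error("non-numeric score", line_number)
  strand <- if (length(fields) >= 6L) fields[6L] else "."
  summit_offset <- -1L
  if (dialect == "narrowPeak") {
    summit_offset <- suppressWarnings(as.integer(fields[10L]))
    if (is.na(summit_offset) || summit_offset < -1L) {
      format_error("narrowPeak summit offset must be an integer >= -1", line_number)
    }
    if (summit_offset >= end - start) {
      format_error("summit offset outside peak", line_number)
    }
  }
  data.frame(chrom = fields[1L], start = start, end = end, name = name,
             score = score, strand = strand, summit_offset = summit_offset,
             stringsAsFactors = FALSE)
}

#' Read a peak file into a peak set
#'
#' @param path BED3/BED6/narrowPeak file.
#' @inheritParams parse_bed_line
#' @param label label for the peak set (defaults to the file name).
#' @param genome_id genome identifier carried for compatibility checks.
#' @return a `peak_set` (see [peak_set()]).
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "bed6", "bed3"),
                       label = basename(path), genome_id = "unspecified") {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  rows <- lapply(idx, function(i) parse_bed_line(lines[i], dialect, i))
  peaks <- if (length(rows)) do.call(rbind, rows) else
    parse_bed_line("chr\t0\t1", "bed3")[0L, ]
  peak_set(peaks, label = label, genome_id = genome_id)
}

#' Write a peak set to BED/narrowPeak
#'
#' Round-trips coordinates and summit offsets byte-for-byte with
#' [read_peaks()] for every dialect.
#'
#' @param peaks a `peak_set` or compatible data.frame.
#' @param path output path.
#' @inheritParams parse_bed_line
#' @export
write_peaks <- function(peaks, path, dialect = c("narrowPeak", "bed6", "bed3")) {
  dialect <- match.arg(dialect)
  score_chr <- ifelse(peaks$score == floor(peaks$score),
                      sprintf("%d", as.integer(peaks$score)),
                      format(peaks$score, trim = TRUE))
  lines <- switch(dialect,
    bed3 = sprintf("%s\t%d\t%d", peaks$chrom, peaks$start, peaks$end),
    bed6 = sprintf("%s\t%d\t%d\t%s\t%s\t%s", peaks$chrom, peaks$start,
                   peaks$end, peaks$name, score_chr, peaks$strand),
    narrowPeak = sprintf("%s\t%d\t%d\t%s\t%s\t%s\t0\t-1\t-1\t%d",
                         peaks$chrom, peaks$start, peaks$end, peaks$name,
                         score_chr, peaks$strand, peaks$summit_offset)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotation as stranded BED6
#'
#' @param path gene BED file: chrom, start, end, gene_id, score, strand.
#' @return data.frame with `gene_id`, `chrom`, `strand`, `start`, `end`
#'   and the derived `tss` (start for `+`, end - 1 for `-`).
#' @export
read_genes_bed <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^(#|track|browser)", lines) & nzchar(lines))
  rows <- lapply(keep, function(i) {
    f <- parse_bed_line(lines[i], "bed6", i)
    if (!f$strand %in% c("+", "-")) {
      format_error(sprintf("gene strand must be + or -, got '%s'", f$strand), i)
    }
    f
  })
  df <- do.call(rbind, rows)
  gene_table(data.frame(gene_id = df$name, chrom = df$chrom, strand = df$strand,
                        start = df$start, end = df$end, stringsAsFactors = FALSE))
}

#' Construct/validate a gene table with derived TSS
#'
#' @param genes data.frame with `gene_id`, `chrom`, `strand` (+/-),
#'   `start`, `end` (0-based half-open).
#' @return the validated data.frame with a `tss` column added.
#' @export
gene_table <- function(genes) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)))
  if (any(genes$start >= genes$end)) usage_error("gene start must be < end")
  if (!all(genes$strand %in% c("+", "-"))) usage_error("gene strand must be + or -")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  class(genes) <- c("gene_table", "data.frame")
  genes
}

#' Parse a JASPAR-format PFM record
#'
#' A record is a `>ID NAME` header followed by four labelled count rows
#' (A, C, G, T), e.g. `A [ 4 19 0 ]`. Bare space-separated rows without the
#' base label and brackets are also accepted.
#'
#' @param text_block character vector of the record's lines, or a single
#'   string with embedded newlines.
#' @return a `pfm`: list with `motif_id`, `name`, and `counts`
#'   (4 x w integer matrix, rows A/C/G/T).
#' @export
parse_jaspar_pfm <- function(text_block) {
  lines <- unlist(strsplit(text_block, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !startsWith(lines[1L], ">")) {
    format_error("JASPAR record must start with a '>' header")
  }
  header <- sub("^>\\s*", "", lines[1L])
  parts <- strsplit(header, "\\s+")[[1L]]
  motif_id <- parts[1L]
  name <- if (length(parts) > 1L) paste(parts[-1L], collapse = " ") else motif_id
  body <- lines[-1L]
  if (length(body) != 4L) {
    format_error(sprintf("motif '%s': expected 4 base rows, got %d",
                         motif_id, length(body)))
  }
  rows <- vector("list", 4L)
  labels <- character(4L)
  for (i in seq_len(4L)) {
    ln <- body[i]
    m <- regmatches(ln, regexec("^([A-Za-z])\\s*\\[?\\s*([-0-9. \t]*?)\\s*\\]?$", ln))[[1L]]
    if (length(m) == 3L && m[2] != "") {
      labels[i] <- toupper(m[2L])
      numtxt <- m[3L]
    } else {
      labels[i] <- DNA_BASES4[i]
      numtxt <- ln
    }
    vals <- suppressWarnings(as.numeric(strsplit(trimws(numtxt), "\\s+")[[1L]]))
    if (!length(vals) || anyNA(vals)) {
      format_error(sprintf("motif '%s': unparseable count row %d", motif_id, i))
    }
    rows[[i]] <- vals
  }
  if (!setequal(labels, DNA_BASES4)) {
    format_error(sprintf("motif '%s': base rows must be labelled A, C, G, T (got %s)",
                         motif_id, paste(labels, collapse = ",")))
  }
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    format_error(sprintf("motif '%s': unequal row lengths (%s)", motif_id,
                         paste(widths, collapse = ",")))
  }
  counts <- do.call(rbind, rows[match(DNA_BASES4, labels)])
  rownames(counts) <- DNA_BASES4
  if (any(counts < 0)) format_error(sprintf("motif '%s': negative counts", motif_id))
  if (any(colSums(counts) == 0)) {
    format_error(sprintf("motif '%s': all-zero column", motif_id))
  }
  structure(list(motif_id = motif_id, name = name, counts = counts),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("PFM %s (%s), width %d, consensus %s\n",
              x$motif_id, x$name, ncol(x$counts), pfm_consensus(x)))
  invisible(x)
}

#' Majority-base consensus of a PFM
#' @param pfm a `pfm`.
#' @export
pfm_consensus <- function(pfm) {
  paste(DNA_BASES4[apply(pfm$counts, 2L, which.max)], collapse = "")
}

#' Read a concatenated JASPAR PFM library file
#'
#' @param path text file of concatenated JASPAR records.
#' @return named list of `pfm` objects (names = motif ids).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- which(startsWith(lines, ">"))
  if (!length(starts)) format_error("no JASPAR records found")
  ends <- c(starts[-1L] - 1L, length(lines))
  motifs <- lapply(seq_along(starts),
                   function(i) parse_jaspar_pfm(lines[starts[i]:ends[i]]))
  names(motifs) <- vapply(motifs, `[[`, "", "motif_id")
  motifs
}

#' Write a PFM library in JASPAR text format
#' @param motifs list of `pfm` objects.
#' @param path output path.
#' @export
write_jaspar <- function(motifs, path) {
  lines <- unlist(lapply(motifs, function(m) {
    c(sprintf(">%s %s", m$motif_id, m$name),
      vapply(seq_len(4L), function(i) {
        sprintf("%s [ %s ]", DNA_BASES4[i],
                paste(format(m$counts[i, ], trim = TRUE), collapse = " "))
      }, ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read aligned tags from a tagAlign (6-column BED) file
#'
#' The 5' end of a tag is `start` on the + strand and `end - 1` on the -
#' strand (half-open convention).
#'
#' @param path tagAlign file.
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `five_prime`.
#' @export
read_tagalign <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^(#|track|browser)", lines) & nzchar(lines))
  rows <- lapply(keep, function(i) {
    f <- parse_bed_line(lines[i], "bed6", i)
    if (!f$strand %in% c("+", "-")) {
      format_error(sprintf("tag strand must be + or -, got '%s'", f$strand), i)
    }
    f
  })
  df <- do.call(rbind, rows)
  tag_table(data.frame(chrom = df$chrom, start = df$start, end = df$end,
                       strand = df$strand, stringsAsFactors = FALSE))
}

#' Construct/validate a tag table with derived 5' ends
#' @param tags data.frame with `chrom`, `start`, `end`, `strand`.
#' @export
tag_table <- function(tags) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(tags)))
  if (any(tags$start >= tags$end)) usage_error("tag start must be < end")
  if (!all(tags$strand %in% c("+", "-"))) usage_error("tag strand must be + or -")
  tags$five_prime <- ifelse(tags$strand == "+", tags$start, tags$end - 1L)
  tags
}

#' Write tags to tagAlign format
#' @param tags tag table.
#' @param path output path.
#' @export
write_tagalign <- function(tags, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", tags$chrom, tags$start,
                     tags$end, sprintf("t%d", seq_len(nrow(tags))), tags$strand),
             path)
  invisible(path)
}

#' Read a chromosome-sizes table ("chrom\\tlength")
#' @param path two-column TSV.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "integer"))
  if (any(df$length <= 0)) format_error("chromosome lengths must be positive")
  setNames(df$length, df$chrom)
}

#' Write a chromosome-sizes table
#' @param sizes named integer vector.
#' @param path output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)), path)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a genome FASTA
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Export binned coverage as fixed-step bedGraph
#'
#' @param binned data.frame with `chrom`, `start`, `end`, `value`
#'   (0-based half-open bins).
#' @param path output path.
#' @param name track name.
#' @export
write_bedgraph <- function(binned, path, name = "coverage") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  writeLines(sprintf("%s\t%d\t%d\t%g", binned$chrom, binned$start,
                     binned$end, binned$value), con)
  invisible(path)
}
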