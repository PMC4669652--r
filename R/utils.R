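#' @importFrom stats cor p.adjust pbinom phyper rbinom runif setNames
#' @importFrom utils read.table write.table
NULL

# Error helpers: every user-facing failure is classified so the analysis
# scripts can distinguish malformed inputs from misuse of the API.
format_error <- function(msg, line_number = NULL) {
  if (!is.null(line_number)) msg <- sprintf("line %d: %s", line_number, msg)
  stop(errorCondition(msg, class = c("chipcoloc_format_error", "chipcoloc_error")))
}

usage_error <- function(msg) {
  stop(errorCondition(msg, class = c("chipcoloc_usage_error", "chipcoloc_error")))
}

sampling_error <- function(msg) {
  stop(errorCondition(msg, class = c("chipcoloc_sampling_error", "chipcoloc_error")))
}

generation_error <- function(msg) {
  stop(errorCondition(msg, class = c("chipcoloc_generation_error", "chipcoloc_error")))
}

#' Evaluate an expression under an isolated, explicitly seeded RNG
#'
#' All stochastic operations in the package route their randomness through
#' this helper: Mersenne-Twister with inversion normals and rejection
#' sampling, seeded explicitly, with the caller's RNG state restored on exit.
#' No function touches the global RNG stream implicitly.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_rng <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    usage_error("seed must be a single integer")
  }
  withr::with_seed(as.integer(seed), expr,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

# DNA <-> integer codes. A,C,G,T -> 1..4; anything else (N and friends) -> 5.
DNA_BASES4 <- c("A", "C", "G", "T")

encode_dna <- function(seq) {
  codes <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]], DNA_BASES4)
  codes[is.na(codes)] <- 5L
  codes
}

revcomp_codes <- function(codes) {
  comp <- c(4L, 3L, 2L, 1L, 5L)
  rev(comp[codes])
}

# Convert the package's 0-based half-open intervals to a GRanges
# (1-based closed) for overlap machinery. `df` needs chrom/start/end.
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}
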