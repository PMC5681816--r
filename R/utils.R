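#' @useDynLib refguide, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom rlang %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join inner_join n row_number desc across all_of
#' @importFrom stats rnorm runif rbinom median sd setNames
#' @importFrom utils head tail
NULL

# canonical alphabet used throughout the pipeline
.ALPHABET <- c("A", "C", "G", "T", "N")

#' Normalize a nucleotide sequence to the ACGTN alphabet
#'
#' Uppercases and collapses IUPAC ambiguity codes (and anything else outside
#' ACGT) to N.
#'
#' @param x character vector of sequences
#' @return character vector over A, C, G, T, N
#' @export
normalize_seq <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

#' Reverse complement
#'
#' @param x character vector of ACGTN sequences
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  cpp_revcomp(as.character(x))
}

#' Decode phred+33 quality strings to integer scores
#'
#' @param qual character vector of phred+33 encoded quality strings
#' @return list of integer vectors
#' @export
qual_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Encode integer phred scores as a phred+33 string
#'
#' @param q integer vector of phred scores
#' @return single quality string
#' @export
int_to_qual <- function(q) {
  intToUtf8(pmin(q, 93L) + 33L)
}

#' Construct a sequence table
#'
#' The package-wide container for named sequences: a tibble with columns
#' `id`, `seq` and `desc`.
#'
#' @param id character vector of unique, non-empty identifiers
#' @param seq character vector of sequences (normalized to ACGTN)
#' @param desc optional description strings
#' @return a tibble with class-invariant columns `id`, `seq`, `desc`
#' @export
seq_tbl <- function(id, seq, desc = NA_character_) {
  stopifnot(length(id) == length(seq))
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  if (anyDuplicated(id)) stop("sequence ids must be unique")
  seq <- normalize_seq(seq)
  if (any(nchar(seq) < 1)) stop("sequences must have length >= 1")
  tibble::tibble(id = as.character(id), seq = seq,
                 desc = rep_len(as.character(desc), length(id)))
}

# total length helper
seq_total_len <- function(seqs) sum(nchar(seqs$seq))

# reference-consumed length of CIGAR strings (M + D)
cigar_ref_len <- function(cigar) cpp_cigar_ref_len(as.character(cigar))

# read-consumed length of CIGAR strings (M + I + S)
cigar_read_len <- function(cigar) cpp_cigar_read_len(as.character(cigar))

# convert 0-based half-open intervals to IRanges (1-based closed)
to_iranges <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# run a function under a fixed seed without disturbing the caller's RNG;
# seed = NULL uses the current RNG stream
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# deterministic per-stage seed fan-out from one master seed
stage_seed <- function(seed, stage) {
  (seed * 97L + stage * 1009L) %% .Machine$integer.max
}
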