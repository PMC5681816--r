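# Minimal seed-and-extend read mapper: k-mer index, banded gapped extension,
# mapping quality from best-versus-second score margin, and proper-pair
# flagging against a library insert model. External SAM import
# (read_sam()) is an equivalent entry point for all downstream steps.

#' Build a k-mer index over a set of reference sequences
#'
#' Indexes every non-N k-mer of both strands.
#'
#' @param reference a [seq_tbl()]
#' @param k odd k-mer length between 9 and 31
#' @return an object of class `kmer_index`
#' @export
build_index <- function(reference, k = 15L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  if (k < 9L || k > 31L) stop("k must be between 9 and 31")
  seqs <- setNames(reference$seq, reference$id)
  ptr <- cpp_build_index(seqs, k)
  st <- cpp_index_stats(ptr)
  structure(list(ptr = ptr, k = k, ref_ids = reference$id,
                 ref_len = setNames(nchar(reference$seq), reference$id),
                 n_fwd = st$n_fwd, n_rev = st$n_rev,
                 n_distinct = st$n_distinct),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("k-mer index: k =", x$k, "|", length(x$ref_ids), "sequence(s) |",
      x$n_fwd, "forward positions\n")
  invisible(x)
}

#' Look up k-mer occurrences in an index
#'
#' @param index a `kmer_index`
#' @param kmers character vector of k-mers
#' @return tibble of hits: `kmer` (query index), `ref_id`, `pos` (0-based),
#'   `strand`
#' @export
index_lookup <- function(index, kmers) {
  df <- cpp_index_lookup(index$ptr, kmers)
  tibble::tibble(kmer = df$kmer, ref_id = index$ref_ids[df$ref],
                 pos = df$pos, strand = ifelse(df$rev == 1, "-", "+"))
}

#' Map reads against a reference
#'
#' Seed-and-extend alignment: k-mer seeds vote for candidate loci, each
#' candidate is scored by banded gapped extension (match +2, mismatch -3,
#' gap open -5, gap extend -2). `"local"` mode allows soft-clipped ends;
#' `"sensitive"` mode aligns the read end to end. Alignments scoring below
#' `20 + 8 ln(read length)` are reported unmapped. Mapping quality is
#' `min(60, 6 * (best - second best))`, and 0 when two loci tie. Only the
#' best alignment per read is reported.
#'
#' @param reads read tibble
#' @param reference a [seq_tbl()] or a prebuilt `kmer_index`
#' @param mode `"local"` or `"sensitive"`
#' @param k seed length when `reference` is not already an index
#' @return alignment tibble; one row per input read, unmapped rows flagged
#' @export
map_reads <- function(reads, reference, mode = c("local", "sensitive"),
                      k = 15L) {
  mode <- match.arg(mode)
  idx <- if (inherits(reference, "kmer_index")) reference
         else build_index(reference, k)
  if (nrow(reads) == 0) return(empty_alignments())
  df <- cpp_map_reads(idx$ptr, reads$seq, mode_local = (mode == "local"))
  tibble::tibble(
    read_id = reads$read_id,
    mate = reads$mate,
    ref_id = ifelse(df$unmapped, NA_character_, idx$ref_ids[df$ref]),
    pos = df$pos,
    strand = ifelse(df$unmapped, NA_character_, ifelse(df$rev, "-", "+")),
    cigar = df$cigar,
    mapq = df$mapq,
    score = df$score,
    paired = FALSE, proper_pair = FALSE,
    unmapped = df$unmapped,
    mate_unmapped = NA,
    mate_ref_id = NA_character_, mate_pos = NA_integer_,
    library_id = if ("library_id" %in% names(reads)) reads$library_id
                 else NA_character_,
    seq = reads$seq, qual = reads$qual)
}

#' Align a single read
#'
#' @param read one-row read tibble
#' @param index a `kmer_index`
#' @param mode `"local"` or `"sensitive"`
#' @return one-row alignment tibble
#' @export
align_read <- function(read, index, mode = c("local", "sensitive")) {
  map_reads(read, index, mode)
}

#' Flag proper pairs against a library insert model
#'
#' A pair is proper when both mates map to the same reference in the
#' library's expected orientation (FR for paired-end, RF for mate-pair) with
#' an observed insert inside `mean +/- 4 sd` (lower bound floored at 2).
#' Also fills the mate fields (`mate_ref_id`, `mate_pos`, `mate_unmapped`).
#'
#' @param alignments alignment tibble carrying `library_id`
#' @param libraries library tibble ([library_spec()] rows)
#' @return the alignment tibble with pairing flags set
#' @export
pair_and_flag <- function(alignments, libraries) {
  a <- alignments
  a$paired <- TRUE
  a$proper_pair <- FALSE
  # join mate info
  key <- paste(a$read_id, a$mate)
  other <- paste(a$read_id, ifelse(a$mate == 1L, 2L, 1L))
  midx <- match(other, key)
  has_mate <- !is.na(midx)
  a$mate_unmapped[has_mate] <- a$unmapped[midx[has_mate]]
  a$mate_unmapped[!has_mate] <- NA
  a$mate_ref_id[has_mate] <- a$ref_id[midx[has_mate]]
  a$mate_pos[has_mate] <- a$pos[midx[has_mate]]
  lib <- libraries[match(a$library_id, libraries$library_id), ]
  both_mapped <- has_mate & !a$unmapped & !is.na(a$mate_unmapped) &
    !a$mate_unmapped & !is.na(lib$library_id)
  if (any(both_mapped)) {
    i <- which(both_mapped)
    j <- midx[i]
    same_ref <- a$ref_id[i] == a$ref_id[j]
    span_i <- a$pos[i] + cigar_ref_len(a$cigar[i])
    span_j <- a$pos[j] + cigar_ref_len(a$cigar[j])
    left_first <- a$pos[i] <= a$pos[j]
    ins <- ifelse(left_first, pmax(span_i, span_j) - a$pos[i],
                  pmax(span_i, span_j) - a$pos[j])
    lo <- pmax(2, lib$insert_mean[i] - 4 * lib$insert_sd[i])
    hi <- lib$insert_mean[i] + 4 * lib$insert_sd[i]
    left_strand <- ifelse(left_first, a$strand[i], a$strand[j])
    right_strand <- ifelse(left_first, a$strand[j], a$strand[i])
    expected_left <- ifelse(lib$kind[i] == "PE", "+", "-")
    expected_right <- ifelse(lib$kind[i] == "PE", "-", "+")
    ok <- same_ref & left_strand == expected_left &
      right_strand == expected_right & ins >= lo & ins <= hi
    a$proper_pair[i] <- ok
  }
  a
}

#' Mapper validation against simulator truth placements
#'
#' Fraction of mapped reads placed at their true coordinates (same reference,
#' same strand, start within `tol` bp).
#'
#' @param alignments alignment tibble
#' @param truth truth tibble from [simulate_reads()]
#' @param tol placement tolerance in bp
#' @return list with `n_mapped`, `n_correct`, `recovery`
#' @export
placement_recovery <- function(alignments, truth, tol = 3L) {
  a <- alignments[!alignments$unmapped, ]
  t <- truth
  m <- dplyr::inner_join(a, t, by = c("read_id", "mate"),
                         suffix = c("", ".truth"))
  ok <- m$ref_id == m$ref_id.truth & m$strand == m$strand.truth &
    abs(m$pos - m$start) <= tol
  list(n_mapped = nrow(a), n_correct = sum(ok),
       recovery = if (nrow(a) == 0) NA_real_ else sum(ok) / nrow(a))
}
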