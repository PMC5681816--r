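# Step 1: quality trimming with Trimmomatic-equivalent rules
# (LEADING/TRAILING 3, SLIDINGWINDOW 4:15, MINLEN 40).

#' Trimming parameters
#'
#' @param lead_trail_q phred threshold for leading/trailing base removal
#' @param window_len sliding window length (bp)
#' @param window_q minimum mean phred quality within the window
#' @param min_len reads trimmed below this length are discarded
#' @return parameter list
#' @export
trim_params <- function(lead_trail_q = 3L, window_len = 4L, window_q = 15,
                        min_len = 40L) {
  stopifnot(lead_trail_q >= 0, window_len >= 0, window_q >= 0, min_len >= 0)
  list(lead_trail_q = as.integer(lead_trail_q),
       window_len = as.integer(window_len),
       window_q = window_q, min_len = as.integer(min_len))
}

#' Quality-trim reads
#'
#' Leading then trailing bases below `lead_trail_q` are removed; the remaining
#' read is scanned left to right with a sliding window and cut at the first
#' base of the first window whose mean quality falls below `window_q`; results
#' shorter than `min_len` are discarded. The output read is always a
#' contiguous substring of the input.
#'
#' @param reads read tibble (`read_id`, `mate`, `seq`, `qual`, ...)
#' @param params a [trim_params()] list
#' @return trimmed read tibble (discarded reads removed), with attribute
#'   `n_discarded`
#' @export
trim_reads <- function(reads, params = trim_params()) {
  if (nrow(reads) == 0) {
    attr(reads, "n_discarded") <- 0L
    return(reads)
  }
  b <- cpp_trim_bounds(reads$qual, params$lead_trail_q, params$window_len,
                       params$window_q)
  len <- b[, 2] - b[, 1]
  keep <- len >= params$min_len & len > 0
  out <- reads[keep, , drop = FALSE]
  out$seq <- substr(out$seq, b[keep, 1] + 1L, b[keep, 2])
  out$qual <- substr(out$qual, b[keep, 1] + 1L, b[keep, 2])
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Trim a single read
#'
#' @param read one-row read tibble
#' @param params a [trim_params()] list
#' @return the trimmed one-row tibble, or `NULL` when discarded
#' @export
trim_read <- function(read, params = trim_params()) {
  out <- trim_reads(read, params)
  if (nrow(out) == 0) NULL else out
}

#' Quality-trim read pairs with pairing bookkeeping
#'
#' Pairs both mates of each read id through [trim_reads()]; when only one
#' mate survives, the survivor becomes an orphan. Unpaired input ids are
#' treated as orphans with a warning.
#'
#' @param reads read tibble containing mates 1 and 2
#' @param params a [trim_params()] list
#' @return list with `pairs` (reads whose both mates survive), `orphans`
#'   (single surviving mates) and `stats` (input/retained/orphan/discarded
#'   counts)
#' @export
trim_pairs <- function(reads, params = trim_params()) {
  counts <- table(reads$read_id)
  unpaired_ids <- names(counts)[counts != 2]
  if (length(unpaired_ids) > 0) {
    warning(length(unpaired_ids), " read id(s) without both mates; treated as orphans")
  }
  trimmed <- trim_reads(reads, params)
  surv <- table(trimmed$read_id)
  pair_ids <- names(surv)[surv == 2 & !(names(surv) %in% unpaired_ids)]
  pairs <- trimmed[trimmed$read_id %in% pair_ids, , drop = FALSE]
  orphans <- trimmed[!(trimmed$read_id %in% pair_ids), , drop = FALSE]
  stats <- list(n_input = nrow(reads),
                n_retained_pairs = length(pair_ids),
                n_orphans = nrow(orphans),
                n_discarded = nrow(reads) - nrow(trimmed))
  list(pairs = pairs, orphans = orphans, stats = stats)
}

#' Per-library read summary statistics
#'
#' A compact QC report: read counts, mean length and mean base quality per
#' library.
#'
#' @param reads read tibble
#' @return tibble with one row per library
#' @export
read_summary <- function(reads) {
  reads |>
    dplyr::mutate(len = nchar(.data$seq),
                  mean_q = vapply(.data$qual,
                                  function(q) mean(utf8ToInt(q)) - 33, 0)) |>
    dplyr::group_by(.data$library_id) |>
    dplyr::summarise(n_reads = dplyr::n(), mean_len = mean(.data$len),
                     min_len = min(.data$len), max_len = max(.data$len),
                     mean_qual = mean(.data$mean_q), .groups = "drop")
}
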