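# Step 2 core: continuous-coverage blocks, proper-pair bridging, overlapping
# superblock construction and read partitioning.

#' Superblock construction parameters
#'
#' @param min_len target minimum superblock length (bp)
#' @param min_overlap minimum overlap between consecutive superblocks (bp)
#' @param max_len maximum superblock length (bp)
#' @param bridge_pairs proper pairs required to bridge two adjacent blocks
#' @return parameter list
#' @export
superblock_params <- function(min_len = 12000L, min_overlap = 300L,
                              max_len = 100000L, bridge_pairs = 10L) {
  if (!(min_overlap < min_len && min_len <= max_len)) {
    stop("require min_overlap < min_len <= max_len")
  }
  list(min_len = as.integer(min_len), min_overlap = as.integer(min_overlap),
       max_len = as.integer(max_len), bridge_pairs = as.integer(bridge_pairs))
}

# aligned reference spans of mapped alignment rows (0-based half-open)
alignment_spans <- function(alignments) {
  a <- alignments[!alignments$unmapped & !is.na(alignments$pos), , drop = FALSE]
  tibble::tibble(read_id = a$read_id, mate = a$mate, ref_id = a$ref_id,
                 start = a$pos, end = a$pos + cigar_ref_len(a$cigar),
                 proper_pair = a$proper_pair)
}

#' Call continuous-coverage blocks from alignments
#'
#' A block is a maximal reference interval in which every base is covered by
#' at least one mapped alignment. Depth is computed from primary alignments
#' regardless of mapping quality.
#'
#' @param alignments alignment tibble
#' @return block tibble: `ref_id`, `start`, `end`, `n_reads`, sorted by
#'   reference and start
#' @export
call_blocks <- function(alignments) {
  sp <- alignment_spans(alignments)
  if (nrow(sp) == 0) {
    return(tibble::tibble(ref_id = character(), start = integer(),
                          end = integer(), n_reads = integer()))
  }
  out <- lapply(split(sp, sp$ref_id), function(s) {
    ir <- to_iranges(s$start, s$end)
    red <- IRanges::reduce(ir)
    hits <- IRanges::countOverlaps(red, ir)
    tibble::tibble(ref_id = s$ref_id[1],
                   start = IRanges::start(red) - 1L,
                   end = IRanges::end(red),
                   n_reads = hits)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$ref_id, .data$start)
}

# block index of every aligned span (NA when between blocks; cannot happen
# for spans used to build the blocks)
span_block <- function(spans, blocks) {
  idx <- rep(NA_integer_, nrow(spans))
  for (r in unique(spans$ref_id)) {
    si <- which(spans$ref_id == r)
    bi <- which(blocks$ref_id == r)
    if (length(bi) == 0) next
    ov <- IRanges::findOverlaps(to_iranges(spans$start[si], spans$end[si]),
                                to_iranges(blocks$start[bi], blocks$end[bi]),
                                select = "first")
    idx[si] <- bi[ov]
  }
  idx
}

#' Bridge adjacent blocks spanned by proper pairs
#'
#' Two adjacent blocks (and the gap between them) are merged when at least
#' `bridge_pairs` proper pairs have one mate in each; merging is transitive
#' left to right.
#'
#' @param blocks block tibble from [call_blocks()]
#' @param alignments alignment tibble with proper-pair flags
#'   (see [pair_and_flag()])
#' @param params a [superblock_params()] list
#' @return merged block tibble
#' @export
bridge_blocks <- function(blocks, alignments, params = superblock_params()) {
  if (nrow(blocks) <= 1) return(blocks)
  sp <- alignment_spans(alignments)
  sp <- sp[sp$proper_pair, , drop = FALSE]
  sp$block <- if (nrow(sp)) span_block(sp, blocks) else integer(0)
  # per proper pair, the two block indices of its mates
  pb <- if (nrow(sp) == 0) {
    tibble::tibble(read_id = character(), b1 = integer(), b2 = integer())
  } else {
    sp |>
      dplyr::filter(!is.na(.data$block)) |>
      dplyr::group_by(.data$read_id) |>
      dplyr::summarise(b1 = min(.data$block), b2 = max(.data$block),
                       .groups = "drop")
  }
  pb <- dplyr::filter(pb, .data$b2 == .data$b1 + 1L)
  bridge_n <- table(factor(pb$b1, levels = seq_len(nrow(blocks) - 1L)))
  adjacent <- blocks$ref_id[-nrow(blocks)] == blocks$ref_id[-1]
  merged_with_next <- adjacent & as.vector(bridge_n) >= params$bridge_pairs
  grp <- cumsum(c(TRUE, !merged_with_next))
  blocks |>
    dplyr::mutate(grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(ref_id = .data$ref_id[1], start = min(.data$start),
                     end = max(.data$end), n_reads = sum(.data$n_reads),
                     .groups = "drop") |>
    dplyr::select(-dplyr::any_of("grp")) |>
    dplyr::arrange(.data$ref_id, .data$start)
}

#' Combine blocks into overlapping superblocks
#'
#' Greedy left-to-right accumulation of consecutive blocks until the span
#' reaches `min_len`; the next superblock starts at the last block of the
#' previous one so that neighbours share at least one block, extending the
#' shared region leftwards block by block until the overlap reaches
#' `min_overlap`. Superblocks exceeding `max_len` are split into pieces of at
#' most `max_len` with exactly `min_overlap` bp overlap. The final superblock
#' on each reference may be shorter than `min_len` and is flagged `terminal`.
#'
#' @param blocks bridged block tibble
#' @param params a [superblock_params()] list
#' @return superblock tibble: `sb_id`, `ref_id`, `start`, `end`, `n_blocks`,
#'   `terminal`
#' @export
build_superblocks <- function(blocks, params = superblock_params()) {
  res <- list()
  for (r in unique(blocks$ref_id)) {
    b <- blocks[blocks$ref_id == r, , drop = FALSE]
    n <- nrow(b)
    i <- 1L
    cur_start <- b$start[1]
    prev_end <- -1L
    repeat {
      j <- i
      while (j < n && (b$end[j] - cur_start < params$min_len ||
                       b$end[j] <= prev_end)) {
        j <- j + 1L
      }
      span <- b$end[j] - cur_start
      terminal <- (j == n) && span < params$min_len
      res[[length(res) + 1L]] <- tibble::tibble(
        ref_id = r, start = cur_start, end = b$end[j],
        n_blocks = j - i + 1L, terminal = terminal)
      if (j == n) break
      # the next superblock shares whole blocks with this one, extended
      # leftwards until the overlap reaches min_overlap; when sharing whole
      # blocks would re-include the entire superblock (e.g. a single huge
      # block), fall back to an exact min_overlap sequence overlap inside
      # the last block
      k <- j
      while (k > i + 1L && b$end[j] - b$start[k] < params$min_overlap) {
        k <- k - 1L
      }
      if (k > i && b$end[j] - b$start[k] >= params$min_overlap) {
        new_start <- b$start[k]
      } else {
        new_start <- max(0L, b$end[j] - params$min_overlap)
        inside <- which(b$start[seq_len(j)] <= new_start)
        k <- if (length(inside)) max(max(inside), i) else j
      }
      prev_end <- b$end[j]
      i <- k
      cur_start <- new_start
    }
  }
  sb <- dplyr::bind_rows(res)
  # split over-long superblocks into <= max_len pieces with exact overlap
  out <- list()
  for (s in seq_len(nrow(sb))) {
    row <- sb[s, ]
    if (row$end - row$start <= params$max_len) {
      out[[length(out) + 1L]] <- row
      next
    }
    step <- params$max_len - params$min_overlap
    starts <- seq(row$start, row$end - params$min_overlap - 1L, by = step)
    ends <- pmin(starts + params$max_len, row$end)
    keep <- c(TRUE, ends[-1] > ends[-length(ends)])
    starts <- starts[keep]; ends <- ends[keep]
    out[[length(out) + 1L]] <- tibble::tibble(
      ref_id = row$ref_id, start = as.integer(starts), end = as.integer(ends),
      n_blocks = row$n_blocks, terminal = row$terminal &
        seq_along(starts) == length(starts))
  }
  sb <- dplyr::bind_rows(out) |>
    dplyr::arrange(.data$ref_id, .data$start)
  sb$sb_id <- sprintf("sb_%s_%03d", sb$ref_id,
                      stats::ave(seq_len(nrow(sb)), sb$ref_id,
                                 FUN = seq_along))
  dplyr::select(sb, dplyr::all_of(c("sb_id", "ref_id", "start", "end",
                                    "n_blocks", "terminal")))
}

#' Partition reads into superblocks
#'
#' A superblock receives every read whose alignment overlaps its interval,
#' plus every unmapped read whose mapped mate overlaps it. Reads in overlap
#' zones belong to both neighbouring superblocks.
#'
#' @param superblocks superblock tibble
#' @param alignments alignment tibble (including unmapped records with mate
#'   information)
#' @return the superblock tibble with a list-column `read_keys` of
#'   `"read_id/mate"` keys
#' @export
partition_reads <- function(superblocks, alignments) {
  sp <- alignment_spans(alignments)
  keys <- vector("list", nrow(superblocks))
  for (s in seq_len(nrow(superblocks))) keys[[s]] <- character(0)
  for (r in unique(superblocks$ref_id)) {
    si <- which(sp$ref_id == r)
    bi <- which(superblocks$ref_id == r)
    if (length(si) == 0 || length(bi) == 0) next
    ov <- IRanges::findOverlaps(to_iranges(sp$start[si], sp$end[si]),
                                to_iranges(superblocks$start[bi],
                                           superblocks$end[bi]))
    qh <- si[S4Vectors::queryHits(ov)]
    sh <- bi[S4Vectors::subjectHits(ov)]
    for (b in unique(sh)) {
      rows <- qh[sh == b]
      keys[[b]] <- c(keys[[b]], paste0(sp$read_id[rows], "/", sp$mate[rows]))
    }
  }
  # unmapped mates of mapped reads: attach to the superblocks of the mapped mate
  un <- alignments[alignments$unmapped, , drop = FALSE]
  if (nrow(un) > 0) {
    mapped_key <- paste0(un$read_id, "/", ifelse(un$mate == 1L, 2L, 1L))
    for (s in seq_along(keys)) {
      hit <- mapped_key %in% keys[[s]]
      if (any(hit)) {
        keys[[s]] <- c(keys[[s]], paste0(un$read_id[hit], "/", un$mate[hit]))
      }
      keys[[s]] <- sort(unique(keys[[s]]))
    }
  } else {
    keys <- lapply(keys, function(k) sort(unique(k)))
  }
  superblocks$read_keys <- keys
  superblocks
}

#' Collect unmapped reads
#'
#' Ids of all reads flagged unmapped: both-mates-unmapped pairs and orphans.
#'
#' @param alignments alignment tibble
#' @return tibble with `read_id`, `mate`
#' @export
collect_unmapped <- function(alignments) {
  un <- alignments[alignments$unmapped, , drop = FALSE]
  tibble::tibble(read_id = un$read_id, mate = un$mate)
}

# extract the read records matching "read_id/mate" keys
reads_by_keys <- function(reads, keys) {
  reads[paste0(reads$read_id, "/", reads$mate) %in% keys, , drop = FALSE]
}
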