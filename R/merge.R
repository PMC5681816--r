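# Step 4: homology-guided redundancy removal. Pooled contigs are anchored to
# the guide reference by co-linear chains of exact k-mer matches, laid out,
# and merged column-by-column into non-redundant supercontigs. Consensus uses
# contig bases only; reference bases are never written into the output.

#' Merge parameters
#'
#' @param max_trim maximum ignorable unaligned contig overhang (bp); contigs
#'   with longer overhangs are set aside as unplaced
#' @param min_overlap minimum reference overlap (bp) for two tiles to merge
#' @param min_anchor_score minimum matched bases in the best anchor chain
#' @param anchor_k exact-anchor k-mer length
#' @param max_gap maximum gap between chained anchors (bp)
#' @param max_drift maximum diagonal drift between chained anchors (bp)
#' @return parameter list
#' @export
merge_params <- function(max_trim = 1000L, min_overlap = 10L,
                         min_anchor_score = 50L, anchor_k = 15L,
                         max_gap = 2000L, max_drift = 200L) {
  stopifnot(max_trim >= 0, min_overlap >= 0, min_anchor_score >= 0)
  list(max_trim = as.integer(max_trim), min_overlap = as.integer(min_overlap),
       min_anchor_score = as.integer(min_anchor_score),
       anchor_k = as.integer(anchor_k), max_gap = as.integer(max_gap),
       max_drift = as.integer(max_drift))
}

# best co-linear exact-anchor chain of a query against an index.
# Returns NULL or list(ref_id, strand, score, segments) where segments are in
# coordinates of the ORIENTED query (reverse-complemented when strand == "-")
# with q and r both increasing.
best_chain <- function(seq, index, max_gap, max_drift, min_score) {
  seg <- cpp_exact_segments(index$ptr, seq)
  if (nrow(seg) == 0) return(NULL)
  qlen <- nchar(seq)
  best <- NULL
  for (ref in unique(seg$ref)) {
    rlen <- unname(index$ref_len[ref])
    for (rev in unique(seg$rev[seg$ref == ref])) {
      s <- seg[seg$ref == ref & seg$rev == rev, , drop = FALSE]
      if (rev == 1) {
        # chain against the reverse-complemented query: mirror q coordinates
        qs <- qlen - s$qend; qe <- qlen - s$qstart
      } else {
        qs <- s$qstart; qe <- s$qend
      }
      ch <- cpp_chain_segments(qs, qe, s$rstart, s$rend,
                               max_gap, max_drift, index$k)
      if (ch$score < min_score) next
      idx <- ch$idx
      cand <- list(ref_id = index$ref_ids[ref],
                   strand = if (rev == 1) "-" else "+",
                   score = ch$score,
                   segments = tibble::tibble(
                     qstart = qs[idx], qend = qe[idx],
                     rstart = s$rstart[idx], rend = s$rend[idx]) |>
                     dplyr::arrange(.data$qstart))
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score &&
           min(cand$segments$rstart) < min(best$segments$rstart))) {
        best <- cand
      }
    }
  }
  best
}

#' Anchor contigs to the guide reference
#'
#' Each contig's best co-linear chain of exact k-mer anchors on one strand
#' determines a unique layout tile. Unalignable contig ends up to `max_trim`
#' are recorded as trims; contigs with longer overhangs, or without a chain,
#' are set aside as unplaced.
#'
#' @param contigs contig tibble (`id`, `seq`)
#' @param reference guide reference [seq_tbl()] or prebuilt `kmer_index`
#' @param params a [merge_params()] list
#' @return list with `tiles` (tibble: `contig_id`, `ref_id`, `ref_start`,
#'   `ref_end`, `strand`, `trim_left`, `trim_right`, `score`, list-column
#'   `segments`) and `unplaced` (character vector of contig ids)
#' @export
anchor_contigs <- function(contigs, reference, params = merge_params()) {
  index <- if (inherits(reference, "kmer_index")) reference
           else build_index(reference, params$anchor_k)
  tiles <- list()
  unplaced <- character(0)
  for (i in seq_len(nrow(contigs))) {
    ch <- best_chain(contigs$seq[i], index, params$max_gap, params$max_drift,
                     params$min_anchor_score)
    if (is.null(ch)) { unplaced <- c(unplaced, contigs$id[i]); next }
    qlen <- nchar(contigs$seq[i])
    tl_oriented <- min(ch$segments$qstart)
    tr_oriented <- qlen - max(ch$segments$qend)
    if (max(tl_oriented, tr_oriented) > params$max_trim) {
      unplaced <- c(unplaced, contigs$id[i]); next
    }
    # report trims in original contig orientation
    if (ch$strand == "-") { tl <- tr_oriented; tr <- tl_oriented }
    else { tl <- tl_oriented; tr <- tr_oriented }
    tiles[[length(tiles) + 1L]] <- tibble::tibble(
      contig_id = contigs$id[i], ref_id = ch$ref_id,
      ref_start = min(ch$segments$rstart), ref_end = max(ch$segments$rend),
      strand = ch$strand, trim_left = tl, trim_right = tr,
      score = ch$score, segments = list(ch$segments))
  }
  tiles <- if (length(tiles)) dplyr::bind_rows(tiles) else
    tibble::tibble(contig_id = character(), ref_id = character(),
                   ref_start = integer(), ref_end = integer(),
                   strand = character(), trim_left = integer(),
                   trim_right = integer(), score = numeric(),
                   segments = list())
  list(tiles = dplyr::arrange(tiles, .data$ref_id, .data$ref_start),
       unplaced = unplaced)
}

#' Report unplaced contigs
#'
#' Ids of contigs absent from the tile layout; their content is recovered
#' later by the unmapped-read rescue step.
#'
#' @param contigs contig tibble
#' @param tiles tile tibble from [anchor_contigs()]
#' @return character vector of contig ids
#' @export
report_unplaced <- function(contigs, tiles) {
  setdiff(contigs$id, tiles$contig_id)
}

# project one tile's oriented contig bases onto reference columns.
# Returns list(cols = 0-based ref positions, codes = 1..5 (ACGT + deletion),
# ins = tibble(col, seq)) — insertions are left-aligned at the boundary.
project_tile <- function(tile, oriented_seq) {
  seg <- tile$segments[[1]]
  code_full <- match(strsplit(oriented_seq, "", fixed = TRUE)[[1]],
                     c("A", "C", "G", "T"))
  cols <- integer(0); codes <- integer(0)
  ins <- list()
  prev_qe <- NA_integer_; prev_re <- NA_integer_
  for (s in seq_len(nrow(seg))) {
    qs <- seg$qstart[s]; qe <- seg$qend[s]
    rs <- seg$rstart[s]; re <- seg$rend[s]
    if (!is.na(prev_qe)) {
      d <- max(prev_qe - qs, prev_re - rs, 0L)
      qs <- qs + d; rs <- rs + d
      if (qs >= qe || rs >= re) next
      gq <- qs - prev_qe; gr <- rs - prev_re
      m <- min(gq, gr)
      if (m > 0) {
        cols <- c(cols, prev_re:(prev_re + m - 1L))
        codes <- c(codes, code_full[(prev_qe + 1L):(prev_qe + m)])
      }
      if (gr > gq) {           # deletion in the contig: deletion votes
        cols <- c(cols, (prev_re + m):(rs - 1L))
        codes <- c(codes, rep(5L, gr - m))
      } else if (gq > gr) {    # insertion relative to the reference
        ins[[length(ins) + 1L]] <- tibble::tibble(
          col = rs, seq = substr(oriented_seq, prev_qe + m + 1L, qs))
      }
    }
    cols <- c(cols, rs:(re - 1L))
    codes <- c(codes, code_full[(qs + 1L):qe])
    prev_qe <- qe; prev_re <- re
  }
  keep <- !duplicated(cols)
  list(cols = cols[keep], codes = codes[keep],
       ins = if (length(ins)) dplyr::bind_rows(ins) else
         tibble::tibble(col = integer(), seq = character()))
}

#' Merge layout tiles into non-redundant supercontigs
#'
#' Tiles whose reference intervals overlap by at least `min_overlap` are
#' grouped into chains; each chain's consensus is called column by column
#' over the tiled contig bases (plurality vote; ties resolved towards the
#' lexicographically smaller base). Columns with a strict deletion majority
#' are dropped, insertions with a strict majority are spliced in, and
#' uncovered columns break the supercontig. Reference bases are never
#' emitted.
#'
#' @param tiles tile tibble from [anchor_contigs()]
#' @param contigs contig tibble providing the sequences
#' @param params a [merge_params()] list
#' @return supercontig [seq_tbl()]-like tibble (`id`, `seq`, `origin`)
#' @export
merge_layout <- function(tiles, contigs, params = merge_params()) {
  out_id <- character(0); out_seq <- character(0)
  if (nrow(tiles) == 0) {
    return(tibble::tibble(id = character(), seq = character(),
                          origin = character()))
  }
  seq_of <- setNames(contigs$seq, contigs$id)
  counter <- 0L
  for (ref in unique(tiles$ref_id)) {
    tl <- tiles[tiles$ref_id == ref, , drop = FALSE]
    tl <- tl[order(tl$ref_start, tl$ref_end), , drop = FALSE]
    # chain groups by >= min_overlap reference overlap
    grp <- integer(nrow(tl)); grp[1] <- 1L
    run_end <- tl$ref_end[1]
    for (i in seq_len(nrow(tl))[-1]) {
      if (tl$ref_start[i] <= run_end - params$min_overlap) {
        grp[i] <- grp[i - 1L]
      } else {
        grp[i] <- grp[i - 1L] + 1L
      }
      run_end <- max(run_end, tl$ref_end[i])
    }
    for (g in unique(grp)) {
      gt <- tl[grp == g, , drop = FALSE]
      span_start <- min(gt$ref_start); span_end <- max(gt$ref_end)
      span <- span_end - span_start
      votes <- matrix(0L, nrow = 5L, ncol = span)
      ins_all <- list()
      for (t in seq_len(nrow(gt))) {
        oseq <- seq_of[[gt$contig_id[t]]]
        if (gt$strand[t] == "-") oseq <- revcomp(oseq)
        pr <- project_tile(gt[t, ], oseq)
        rel <- pr$cols - span_start + 1L
        ok <- !is.na(pr$codes)
        idx <- cbind(pr$codes[ok], rel[ok])
        votes[idx] <- votes[idx] + 1L
        if (nrow(pr$ins) > 0) ins_all[[length(ins_all) + 1L]] <- pr$ins
      }
      depth <- colSums(votes)
      pick <- max.col(t(votes), ties.method = "first")
      is_del <- votes[5L, ] * 2L > depth
      emit <- depth > 0L & !is_del
      # strict-majority insertions
      ins_ok <- tibble::tibble(col = integer(), seq = character())
      if (length(ins_all) > 0) {
        ins_ok <- dplyr::bind_rows(ins_all) |>
          dplyr::count(.data$col, .data$seq, name = "n_sup") |>
          dplyr::mutate(rel = .data$col - span_start + 1L) |>
          dplyr::filter(.data$rel >= 1L, .data$rel <= span,
                        .data$n_sup * 2L > depth[.data$rel]) |>
          dplyr::arrange(.data$col)
      }
      # walk columns, breaking at uncovered stretches
      base_chr <- c("A", "C", "G", "T", "")[pick]
      base_chr[!emit] <- ""
      covered <- depth > 0L
      piece_id <- cumsum(c(TRUE, diff(covered) != 0))
      for (p in unique(piece_id[covered])) {
        sel <- which(piece_id == p & covered)
        pseq <- base_chr[sel]
        if (nrow(ins_ok) > 0) {
          rels <- ins_ok$rel[ins_ok$rel %in% sel]
          for (rins in rev(rels)) {
            at <- match(rins, sel)
            pseq[at] <- paste0(ins_ok$seq[ins_ok$rel == rins][1], pseq[at])
          }
        }
        s <- paste(pseq, collapse = "")
        if (nchar(s) == 0) next
        counter <- counter + 1L
        out_id <- c(out_id, sprintf("sc_%05d", counter))
        out_seq <- c(out_seq, s)
      }
    }
  }
  tibble::tibble(id = out_id, seq = out_seq, origin = "MERGE")
}

#' Homology-guided redundancy removal
#'
#' Convenience wrapper: anchors contigs to the guide reference and merges the
#' layout into supercontigs.
#'
#' @param contigs contig tibble
#' @param reference guide reference [seq_tbl()]
#' @param params a [merge_params()] list
#' @return list with `supercontigs`, `tiles`, `unplaced`
#' @export
merge_reduce <- function(contigs, reference, params = merge_params()) {
  anch <- anchor_contigs(contigs, reference, params)
  sc <- merge_layout(anch$tiles, contigs, params)
  list(supercontigs = sc, tiles = anch$tiles, unplaced = anch$unplaced)
}

#' Write tiles as a PAF-like layout file
#'
#' @param tiles tile tibble from [anchor_contigs()]
#' @param contigs contig tibble (for query lengths)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_layout <- function(tiles, contigs, path) {
  qlen <- nchar(contigs$seq)[match(tiles$contig_id, contigs$id)]
  writeLines(paste(tiles$contig_id, qlen, tiles$trim_left,
                   qlen - tiles$trim_right, tiles$strand, tiles$ref_id,
                   tiles$ref_start, tiles$ref_end, round(tiles$score),
                   sep = "\t"), path)
  invisible(path)
}
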