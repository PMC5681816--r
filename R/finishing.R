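# Steps 5-7: unmapped-read rescue, pileup error correction with splitting,
# and ranked scaffolding with gap closing.

#' Finishing parameters
#'
#' @param correction_mapq alignments below this mapping quality are ignored
#'   during correction and link building
#' @param min_supercontig corrected supercontigs shorter than this are
#'   discarded (bp)
#' @param min_scaffold scaffolds shorter than this are discarded (bp)
#' @param min_link_pairs minimum read pairs supporting a scaffold link
#' @return parameter list
#' @export
finishing_params <- function(correction_mapq = 10L, min_supercontig = 200L,
                             min_scaffold = 1000L, min_link_pairs = 3L) {
  stopifnot(correction_mapq >= 0, min_supercontig >= 0, min_scaffold >= 0,
            min_link_pairs >= 1)
  list(correction_mapq = as.integer(correction_mapq),
       min_supercontig = as.integer(min_supercontig),
       min_scaffold = as.integer(min_scaffold),
       min_link_pairs = as.integer(min_link_pairs))
}

#' Rescue diverged regions lost during merging
#'
#' Aligns the trimmed reads back to the current supercontigs (sensitive
#' mode); all reads that remain unmapped are de novo assembled and the
#' resulting contigs are appended to the supercontig list with origin
#' `RESCUE`.
#'
#' @param reads trimmed read tibble
#' @param supercontigs supercontig tibble (`id`, `seq`)
#' @param k k-mer length of the rescue assembly
#' @param min_edge_mult minimum k-mer multiplicity in the rescue assembly
#' @return list with `supercontigs` (augmented tibble) and `rescued`
#'   (the new contigs only)
#' @export
rescue_unmapped <- function(reads, supercontigs, k = 31L, min_edge_mult = 2L) {
  if (nrow(supercontigs) == 0) {
    un_reads <- reads
  } else {
    aln <- map_reads(reads, seq_tbl(supercontigs$id, supercontigs$seq),
                     mode = "sensitive")
    un <- collect_unmapped(aln)
    un_reads <- reads_by_keys(reads, paste0(un$read_id, "/", un$mate))
  }
  rescued <- assemble_reads(un_reads, k = k, min_edge_mult = min_edge_mult,
                            origin = "RESCUE")
  if (nrow(rescued) > 0) {
    rescued$id <- sprintf("rescue_%05d", seq_len(nrow(rescued)))
  }
  combined <- dplyr::bind_rows(
    supercontigs[, c("id", "seq", intersect("origin", names(supercontigs)))],
    rescued[, c("id", "seq", "origin")])
  list(supercontigs = combined, rescued = rescued)
}

#' Error correct supercontigs from a read pileup
#'
#' Alignments below `correction_mapq` are dropped. Per column, a non-reference
#' base with a strict majority of the filtered depth (and at least two
#' supporting reads) replaces the supercontig base; columns with a strict
#' deletion majority are removed; insertions with a strict majority are
#' spliced in (left-aligned). Stretches of zero filtered coverage are excised
#' and the supercontig is split there; pieces shorter than `min_supercontig`
#' are discarded.
#'
#' @param supercontigs supercontig tibble (`id`, `seq`)
#' @param alignments alignments of trimmed paired-end reads against the
#'   supercontigs
#' @param params a [finishing_params()] list
#' @return corrected supercontig tibble with attribute `correction_stats`
#' @export
correct_supercontigs <- function(supercontigs, alignments,
                                 params = finishing_params()) {
  a <- alignments[!alignments$unmapped & alignments$mapq >= params$correction_mapq, ,
                  drop = FALSE]
  tgt <- match(a$ref_id, supercontigs$id)
  oriented <- ifelse(a$strand == "-", revcomp(a$seq), a$seq)
  pu <- cpp_pileup(nchar(supercontigs$seq), tgt, a$pos, a$cigar, oriented)
  bases <- c("A", "C", "G", "T")
  out_id <- character(0); out_seq <- character(0)
  n_sub <- 0L; n_del <- 0L; n_ins <- 0L; n_split <- 0L; n_dropped <- 0L
  for (t in seq_len(nrow(supercontigs))) {
    counts <- pu$counts[[t]]
    L <- ncol(counts)
    chars <- strsplit(supercontigs$seq[t], "", fixed = TRUE)[[1]]
    depth <- colSums(counts)
    refcode <- match(chars, bases)
    bm <- max.col(t(counts[1:4, , drop = FALSE]), ties.method = "first")
    bn <- counts[cbind(bm, seq_len(L))]
    sub <- depth > 0L & bn >= 2L & bn * 2L > depth &
      (is.na(refcode) | bm != refcode)
    chars[sub] <- bases[bm[sub]]
    n_sub <- n_sub + sum(sub)
    deld <- counts[5L, ] >= 2L & counts[5L, ] * 2L > depth
    n_del <- n_del + sum(deld)
    ins <- pu$ins[pu$ins$target == t, , drop = FALSE]
    if (nrow(ins) > 0) {
      dcol <- pmin(ins$pos + 1L, L)
      ok <- ins$count >= 2L & ins$count * 2L > depth[dcol]
      ins <- ins[ok, , drop = FALSE]
      for (r in seq_len(nrow(ins))) {
        at <- min(ins$pos[r] + 1L, L)
        chars[at] <- paste0(ins$seq[r], chars[at])
        n_ins <- n_ins + 1L
      }
    }
    covered <- depth > 0L
    keep <- covered & !deld
    piece <- cumsum(c(TRUE, diff(covered) != 0L))
    pieces_here <- 0L
    for (p in unique(piece[covered])) {
      sel <- keep & piece == p
      s <- paste(chars[sel], collapse = "")
      if (nchar(s) < params$min_supercontig) { n_dropped <- n_dropped + 1L; next }
      pieces_here <- pieces_here + 1L
      out_id <- c(out_id, if (all(covered)) supercontigs$id[t] else
        sprintf("%s_p%d", supercontigs$id[t], pieces_here))
      out_seq <- c(out_seq, s)
    }
    if (pieces_here > 1L) n_split <- n_split + 1L
  }
  out <- tibble::tibble(id = out_id, seq = out_seq)
  attr(out, "correction_stats") <- list(
    n_substituted = n_sub, n_deleted_cols = n_del, n_inserted = n_ins,
    n_split = n_split, n_dropped = n_dropped,
    n_in = nrow(supercontigs), n_out = nrow(out))
  out
}

# does a mapped mate point towards the right end of its target?
# (kind is scalar: FR libraries point along the read strand, RF against it)
points_right <- function(strand, kind) {
  if (kind == "PE") strand == "+" else strand == "-"
}

#' Build scaffold links from read pairs bridging supercontigs
#'
#' Pairs with both mates mapped to different supercontigs at mapping quality
#' at least `correction_mapq` vote for an oriented junction. The gap estimate
#' is the library insert mean minus the two mates' distances to their
#' supercontigs' inner ends, averaged over pairs. Links supported by fewer
#' than `min_link_pairs` pairs are dropped.
#'
#' @param alignments alignments of one library's reads against the
#'   supercontigs
#' @param library one-row library tibble
#' @param sc_len named vector of supercontig lengths
#' @param params a [finishing_params()] list
#' @return link tibble: `sc1`, `end1`, `sc2`, `end2`, `n_pairs`, `gap`,
#'   `library_id`
#' @export
build_links <- function(alignments, library, sc_len,
                        params = finishing_params()) {
  a <- alignments[!alignments$unmapped &
                    alignments$mapq >= params$correction_mapq, , drop = FALSE]
  empty <- tibble::tibble(sc1 = character(), end1 = character(),
                          sc2 = character(), end2 = character(),
                          n_pairs = integer(), gap = numeric(),
                          library_id = character())
  if (nrow(a) < 2) return(empty)
  m1 <- a[a$mate == 1L, , drop = FALSE]
  m2 <- a[a$mate == 2L, , drop = FALSE]
  j <- match(m1$read_id, m2$read_id)
  okj <- !is.na(j)
  m1 <- m1[okj, , drop = FALSE]; m2 <- m2[j[okj], , drop = FALSE]
  diffsc <- m1$ref_id != m2$ref_id
  m1 <- m1[diffsc, , drop = FALSE]; m2 <- m2[diffsc, , drop = FALSE]
  if (nrow(m1) == 0) return(empty)
  kind <- library$kind[1]
  pr1 <- points_right(m1$strand, kind)
  pr2 <- points_right(m2$strand, kind)
  d1 <- ifelse(pr1, sc_len[m1$ref_id] - m1$pos,
               m1$pos + cigar_ref_len(m1$cigar))
  d2 <- ifelse(pr2, sc_len[m2$ref_id] - m2$pos,
               m2$pos + cigar_ref_len(m2$cigar))
  gap <- library$insert_mean[1] - d1 - d2
  e1 <- ifelse(pr1, "R", "L"); e2 <- ifelse(pr2, "R", "L")
  swap <- m1$ref_id > m2$ref_id
  links <- tibble::tibble(
    sc1 = ifelse(swap, m2$ref_id, m1$ref_id),
    end1 = ifelse(swap, e2, e1),
    sc2 = ifelse(swap, m1$ref_id, m2$ref_id),
    end2 = ifelse(swap, e1, e2),
    gap = gap)
  links |>
    dplyr::group_by(.data$sc1, .data$end1, .data$sc2, .data$end2) |>
    dplyr::summarise(n_pairs = dplyr::n(), gap = mean(.data$gap),
                     .groups = "drop") |>
    dplyr::filter(.data$n_pairs >= params$min_link_pairs) |>
    dplyr::mutate(library_id = library$library_id[1]) |>
    dplyr::arrange(dplyr::desc(.data$n_pairs), .data$sc1, .data$sc2)
}

# simple union-find over character ids
uf_new <- function(ids) {
  e <- new.env(parent = emptyenv())
  for (i in ids) assign(i, i, envir = e)
  e
}
uf_find <- function(e, x) {
  while (get(x, envir = e) != x) {
    assign(x, get(get(x, envir = e), envir = e), envir = e)
    x <- get(x, envir = e)
  }
  x
}
uf_union <- function(e, a, b) assign(uf_find(e, a), uf_find(e, b), envir = e)

#' Ranked scaffolding with gap closing
#'
#' Libraries are processed in rank order of ascending insert size; within a
#' library, links are accepted in descending support. A link is rejected when
#' an involved supercontig end is already joined or when it would close a
#' cycle. Joined sequences are concatenated with `max(gap, 10)` N's; when
#' read alignments are supplied, each N gap is replaced by the unique k-mer
#' read path bridging the junction, if exactly one exists. Scaffolds shorter
#' than `min_scaffold` are discarded.
#'
#' @param supercontigs supercontig tibble (`id`, `seq`)
#' @param links combined link tibble from [build_links()]
#' @param libraries library tibble (provides the rank order)
#' @param params a [finishing_params()] list
#' @param junction_reads optional alignment tibble against the supercontigs;
#'   its reads feed the gap-closing k-mer graph
#' @param gap_k k-mer length of the gap-closing graph
#' @return list with `scaffolds` (tibble `id`, `seq`), `agp` (composition
#'   tibble) and `stats`
#' @export
scaffold <- function(supercontigs, links, libraries,
                     params = finishing_params(), junction_reads = NULL,
                     gap_k = 31L) {
  sc_len <- setNames(nchar(supercontigs$seq), supercontigs$id)
  rank <- libraries$library_id[order(libraries$insert_mean)]
  used_end <- new.env(parent = emptyenv())
  uf <- uf_new(supercontigs$id)
  accepted <- list()
  n_rejected <- 0L
  for (lib in rank) {
    lk <- links[links$library_id == lib, , drop = FALSE]
    if (nrow(lk) == 0) next
    lk <- lk[order(-lk$n_pairs, lk$sc1, lk$sc2, lk$end1, lk$end2), ,
             drop = FALSE]
    for (i in seq_len(nrow(lk))) {
      k1 <- paste0(lk$sc1[i], ":", lk$end1[i])
      k2 <- paste0(lk$sc2[i], ":", lk$end2[i])
      if (!is.null(used_end[[k1]]) || !is.null(used_end[[k2]]) ||
          uf_find(uf, lk$sc1[i]) == uf_find(uf, lk$sc2[i])) {
        n_rejected <- n_rejected + 1L
        next
      }
      used_end[[k1]] <- TRUE; used_end[[k2]] <- TRUE
      uf_union(uf, lk$sc1[i], lk$sc2[i])
      accepted[[length(accepted) + 1L]] <- lk[i, ]
    }
  }
  acc <- if (length(accepted)) dplyr::bind_rows(accepted) else
    tibble::tibble(sc1 = character(), end1 = character(), sc2 = character(),
                   end2 = character(), n_pairs = integer(), gap = numeric(),
                   library_id = character())
  # adjacency per supercontig end
  adj <- new.env(parent = emptyenv())
  if (nrow(acc) > 0) {
    for (i in seq_len(nrow(acc))) {
      adj[[paste0(acc$sc1[i], ":", acc$end1[i])]] <-
        list(to = acc$sc2[i], to_end = acc$end2[i], gap = acc$gap[i],
             lib = acc$library_id[i])
      adj[[paste0(acc$sc2[i], ":", acc$end2[i])]] <-
        list(to = acc$sc1[i], to_end = acc$end1[i], gap = acc$gap[i],
             lib = acc$library_id[i])
    }
  }
  seq_of <- setNames(supercontigs$seq, supercontigs$id)
  visited <- new.env(parent = emptyenv())
  scaffolds_id <- character(0); scaffolds_seq <- character(0)
  agp <- list()
  n_closed <- 0L
  scaffold_counter <- 0L
  for (sc in supercontigs$id) {
    if (!is.null(visited[[sc]])) next
    # find a terminus of the path containing sc
    start <- sc; start_orient <- "+"
    guard <- 0L
    repeat {
      left_end <- if (start_orient == "+") "L" else "R"
      lk <- adj[[paste0(start, ":", left_end)]]
      if (is.null(lk)) break
      guard <- guard + 1L
      if (guard > length(seq_of)) break  # safety (cycles are rejected above)
      start <- lk$to
      start_orient <- if (lk$to_end == "R") "+" else "-"
    }
    # walk rightwards from the terminus
    cur <- start; orient <- start_orient
    visited[[cur]] <- TRUE
    pieces <- list(list(sc = cur, orient = orient, gap_before = NA_real_))
    repeat {
      right_end <- if (orient == "+") "R" else "L"
      lk <- adj[[paste0(cur, ":", right_end)]]
      if (is.null(lk)) break
      cur <- lk$to
      orient <- if (lk$to_end == "L") "+" else "-"
      if (!is.null(visited[[cur]])) break
      visited[[cur]] <- TRUE
      pieces[[length(pieces) + 1L]] <-
        list(sc = cur, orient = orient, gap_before = lk$gap)
    }
    # stitch the path
    scaffold_counter <- scaffold_counter + 1L
    sid <- sprintf("scaffold_%04d", scaffold_counter)
    oriented <- vapply(pieces, function(p) {
      if (p$orient == "+") seq_of[[p$sc]] else revcomp(seq_of[[p$sc]])
    }, "")
    out <- oriented[1]
    for (p in seq_along(pieces)[-1]) {
      gap_n <- max(round(pieces[[p]]$gap_before), 10)
      closed <- FALSE
      if (!is.null(junction_reads)) {
        left_seq <- out; right_seq <- oriented[p]
        if (nchar(left_seq) >= gap_k && nchar(right_seq) >= gap_k) {
          la <- substr(left_seq, nchar(left_seq) - gap_k + 1L, nchar(left_seq))
          ra <- substr(right_seq, 1L, gap_k)
          near <- junction_near_reads(junction_reads, pieces, p, gap_n)
          if (length(near) > 0) {
            path <- cpp_unique_path(near, gap_k, la, ra,
                                    as.integer(gap_n + 2L * gap_k + 1000L))
            if (nchar(path) > 0) {
              mid <- substr(path, gap_k + 1L, nchar(path) - gap_k)
              out <- paste0(left_seq, mid, right_seq)
              closed <- TRUE
              n_closed <- n_closed + 1L
            }
          }
        }
      }
      if (!closed) {
        out <- paste0(out, strrep("N", gap_n), oriented[p])
      }
    }
    agp[[length(agp) + 1L]] <- tibble::tibble(
      scaffold_id = sid,
      part = seq_along(pieces),
      sc_id = vapply(pieces, `[[`, "", "sc"),
      orient = vapply(pieces, `[[`, "", "orient"),
      gap_before = vapply(pieces, function(p) {
        g <- p$gap_before
        if (is.na(g)) NA_real_ else max(round(g), 10)
      }, 0))
    scaffolds_id <- c(scaffolds_id, sid)
    scaffolds_seq <- c(scaffolds_seq, out)
  }
  keep <- nchar(scaffolds_seq) >= params$min_scaffold
  scaffolds <- tibble::tibble(id = scaffolds_id[keep],
                              seq = scaffolds_seq[keep])
  list(scaffolds = scaffolds,
       agp = dplyr::bind_rows(agp),
       stats = list(n_links_accepted = nrow(acc), n_links_rejected = n_rejected,
                    n_gaps_closed = n_closed,
                    n_scaffolds = nrow(scaffolds),
                    n_dropped_short = sum(!keep)))
}

# reads feeding the gap-closing graph of one junction: reads aligned to
# either joined supercontig plus unmapped reads whose mate aligns there (the
# latter carry the gap sequence itself)
junction_near_reads <- function(junction_reads, pieces, p, gap_n) {
  left <- pieces[[p - 1L]]; right <- pieces[[p]]
  a <- junction_reads
  mapped <- !a$unmapped & a$ref_id %in% c(left$sc, right$sc)
  mate_in <- a$unmapped & a$read_id %in% a$read_id[mapped]
  a$seq[mapped | mate_in]
}
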