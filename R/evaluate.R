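# Assembly evaluation against a truth genome: continuity statistics,
# truth-alignment misassembly classification, COMPASS metrics, read-mapping
# rates, a read-pair consistency (REAPR-like) score, and gene recovery.

#' N50 of a length set
#'
#' Length of the sequence at which, walking lengths in descending order, the
#' cumulative sum first reaches half the total assembly length.
#'
#' @param lengths positive sequence lengths
#' @return N50 in bp; 0 for empty input
#' @export
n50 <- function(lengths) {
  lengths <- lengths[!is.na(lengths) & lengths > 0]
  if (length(lengths) == 0) return(0)
  s <- sort(unname(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' NG50 of a length set relative to a known genome size
#'
#' As [n50()], but the cumulative sum is compared to half the genome length;
#' 0 when the assembly never reaches it.
#'
#' @param lengths positive sequence lengths
#' @param genome_size known genome length (bp)
#' @return NG50 in bp; 0 when unreached
#' @export
ng50 <- function(lengths, genome_size) {
  stopifnot(genome_size > 0)
  lengths <- lengths[!is.na(lengths) & lengths > 0]
  if (length(lengths) == 0) return(0)
  s <- sort(unname(lengths), decreasing = TRUE)
  i <- which(cumsum(s) >= genome_size / 2)
  if (length(i) == 0) 0 else s[i[1]]
}

#' Decompose assembly sequences into co-linear truth placements
#'
#' Each scaffold is decomposed into maximal co-linear segments by iterative
#' extraction of the best exact-anchor chain against the truth genome;
#' segments shorter than `min_segment` are ignored.
#'
#' @param assembly assembly tibble (`id`, `seq`)
#' @param truth truth genome [seq_tbl()] or prebuilt `kmer_index`
#' @param min_segment minimum reported segment length on the assembly (bp)
#' @param max_gap,max_drift chaining limits (bp); chains break at diagonal
#'   drifts above `max_drift`, so larger rearrangements surface as separate
#'   segments
#' @param min_match minimum matched bases per chain
#' @return placement tibble: `scaffold_id`, `qstart`, `qend`, `ref_id`,
#'   `rstart`, `rend`, `strand`, `matched`, `n_indel`, ordered by scaffold
#'   position
#' @export
align_to_truth <- function(assembly, truth, min_segment = 500L,
                           max_gap = 5000L, max_drift = 600L,
                           min_match = 100L) {
  index <- if (inherits(truth, "kmer_index")) truth else build_index(truth, 15L)
  res <- list()
  for (i in seq_len(nrow(assembly))) {
    seg <- cpp_exact_segments(index$ptr, assembly$seq[i])
    if (nrow(seg) == 0) next
    repeat {
      best <- NULL
      for (ref in unique(seg$ref)) {
        rlen <- unname(index$ref_len[ref])
        for (rev in unique(seg$rev[seg$ref == ref])) {
          s <- seg[seg$ref == ref & seg$rev == rev, , drop = FALSE]
          if (nrow(s) == 0) next
          if (rev == 1) {  # mirror reference so both axes increase
            rs <- rlen - s$rend; re <- rlen - s$rstart
          } else {
            rs <- s$rstart; re <- s$rend
          }
          ch <- cpp_chain_segments(s$qstart, s$qend, rs, re, max_gap,
                                   max_drift, index$k)
          if (is.null(best) || ch$score > best$score) {
            best <- list(score = ch$score, rows = s[ch$idx, , drop = FALSE],
                         ref = ref, rev = rev)
          }
        }
      }
      if (is.null(best) || best$score < min_match) break
      rows <- best$rows
      q0 <- min(rows$qstart); q1 <- max(rows$qend)
      if (q1 - q0 >= min_segment) {
        dq <- rows$qstart[-1] - rows$qend[-nrow(rows)]
        dr <- if (best$rev == 1) {
          rows$rstart[-nrow(rows)] - rows$rend[-1]
        } else {
          rows$rstart[-1] - rows$rend[-nrow(rows)]
        }
        res[[length(res) + 1L]] <- tibble::tibble(
          scaffold_id = assembly$id[i], qstart = q0, qend = q1,
          ref_id = index$ref_ids[best$ref],
          rstart = min(rows$rstart), rend = max(rows$rend),
          strand = if (best$rev == 1) "-" else "+",
          matched = best$score,
          n_indel = if (nrow(rows) > 1) sum(dq != dr) else 0L)
      }
      mid <- (seg$qstart + seg$qend) / 2
      seg <- seg[!(mid >= q0 & mid < q1), , drop = FALSE]
      if (nrow(seg) == 0) break
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(scaffold_id = character(), qstart = integer(),
                          qend = integer(), ref_id = character(),
                          rstart = integer(), rend = integer(),
                          strand = character(), matched = numeric(),
                          n_indel = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(res), .data$scaffold_id, .data$qstart)
}

#' Identity of aligned regions
#'
#' Mean per-base identity over all truth placements, weighted by segment
#' length (banded alignment of each segment pair).
#'
#' @param assembly assembly tibble
#' @param truth truth genome [seq_tbl()]
#' @param placements optional precomputed [align_to_truth()] result
#' @param band alignment band width (bp)
#' @return list with `identity` (in `[0, 1]`), `matched`, `aligned_bases`
#' @export
aligned_identity <- function(assembly, truth, placements = NULL, band = 700L) {
  p <- placements %||% align_to_truth(assembly, truth)
  if (nrow(p) == 0) return(list(identity = 0, matched = 0, aligned_bases = 0))
  aseq <- setNames(assembly$seq, assembly$id)
  tseq <- setNames(truth$seq, truth$id)
  total_m <- 0; total_b <- 0
  for (i in seq_len(nrow(p))) {
    q <- substr(aseq[[p$scaffold_id[i]]], p$qstart[i] + 1L, p$qend[i])
    r <- substr(tseq[[p$ref_id[i]]], p$rstart[i] + 1L, p$rend[i])
    if (p$strand[i] == "-") q <- revcomp(q)
    total_m <- total_m + cpp_banded_matches(q, r, band)
    total_b <- total_b + max(nchar(q), nchar(r))
  }
  list(identity = total_m / total_b, matched = total_m,
       aligned_bases = total_b)
}

#' Fraction of the truth genome covered by an assembly
#'
#' @param placements [align_to_truth()] result
#' @param truth truth genome [seq_tbl()]
#' @return covered fraction in `[0, 1]`
#' @export
truth_coverage <- function(placements, truth) {
  if (nrow(placements) == 0) return(0)
  cov <- 0
  for (r in unique(placements$ref_id)) {
    p <- placements[placements$ref_id == r, ]
    cov <- cov + sum(IRanges::width(IRanges::reduce(
      to_iranges(p$rstart, p$rend))))
  }
  cov / sum(nchar(truth$seq))
}

#' Classify misassemblies from adjacent truth placements
#'
#' Each adjacent segment pair within a scaffold is examined: different truth
#' chromosomes give a translocation; the same chromosome on opposite strands
#' an inversion; the same strand with a truth gap or overlap beyond
#' `threshold` a relocation; smaller inconsistencies above `local_min` a
#' local misassembly. Precedence: translocation > inversion > relocation >
#' local.
#'
#' @param placements [align_to_truth()] result
#' @param assembly assembly tibble (for scaffold lengths in the summary)
#' @param threshold relocation distance threshold (bp)
#' @param local_min minimum inconsistency called as a local event (bp)
#' @return list with `events` (tibble: `scaffold_id`, `type`, `breakpoint`,
#'   flanking placement coordinates) and `summary`
#' @export
classify_misassemblies <- function(placements, assembly, threshold = 1000L,
                                   local_min = 85L) {
  ev <- list()
  for (sc in unique(placements$scaffold_id)) {
    p <- placements[placements$scaffold_id == sc, , drop = FALSE]
    if (nrow(p) < 2) next
    for (i in seq_len(nrow(p) - 1L)) {
      a <- p[i, ]; b <- p[i + 1L, ]
      type <- NA_character_
      if (a$ref_id != b$ref_id) {
        type <- "translocation"
      } else if (a$strand != b$strand) {
        type <- "inversion"
      } else {
        gr <- if (a$strand == "+") b$rstart - a$rend else a$rstart - b$rend
        gq <- b$qstart - a$qend
        if (gr > threshold || gr < -threshold) {
          type <- "relocation"
        } else if (abs(gr - gq) > local_min) {
          type <- "local"
        }
      }
      if (!is.na(type)) {
        ev[[length(ev) + 1L]] <- tibble::tibble(
          scaffold_id = sc, type = type,
          breakpoint = as.integer(floor((a$qend + b$qstart) / 2)),
          left_ref = a$ref_id, left_rend = a$rend, left_strand = a$strand,
          right_ref = b$ref_id, right_rstart = b$rstart,
          right_strand = b$strand)
      }
    }
  }
  events <- if (length(ev)) dplyr::bind_rows(ev) else
    tibble::tibble(scaffold_id = character(), type = character(),
                   breakpoint = integer(), left_ref = character(),
                   left_rend = integer(), left_strand = character(),
                   right_ref = character(), right_rstart = integer(),
                   right_strand = character())
  non_local <- events[events$type != "local", , drop = FALSE]
  mis_sc <- unique(non_local$scaffold_id)
  lens <- setNames(nchar(assembly$seq), assembly$id)
  summary <- list(
    n_translocation = sum(events$type == "translocation"),
    n_relocation = sum(events$type == "relocation"),
    n_inversion = sum(events$type == "inversion"),
    n_local = sum(events$type == "local"),
    n_misassemblies = nrow(non_local),
    pct_misassembled_scaffolds =
      if (nrow(assembly) == 0) 0 else 100 * length(mis_sc) / nrow(assembly),
    pct_misassembled_length =
      if (sum(lens) == 0) 0 else 100 * sum(lens[mis_sc]) / sum(lens))
  list(events = events, summary = summary)
}

#' Error-corrected NG50
#'
#' NG50 recomputed after breaking every scaffold at each non-local
#' misassembly breakpoint.
#'
#' @param assembly assembly tibble
#' @param events misassembly event tibble from [classify_misassemblies()]
#' @param genome_size known genome length (bp)
#' @return list with `corrected_ng50`, `raw_ng50` and their `ratio`
#' @export
corrected_ng50 <- function(assembly, events, genome_size) {
  ev <- events[events$type != "local", , drop = FALSE]
  frags <- numeric(0)
  for (i in seq_len(nrow(assembly))) {
    L <- nchar(assembly$seq[i])
    bp <- sort(unique(ev$breakpoint[ev$scaffold_id == assembly$id[i]]))
    bp <- bp[bp > 0 & bp < L]
    frags <- c(frags, diff(c(0, bp, L)))
  }
  raw <- ng50(nchar(assembly$seq), genome_size)
  corr <- ng50(frags, genome_size)
  list(corrected_ng50 = corr, raw_ng50 = raw,
       ratio = if (raw == 0) 1 else corr / raw)
}

#' COMPASS metrics: coverage, validity, multiplicity, parsimony
#'
#' Coverage is the fraction of truth bases covered by at least one aligned
#' segment; validity the fraction of assembly bases inside segments;
#' multiplicity the mean number of times a covered truth base is covered;
#' parsimony the assembly cost (assembled over validated bases).
#'
#' @param assembly assembly tibble
#' @param truth truth genome [seq_tbl()]
#' @param placements optional precomputed [align_to_truth()] result
#' @return list with `coverage`, `validity`, `multiplicity`, `parsimony`
#' @export
compass_metrics <- function(assembly, truth, placements = NULL) {
  asm_len <- sum(nchar(assembly$seq))
  if (asm_len == 0) {
    return(list(coverage = 0, validity = 0, multiplicity = 0,
                parsimony = Inf))
  }
  p <- placements %||% align_to_truth(assembly, truth)
  if (nrow(p) == 0) {
    return(list(coverage = 0, validity = 0, multiplicity = 0,
                parsimony = Inf))
  }
  covered <- 0
  for (r in unique(p$ref_id)) {
    pr <- p[p$ref_id == r, ]
    covered <- covered + sum(IRanges::width(IRanges::reduce(
      to_iranges(pr$rstart, pr$rend))))
  }
  validated <- 0
  for (sc in unique(p$scaffold_id)) {
    ps <- p[p$scaffold_id == sc, ]
    validated <- validated + sum(IRanges::width(IRanges::reduce(
      to_iranges(ps$qstart, ps$qend))))
  }
  list(coverage = covered / sum(nchar(truth$seq)),
       validity = validated / asm_len,
       multiplicity = sum(p$rend - p$rstart) / covered,
       parsimony = asm_len / validated)
}

#' Read-mapping statistics against an assembly
#'
#' @param reads read tibble (paired-end)
#' @param assembly assembly tibble
#' @param libraries library tibble for proper-pair flagging
#' @return list with `pct_mapped`, `pct_mapped_q10`, `pct_proper_q10`
#' @export
mapping_stats <- function(reads, assembly, libraries) {
  aln <- map_reads(reads, seq_tbl(assembly$id, assembly$seq),
                   mode = "sensitive")
  aln <- pair_and_flag(aln, libraries)
  n <- nrow(aln)
  list(pct_mapped = 100 * sum(!aln$unmapped) / n,
       pct_mapped_q10 = 100 * sum(!aln$unmapped & aln$mapq >= 10) / n,
       pct_proper_q10 = 100 * sum(aln$proper_pair & aln$mapq >= 10) / n,
       alignments = aln)
}

#' N content per 100 kb
#'
#' @param assembly assembly tibble
#' @return average number of N bases per 100 kb of assembly
#' @export
ns_per_100kb <- function(assembly) {
  total <- sum(nchar(assembly$seq))
  if (total == 0) return(0)
  ns <- sum(nchar(gsub("[^N]", "", assembly$seq)))
  1e5 * ns / total
}

#' Indel events per 100 kb of aligned assembly
#'
#' Counts diagonal shifts within truth-alignment chains.
#'
#' @param placements [align_to_truth()] result
#' @return indels per 100 kb aligned
#' @export
indels_per_100kb <- function(placements) {
  aligned <- sum(placements$qend - placements$qstart)
  if (aligned == 0) return(0)
  1e5 * sum(placements$n_indel) / aligned
}

#' Duplication ratio
#'
#' Total aligned assembly bases over covered truth bases.
#'
#' @param placements [align_to_truth()] result
#' @param truth truth genome [seq_tbl()]
#' @return duplication ratio (1 = no duplication)
#' @export
duplication_ratio <- function(placements, truth) {
  if (nrow(placements) == 0) return(0)
  covered <- 0
  for (r in unique(placements$ref_id)) {
    pr <- placements[placements$ref_id == r, ]
    covered <- covered + sum(IRanges::width(IRanges::reduce(
      to_iranges(pr$rstart, pr$rend))))
  }
  sum(placements$qend - placements$qstart) / covered
}

#' Gene recovery from truth placements
#'
#' A gene is recovered in full when at least `full_frac` of its span is
#' covered by segments of a single scaffold, and in part when at least one
#' base is covered by any segment.
#'
#' @param placements [align_to_truth()] result
#' @param genes gene tibble from [random_genes()]
#' @param full_frac single-scaffold coverage fraction counting as full
#' @return list with `n_full`, `n_partial`, `n_genes`, `covered_genes`
#' @export
gene_recovery <- function(placements, genes, full_frac = 0.95) {
  n_full <- 0L; n_partial <- 0L
  for (g in seq_len(nrow(genes))) {
    p <- placements[placements$ref_id == genes$ref_id[g] &
                      placements$rend > genes$start[g] &
                      placements$rstart < genes$end[g], , drop = FALSE]
    if (nrow(p) == 0) next
    n_partial <- n_partial + 1L
    glen <- genes$end[g] - genes$start[g]
    best <- 0
    for (sc in unique(p$scaffold_id)) {
      ps <- p[p$scaffold_id == sc, ]
      ir <- IRanges::intersect(
        IRanges::reduce(to_iranges(ps$rstart, ps$rend)),
        to_iranges(genes$start[g], genes$end[g]))
      best <- max(best, sum(IRanges::width(ir)) / glen)
    }
    if (best >= full_frac) n_full <- n_full + 1L
  }
  list(n_full = n_full, n_partial = n_partial, n_genes = nrow(genes),
       covered_genes = n_partial)
}

#' Read-pair consistency score
#'
#' Error regions are internal stretches with zero proper-pair fragment
#' coverage, plus positions where at least `min_inconsistent` same-scaffold
#' pairs are orientation- or insert-inconsistent. The score is the fraction
#' of error-free bases times the ratio of the error-broken N50 to the raw
#' N50, giving 1.0 for a perfectly supported assembly.
#'
#' @param assembly assembly tibble
#' @param pe_alignments paired-end alignments against the assembly, flagged
#'   by [pair_and_flag()]
#' @param mp_alignments optional mate-pair alignments (adds long-range
#'   fragment coverage)
#' @param min_inconsistent inconsistent pairs needed to call an error
#' @return list with `n_errors`, `score`, `broken_n50`, `raw_n50`
#' @export
reapr_like_score <- function(assembly, pe_alignments, mp_alignments = NULL,
                             min_inconsistent = 5L) {
  lens <- setNames(nchar(assembly$seq), assembly$id)
  frag_of <- function(aln) {
    a <- aln[!aln$unmapped & aln$proper_pair, , drop = FALSE]
    m1 <- a[a$mate == 1L, ]; m2 <- a[a$mate == 2L, ]
    j <- match(m1$read_id, m2$read_id)
    ok <- !is.na(j)
    m1 <- m1[ok, ]; m2 <- m2[j[ok], ]
    tibble::tibble(ref_id = m1$ref_id,
                   start = pmin(m1$pos, m2$pos),
                   end = pmax(m1$pos + cigar_ref_len(m1$cigar),
                              m2$pos + cigar_ref_len(m2$cigar)))
  }
  frags <- frag_of(pe_alignments)
  if (!is.null(mp_alignments)) frags <- dplyr::bind_rows(frags, frag_of(mp_alignments))
  incons_of <- function(aln) {
    a <- aln[!aln$unmapped, , drop = FALSE]
    m1 <- a[a$mate == 1L, ]; m2 <- a[a$mate == 2L, ]
    j <- match(m1$read_id, m2$read_id)
    ok <- !is.na(j)
    m1 <- m1[ok, ]; m2 <- m2[j[ok], ]
    same <- m1$ref_id == m2$ref_id & !m1$proper_pair
    tibble::tibble(ref_id = m1$ref_id[same],
                   pos = floor((m1$pos[same] + m2$pos[same]) / 2))
  }
  incons <- incons_of(pe_alignments)
  n_errors <- 0L
  err_len <- 0
  frag_list <- numeric(0)
  for (sc in names(lens)) {
    L <- lens[[sc]]
    f <- frags[frags$ref_id == sc, , drop = FALSE]
    cov <- integer(L)
    if (nrow(f) > 0) {
      covr <- IRanges::coverage(to_iranges(pmax(f$start, 0L), pmin(f$end, L)),
                                width = L)
      cov <- as.integer(covr)
    }
    bad <- cov == 0L
    inc <- incons[incons$ref_id == sc, , drop = FALSE]
    if (nrow(inc) > 0) {
      tabp <- table(pmin(pmax(inc$pos, 0L), L - 1L))
      hot <- as.integer(names(tabp)[tabp >= min_inconsistent])
      bad[hot + 1L] <- TRUE
    }
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    internal <- r$values & starts > 1L & ends < L
    n_errors <- n_errors + sum(internal)
    err_len <- err_len + sum(r$lengths[internal])
    # break at internal error regions
    cuts <- sort(c(starts[internal] - 1L, ends[internal]))
    frag_list <- c(frag_list, diff(c(0L, cuts, L)))
  }
  total <- sum(lens)
  raw <- n50(lens)
  broken <- n50(frag_list)
  score <- if (total == 0 || raw == 0) 0 else
    ((total - err_len) / total) * (broken / raw)
  list(n_errors = n_errors, score = score, broken_n50 = broken, raw_n50 = raw)
}

#' Split scaffolds into contigs at N gaps
#'
#' @param assembly assembly tibble
#' @param min_gap minimum run of N's treated as a gap
#' @return contig tibble (`id`, `seq`)
#' @export
split_scaffolds_at_gaps <- function(assembly, min_gap = 1L) {
  out_id <- character(0); out_seq <- character(0)
  for (i in seq_len(nrow(assembly))) {
    parts <- strsplit(gsub(sprintf("N{%d,}", min_gap), "\n",
                           assembly$seq[i]), "\n", fixed = TRUE)[[1]]
    parts <- parts[nchar(parts) > 0]
    if (length(parts) == 0) next
    out_id <- c(out_id, if (length(parts) == 1) assembly$id[i] else
      sprintf("%s_c%d", assembly$id[i], seq_along(parts)))
    out_seq <- c(out_seq, parts)
  }
  tibble::tibble(id = out_id, seq = out_seq)
}

#' Compute the full evaluation statistic vector for one assembly
#'
#' The 34-statistic registry: contig and scaffold continuity, length
#' differences versus the known genome size, misassembly counts and
#' fractions, read-mapping rates, COMPASS metrics, gene recovery and the
#' read-pair consistency score. Each statistic carries an orientation used by
#' the z-score ranking: `"higher"` (better when larger), `"lower"` (better
#' when smaller) or `"near_one"` (better the closer to 1).
#'
#' @param scaffolds scaffold tibble (`id`, `seq`)
#' @param truth truth genome [seq_tbl()]
#' @param contigs contig-level tibble; defaults to the scaffolds split at
#'   N gaps
#' @param genes optional gene tibble (gene statistics reported when given)
#' @param reads optional paired-end read tibble (mapping statistics and the
#'   consistency score reported when given)
#' @param libraries library tibble (required with `reads`)
#' @param genome_size known genome size; defaults to the truth length
#' @param gene_sized_min minimum length of a "gene-sized" sequence (bp)
#' @return an `assembly_eval` tibble (`stat`, `value`, `orientation`) with
#'   `placements` and `events` attributes
#' @export
evaluate_assembly <- function(scaffolds, truth, contigs = NULL, genes = NULL,
                              reads = NULL, libraries = NULL,
                              genome_size = NULL, gene_sized_min = 1200L) {
  genome_size <- genome_size %||% sum(nchar(truth$seq))
  contigs <- contigs %||% split_scaffolds_at_gaps(scaffolds)
  tindex <- build_index(truth, 15L)
  pl_sc <- align_to_truth(scaffolds, tindex)
  pl_ct <- align_to_truth(contigs, tindex)
  mis_sc <- classify_misassemblies(pl_sc, scaffolds)
  mis_ct <- classify_misassemblies(pl_ct, contigs)
  cng <- corrected_ng50(scaffolds, mis_sc$events, genome_size)
  comp <- compass_metrics(scaffolds, truth, pl_sc)
  clen <- nchar(contigs$seq); slen <- nchar(scaffolds$seq)
  unaligned <- setdiff(scaffolds$id, pl_sc$scaffold_id)
  add <- function(df, stat, value, orientation) {
    dplyr::bind_rows(df, tibble::tibble(stat = stat, value = as.numeric(value),
                                        orientation = orientation))
  }
  st <- tibble::tibble(stat = character(), value = numeric(),
                       orientation = character())
  st <- add(st, "n_contigs", length(clen), "lower")
  st <- add(st, "contig_n50", n50(clen), "higher")
  st <- add(st, "contig_ng50", ng50(clen, genome_size), "higher")
  st <- add(st, "contig_gene_sized_length_diff",
            abs(genome_size - sum(clen[clen >= gene_sized_min])), "lower")
  st <- add(st, "contig_misassemblies", mis_ct$summary$n_misassemblies, "lower")
  st <- add(st, "contig_duplication_ratio",
            duplication_ratio(pl_ct, truth), "near_one")
  st <- add(st, "n_scaffolds", length(slen), "lower")
  st <- add(st, "scaffold_n50", n50(slen), "higher")
  st <- add(st, "scaffold_length_diff", abs(genome_size - sum(slen)), "lower")
  st <- add(st, "scaffold_gene_sized_length_diff",
            abs(genome_size - sum(slen[slen >= gene_sized_min])), "lower")
  st <- add(st, "scaffold_ng50", ng50(slen, genome_size), "higher")
  st <- add(st, "corrected_ng50", cng$corrected_ng50, "higher")
  st <- add(st, "corrected_ng50_ratio", cng$ratio, "higher")
  st <- add(st, "ns_per_100kb", ns_per_100kb(scaffolds), "lower")
  st <- add(st, "scaffold_misassemblies", mis_sc$summary$n_misassemblies,
            "lower")
  st <- add(st, "pct_misassembled_scaffolds",
            mis_sc$summary$pct_misassembled_scaffolds, "lower")
  st <- add(st, "pct_misassembled_length",
            mis_sc$summary$pct_misassembled_length, "lower")
  st <- add(st, "local_misassemblies", mis_sc$summary$n_local, "lower")
  st <- add(st, "pct_unaligned_scaffolds",
            if (nrow(scaffolds) == 0) 0 else
              100 * length(unaligned) / nrow(scaffolds), "lower")
  st <- add(st, "scaffold_duplication_ratio",
            duplication_ratio(pl_sc, truth), "near_one")
  st <- add(st, "indels_per_100kb", indels_per_100kb(pl_sc), "lower")
  st <- add(st, "compass_coverage", comp$coverage, "higher")
  st <- add(st, "compass_validity", comp$validity, "higher")
  st <- add(st, "compass_multiplicity", comp$multiplicity, "lower")
  st <- add(st, "compass_parsimony",
            if (is.finite(comp$parsimony)) comp$parsimony else 1e6, "lower")
  if (!is.null(genes)) {
    gr_sc <- gene_recovery(pl_sc, genes)
    gr_ct <- gene_recovery(pl_ct, genes)
    st <- add(st, "contig_covered_genes", gr_ct$covered_genes, "higher")
    st <- add(st, "scaffold_covered_genes", gr_sc$covered_genes, "higher")
    st <- add(st, "gene_recovery_full", gr_sc$n_full, "higher")
    st <- add(st, "gene_recovery_partial", gr_sc$n_partial, "higher")
  }
  if (!is.null(reads)) {
    stopifnot(!is.null(libraries))
    ms <- mapping_stats(reads, scaffolds, libraries)
    st <- add(st, "pct_reads_mapped", ms$pct_mapped, "higher")
    st <- add(st, "pct_mapped_q10", ms$pct_mapped_q10, "higher")
    st <- add(st, "pct_proper_q10", ms$pct_proper_q10, "higher")
    rp <- reapr_like_score(scaffolds, ms$alignments)
    st <- add(st, "reapr_errors", rp$n_errors, "lower")
    st <- add(st, "reapr_score", rp$score, "higher")
  }
  structure(st, placements = pl_sc, events = mis_sc$events,
            contig_placements = pl_ct,
            class = c("assembly_eval", class(st)))
}
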