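# Synthetic-data generator: heterozygous diploid haplotypes and Illumina-like
# paired-end / mate-pair reads, plus the rearranged diverged guide reference
# used to exercise the reference-guided pipeline.

#' Generate a random genome
#'
#' Draws uniform ACGT sequence, optionally seeding tandem copies of repeat
#' elements to mimic a repetitive plant-like genome.
#'
#' @param lengths integer vector of chromosome lengths (bp)
#' @param repeat_fraction approximate fraction of each chromosome covered by
#'   copies of a shared repeat family
#' @param repeat_unit length of the repeat element (bp)
#' @param seed optional RNG seed
#' @return a [seq_tbl()] with chromosomes `chr1`, `chr2`, ...
#' @export
random_genome <- function(lengths = 2e5, repeat_fraction = 0, repeat_unit = 500L,
                          seed = NULL) {
  with_seed_or_not(seed, {
    seqs <- vapply(lengths, function(L) {
      s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      if (repeat_fraction > 0) {
        unit <- sample(c("A", "C", "G", "T"), repeat_unit, replace = TRUE)
        n_copies <- max(1L, floor(L * repeat_fraction / repeat_unit))
        starts <- sort(sample.int(L - repeat_unit, n_copies))
        for (st in starts) s[st:(st + repeat_unit - 1L)] <- unit
      }
      paste(s, collapse = "")
    }, "")
    seq_tbl(paste0("chr", seq_along(lengths)), seqs)
  })
}

#' Mutate a genome into a heterozygous haplotype
#'
#' Every non-N base is independently substituted with probability `rate` by
#' one of the three other bases chosen uniformly; N positions are untouched.
#' The default rate of 1% emulates a strongly heterozygous diploid.
#'
#' @param genome a [seq_tbl()]
#' @param rate per-base substitution probability in `[0, 1]`
#' @param seed optional RNG seed
#' @return list with `haplotype` (a [seq_tbl()]) and `mutations`
#'   (tibble `ref_id`, `pos` 0-based, `ref_base`, `alt_base`)
#' @export
mutate_genome <- function(genome, rate = 0.01, seed = NULL) {
  if (!is.numeric(rate) || rate < 0 || rate > 1) {
    stop("rate must be in [0, 1]")
  }
  with_seed_or_not(seed, {
    muts <- vector("list", nrow(genome))
    haps <- character(nrow(genome))
    # for each base code, the three possible substitutions
    alt_tab <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                     c("A", "C", "T"), c("A", "C", "G"))
    rownames(alt_tab) <- c("A", "C", "G", "T")
    for (i in seq_len(nrow(genome))) {
      s <- strsplit(genome$seq[i], "", fixed = TRUE)[[1]]
      eligible <- s != "N"
      hit <- eligible & (runif(length(s)) < rate)
      idx <- which(hit)
      if (length(idx) > 0) {
        ref_b <- s[idx]
        alt_b <- alt_tab[cbind(match(ref_b, rownames(alt_tab)), sample.int(3L, length(idx), replace = TRUE))]
        s[idx] <- alt_b
        muts[[i]] <- tibble::tibble(ref_id = genome$id[i], pos = idx - 1L,
                                    ref_base = ref_b, alt_base = alt_b)
      } else {
        muts[[i]] <- tibble::tibble(ref_id = character(), pos = integer(),
                                    ref_base = character(), alt_base = character())
      }
      haps[i] <- paste(s, collapse = "")
    }
    list(haplotype = seq_tbl(genome$id, haps, genome$desc),
         mutations = dplyr::bind_rows(muts))
  })
}

#' Construct a sequencing library specification
#'
#' @param library_id library name
#' @param kind `"PE"` (short-insert, FR orientation) or `"MP"` (long-insert
#'   jumping library, RF orientation)
#' @param insert_mean,insert_sd fragment length mean and standard deviation (bp)
#' @param read_len read length (bp)
#' @param coverage fold coverage contributed by this library
#' @return one-row tibble
#' @export
library_spec <- function(library_id, kind = c("PE", "MP"), insert_mean,
                         insert_sd, read_len = 100L, coverage = 10) {
  kind <- match.arg(kind)
  if (coverage <= 0) stop("coverage must be > 0")
  tibble::tibble(library_id = library_id, kind = kind,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 read_len = as.integer(read_len), coverage = coverage,
                 orientation = if (kind == "PE") "FR" else "RF")
}

#' The study's eight-library design
#'
#' Three paired-end libraries (inserts 150/200/400 bp, sd 34/36/87, coverage
#' 72/72/40x) and five mate-pair libraries (inserts 3/5/7/11/15 kb, sd 400,
#' coverage 76/82/104/44/40x), all 100 bp reads. `scale` multiplies every
#' coverage; `scale = 0.1` reproduces the low-coverage design.
#'
#' @param scale coverage multiplier in `(0, 1]`
#' @return library tibble with one row per library
#' @export
paper_libraries <- function(scale = 1) {
  if (!is.numeric(scale) || scale <= 0 || scale > 1) {
    stop("scale must be in (0, 1]")
  }
  dplyr::bind_rows(
    library_spec("pe150", "PE", 150, 34, 100L, 72 * scale),
    library_spec("pe200", "PE", 200, 36, 100L, 72 * scale),
    library_spec("pe400", "PE", 400, 87, 100L, 40 * scale),
    library_spec("mp3k", "MP", 3000, 400, 100L, 76 * scale),
    library_spec("mp5k", "MP", 5000, 400, 100L, 82 * scale),
    library_spec("mp7k", "MP", 7000, 400, 100L, 104 * scale),
    library_spec("mp11k", "MP", 11000, 400, 100L, 44 * scale),
    library_spec("mp15k", "MP", 15000, 400, 100L, 40 * scale))
}

# draw per-base substitution errors into a batch of read sequences
apply_errors <- function(seqs, rate_profile) {
  if (length(rate_profile) == 1 && rate_profile[1] <= 0) return(seqs)
  lens <- nchar(seqs)
  alt_tab <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                   c("A", "C", "T"), c("A", "C", "G"))
  rownames(alt_tab) <- c("A", "C", "G", "T")
  if (length(rate_profile) == 1) {
    n_err <- rbinom(length(seqs), lens, rate_profile)
    hit <- which(n_err > 0)
    for (i in hit) {
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      pos <- sample.int(lens[i], n_err[i])
      ok <- ch[pos] != "N"
      pos <- pos[ok]
      if (length(pos) > 0) {
        ch[pos] <- alt_tab[cbind(match(ch[pos], rownames(alt_tab)), sample.int(3L, length(pos), TRUE))]
        seqs[i] <- paste(ch, collapse = "")
      }
    }
  } else {
    # position-dependent rates (profile recycled/truncated to read length)
    for (i in seq_along(seqs)) {
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      r <- rep_len(rate_profile, length(ch))
      pos <- which(runif(length(ch)) < r & ch != "N")
      if (length(pos) > 0) {
        ch[pos] <- alt_tab[cbind(match(ch[pos], rownames(alt_tab)), sample.int(3L, length(pos), TRUE))]
        seqs[i] <- paste(ch, collapse = "")
      }
    }
  }
  seqs
}

#' Simulate Illumina-like reads from one or two haplotypes
#'
#' Fragment starts are uniform; insert lengths are normal, truncated to
#' `[2, contig length]`. Paired-end pairs are emitted FR, mate-pair pairs RF
#' (or FR when `mp_as_fr = TRUE`). With two haplotypes, fragments alternate
#' between them so each contributes half the pairs. Base qualities encode the
#' substitution error rate as `Q = -10 log10(rate)` (capped at 40).
#'
#' @param haplotypes a [seq_tbl()] or a list of one or two of them
#' @param library one-row library tibble from [library_spec()]
#' @param error_rate flat per-base substitution error rate, or a vector of
#'   per-position rates along the read
#' @param seed optional RNG seed
#' @param mp_as_fr emit mate-pair reads already reverse-complemented to FR
#' @return list with `reads` (read tibble) and `truth` (tibble of true
#'   placements: `read_id`, `mate`, `hap`, `ref_id`, `start`, `end`, `strand`)
#' @export
simulate_reads <- function(haplotypes, library, error_rate = 0.002,
                           seed = NULL, mp_as_fr = FALSE) {
  if (is.data.frame(haplotypes)) haplotypes <- list(haplotypes)
  stopifnot(length(haplotypes) >= 1, length(haplotypes) <= 2)
  rl <- library$read_len[1]
  is_mp <- library$kind[1] == "MP"
  with_seed_or_not(seed, {
    contigs <- haplotypes[[1]]
    keep <- nchar(contigs$seq) >= rl
    if (!all(keep)) {
      warning("skipping ", sum(!keep), " contig(s) shorter than read_len")
    }
    total_len <- sum(nchar(contigs$seq[keep]))
    n_pairs <- max(1L, round(library$coverage[1] * total_len / (2 * rl)))
    hap_of <- rep_len(seq_along(haplotypes), n_pairs)
    clens <- nchar(contigs$seq[keep])
    cids <- contigs$id[keep]
    contig_of <- sample(seq_along(cids), n_pairs, replace = TRUE,
                        prob = clens / sum(clens))
    ins <- round(rnorm(n_pairs, library$insert_mean[1], library$insert_sd[1]))
    ins <- pmin(pmax(ins, 2L), clens[contig_of])
    start <- floor(runif(n_pairs) * (clens[contig_of] - ins + 1))
    l1 <- pmin(rl, ins)
    l2 <- pmin(rl, ins)
    seqs_by_hap <- lapply(haplotypes, function(h) setNames(h$seq, h$id))
    r1 <- character(n_pairs); r2 <- character(n_pairs)
    for (h in seq_along(haplotypes)) {
      sel <- which(hap_of == h)
      if (length(sel) == 0) next
      hs <- seqs_by_hap[[h]][cids[contig_of[sel]]]
      r1[sel] <- substr(hs, start[sel] + 1L, start[sel] + l1[sel])
      r2[sel] <- substr(hs, start[sel] + ins[sel] - l2[sel] + 1L,
                        start[sel] + ins[sel])
    }
    r2 <- revcomp(r2)           # FR orientation
    if (is_mp && !mp_as_fr) {   # RF: both mates flipped
      r1 <- revcomp(r1)
      r2 <- revcomp(r2)
    }
    rid <- sprintf("%s_%07d", library$library_id[1], seq_len(n_pairs))
    r1 <- apply_errors(r1, error_rate)
    r2 <- apply_errors(r2, error_rate)
    mean_rate <- mean(rep_len(error_rate, rl))
    q <- if (mean_rate <= 0) 40L else min(40L, round(-10 * log10(mean_rate)))
    qstr1 <- vapply(l1, function(n) strrep(intToUtf8(q + 33L), n), "")
    qstr2 <- vapply(l2, function(n) strrep(intToUtf8(q + 33L), n), "")
    reads <- tibble::tibble(
      read_id = rep(rid, 2L),
      mate = rep(c(1L, 2L), each = n_pairs),
      seq = c(r1, r2), qual = c(qstr1, qstr2),
      library_id = library$library_id[1])
    s1 <- ifelse(rep(is_mp && !mp_as_fr, n_pairs), "-", "+")
    s2 <- ifelse(s1 == "+", "-", "+")
    tstart <- c(start, start + ins - l2)
    tend <- c(start + l1, start + ins)
    truth <- tibble::tibble(
      read_id = rep(rid, 2L),
      mate = rep(c(1L, 2L), each = n_pairs),
      hap = rep(hap_of, 2L),
      ref_id = rep(cids[contig_of], 2L),
      start = tstart,
      end = tend,
      strand = c(s1, s2),
      library_id = library$library_id[1])
    list(reads = reads, truth = truth)
  })
}

#' Simulate the full heterozygous multi-library design
#'
#' Builds a second haplotype by substituting 1% of non-N bases, then simulates
#' every library in [paper_libraries()] with half the pairs drawn from each
#' haplotype.
#'
#' @param genome truth genome as a [seq_tbl()]
#' @param scale coverage multiplier in `(0, 1]`
#' @param het_rate heterozygosity (per-base substitution rate of haplotype 2)
#' @param error_rate sequencing error rate passed to [simulate_reads()]
#' @param seed optional RNG seed
#' @param libraries custom library tibble; defaults to [paper_libraries()]
#' @return list with `libraries`, `reads`, `truth`, `mutations`, `haplotypes`
#' @export
paper_profile <- function(genome, scale = 1, het_rate = 0.01,
                          error_rate = 0.002, seed = NULL, libraries = NULL) {
  libs <- libraries %||% paper_libraries(scale)
  with_seed_or_not(seed, {
    mut <- mutate_genome(genome, het_rate)
    haps <- list(genome, mut$haplotype)
    sims <- lapply(seq_len(nrow(libs)), function(i) {
      simulate_reads(haps, libs[i, ], error_rate = error_rate)
    })
    list(libraries = libs,
         reads = dplyr::bind_rows(lapply(sims, `[[`, "reads")),
         truth = dplyr::bind_rows(lapply(sims, `[[`, "truth")),
         mutations = mut$mutations,
         haplotypes = haps)
  })
}

#' Derive a diverged, rearranged guide reference from a genome
#'
#' Emulates the genome of a related species: substitutes bases at the given
#' divergence, cuts the genome into segments, shuffles them across output
#' chromosomes and inverts a fraction — so the guide differs from the target
#' by point divergence and large-scale rearrangement, never by sharing
#' coordinates.
#'
#' @param genome truth genome as a [seq_tbl()]
#' @param divergence per-base substitution rate between species
#' @param n_segments number of segments to shuffle
#' @param inversion_prob probability a segment is inverted
#' @param n_chrom number of chromosomes in the output reference
#' @param seed optional RNG seed
#' @return a [seq_tbl()] with chromosomes `ref1`, `ref2`, ...
#' @export
diverged_reference <- function(genome, divergence = 0.05, n_segments = 8L,
                               inversion_prob = 0.3, n_chrom = 2L, seed = NULL) {
  with_seed_or_not(seed, {
    div <- mutate_genome(genome, divergence)$haplotype
    pieces <- character(0)
    for (i in seq_len(nrow(div))) {
      L <- nchar(div$seq[i])
      nseg <- max(1L, round(n_segments * L / sum(nchar(div$seq))))
      cuts <- sort(sample.int(L - 1L, min(nseg - 1L, L - 2L)))
      bounds <- unique(c(0L, cuts, L))
      segs <- substring(div$seq[i], head(bounds, -1) + 1L, tail(bounds, -1))
      pieces <- c(pieces, segs)
    }
    pieces <- pieces[sample.int(length(pieces))]
    flip <- runif(length(pieces)) < inversion_prob
    pieces[flip] <- revcomp(pieces[flip])
    chrom_of <- rep_len(seq_len(n_chrom), length(pieces))
    out <- vapply(seq_len(n_chrom), function(ch) {
      paste(pieces[chrom_of == ch], collapse = "")
    }, "")
    keep <- nzchar(out)
    seq_tbl(paste0("ref", seq_len(n_chrom))[keep], out[keep])
  })
}

#' Draw synthetic gene intervals on a genome
#'
#' Gene-sized intervals used by the gene-recovery evaluation statistics.
#'
#' @param genome a [seq_tbl()]
#' @param n number of genes
#' @param mean_len,sd_len gene length distribution (bp)
#' @param seed optional RNG seed
#' @return tibble with `gene_id`, `ref_id`, `start`, `end` (0-based half-open)
#' @export
random_genes <- function(genome, n = 50L, mean_len = 1500, sd_len = 300,
                         seed = NULL) {
  with_seed_or_not(seed, {
    clens <- nchar(genome$seq)
    contig <- sample(seq_len(nrow(genome)), n, replace = TRUE,
                     prob = clens / sum(clens))
    len <- pmax(200L, round(rnorm(n, mean_len, sd_len)))
    len <- pmin(len, clens[contig] - 1L)
    start <- floor(runif(n) * (clens[contig] - len))
    tibble::tibble(gene_id = sprintf("gene%04d", seq_len(n)),
                   ref_id = genome$id[contig],
                   start = as.integer(start),
                   end = as.integer(start + len))
  })
}

#' Write simulator truth placements to a TSV file
#'
#' @param truth truth tibble from [simulate_reads()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a mutation set as a minimal VCF-like file
#'
#' @param mutations mutation tibble from [mutate_genome()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_mutations <- function(mutations, path) {
  lines <- c("##fileformat=VCFv4.2",
             "#CHROM\tPOS\tID\tREF\tALT",
             sprintf("%s\t%d\t.\t%s\t%s", mutations$ref_id,
                     mutations$pos + 1L, mutations$ref_base,
                     mutations$alt_base))
  writeLines(lines, path)
  invisible(path)
}
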