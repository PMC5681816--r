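# Seed-and-extend mapper: index, alignment, mapping quality, proper pairs.

test_that("build_index indexes every non-N k-mer of both strands", {
  ref <- seq_tbl("r", "ACGTACGGTACCGATTGCAA")
  idx <- build_index(ref, k = 15)
  expect_equal(idx$n_fwd, 6)  # 20 - 15 + 1
  expect_equal(idx$n_rev, 6)
  # reverse complement of an indexed k-mer is indexed at the same position
  # on the minus strand
  km <- substr(ref$seq, 1, 15)
  hits <- index_lookup(idx, c(km, revcomp(km)))
  expect_equal(hits$pos[hits$kmer == 1 & hits$strand == "+"], 0)
  expect_equal(hits$pos[hits$kmer == 2 & hits$strand == "-"], 0)
})

test_that("an all-N reference yields an empty index", {
  idx <- build_index(seq_tbl("n", strrep("N", 100)), k = 15)
  expect_equal(idx$n_fwd, 0)
})

test_that("build_index validates k", {
  ref <- seq_tbl("r", strrep("ACGT", 20))
  expect_error(build_index(ref, 14), "odd")
  expect_error(build_index(ref, 7), "between")
})

test_that("a unique exact read maps at truth with mapq 60 and all-M cigar", {
  set.seed(31)
  ref <- random_genome(5000, seed = 31)
  idx <- build_index(ref, 15)
  read <- tibble::tibble(read_id = "r", mate = 1L,
                         seq = substr(ref$seq, 1001, 1100),
                         qual = strrep("I", 100), library_id = "l")
  for (mode in c("local", "sensitive")) {
    a <- map_reads(read, idx, mode = mode)
    expect_false(a$unmapped)
    expect_equal(a$pos, 1000L)
    expect_equal(a$strand, "+")
    expect_equal(a$mapq, 60L)
    expect_equal(a$cigar, "100M")
    expect_equal(a$score, 200L)
  }
  # reverse-complemented read maps to the minus strand at the same interval
  rc <- read; rc$seq <- revcomp(read$seq)
  a <- map_reads(rc, idx, mode = "local")
  expect_equal(a$pos, 1000L)
  expect_equal(a$strand, "-")
})

test_that("a read matching two identical loci gets mapq 0", {
  core <- random_genome(300, seed = 32)$seq
  filler <- random_genome(c(500, 500), seed = 33)
  ref <- seq_tbl("r", paste0(filler$seq[1], core, filler$seq[2], core))
  read <- tibble::tibble(read_id = "r", mate = 1L,
                         seq = substr(core, 50, 149),
                         qual = strrep("I", 100), library_id = "l")
  a <- map_reads(read, ref)
  expect_false(a$unmapped)
  expect_equal(a$mapq, 0L)
})

test_that("a random read against an unrelated reference stays unmapped", {
  ref <- random_genome(5000, seed = 34)
  other <- random_genome(200, seed = 35)
  read <- tibble::tibble(read_id = "r", mate = 1L,
                         seq = substr(other$seq, 1, 100),
                         qual = strrep("I", 100), library_id = "l")
  a <- map_reads(read, ref)
  expect_true(a$unmapped)
})

test_that("alignment scores equal re-scoring the cigar against the reference", {
  # independent oracle: walk the cigar, re-score with the mapper's constants
  rescore <- function(cigar, seq, strand, pos, refseq) {
    if (strand == "-") seq <- revcomp(seq)
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDS]", cigar))[[1]]
    qp <- 0L; rp <- pos; sc <- 0L
    for (op in ops) {
      n <- as.integer(sub("[MIDS]", "", op))
      t <- sub("[0-9]+", "", op)
      if (t == "M") {
        for (x in seq_len(n)) {
          qb <- substr(seq, qp + x, qp + x)
          rb <- substr(refseq, rp + x, rp + x)
          sc <- sc + if (qb == rb) 2L else -3L
        }
        qp <- qp + n; rp <- rp + n
      } else if (t == "I") { sc <- sc - 5L - 2L * (n - 1L); qp <- qp + n }
      else if (t == "D") { sc <- sc - 5L - 2L * (n - 1L); rp <- rp + n }
      else qp <- qp + n
    }
    sc
  }
  g <- random_genome(20000, seed = 36)
  m <- mutate_genome(g, 0.03, seed = 37)  # mismatches force partial scores
  lib <- library_spec("pe", "PE", 300, 30, 100L, 3)
  sim <- simulate_reads(m$haplotype, lib, error_rate = 0, seed = 38)
  a <- map_reads(sim$reads[1:120, ], g, mode = "local")
  a <- a[!a$unmapped, ]
  ora <- vapply(seq_len(nrow(a)), function(i) {
    rescore(a$cigar[i], a$seq[i], a$strand[i], a$pos[i], g$seq)
  }, 0L)
  expect_equal(a$score, ora)
})

test_that("the mapper recovers truth placements of error-free reads", {
  g <- random_genome(30000, seed = 39)
  lib <- library_spec("pe", "PE", 300, 30, 100L, 10)
  sim <- simulate_reads(g, lib, error_rate = 0, seed = 40)
  a <- map_reads(sim$reads, g, mode = "local")
  rec <- placement_recovery(a, sim$truth)
  expect_gte(rec$recovery, 0.99)
})

test_that("sensitive mode refuses clipped alignments that local mode accepts", {
  ref <- random_genome(4000, seed = 41)
  chim <- paste0(substr(ref$seq, 501, 560),
                 substr(random_genome(200, seed = 42)$seq, 1, 40))
  read <- tibble::tibble(read_id = "r", mate = 1L, seq = chim,
                         qual = strrep("I", 100), library_id = "l")
  loc <- map_reads(read, ref, mode = "local")
  sen <- map_reads(read, ref, mode = "sensitive")
  expect_false(loc$unmapped)
  expect_match(loc$cigar, "S")
  expect_gt(loc$score, sen$score * (!sen$unmapped))
})

test_that("pair_and_flag applies orientation and insert-window rules", {
  libs <- library_spec("pe", "PE", 300, 30, 100L, 10)
  mk <- function(pos1, pos2, s1 = "+", s2 = "-", ref2 = "chr1") {
    dplyr::bind_rows(
      aln_row("p", 1L, "chr1", pos1, s1, "100M", library_id = "pe"),
      aln_row("p", 2L, ref2, pos2, s2, "100M", library_id = "pe"))
  }
  # FR with insert exactly the mean
  a <- pair_and_flag(mk(1000L, 1200L), libs)
  expect_true(all(a$proper_pair))
  expect_equal(a$mate_pos, c(1200L, 1000L))
  # mates on different references
  expect_false(any(pair_and_flag(mk(1000L, 1200L, ref2 = "chr2"),
                                 libs)$proper_pair))
  # insert beyond mean + 4 sd
  expect_false(any(pair_and_flag(mk(1000L, 1000L + 300L + 5L * 30L),
                                 libs)$proper_pair))
  # wrong orientation (RF for a PE library)
  expect_false(any(pair_and_flag(mk(1000L, 1200L, s1 = "-", s2 = "+"),
                                 libs)$proper_pair))
  # MP library expects RF
  mlib <- library_spec("mp", "MP", 3000, 300, 100L, 10)
  mpa <- dplyr::bind_rows(
    aln_row("p", 1L, "chr1", 1000L, "-", "100M", library_id = "mp"),
    aln_row("p", 2L, "chr1", 3900L, "+", "100M", library_id = "mp"))
  expect_true(all(pair_and_flag(mpa, mlib)$proper_pair))
})
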