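# Homology-guided redundancy removal: anchoring, layout, consensus.

test_that("an exact reference substring anchors at truth with zero trims", {
  ref <- random_genome(10000, seed = 71)
  ctg <- tibble::tibble(id = "e", seq = substr(ref$seq, 1001, 3000))
  an <- anchor_contigs(ctg, ref)
  expect_equal(nrow(an$tiles), 1L)
  expect_equal(an$tiles$ref_start, 1000L)
  expect_equal(an$tiles$ref_end, 3000L)
  expect_equal(an$tiles$strand, "+")
  expect_equal(an$tiles$trim_left + an$tiles$trim_right, 0L)
})

test_that("unalignable overhangs up to max_trim are trimmed, beyond unplaced", {
  ref <- random_genome(10000, seed = 72)
  tails <- random_genome(c(500, 1500), seed = 73)
  ok <- tibble::tibble(id = "t500",
                       seq = paste0(substr(ref$seq, 2001, 5000),
                                    tails$seq[1]))
  an <- anchor_contigs(ok, ref)
  expect_equal(nrow(an$tiles), 1L)
  # a random tail can extend the last exact anchor by a base or two
  expect_lte(abs(an$tiles$trim_right - 500L), 3L)
  expect_lte(an$tiles$trim_left, 3L)
  over <- tibble::tibble(id = "t1500",
                         seq = paste0(substr(ref$seq, 2001, 5000),
                                      tails$seq[2]))
  an2 <- anchor_contigs(over, ref)
  expect_equal(nrow(an2$tiles), 0L)
  expect_equal(an2$unplaced, "t1500")
})

test_that("report_unplaced partitions the contig set", {
  ref <- random_genome(8000, seed = 74)
  ctg <- tibble::tibble(
    id = c("good", "junk"),
    seq = c(substr(ref$seq, 1, 3000), random_genome(2000, seed = 75)$seq))
  an <- anchor_contigs(ctg, ref)
  up <- report_unplaced(ctg, an$tiles)
  expect_equal(up, "junk")
  expect_setequal(c(an$tiles$contig_id, up), ctg$id)
})

test_that("two identical co-placed contigs merge into one supercontig", {
  ref <- random_genome(6000, seed = 76)
  s <- substr(ref$seq, 501, 4500)
  ctg <- tibble::tibble(id = c("a", "b"), seq = c(s, s))
  mr <- merge_reduce(ctg, ref)
  expect_equal(nrow(mr$supercontigs), 1L)
  expect_equal(mr$supercontigs$seq, s)
})

test_that("the 10 bp minimum overlap separates merge from break", {
  ref <- random_genome(9000, seed = 77)
  mk <- function(ov) {
    tibble::tibble(id = c("l", "r"),
                   seq = c(substr(ref$seq, 1, 4000),
                           substr(ref$seq, 4001 - ov, 8000)))
  }
  merged <- merge_reduce(mk(10), ref)$supercontigs
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$seq, substr(ref$seq, 1, 8000))
  split <- merge_reduce(mk(9), ref)$supercontigs
  expect_equal(nrow(split), 2L)
})

test_that("tiling fragments with 10 bp overlaps rebuild each reference", {
  refs <- random_genome(c(12000, 8000), seed = 78)
  pieces <- list()
  for (r in 1:2) {
    L <- nchar(refs$seq[r])
    starts <- seq(1, L - 2000, by = 1990)  # 10 bp overlaps
    for (s in starts) {
      e <- min(s + 1999, L)
      pieces[[length(pieces) + 1L]] <- tibble::tibble(
        id = sprintf("f_%d_%d", r, s),
        seq = substr(refs$seq[r], s, e))
    }
    if (max(starts) + 1999 < L) {
      # 400 bp tail: overlaps the previous piece and clears the minimum
      # anchor-chain score
      pieces[[length(pieces) + 1L]] <- tibble::tibble(
        id = sprintf("f_%d_tail", r),
        seq = substr(refs$seq[r], L - 399, L))
    }
  }
  ctg <- dplyr::bind_rows(pieces)
  mr <- merge_reduce(ctg, refs)
  expect_equal(nrow(mr$supercontigs), 2L)
  expect_setequal(mr$supercontigs$seq, refs$seq)
})

test_that("consensus writes contig bases, never reference bases", {
  ref <- random_genome(8000, seed = 79)
  target <- mutate_genome(ref, 0.04, seed = 80)$haplotype
  ctg <- tibble::tibble(
    id = c("a", "b"),
    seq = c(substr(target$seq, 1, 4500), substr(target$seq, 4001, 8000)))
  mr <- merge_reduce(ctg, ref)
  expect_equal(nrow(mr$supercontigs), 1L)
  sc <- mr$supercontigs$seq
  m_target <- refguide:::cpp_banded_matches(sc, target$seq, 50)
  m_ref <- refguide:::cpp_banded_matches(sc, ref$seq, 50)
  expect_gt(m_target / nchar(sc), 0.999)
  expect_lt(m_ref / nchar(sc), 0.97)
})

test_that("majority vote corrects a minority base among co-placed contigs", {
  ref <- random_genome(5000, seed = 81)
  s <- substr(ref$seq, 1, 4000)
  bad <- s
  substr(bad, 2000, 2000) <- if (substr(s, 2000, 2000) == "A") "C" else "A"
  ctg <- tibble::tibble(id = c("a", "b", "c"), seq = c(s, s, bad))
  mr <- merge_reduce(ctg, ref)
  expect_equal(mr$supercontigs$seq, s)
})

test_that("reverse-strand contigs are laid out correctly", {
  ref <- random_genome(6000, seed = 82)
  ctg <- tibble::tibble(
    id = c("f", "r"),
    seq = c(substr(ref$seq, 1, 3500), revcomp(substr(ref$seq, 3001, 6000))))
  an <- anchor_contigs(ctg, ref)
  expect_equal(an$tiles$strand, c("+", "-"))
  mr <- merge_reduce(ctg, ref)
  expect_equal(mr$supercontigs$seq, ref$seq)
})

test_that("supercontig count never exceeds tile count on clean layouts", {
  set.seed(83)
  ref <- random_genome(20000, seed = 83)
  starts <- sort(sample(1:16000, 8))
  ctg <- tibble::tibble(id = sprintf("c%d", seq_along(starts)),
                        seq = substr(rep(ref$seq, length(starts)),
                                     starts, starts + 3999))
  mr <- merge_reduce(ctg, ref)
  expect_lte(nrow(mr$supercontigs), nrow(mr$tiles))
})
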