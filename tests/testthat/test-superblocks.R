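# Coverage blocks, proper-pair bridging, superblock construction,
# read partitioning.

test_that("call_blocks unions overlapping spans and separates gaps", {
  expect_equal(nrow(call_blocks(empty_aln <- aln_row("x")[0, ])), 0L)
  a <- dplyr::bind_rows(aln_row("r1", pos = 0L), aln_row("r2", pos = 50L))
  b <- call_blocks(a)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start, b$end), c(0L, 150L))
  expect_equal(b$n_reads, 2L)
  a2 <- dplyr::bind_rows(aln_row("r1", pos = 0L), aln_row("r2", pos = 200L))
  b2 <- call_blocks(a2)
  expect_equal(nrow(b2), 2L)
  expect_equal(b2$start, c(0L, 200L))
})

# n proper pairs bridging two continuously covered blocks [0,1000) and
# [2000,3000)
bridging_fixture <- function(n_bridge, proper = TRUE) {
  base <- dplyr::bind_rows(lapply(seq(0L, 900L, by = 100L), function(p) {
    dplyr::bind_rows(aln_row(sprintf("a%04d", p), pos = p),
                     aln_row(sprintf("b%04d", p), pos = 2000L + p))
  }))
  pairs <- dplyr::bind_rows(lapply(seq_len(n_bridge), function(i) {
    dplyr::bind_rows(
      aln_row(sprintf("p%02d", i), 1L, pos = 850L, proper_pair = proper),
      aln_row(sprintf("p%02d", i), 2L, pos = 2050L, proper_pair = proper))
  }))
  dplyr::bind_rows(base, pairs)
}

test_that("blocks merge at 10 bridging proper pairs and not at 9", {
  p <- superblock_params()
  a10 <- bridging_fixture(10)
  b10 <- bridge_blocks(call_blocks(a10), a10, p)
  expect_equal(nrow(b10), 1L)
  expect_equal(c(b10$start, b10$end), c(0L, 3000L))
  a9 <- bridging_fixture(9)
  expect_equal(nrow(bridge_blocks(call_blocks(a9), a9, p)), 2L)
  imp <- bridging_fixture(20, proper = FALSE)
  expect_equal(nrow(bridge_blocks(call_blocks(imp), imp, p)), 2L)
})

test_that("bridging is monotone in the pair threshold", {
  a <- bridging_fixture(10)
  blocks <- call_blocks(a)
  for (thr in c(5L, 10L, 11L, 20L)) {
    n <- nrow(bridge_blocks(blocks, a,
                            superblock_params(bridge_pairs = thr)))
    if (thr <= 10) expect_equal(n, 1L) else expect_equal(n, 2L)
  }
})

mk_blocks <- function(starts, ends, ref = "chr1") {
  tibble::tibble(ref_id = ref, start = as.integer(starts),
                 end = as.integer(ends), n_reads = 10L)
}

test_that("two 7 kb blocks combine into one superblock", {
  sb <- build_superblocks(mk_blocks(c(0, 7000), c(7000, 14000)))
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$end - sb$start, 14000L)
  expect_false(sb$terminal)
})

test_that("a 250 kb block splits into <=100 kb pieces with 300 bp overlaps", {
  sb <- build_superblocks(mk_blocks(0, 250000))
  expect_equal(nrow(sb), 3L)
  expect_true(all(sb$end - sb$start <= 100000))
  ov <- sb$end[-nrow(sb)] - sb$start[-1]
  expect_true(all(ov == 300L))
  expect_equal(sb$start[1], 0L)
  expect_equal(sb$end[nrow(sb)], 250000L)
})

test_that("a short trailing block becomes a terminal superblock", {
  # a lone 5 kb block at the end of a reference is kept as terminal
  sb2 <- build_superblocks(mk_blocks(0, 5000))
  expect_true(sb2$terminal)
  expect_equal(sb2$end - sb2$start, 5000L)
  # after a single huge block, the trailing block joins a superblock that
  # shares an exact min_overlap stretch of the previous one
  sb <- build_superblocks(mk_blocks(c(0, 20000), c(13000, 25000)))
  expect_equal(nrow(sb), 2L)
  expect_equal(sb$start[2], 13000L - 300L)
  expect_equal(sb$end[2], 25000L)
})

test_that("superblock lengths and overlaps hold over random block fixtures", {
  set.seed(51)
  p <- superblock_params()
  for (rep in 1:20) {
    n <- sample(3:25, 1)
    lens <- sample(500:20000, n, replace = TRUE)
    gaps <- sample(0:500, n, replace = TRUE)
    starts <- cumsum(c(0L, head(lens + gaps, -1)))
    sb <- build_superblocks(mk_blocks(starts, starts + lens), p)
    span <- sb$end - sb$start
    non_term <- !sb$terminal
    expect_true(all(span[non_term] >= p$min_len))
    expect_true(all(span <= p$max_len))
    if (nrow(sb) > 1) {
      ov <- sb$end[-nrow(sb)] - sb$start[-1]
      expect_true(all(ov >= p$min_overlap))
    }
  }
})

test_that("partition assigns mapped reads, unmapped mates and overlap zones", {
  sbs <- tibble::tibble(sb_id = c("s1", "s2"), ref_id = "chr1",
                        start = c(0L, 11700L), end = c(12000L, 24000L),
                        n_blocks = 1L, terminal = c(FALSE, TRUE))
  a <- dplyr::bind_rows(
    aln_row("in", 1L, pos = 500L), aln_row("in", 2L, pos = 700L),
    aln_row("um", 1L, pos = 5000L), aln_row("um", 2L, unmapped = TRUE),
    aln_row("ov", 1L, pos = 11850L),
    aln_row("far", 1L, pos = 20000L))
  ps <- partition_reads(sbs, a)
  expect_true(all(c("in/1", "in/2", "um/1", "um/2") %in% ps$read_keys[[1]]))
  expect_true("ov/1" %in% ps$read_keys[[1]])
  expect_true("ov/1" %in% ps$read_keys[[2]])
  expect_false("far/1" %in% ps$read_keys[[1]])
  expect_true("far/1" %in% ps$read_keys[[2]])
})

test_that("every read lands in a superblock or the unmapped pool", {
  g <- random_genome(40000, seed = 52)
  lib <- library_spec("pe", "PE", 300, 30, 100L, 8)
  sim <- simulate_reads(g, lib, error_rate = 0, seed = 53)
  a <- pair_and_flag(map_reads(sim$reads, g), lib)
  blocks <- bridge_blocks(call_blocks(a), a)
  sbs <- partition_reads(build_superblocks(blocks), a)
  un <- collect_unmapped(a)
  un_keys <- if (nrow(un) > 0) paste0(un$read_id, "/", un$mate) else character(0)
  assigned <- unique(c(unlist(sbs$read_keys), un_keys))
  expect_setequal(assigned, paste0(a$read_id, "/", a$mate))
})

test_that("collect_unmapped returns both-unmapped pairs and orphans", {
  a <- dplyr::bind_rows(
    aln_row("m", 1L), aln_row("m", 2L, pos = 200L),
    aln_row("u", 1L, unmapped = TRUE), aln_row("u", 2L, unmapped = TRUE))
  un <- collect_unmapped(a)
  expect_equal(sort(un$read_id), c("u", "u"))
  expect_equal(nrow(collect_unmapped(a[1:2, ])), 0L)
})
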