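# Rescue, pileup correction, link building, scaffolding.

test_that("rescue adds nothing when all reads map to the supercontigs", {
  g <- random_genome(8000, seed = 91)
  lib <- library_spec("pe", "PE", 300, 30, 100L, 10)
  sim <- simulate_reads(g, lib, error_rate = 0, seed = 92)
  res <- rescue_unmapped(sim$reads, tibble::tibble(id = g$id, seq = g$seq))
  expect_equal(nrow(res$rescued), 0L)
  expect_equal(nrow(res$supercontigs), 1L)
})

test_that("rescue recovers a region missing from the supercontigs", {
  g <- random_genome(20000, seed = 93)
  lib <- library_spec("pe", "PE", 300, 30, 100L, 20)
  sim <- simulate_reads(g, lib, error_rate = 0, seed = 94)
  # supercontigs lack the middle 5 kb
  partial <- tibble::tibble(id = c("left", "right"),
                            seq = c(substr(g$seq, 1, 7500),
                                    substr(g$seq, 12501, 20000)))
  res <- rescue_unmapped(sim$reads, partial, k = 31L)
  expect_gt(nrow(res$rescued), 0L)
  pl <- align_to_truth(res$rescued, g, min_segment = 400L)
  expect_gt(nrow(pl), 0L)
  covered <- sum(pl$rend - pl$rstart)
  expect_gt(covered, 3000)
  expect_true(all(pl$rstart > 7000 & pl$rend < 13000))
})

test_that("an empty supercontig set sends every read to the rescue assembly", {
  g <- random_genome(5000, seed = 95)
  sim <- simulate_reads(g, library_spec("pe", "PE", 300, 30, 100L, 15),
                        error_rate = 0, seed = 96)
  res <- rescue_unmapped(sim$reads,
                         tibble::tibble(id = character(), seq = character()))
  expect_gt(nrow(res$rescued), 0L)
})

test_that("a base contradicted by every covering read is corrected", {
  g <- random_genome(6000, seed = 97)
  reads <- tiling_reads(g$seq, step = 5L)
  bad <- g$seq
  substr(bad, 3000, 3000) <- if (substr(bad, 3000, 3000) == "A") "G" else "A"
  sc <- tibble::tibble(id = "sc1", seq = bad)
  aln <- map_reads(reads, seq_tbl(sc$id, sc$seq), mode = "sensitive")
  out <- correct_supercontigs(sc, aln)
  expect_equal(out$seq, g$seq)
  expect_gte(attr(out, "correction_stats")$n_substituted, 1L)
})

test_that("correction leaves majority-supported columns untouched", {
  g <- random_genome(6000, seed = 99)
  reads <- tiling_reads(g$seq, step = 5L)
  sc <- tibble::tibble(id = "sc1", seq = g$seq)
  aln <- map_reads(reads, seq_tbl(sc$id, sc$seq), mode = "sensitive")
  out <- correct_supercontigs(sc, aln)
  expect_equal(out$seq, g$seq)
  expect_equal(attr(out, "correction_stats")$n_substituted, 0L)
})

test_that("uncovered interior stretches split the supercontig", {
  g <- random_genome(12000, seed = 101)
  # reads only from the two flanks; middle 2 kb unsequenced
  reads <- dplyr::bind_rows(
    tiling_reads(substr(g$seq, 1, 5000), step = 5L),
    tiling_reads(substr(g$seq, 7001, 12000), step = 5L))
  reads$read_id <- sprintf("t%05d", seq_len(nrow(reads)))
  sc <- tibble::tibble(id = "sc1", seq = g$seq)
  aln <- map_reads(reads, seq_tbl(sc$id, sc$seq), mode = "sensitive")
  out <- correct_supercontigs(sc, aln)
  expect_equal(nrow(out), 2L)
  expect_true(all(grepl("^sc1_p", out$id)))
  expect_equal(out$seq, c(substr(g$seq, 1, 5000), substr(g$seq, 7001, 12000)))
})

test_that("pieces shorter than min_supercontig are discarded", {
  g <- random_genome(3000, seed = 103)
  reads <- dplyr::bind_rows(
    tiling_reads(substr(g$seq, 1, 150), read_len = 80L, step = 10L),
    tiling_reads(substr(g$seq, 501, 3000), read_len = 80L, step = 10L))
  reads$read_id <- sprintf("t%05d", seq_len(nrow(reads)))
  sc <- tibble::tibble(id = "sc1", seq = g$seq)
  aln <- map_reads(reads, seq_tbl(sc$id, sc$seq), mode = "sensitive")
  out <- correct_supercontigs(sc, aln)
  expect_equal(nrow(out), 1L)
  expect_true(all(nchar(out$seq) >= 200))
  expect_gte(attr(out, "correction_stats")$n_dropped, 1L)
})

link_fixture <- function(n_pairs, gap = 300L, seed = 105) {
  g <- random_genome(12000, seed = seed)
  a_end <- 6000L
  sc <- tibble::tibble(id = c("A", "B"),
                       seq = c(substr(g$seq, 1, a_end),
                               substr(g$seq, a_end + gap + 1, 12000)))
  lib <- library_spec("mp", "MP", 3000, 300, 100L,
                      coverage = n_pairs * 200 / 12000)
  sim <- simulate_reads(g, lib, error_rate = 0, seed = seed + 1L)
  aln <- map_reads(sim$reads, seq_tbl(sc$id, sc$seq), mode = "sensitive")
  aln <- pair_and_flag(aln, lib)
  list(genome = g, sc = sc, lib = lib, aln = aln,
       sc_len = setNames(nchar(sc$seq), sc$id))
}

test_that("bridging pairs become a single oriented link with a gap estimate", {
  fx <- link_fixture(150, gap = 300L)
  links <- build_links(fx$aln, fx$lib, fx$sc_len)
  expect_equal(nrow(links), 1L)
  expect_gte(links$n_pairs, 20)
  se <- 300 / sqrt(links$n_pairs)
  expect_lt(abs(links$gap - 300), 3 * se + 5)
  expect_equal(paste0(links$sc1, links$end1, links$sc2, links$end2), "ARBL")
})

test_that("links below min_link_pairs are dropped", {
  fx <- link_fixture(150)
  ids <- unique(fx$aln$read_id)[1:2]
  few <- fx$aln[fx$aln$read_id %in% ids, , drop = FALSE]
  links <- build_links(few, fx$lib, fx$sc_len)
  expect_equal(nrow(links), 0L)
})

test_that("scaffolding joins linked supercontigs across an N gap", {
  fx <- link_fixture(150, gap = 100L)
  links <- build_links(fx$aln, fx$lib, fx$sc_len)
  sc <- scaffold(fx$sc, links, fx$lib)
  expect_equal(nrow(sc$scaffolds), 1L)
  L <- nchar(sc$scaffolds$seq)
  expect_gt(L, 11800); expect_lt(L, 12400)
  expect_match(sc$scaffolds$seq, "N")
  # conservation: both supercontigs appear intact; non-N bases add up
  for (s in fx$sc$seq) {
    expect_true(grepl(s, sc$scaffolds$seq, fixed = TRUE) ||
                  grepl(revcomp(s), sc$scaffolds$seq, fixed = TRUE))
  }
  non_n <- nchar(gsub("N", "", sc$scaffolds$seq))
  expect_equal(non_n, sum(nchar(fx$sc$seq)))
})

test_that("gap closing replaces the N run by the unique read path", {
  g <- random_genome(12000, seed = 111)
  gap <- 100L
  sc <- tibble::tibble(id = c("A", "B"),
                       seq = c(substr(g$seq, 1, 6000),
                               substr(g$seq, 6000 + gap + 1, 12000)))
  lib <- library_spec("pe", "PE", 300, 30, 100L, 20)
  sim <- simulate_reads(g, lib, error_rate = 0, seed = 112)
  aln <- map_reads(sim$reads, seq_tbl(sc$id, sc$seq), mode = "sensitive")
  aln <- pair_and_flag(aln, lib)
  links <- build_links(aln, lib, setNames(nchar(sc$seq), sc$id))
  expect_equal(nrow(links), 1L)
  out <- scaffold(sc, links, lib, junction_reads = aln)
  expect_equal(nrow(out$scaffolds), 1L)
  expect_equal(out$stats$n_gaps_closed, 1L)
  expect_equal(out$scaffolds$seq, g$seq)
})

test_that("conflicting links are resolved towards the higher support", {
  sc <- tibble::tibble(id = c("A", "B", "C"),
                       seq = c(random_genome(5000, seed = 106)$seq,
                               random_genome(5000, seed = 107)$seq,
                               random_genome(5000, seed = 108)$seq))
  lib <- library_spec("mp", "MP", 3000, 300, 100L, 5)
  links <- tibble::tibble(
    sc1 = c("A", "A"), end1 = c("R", "R"), sc2 = c("B", "C"),
    end2 = c("L", "L"), n_pairs = c(10L, 4L), gap = c(100, 100),
    library_id = "mp")
  out <- scaffold(sc, links, lib)
  expect_equal(nrow(out$scaffolds), 2L)
  joined <- out$agp |> dplyr::count(scaffold_id) |> dplyr::filter(n == 2)
  parts <- out$agp$sc_id[out$agp$scaffold_id == joined$scaffold_id]
  expect_setequal(parts, c("A", "B"))
  expect_equal(out$stats$n_links_rejected, 1L)
})

test_that("scaffolds shorter than min_scaffold are discarded", {
  sc <- tibble::tibble(id = c("big", "tiny"),
                       seq = c(random_genome(5000, seed = 109)$seq,
                               random_genome(900, seed = 110)$seq))
  lib <- library_spec("mp", "MP", 3000, 300, 100L, 5)
  links <- tibble::tibble(sc1 = character(), end1 = character(),
                          sc2 = character(), end2 = character(),
                          n_pairs = integer(), gap = numeric(),
                          library_id = character())
  out <- scaffold(sc, links, lib)
  expect_equal(nrow(out$scaffolds), 1L)
  expect_equal(nchar(out$scaffolds$seq), 5000L)
})
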