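# Evaluation statistics: N50/NG50, truth placements, misassembly
# classification, COMPASS metrics, mapping rates, gene recovery.

test_that("n50 and ng50 match the worked examples", {
  expect_equal(n50(c(10, 10, 10)), 10)
  expect_equal(n50(c(5, 4, 3, 2, 1)), 4)
  expect_equal(ng50(c(5, 4, 3, 2, 1), 20), 3)
  expect_equal(n50(numeric(0)), 0)
  expect_equal(ng50(numeric(0), 100), 0)
  expect_equal(ng50(c(3, 2), 100), 0)  # assembly never reaches half the genome
})

test_that("n50 and ng50 agree with a brute-force oracle", {
  # oracle: explicit cumulative scan, written independently
  oracle_n50 <- function(lens, half) {
    s <- sort(lens, decreasing = TRUE)
    tot <- 0
    for (x in s) {
      tot <- tot + x
      if (tot >= half) return(x)
    }
    0
  }
  set.seed(121)
  for (i in 1:1000) {
    lens <- sample(1:5000, sample(1:40, 1), replace = TRUE)
    gs <- sample(1:(2 * sum(lens)), 1)
    expect_equal(n50(lens), oracle_n50(lens, sum(lens) / 2))
    expect_equal(ng50(lens, gs), oracle_n50(lens, gs / 2))
  }
})

test_that("align_to_truth decomposes scaffolds into co-linear segments", {
  truth <- random_genome(c(20000, 20000), seed = 122)
  # exact substring: one segment
  a1 <- tibble::tibble(id = "s", seq = substr(truth$seq[1], 2001, 8000))
  p1 <- align_to_truth(a1, truth)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$ref_id, "chr1")
  expect_lt(abs(p1$rstart - 2000), 20)
  expect_lt(abs(p1$rend - 8000), 20)
  expect_equal(p1$strand, "+")
  # chimera: two segments on different references
  a2 <- tibble::tibble(id = "chim",
                       seq = paste0(substr(truth$seq[1], 1, 5000),
                                    substr(truth$seq[2], 5001, 10000)))
  p2 <- align_to_truth(a2, truth)
  expect_equal(nrow(p2), 2L)
  expect_setequal(p2$ref_id, c("chr1", "chr2"))
  # random sequence: no segments
  a3 <- tibble::tibble(id = "junk", seq = random_genome(3000, seed = 123)$seq)
  expect_equal(nrow(align_to_truth(a3, truth)), 0L)
})

test_that("the truth genome evaluates to zero misassemblies", {
  truth <- random_genome(c(15000, 15000), seed = 124)
  asm <- tibble::tibble(id = truth$id, seq = truth$seq)
  pl <- align_to_truth(asm, truth)
  mis <- classify_misassemblies(pl, asm)
  expect_equal(nrow(mis$events), 0L)
  expect_equal(mis$summary$pct_misassembled_scaffolds, 0)
})

test_that("injected chimeras yield exactly the expected event types", {
  truth <- random_genome(c(30000, 30000), seed = 125)
  # translocation: chr1 piece + chr2 piece
  tr <- tibble::tibble(id = "tr",
                       seq = paste0(substr(truth$seq[1], 1, 6000),
                                    substr(truth$seq[2], 10001, 16000)))
  # relocation: two chr1 pieces 2 kb apart
  re <- tibble::tibble(id = "re",
                       seq = paste0(substr(truth$seq[1], 1, 6000),
                                    substr(truth$seq[1], 8001, 14000)))
  # inversion: chr1 piece + reverse-complemented adjacent chr1 piece
  iv <- tibble::tibble(id = "iv",
                       seq = paste0(substr(truth$seq[1], 1, 6000),
                                    revcomp(substr(truth$seq[1], 6001, 12000))))
  for (case in list(list(tr, "translocation"), list(re, "relocation"),
                    list(iv, "inversion"))) {
    pl <- align_to_truth(case[[1]], truth)
    mis <- classify_misassemblies(pl, case[[1]])
    expect_equal(nrow(mis$events), 1L, info = case[[2]])
    expect_equal(mis$events$type, case[[2]])
  }
})

test_that("corrected NG50 breaks scaffolds at misassembly breakpoints", {
  truth <- random_genome(c(30000, 30000), seed = 126)
  clean <- tibble::tibble(id = "ok", seq = substr(truth$seq[1], 1, 10000))
  pl <- align_to_truth(clean, truth)
  ev <- classify_misassemblies(pl, clean)$events
  cn <- corrected_ng50(clean, ev, 10000)
  expect_equal(cn$ratio, 1)
  expect_equal(cn$corrected_ng50, cn$raw_ng50)
  chim <- tibble::tibble(id = "chim",
                         seq = paste0(substr(truth$seq[1], 1, 5000),
                                      substr(truth$seq[2], 1, 5000)))
  plc <- align_to_truth(chim, truth)
  evc <- classify_misassemblies(plc, chim)$events
  cnc <- corrected_ng50(chim, evc, 10000)
  expect_lt(abs(cnc$corrected_ng50 - 5000), 50)
  expect_lte(cnc$ratio, 1)
})

test_that("compass metrics match their constructive cases", {
  truth <- random_genome(20000, seed = 127)
  exact <- tibble::tibble(id = "e", seq = truth$seq)
  cm <- compass_metrics(exact, truth)
  expect_equal(cm$coverage, 1, tolerance = 1e-3)
  expect_equal(cm$validity, 1, tolerance = 1e-3)
  expect_equal(cm$multiplicity, 1, tolerance = 1e-3)
  expect_equal(cm$parsimony, 1, tolerance = 1e-3)
  # duplicated assembly: coverage 1, multiplicity 2
  dup <- tibble::tibble(id = c("a", "b"), seq = c(truth$seq, truth$seq))
  cmd <- compass_metrics(dup, truth)
  expect_equal(cmd$coverage, 1, tolerance = 1e-3)
  expect_equal(cmd$multiplicity, 2, tolerance = 1e-3)
  # half-random assembly: validity 0.5, parsimony 2
  half <- tibble::tibble(id = "h",
                         seq = paste0(truth$seq,
                                      random_genome(20000, seed = 128)$seq))
  cmh <- compass_metrics(half, truth)
  expect_equal(cmh$validity, 0.5, tolerance = 5e-3)
  expect_equal(cmh$parsimony, 2, tolerance = 2e-2)
  # empty assembly
  cme <- compass_metrics(tibble::tibble(id = character(), seq = character()),
                         truth)
  expect_equal(cme$coverage, 0)
  expect_false(is.finite(cme$parsimony))
})

test_that("duplication ratio counts aligned bases per covered truth base", {
  truth <- random_genome(15000, seed = 129)
  dup <- tibble::tibble(id = c("a", "b"), seq = c(truth$seq, truth$seq))
  pl <- align_to_truth(dup, truth)
  expect_equal(duplication_ratio(pl, truth), 2, tolerance = 1e-3)
})

test_that("a perfect assembly maps all error-free reads", {
  g <- random_genome(20000, seed = 130)
  lib <- library_spec("pe", "PE", 300, 30, 100L, 5)
  sim <- simulate_reads(g, lib, error_rate = 0, seed = 131)
  ms <- mapping_stats(sim$reads, tibble::tibble(id = g$id, seq = g$seq), lib)
  expect_equal(ms$pct_mapped, 100)
  expect_gt(ms$pct_mapped_q10, 95)
  expect_gt(ms$pct_proper_q10, 90)
})

test_that("N content is reported per 100 kb", {
  asm <- tibble::tibble(id = "a",
                        seq = paste0(strrep("A", 9900), strrep("N", 100)))
  expect_equal(ns_per_100kb(asm), 1000)
  expect_equal(ns_per_100kb(tibble::tibble(id = "b", seq = "ACGT")), 0)
})

test_that("gene recovery distinguishes full from partial coverage", {
  truth <- random_genome(30000, seed = 132)
  genes <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                          ref_id = "chr1",
                          start = c(1000L, 10000L, 20000L),
                          end = c(2500L, 11500L, 21500L))
  # assembly covers g1 fully, g2 half, g3 not at all
  asm <- tibble::tibble(id = c("s1", "s2"),
                        seq = c(substr(truth$seq, 1, 5000),
                                substr(truth$seq, 9500, 10750)))
  pl <- align_to_truth(asm, truth)
  gr <- gene_recovery(pl, genes)
  expect_equal(gr$n_full, 1L)
  expect_equal(gr$n_partial, 2L)
  expect_equal(gr$n_genes, 3L)
})

test_that("the read-pair consistency score is 1 for a perfect assembly", {
  g <- random_genome(20000, seed = 133)
  lib <- library_spec("pe", "PE", 300, 30, 100L, 20)
  sim <- simulate_reads(g, lib, error_rate = 0, seed = 134)
  asm <- tibble::tibble(id = g$id, seq = g$seq)
  aln <- pair_and_flag(map_reads(sim$reads, g, mode = "sensitive"), lib)
  rp <- reapr_like_score(asm, aln)
  expect_equal(rp$n_errors, 0L)
  expect_equal(rp$score, 1)
})

test_that("a chimeric junction halves the consistency score", {
  g <- random_genome(c(20000, 20000), seed = 135)
  lib <- library_spec("pe", "PE", 300, 30, 100L, 20)
  sim <- simulate_reads(g, lib, error_rate = 0, seed = 136)
  chim <- tibble::tibble(id = "chim",
                         seq = paste0(g$seq[1], g$seq[2]))
  aln <- pair_and_flag(map_reads(sim$reads, seq_tbl(chim$id, chim$seq),
                                 mode = "sensitive"), lib)
  rp <- reapr_like_score(chim, aln)
  expect_gte(rp$n_errors, 1L)
  expect_lt(rp$score, 0.51)
  expect_gte(rp$score, 0)
})

test_that("evaluate_assembly returns the full oriented statistic registry", {
  g <- random_genome(20000, seed = 137)
  lib <- library_spec("pe", "PE", 300, 30, 100L, 8)
  sim <- simulate_reads(g, lib, error_rate = 0, seed = 138)
  genes <- random_genes(g, n = 10L, seed = 139)
  ev <- evaluate_assembly(tibble::tibble(id = g$id, seq = g$seq), g,
                          genes = genes, reads = sim$reads, libraries = lib)
  expect_equal(nrow(ev), 34L)
  expect_true(all(ev$orientation %in% c("higher", "lower", "near_one")))
  expect_true(all(is.finite(ev$value)))
  pct <- ev$value[grepl("^pct_", ev$stat)]
  expect_true(all(pct >= 0 & pct <= 100))
  expect_s3_class(ev, "assembly_eval")
  expect_true(!is.null(attr(ev, "placements")))
})
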