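# Diploid genome mutation and Illumina-like read simulation.

test_that("mutate_genome at rate 0 is the identity", {
  g <- random_genome(1000, seed = 1)
  m <- mutate_genome(g, 0)
  expect_equal(m$haplotype$seq, g$seq)
  expect_equal(nrow(m$mutations), 0L)
})

test_that("mutate_genome at rate 1 substitutes every non-N base", {
  g <- seq_tbl("c", "ACGNT")
  m <- mutate_genome(g, 1, seed = 3)
  h <- strsplit(m$haplotype$seq, "")[[1]]
  s <- strsplit(g$seq, "")[[1]]
  expect_true(all(h[s != "N"] != s[s != "N"]))
  expect_equal(h[4], "N")
  expect_equal(nrow(m$mutations), 4L)
  expect_true(all(m$mutations$ref_base != m$mutations$alt_base))
})

test_that("mutate_genome substitution count follows the binomial model", {
  g <- random_genome(1e5, seed = 4)
  m <- mutate_genome(g, 0.01, seed = 5)
  n <- nchar(g$seq)
  lo <- qbinom(5e-4, n, 0.01)
  hi <- qbinom(1 - 5e-4, n, 0.01)
  expect_gte(nrow(m$mutations), lo)
  expect_lte(nrow(m$mutations), hi)
  # positions unique, N untouched
  expect_false(anyDuplicated(m$mutations$pos) > 0)
})

test_that("mutate_genome rejects rates outside [0, 1]", {
  g <- seq_tbl("c", "ACGT")
  expect_error(mutate_genome(g, -0.1), "rate")
  expect_error(mutate_genome(g, 1.5), "rate")
})

test_that("error-free reads are exact substrings of the haplotype", {
  g <- random_genome(20000, seed = 6)
  lib <- library_spec("pe", "PE", 300, 30, 100L, 5)
  sim <- simulate_reads(g, lib, error_rate = 0, seed = 7)
  hits <- vapply(sim$reads$seq[1:200], function(s) {
    grepl(s, g$seq, fixed = TRUE) || grepl(revcomp(s), g$seq, fixed = TRUE)
  }, TRUE)
  expect_true(all(hits))
})

test_that("read count honours the coverage arithmetic", {
  g <- random_genome(50000, seed = 8)
  lib <- library_spec("pe", "PE", 300, 30, 100L, 10)
  sim <- simulate_reads(g, lib, error_rate = 0, seed = 9)
  expect_lte(abs(nrow(sim$reads) / 2 - 10 * 50000 / 200), 1)
})

test_that("two haplotypes contribute half the pairs each", {
  g <- random_genome(30000, seed = 10)
  m <- mutate_genome(g, 0.01, seed = 11)
  lib <- library_spec("pe", "PE", 300, 30, 100L, 20)
  sim <- simulate_reads(list(g, m$haplotype), lib, error_rate = 0, seed = 12)
  frac <- mean(sim$truth$hap == 1)
  expect_lt(abs(frac - 0.5), 0.01)  # alternating assignment is exact +- 1
})

test_that("observed insert sizes match the library model", {
  g <- random_genome(60000, seed = 13)
  lib <- library_spec("pe", "PE", 300, 30, 100L, 40)
  sim <- simulate_reads(g, lib, error_rate = 0, seed = 14)
  t1 <- sim$truth[sim$truth$mate == 1, ]
  t2 <- sim$truth[sim$truth$mate == 2, ]
  ins <- t2$end - t1$start
  expect_gte(length(ins), 1e4)
  se <- 30 / sqrt(length(ins))
  expect_lt(abs(mean(ins) - 300), 3 * se + 0.5)  # +0.5 for rounding to bp
})

test_that("substitution errors occur at the profile rate", {
  g <- random_genome(30000, seed = 15)
  lib <- library_spec("pe", "PE", 300, 30, 100L, 20)
  rate <- 0.005
  sim0 <- simulate_reads(g, lib, error_rate = 0, seed = 16)
  sim1 <- simulate_reads(g, lib, error_rate = rate, seed = 16)
  # same fragments (same seed): differences are exactly the injected errors
  n_err <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, sim0$reads$seq, sim1$reads$seq))
  n_bases <- sum(nchar(sim1$reads$seq))
  lo <- qbinom(5e-4, n_bases, rate); hi <- qbinom(1 - 5e-4, n_bases, rate)
  expect_gte(n_err, lo)
  expect_lte(n_err, hi)
  # qualities encode the error rate
  q <- utf8ToInt(substr(sim1$reads$qual[1], 1, 1)) - 33
  expect_equal(q, round(-10 * log10(rate)))
})

test_that("simulation is byte-identical under a fixed seed", {
  g <- random_genome(10000, seed = 17)
  lib <- library_spec("mp", "MP", 3000, 300, 100L, 5)
  a <- simulate_reads(g, lib, seed = 18)
  b <- simulate_reads(g, lib, seed = 18)
  expect_identical(a, b)
})

test_that("mate-pair reads map RF and paired-end reads FR", {
  g <- random_genome(20000, seed = 19)
  for (kind in c("PE", "MP")) {
    lib <- library_spec("l", kind, if (kind == "PE") 500 else 3000, 100,
                        100L, 3)
    sim <- simulate_reads(g, lib, error_rate = 0, seed = 20)
    t1 <- sim$truth[sim$truth$mate == 1, ][1, ]
    expect_equal(t1$strand, if (kind == "PE") "+" else "-")
  }
})

test_that("the library profile reproduces the eight-library design", {
  libs <- paper_libraries(1)
  expect_equal(libs$coverage, c(72, 72, 40, 76, 82, 104, 44, 40))
  expect_equal(libs$insert_mean,
               c(150, 200, 400, 3000, 5000, 7000, 11000, 15000))
  expect_equal(libs$insert_sd, c(34, 36, 87, 400, 400, 400, 400, 400))
  expect_equal(libs$kind, rep(c("PE", "MP"), c(3, 5)))
  low <- paper_libraries(0.1)
  expect_equal(low$coverage, libs$coverage / 10)
  expect_error(paper_libraries(0), "scale")
})

test_that("contigs shorter than the read length are skipped with a warning", {
  g <- seq_tbl(c("a", "b"), c(strrep("ACGT", 500), "ACGTACGT"))
  lib <- library_spec("pe", "PE", 300, 30, 100L, 2)
  expect_warning(sim <- simulate_reads(g, lib, seed = 21), "shorter")
  expect_true(all(sim$truth$ref_id == "a"))
})

test_that("the diverged reference differs by substitutions and rearrangement", {
  g <- random_genome(30000, seed = 22)
  ref <- diverged_reference(g, divergence = 0.05, n_segments = 6,
                            seed = 23)
  expect_equal(sum(nchar(ref$seq)), 30000)
  expect_false(any(ref$seq == g$seq))
})
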