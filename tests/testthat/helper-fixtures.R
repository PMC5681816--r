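# Shared fixtures, all generated in code. Expensive end-to-end runs are
# memoised in a helper environment so several tests can share one run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# exact tiling read pairs over a sequence (error free, constant quality)
tiling_reads <- function(seq, read_len = 100L, step = 5L, qual = 40L) {
  starts <- seq(0L, nchar(seq) - read_len, by = step)
  q <- strrep(intToUtf8(qual + 33L), read_len)
  tibble::tibble(
    read_id = sprintf("t%05d", seq_along(starts)),
    mate = 1L,
    seq = substr(rep(seq, length(starts)), starts + 1L, starts + read_len),
    qual = q, library_id = "tile")
}

# a minimal alignment tibble row; defaults describe a mapped 100M read
aln_row <- function(read_id, mate = 1L, ref_id = "chr1", pos = 0L,
                    strand = "+", cigar = "100M", mapq = 60L,
                    unmapped = FALSE, proper_pair = FALSE,
                    library_id = "pe", seq = NA_character_,
                    qual = NA_character_) {
  tibble::tibble(read_id = read_id, mate = mate,
                 ref_id = ifelse(unmapped, NA_character_, ref_id),
                 pos = ifelse(unmapped, NA_integer_, as.integer(pos)),
                 strand = ifelse(unmapped, NA_character_, strand),
                 cigar = ifelse(unmapped, NA_character_, cigar),
                 mapq = as.integer(mapq), score = NA_integer_,
                 paired = TRUE, proper_pair = proper_pair,
                 unmapped = unmapped, mate_unmapped = NA,
                 mate_ref_id = NA_character_, mate_pos = NA_integer_,
                 library_id = library_id, seq = seq, qual = qual)
}

# the diploid study conditions at desk scale: 200 kb heterozygous genome,
# 5%-diverged rearranged guide reference, one PE + one MP library
e2e_conditions <- function() {
  memo("e2e_conditions", {
    genome <- random_genome(2e5, seed = 101)
    reference <- diverged_reference(genome, divergence = 0.05,
                                    n_segments = 8, seed = 102)
    libraries <- dplyr::bind_rows(
      library_spec("pe300", "PE", 300, 30, 100L, 25),
      library_spec("mp3k", "MP", 3000, 300, 100L, 8))
    profile <- paper_profile(genome, seed = 103, libraries = libraries)
    list(genome = genome, reference = reference, libraries = libraries,
         profile = profile)
  })
}

e2e_run <- function(enable_step5 = TRUE) {
  key <- paste0("e2e_run_", enable_step5)
  memo(key, {
    cond <- e2e_conditions()
    cfg <- pipeline_config(cond$reference, cond$profile$reads,
                           cond$libraries, enable_step5 = enable_step5,
                           seed = 5)
    run <- run_pipeline(cfg)
    placements <- align_to_truth(run$scaffolds, cond$genome)
    list(run = run, placements = placements,
         coverage = truth_coverage(placements, cond$genome))
  })
}
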