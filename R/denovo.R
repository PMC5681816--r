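# Step 3: built-in minimal de Bruijn assembler for desk-scale runs, multi-k
# orchestration, and a plugin hook for external assemblers.

#' Assemble reads with the built-in de Bruijn assembler
#'
#' Builds a canonical k-mer graph from both strands, drops edges below
#' `min_edge_mult`, clips tips shorter than `tip_len`, pops simple two-arm
#' bubbles keeping the higher-multiplicity arm, and emits maximal
#' non-branching paths as contigs in canonical orientation.
#'
#' @param reads read tibble (only `seq` is used)
#' @param k odd k-mer length, shorter than the reads
#' @param min_edge_mult minimum k-mer multiplicity retained in the graph
#' @param tip_len dead-end paths shorter than this are clipped (default `2k`)
#' @param origin origin label recorded on every contig (superblock id,
#'   `"UNMAPPED"` or `"RESCUE"`)
#' @return contig tibble: `id`, `seq`, `origin`, `k_used`
#' @export
assemble_reads <- function(reads, k = 31L, min_edge_mult = 2L,
                           tip_len = NULL, origin = NA_character_) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  if (k < 5L || k > 63L) stop("k must be between 5 and 63")
  tip_len <- as.integer(tip_len %||% (2L * k))
  if (nrow(reads) == 0) {
    return(tibble::tibble(id = character(), seq = character(),
                          origin = character(), k_used = integer()))
  }
  contigs <- cpp_assemble(reads$seq, k, as.integer(min_edge_mult), tip_len)
  if (length(contigs) == 0) {
    return(tibble::tibble(id = character(), seq = character(),
                          origin = character(), k_used = integer()))
  }
  tibble::tibble(
    id = sprintf("%s_k%d_c%04d",
                 ifelse(is.na(origin), "ctg", origin), k,
                 seq_along(contigs)),
    seq = as.character(contigs),
    origin = origin, k_used = k)
}

#' Multi-k assembly
#'
#' Repeats the de Bruijn assembly with several k-mer lengths and pools all
#' contigs; no deduplication is performed here (redundancy removal is the
#' merge step's job).
#'
#' @param reads read tibble
#' @param k_list integer vector of odd k values
#' @param min_edge_mult,origin passed to [assemble_reads()]
#' @return pooled contig tibble with `k_used` recording the k of each contig
#' @export
multi_k_assemble <- function(reads, k_list = c(21L, 31L, 41L),
                             min_edge_mult = 2L, origin = NA_character_) {
  dplyr::bind_rows(lapply(k_list, function(k) {
    assemble_reads(reads, k = k, min_edge_mult = min_edge_mult,
                   origin = origin)
  }))
}

#' Run an external assembler through a command template
#'
#' The template must contain `{reads}` and `{out}` placeholders; reads are
#' written as FASTQ to `{reads}` and the resulting FASTA at `{out}` is parsed
#' into contigs. A failing external process yields an empty contig set with a
#' warning so the pipeline can continue.
#'
#' @param reads read tibble
#' @param command_template shell command with `{reads}` and `{out}`
#' @param workdir working directory for the exchange files
#' @param origin origin label for the parsed contigs
#' @return contig tibble (possibly empty)
#' @export
external_assembler <- function(reads, command_template,
                               workdir = tempfile("asm"), origin = NA_character_) {
  if (!grepl("{reads}", command_template, fixed = TRUE) ||
      !grepl("{out}", command_template, fixed = TRUE)) {
    stop("command_template must contain {reads} and {out} placeholders")
  }
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  reads_path <- file.path(workdir, "reads.fq")
  out_path <- file.path(workdir, "contigs.fa")
  write_fastq(reads, reads_path)
  cmd <- gsub("{reads}", reads_path,
              gsub("{out}", out_path, command_template, fixed = TRUE),
              fixed = TRUE)
  status <- system(cmd, ignore.stdout = TRUE, ignore.stderr = TRUE)
  empty <- tibble::tibble(id = character(), seq = character(),
                          origin = character(), k_used = integer())
  if (status != 0) {
    warning("external assembler exited with status ", status,
            "; returning no contigs")
    return(empty)
  }
  if (!file.exists(out_path)) {
    warning("external assembler produced no output; returning no contigs")
    return(empty)
  }
  fa <- read_fasta(out_path)
  tibble::tibble(id = fa$id, seq = fa$seq, origin = origin,
                 k_used = NA_integer_)
}

#' Assemble every superblock plus the unmapped read pool
#'
#' Runs the multi-k assembly per superblock and once over all unmapped reads,
#' pooling the contigs for the merge step.
#'
#' @param superblocks superblock tibble with `read_keys`
#'   (see [partition_reads()])
#' @param reads trimmed read tibble
#' @param unmapped tibble from [collect_unmapped()]
#' @param k_list k values for the multi-k assembly
#' @param min_edge_mult minimum k-mer multiplicity
#' @return pooled contig tibble
#' @export
assemble_superblocks <- function(superblocks, reads, unmapped,
                                 k_list = c(21L, 31L, 41L),
                                 min_edge_mult = 2L) {
  pieces <- lapply(seq_len(nrow(superblocks)), function(s) {
    sub <- reads_by_keys(reads, superblocks$read_keys[[s]])
    multi_k_assemble(sub, k_list, min_edge_mult,
                     origin = superblocks$sb_id[s])
  })
  un_reads <- reads[paste0(reads$read_id, "/", reads$mate) %in%
                      paste0(unmapped$read_id, "/", unmapped$mate), ,
                    drop = FALSE]
  pieces[[length(pieces) + 1L]] <-
    multi_k_assemble(un_reads, k_list, min_edge_mult, origin = "UNMAPPED")
  contigs <- dplyr::bind_rows(pieces)
  if (nrow(contigs) > 0) {
    contigs$id <- sprintf("%s_%05d", contigs$id, seq_len(nrow(contigs)))
  }
  contigs
}
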