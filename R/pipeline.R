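# Orchestration of the seven pipeline steps with config, manifest,
# checkpointing and the with/without-rescue ablation switch.

#' Build a pipeline configuration
#'
#' @param reference guide reference: a [seq_tbl()] or a FASTA path
#' @param reads read tibble (with `library_id`) or NULL when `read_files`
#'   is given
#' @param libraries library tibble ([library_spec()] rows)
#' @param read_files optional named list `library_id -> c(R1, R2)` of FASTQ
#'   paths
#' @param workdir optional working directory for artifacts and checkpoints
#' @param trim a [trim_params()] list
#' @param superblock a [superblock_params()] list
#' @param k_list k values of the multi-k superblock assembly
#' @param min_edge_mult minimum k-mer multiplicity in the assemblies
#' @param merge a [merge_params()] list
#' @param finishing a [finishing_params()] list
#' @param enable_step5 run the unmapped-read rescue step (the ablation
#'   switch)
#' @param rescue_k k-mer length of the rescue assembly
#' @param map_k seed length of the read mapper
#' @param close_gaps attempt read-path gap closing during scaffolding
#' @param resume reuse stage checkpoints found in `workdir`
#' @param seed master seed fanned out per stage
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(reference, reads = NULL, libraries,
                            read_files = NULL, workdir = NULL,
                            trim = trim_params(),
                            superblock = superblock_params(),
                            k_list = c(21L, 31L, 41L), min_edge_mult = 2L,
                            merge = merge_params(),
                            finishing = finishing_params(),
                            enable_step5 = TRUE, rescue_k = 31L,
                            map_k = 15L, close_gaps = TRUE, resume = FALSE,
                            seed = 1L) {
  if (is.character(reference)) {
    if (!file.exists(reference)) stop("reference file not found: ", reference)
    reference <- read_fasta(reference)
  }
  if (is.null(reads)) {
    if (is.null(read_files)) stop("either reads or read_files is required")
    reads <- dplyr::bind_rows(lapply(names(read_files), function(lib) {
      fp <- read_files[[lib]]
      if (!all(file.exists(fp))) stop("read file not found for ", lib)
      read_fastq_pair(fp[1], fp[2], library_id = lib)
    }))
  }
  if (!is.null(workdir)) dir.create(workdir, recursive = TRUE,
                                    showWarnings = FALSE)
  structure(list(reference = reference, reads = reads, libraries = libraries,
                 workdir = workdir, trim = trim, superblock = superblock,
                 k_list = as.integer(k_list),
                 min_edge_mult = as.integer(min_edge_mult), merge = merge,
                 finishing = finishing, enable_step5 = isTRUE(enable_step5),
                 rescue_k = as.integer(rescue_k), map_k = as.integer(map_k),
                 close_gaps = isTRUE(close_gaps), resume = isTRUE(resume),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# run one stage with optional checkpointing; returns its value and appends a
# manifest entry via the callback
run_stage <- function(config, name, counter, fun) {
  ckpt <- if (!is.null(config$workdir)) {
    file.path(config$workdir, "checkpoints", paste0(name, ".rds"))
  }
  if (!is.null(ckpt) && config$resume && file.exists(ckpt)) {
    return(readRDS(ckpt))
  }
  set.seed(stage_seed(config$seed, counter))
  val <- fun()
  if (!is.null(ckpt)) {
    dir.create(dirname(ckpt), recursive = TRUE, showWarnings = FALSE)
    saveRDS(val, ckpt)
  }
  val
}

artifact_entry <- function(workdir, name, file, counts) {
  entry <- list(stage = name, counts = counts)
  if (!is.null(workdir) && !is.null(file)) {
    fp <- file.path(workdir, file)
    if (file.exists(fp)) {
      entry$artifact <- file
      entry$md5 <- unname(tools::md5sum(fp))
    }
  }
  entry
}

#' Run the reference-guided de novo assembly pipeline
#'
#' Executes trim, reference mapping, superblock partitioning, per-superblock
#' multi-k assembly plus unmapped-read assembly, homology-guided merging,
#' optional unmapped-read rescue, pileup error correction and ranked
#' scaffolding. Every stage records counts in a JSON manifest; with a
#' `workdir`, artifacts are written and stages can resume from checkpoints.
#'
#' @param config a [pipeline_config()]
#' @return a `refguide_run` list: `scaffolds`, `supercontigs`, `contigs`,
#'   `superblocks`, `blocks`, `agp`, `manifest`, `config`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  wd <- config$workdir
  manifest <- list()
  t0 <- Sys.time()

  # step 1: quality trimming
  trimmed <- run_stage(config, "trim", 1L, function() {
    tp <- trim_pairs(config$reads, config$trim)
    dplyr::bind_rows(tp$pairs, tp$orphans)
  })
  manifest$trim <- artifact_entry(wd, "trim", NULL,
                                  list(n_in = nrow(config$reads),
                                       n_out = nrow(trimmed)))

  # step 2: map against the guide reference, call blocks and superblocks
  aln <- run_stage(config, "map", 2L, function() {
    a <- map_reads(trimmed, build_index(config$reference, config$map_k),
                   mode = "local")
    pair_and_flag(a, config$libraries)
  })
  manifest$map <- artifact_entry(wd, "map", NULL,
                                 list(n_reads = nrow(aln),
                                      n_mapped = sum(!aln$unmapped)))

  sbs <- run_stage(config, "superblocks", 3L, function() {
    blocks <- call_blocks(aln)
    bridged <- bridge_blocks(blocks, aln, config$superblock)
    sb <- build_superblocks(bridged, config$superblock)
    sb <- partition_reads(sb, aln)
    list(blocks = blocks, bridged = bridged, superblocks = sb,
         unmapped = collect_unmapped(aln))
  })
  if (!is.null(wd)) {
    write_bed(sbs$bridged, file.path(wd, "blocks.bed"))
    write_bed(sbs$superblocks, file.path(wd, "superblocks.bed"),
              name_col = "sb_id")
  }
  manifest$superblocks <- artifact_entry(
    wd, "superblocks", "superblocks.bed",
    list(n_blocks = nrow(sbs$blocks), n_bridged = nrow(sbs$bridged),
         n_superblocks = nrow(sbs$superblocks),
         n_unmapped_reads = nrow(sbs$unmapped)))

  # step 3: per-superblock multi-k assembly + unmapped assembly (PE reads)
  pe_libs <- config$libraries$library_id[config$libraries$kind == "PE"]
  reads_pe <- trimmed[trimmed$library_id %in% pe_libs, , drop = FALSE]
  contigs <- run_stage(config, "assemble", 4L, function() {
    assemble_superblocks(sbs$superblocks, reads_pe, sbs$unmapped,
                         config$k_list, config$min_edge_mult)
  })
  if (!is.null(wd) && nrow(contigs) > 0) {
    write_fasta(seq_tbl(contigs$id, contigs$seq), file.path(wd, "contigs.fa"))
  }
  manifest$assemble <- artifact_entry(wd, "assemble", "contigs.fa",
                                      list(n_contigs = nrow(contigs)))

  # step 4: homology-guided redundancy removal
  merged <- run_stage(config, "merge", 5L, function() {
    merge_reduce(contigs, config$reference, config$merge)
  })
  supercontigs <- merged$supercontigs
  if (!is.null(wd) && nrow(supercontigs) > 0) {
    write_fasta(seq_tbl(supercontigs$id, supercontigs$seq),
                file.path(wd, "supercontigs.fa"))
  }
  manifest$merge <- artifact_entry(
    wd, "merge", "supercontigs.fa",
    list(n_tiles = nrow(merged$tiles), n_unplaced = length(merged$unplaced),
         n_supercontigs = nrow(supercontigs)))

  # step 5 (optional): rescue of diverged regions from unmapped reads
  if (config$enable_step5) {
    rescued <- run_stage(config, "rescue", 6L, function() {
      rescue_unmapped(trimmed, supercontigs, k = config$rescue_k,
                      min_edge_mult = config$min_edge_mult)
    })
    supercontigs <- rescued$supercontigs
    manifest$rescue <- artifact_entry(
      wd, "rescue", NULL, list(n_rescued = nrow(rescued$rescued),
                               n_supercontigs = nrow(supercontigs)))
  }

  # step 6: pileup error correction with splitting
  corrected <- run_stage(config, "correct", 7L, function() {
    sc_tbl <- seq_tbl(supercontigs$id, supercontigs$seq)
    a6 <- map_reads(reads_pe, sc_tbl, mode = "sensitive")
    a6 <- pair_and_flag(a6, config$libraries)
    correct_supercontigs(supercontigs, a6, config$finishing)
  })
  if (!is.null(wd) && nrow(corrected) > 0) {
    write_fasta(seq_tbl(corrected$id, corrected$seq),
                file.path(wd, "corrected.fa"))
  }
  manifest$correct <- artifact_entry(
    wd, "correct", "corrected.fa",
    c(list(n_supercontigs = nrow(corrected)),
      attr(corrected, "correction_stats")))

  # step 7: ranked scaffolding and gap closing
  scaf <- run_stage(config, "scaffold", 8L, function() {
    if (nrow(corrected) == 0) {
      return(list(scaffolds = tibble::tibble(id = character(),
                                             seq = character()),
                  agp = tibble::tibble(), stats = list()))
    }
    sc_tbl <- seq_tbl(corrected$id, corrected$seq)
    a7 <- map_reads(trimmed, sc_tbl, mode = "sensitive")
    a7 <- pair_and_flag(a7, config$libraries)
    sc_len <- setNames(nchar(corrected$seq), corrected$id)
    links <- dplyr::bind_rows(lapply(seq_len(nrow(config$libraries)),
                                     function(i) {
      lib <- config$libraries[i, ]
      build_links(a7[a7$library_id == lib$library_id, , drop = FALSE],
                  lib, sc_len, config$finishing)
    }))
    junction <- if (config$close_gaps) {
      a7[a7$library_id %in% pe_libs, , drop = FALSE]
    }
    scaffold(corrected, links, config$libraries, config$finishing,
             junction_reads = junction)
  })
  if (!is.null(wd) && nrow(scaf$scaffolds) > 0) {
    write_fasta(seq_tbl(scaf$scaffolds$id, scaf$scaffolds$seq),
                file.path(wd, "scaffolds.fa"))
  }
  manifest$scaffold <- artifact_entry(
    wd, "scaffold", "scaffolds.fa",
    c(list(n_scaffolds = nrow(scaf$scaffolds)), scaf$stats))

  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!is.null(wd)) {
    jsonlite::write_json(manifest, file.path(wd, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(scaffolds = scaf$scaffolds, supercontigs = corrected,
                 contigs = contigs, superblocks = sbs$superblocks,
                 blocks = sbs$bridged, agp = scaf$agp, manifest = manifest,
                 config = config),
            class = "refguide_run")
}

#' @export
print.refguide_run <- function(x, ...) {
  cat("reference-guided assembly run\n")
  cat("  scaffolds:   ", nrow(x$scaffolds), " (",
      sum(nchar(x$scaffolds$seq)), " bp, N50 ",
      n50(nchar(x$scaffolds$seq)), ")\n", sep = "")
  cat("  supercontigs:", nrow(x$supercontigs), "\n")
  cat("  superblocks: ", nrow(x$superblocks), "\n")
  invisible(x)
}

#' Evaluate and rank several assemblies against a truth genome
#'
#' Runs the full statistic registry for every assembly, ranks methods by
#' summed z-scores and reports pairwise one-sided Wilcoxon rank-sum
#' p-values.
#'
#' @param assemblies named list of scaffold tibbles (`id`, `seq`) or
#'   `refguide_run` objects
#' @param truth truth genome [seq_tbl()]
#' @param genes optional gene tibble
#' @param reads optional paired-end read tibble
#' @param libraries library tibble (required with `reads`)
#' @param genome_size known genome size (bp)
#' @return an `assembly_comparison` list: `evals`, `ranking`
#'   (a `zscore_table`), `pvalues`
#' @export
run_comparison <- function(assemblies, truth, genes = NULL, reads = NULL,
                           libraries = NULL, genome_size = NULL) {
  if (length(assemblies) < 2) stop("at least two assemblies are required")
  if (is.null(names(assemblies))) stop("assemblies must be a named list")
  evals <- lapply(assemblies, function(a) {
    scaf <- if (inherits(a, "refguide_run")) a$scaffolds else a
    evaluate_assembly(scaf, truth, genes = genes, reads = reads,
                      libraries = libraries, genome_size = genome_size)
  })
  ranking <- zscore_rank(evals)
  structure(list(evals = evals, ranking = ranking,
                 pvalues = pairwise_wilcoxon(ranking)),
            class = "assembly_comparison")
}

#' @export
print.assembly_comparison <- function(x, ...) {
  print(x$ranking)
  cat("\npairwise one-sided Wilcoxon p-values:\n")
  print(x$pvalues)
  invisible(x)
}
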