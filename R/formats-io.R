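# Readers/writers for FASTA, FASTQ and SAM-compatible alignment records.
# All positions are 0-based half-open internally; only SAM emission converts
# to the 1-based wire format.

#' Read a FASTA file into a sequence table
#'
#' Lowercase bases are folded to uppercase and IUPAC ambiguity codes outside
#' ACGT become N. Gzipped input is detected by file content.
#'
#' @param path path to a FASTA file (optionally gzipped)
#' @return a [seq_tbl()] tibble with columns `id`, `seq`, `desc`
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0) stop("no records in FASTA file: ", path)
  nm <- names(set)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), NA_character_)
  seqs <- unname(as.character(set))
  if (any(nchar(seqs) == 0)) {
    bad <- id[nchar(seqs) == 0][1]
    stop("empty sequence for record '", bad, "' in ", path)
  }
  if (any(!nzchar(id))) stop("record with empty header in ", path)
  if (anyDuplicated(id)) stop("duplicate sequence id in ", path, ": ",
                              id[duplicated(id)][1])
  seq_tbl(id, seqs, desc)
}

#' Write a sequence table to FASTA
#'
#' @param seqs a [seq_tbl()] tibble
#' @param path output path; a `.gz` suffix triggers gzip compression
#' @param width line width for wrapping
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  has_desc <- !is.na(seqs$desc) & nzchar(seqs$desc)
  names(set)[has_desc] <- paste(seqs$id[has_desc], seqs$desc[has_desc])
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# infer mate number from a FASTQ read name; NA when not encoded
infer_mate <- function(nm) {
  mate <- rep(NA_integer_, length(nm))
  m1 <- grepl("/1$", nm) | grepl("^\\S+\\s+1[:\\s]", nm)
  m2 <- grepl("/2$", nm) | grepl("^\\S+\\s+2[:\\s]", nm)
  mate[m1] <- 1L
  mate[m2] <- 2L
  mate
}

#' Read a FASTQ file into a read table
#'
#' Expects 4-line records with phred+33 qualities. Mates are inferred from
#' `/1`, `/2` or Casava-style ` 1:` / ` 2:` name suffixes; use
#' [read_fastq_pair()] for mate assignment by file position.
#'
#' @param path path to a FASTQ file (optionally gzipped)
#' @param library_id library identifier attached to every read
#' @param default_mate mate number used when the name does not encode one
#' @return tibble with columns `read_id`, `mate`, `seq`, `qual`, `library_id`
#' @export
read_fastq <- function(path, library_id = NA_character_, default_mate = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- tryCatch({
    set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
    list(nm = names(set),
         qual = unname(as.character(S4Vectors::mcols(set)$qualities)),
         seqs = normalize_seq(unname(as.character(set))))
  }, error = function(e) stop("malformed FASTQ in ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  nm <- parsed$nm
  qual <- parsed$qual
  seqs <- parsed$seqs
  if (anyNA(qual) || anyNA(seqs) ||
      !all(validUTF8(qual)) || !all(validUTF8(nm))) {
    stop("malformed FASTQ in ", path)
  }
  if (any(nchar(seqs, type = "bytes") != nchar(qual, type = "bytes"))) {
    bad <- which(nchar(seqs, type = "bytes") != nchar(qual, type = "bytes"))[1]
    stop("seq/qual length mismatch at record ", bad, " in ", path)
  }
  mate <- infer_mate(nm)
  mate[is.na(mate)] <- default_mate
  id <- sub("/[12]$", "", sub("\\s.*$", "", nm))
  tibble::tibble(read_id = id, mate = as.integer(mate), seq = seqs, qual = qual,
                 library_id = rep_len(as.character(library_id), length(id)))
}

#' Read a pair of FASTQ files as mates 1 and 2
#'
#' @param path1,path2 paths to the mate-1 and mate-2 FASTQ files
#' @param library_id library identifier attached to every read
#' @return combined read tibble; mates are paired by file position
#' @export
read_fastq_pair <- function(path1, path2, library_id = NA_character_) {
  r1 <- read_fastq(path1, library_id, default_mate = 1L)
  r2 <- read_fastq(path2, library_id, default_mate = 2L)
  r1$mate <- 1L
  r2$mate <- 2L
  if (nrow(r1) != nrow(r2)) stop("mate files differ in record count")
  dplyr::bind_rows(r1, r2)
}

#' Write a read table to FASTQ
#'
#' @param reads read tibble (`read_id`, `mate`, `seq`, `qual`)
#' @param path output path; `.gz` suffix compresses
#' @return `path`, invisibly
#' @export
write_fastq <- function(reads, path) {
  nm <- ifelse(is.na(reads$mate), reads$read_id,
               paste0(reads$read_id, "/", reads$mate))
  lines <- as.vector(rbind(paste0("@", nm), reads$seq, "+", reads$qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# an empty alignment tibble with the canonical column set
empty_alignments <- function() {
  tibble::tibble(read_id = character(), mate = integer(), ref_id = character(),
                 pos = integer(), strand = character(), cigar = character(),
                 mapq = integer(), score = integer(), paired = logical(),
                 proper_pair = logical(), unmapped = logical(),
                 mate_unmapped = logical(), mate_ref_id = character(),
                 mate_pos = integer(), library_id = character(),
                 seq = character(), qual = character())
}

sam_flag <- function(aln) {
  fl <- integer(nrow(aln))
  fl <- fl + ifelse(isTRUE_v(aln$paired), 1L, 0L)
  fl <- fl + ifelse(isTRUE_v(aln$proper_pair), 2L, 0L)
  fl <- fl + ifelse(isTRUE_v(aln$unmapped), 4L, 0L)
  fl <- fl + ifelse(isTRUE_v(aln$mate_unmapped), 8L, 0L)
  fl <- fl + ifelse(!isTRUE_v(aln$unmapped) & aln$strand == "-", 16L, 0L)
  fl <- fl + ifelse(aln$mate == 1L, 64L, ifelse(aln$mate == 2L, 128L, 0L))
  fl
}

isTRUE_v <- function(x) !is.na(x) & x

#' Write alignments as SAM text
#'
#' Internal 0-based positions are emitted 1-based per the SAM convention.
#' Mandatory `@SQ` header lines are written for every reference sequence.
#'
#' @param alignments alignment tibble (see [map_reads()])
#' @param refs reference [seq_tbl()] providing the header dictionary
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sam <- function(alignments, refs, path) {
  known <- alignments$ref_id[!is.na(alignments$ref_id)]
  if (length(setdiff(known, refs$id)) > 0) {
    stop("alignment references unknown ref_id: ",
         setdiff(known, refs$id)[1])
  }
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", refs$id, nchar(refs$seq)))
  a <- alignments
  body <- paste(a$read_id,
                sam_flag(a),
                ifelse(is.na(a$ref_id), "*", a$ref_id),
                ifelse(is.na(a$pos), 0L, a$pos + 1L),
                ifelse(is.na(a$mapq), 0L, a$mapq),
                ifelse(is.na(a$cigar), "*", a$cigar),
                ifelse(is.na(a$mate_ref_id), "*",
                       ifelse(a$mate_ref_id == a$ref_id & !is.na(a$ref_id),
                              "=", a$mate_ref_id)),
                ifelse(is.na(a$mate_pos), 0L, a$mate_pos + 1L),
                0L,
                ifelse(is.na(a$seq), "*", a$seq),
                ifelse(is.na(a$qual), "*", a$qual),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read SAM text into an alignment tibble
#'
#' @param path path to a SAM file with `@SQ` header lines
#' @return alignment tibble with 0-based positions
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0) return(empty_alignments())
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- vapply(f, length, 1L)
  if (any(nf < 11)) stop("SAM record with fewer than 11 fields at line ",
                         which(nf < 11)[1] + length(hdr))
  g <- function(i) vapply(f, `[[`, "", i)
  flag <- as.integer(g(2))
  unmapped <- bitwAnd(flag, 4L) > 0
  ref_id <- g(3); ref_id[ref_id == "*"] <- NA_character_
  pos <- as.integer(g(4)) - 1L; pos[unmapped | pos < 0] <- NA_integer_
  cig <- g(6); cig[cig == "*"] <- NA_character_
  rnext <- g(7)
  mate_ref <- ifelse(rnext == "=", ref_id, ifelse(rnext == "*", NA, rnext))
  pnext <- as.integer(g(8)) - 1L
  pnext[pnext < 0] <- NA_integer_
  sq <- g(10); sq[sq == "*"] <- NA_character_
  ql <- g(11); ql[ql == "*"] <- NA_character_
  tibble::tibble(
    read_id = g(1),
    mate = ifelse(bitwAnd(flag, 64L) > 0, 1L,
                  ifelse(bitwAnd(flag, 128L) > 0, 2L, NA_integer_)),
    ref_id = ref_id, pos = pos,
    strand = ifelse(unmapped, NA_character_,
                    ifelse(bitwAnd(flag, 16L) > 0, "-", "+")),
    cigar = ifelse(unmapped, NA_character_, cig),
    mapq = as.integer(g(5)),
    score = NA_integer_,
    paired = bitwAnd(flag, 1L) > 0,
    proper_pair = bitwAnd(flag, 2L) > 0,
    unmapped = unmapped,
    mate_unmapped = bitwAnd(flag, 8L) > 0,
    mate_ref_id = mate_ref, mate_pos = pnext,
    library_id = NA_character_, seq = sq, qual = ql)
}

#' Write blocks or superblocks as BED
#'
#' Intervals are already 0-based half-open, matching BED directly.
#'
#' @param x tibble with `ref_id`, `start`, `end` and optionally a name column
#' @param path output path
#' @param name_col column used for the BED name field
#' @return `path`, invisibly
#' @export
write_bed <- function(x, path, name_col = NULL) {
  nm <- if (!is.null(name_col) && name_col %in% names(x)) x[[name_col]]
        else seq_len(nrow(x))
  writeLines(paste(x$ref_id, x$start, x$end, nm, sep = "\t"), path)
  invisible(path)
}
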