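# Readers and writers for the standard formats the pipeline touches.
# Sequences are plain named character vectors internally; coordinates are
# 0-based half-open internally and converted at VCF/SAM boundaries.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on read; duplicate identifiers and empty files are
#' format errors.
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA: ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA identifier: ", ids[duplicated(ids)][1L], call. = FALSE)
  if (any(Biostrings::width(set) < 1L))
    stop("zero-length FASTA record", call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read an alignment-hit table
#'
#' Two dialects are supported: \code{blast-tab-12} (BLAST outfmt 6: qseqid,
#' sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#' evalue, bitscore) and \code{sam-min} (a minimal SAM subset using QNAME,
#' FLAG, RNAME, POS, MAPQ, CIGAR, SEQ, QUAL; unmapped records are excluded).
#' Subject coordinates are normalised ascending with a strand flag; internally
#' all coordinates are 0-based half-open.
#'
#' @param path input file.
#' @param dialect \code{"blast-tab-12"} or \code{"sam-min"}.
#' @return \code{data.table} of hits. For BLAST: query_id, subject_id,
#'   identity (percent, 0-100), length, mismatch, gapopen, qstart, qend,
#'   sstart, send (0-based half-open, ascending), strand, evalue, bitscore.
#'   For SAM: read_id, flag, transcript, pos (0-based), mapq, cigar, seq, qual.
#' @export
read_alignment_table <- function(path, dialect = c("blast-tab-12", "sam-min")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "blast-tab-12") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 12L))
      stop(sprintf("line %d: expected 12 tab-separated columns, found %d",
                   which(nf != 12L)[1L], nf[nf != 12L][1L]), call. = FALSE)
    m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
    dt <- data.table(
      query_id = m[, 1L], subject_id = m[, 2L],
      identity = as.numeric(m[, 3L]), length = as.integer(m[, 4L]),
      mismatch = as.integer(m[, 5L]), gapopen = as.integer(m[, 6L]),
      qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
      sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
      evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L])
    )
    # 1-based inclusive -> 0-based half-open; reverse-strand subjects
    # (sstart > send) normalised ascending
    rev <- dt$sstart > dt$send
    s1 <- ifelse(rev, dt$send, dt$sstart)
    s2 <- ifelse(rev, dt$sstart, dt$send)
    dt[, `:=`(sstart = as.integer(s1 - 1L), send = as.integer(s2),
              strand = ifelse(rev, "-", "+"),
              qstart = as.integer(qstart - 1L))]
    dt[]
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
    if (length(lines) == 0L)
      return(data.table(read_id = character(), flag = integer(),
                        transcript = character(), pos = integer(),
                        mapq = integer(), cigar = character(),
                        seq = character(), qual = character()))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 11L))
      stop(sprintf("line %d: SAM record has %d fields (need >= 11)",
                   which(nf < 11L)[1L], nf[nf < 11L][1L]), call. = FALSE)
    m <- t(vapply(fields, function(f) f[1:11], character(11L)))
    dt <- data.table(
      read_id = m[, 1L], flag = as.integer(m[, 2L]),
      transcript = m[, 3L], pos = as.integer(m[, 4L]) - 1L,
      mapq = as.integer(m[, 5L]), cigar = m[, 6L],
      seq = m[, 10L], qual = m[, 11L]
    )
    dt[bitwAnd(flag, 4L) == 0L][]
  }
}

#' Write simulated/aligned reads as a minimal SAM file
#'
#' One record per read; mates carry the paired/first/second flags. Alignments
#' are ungapped full-length matches, so CIGAR is `<len>M`.
#'
#' @param aln alignment \code{data.table} with read_id, transcript, pos
#'   (0-based), mate, seq, qual columns.
#' @param reference named character vector used for the @SQ header lines.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_sam <- function(aln, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference)))
  flag <- ifelse(aln$mate == 1L, 99L, 147L)  # proper pair, mate flags
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t0\t0\t%s\t%s",
                 aln$read_id, flag, aln$transcript, aln$pos + 1L,
                 nchar(aln$seq), aln$seq, aln$qual)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write paired reads as a pair of FASTQ files
#'
#' Mate 2 is written reverse-complemented (sequencing orientation).
#'
#' @param reads read table from \code{\link{simulate_reads}}.
#' @param prefix output prefix; files are \code{<prefix>_1.fastq} and
#'   \code{<prefix>_2.fastq}.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  out <- c(paste0(prefix, "_1.fastq"), paste0(prefix, "_2.fastq"))
  for (m in 1:2) {
    r <- reads[reads$mate == m, ]
    seq <- r$seq
    qual <- r$qual
    if (m == 2L) {
      seq <- .revcomp(seq)
      qual <- .revstring(qual)
    }
    writeLines(as.vector(rbind(paste0("@", r$read_id, "/", m),
                               seq, "+", qual)), out[m])
  }
  invisible(out)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.revstring <- function(x) {
  vapply(strsplit(x, NULL), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Write per-variety variant calls as a VCF v4.2 file
#'
#' Only non-reference genotypes are emitted as records; GT and DP are written
#' per sample and the supporting allele frequency as the AF info field.
#' Positions are converted to 1-based.
#'
#' @param calls \code{data.table} with transcript, pos (0-based), ref, alt,
#'   genotype ("HOM_ALT" or "HET"), coverage, freq columns for one variety.
#' @param variety sample name for the header column.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_variant_vcf <- function(calls, variety, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=tetrasnp",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Supporting allele frequency\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Filtered read depth\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", variety))
  keep <- calls$genotype %in% c("HOM_ALT", "HET")
  calls <- calls[keep, ]
  gt <- ifelse(calls$genotype == "HOM_ALT", "1/1", "0/1")
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.4f\tGT:DP\t%s:%d",
                 calls$transcript, calls$pos + 1L, calls$ref, calls$alt,
                 calls$freq, gt, calls$coverage)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a per-variety VCF written by \code{\link{write_variant_vcf}}
#'
#' A plain-text VCF v4.x reader for the subset this pipeline emits (GT and DP
#' format fields, AF info). Positions are converted back to 0-based.
#'
#' @param path VCF file.
#' @return \code{data.table} with transcript, pos, ref, alt, genotype,
#'   coverage, freq and the sample name as attribute \code{"variety"}.
#' @export
read_variant_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (length(hdr) != 1L) stop("missing #CHROM header line", call. = FALSE)
  variety <- tail(strsplit(hdr, "\t", fixed = TRUE)[[1]], 1L)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    out <- data.table(transcript = character(), pos = integer(),
                      ref = character(), alt = character(),
                      genotype = character(), coverage = integer(),
                      freq = numeric())
    attr(out, "variety") <- variety
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  m <- t(vapply(f, function(x) x[c(1, 2, 4, 5, 8, 10)], character(6L)))
  sample_f <- strsplit(m[, 6L], ":", fixed = TRUE)
  gt <- vapply(sample_f, `[`, character(1), 1L)
  dp <- as.integer(vapply(sample_f, `[`, character(1), 2L))
  af <- as.numeric(sub("^AF=", "", m[, 5L]))
  out <- data.table(
    transcript = m[, 1L], pos = as.integer(m[, 2L]) - 1L,
    ref = m[, 3L], alt = m[, 4L],
    genotype = ifelse(gt %in% c("1/1", "1|1"), "HOM_ALT", "HET"),
    coverage = dp, freq = af
  )
  attr(out, "variety") <- variety
  out
}
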