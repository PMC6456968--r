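# Per-position variant calling against the transcript reference.
#
# Reads pass a quality window centred on the candidate base (window length 11,
# <= 6 gaps+mismatches, central quality >= 20, mean window quality >= 15); a
# position is callable at >= 8 filtered reads; an alternative allele is
# supported when backed by >= 4 reads and either >= 10% frequency or >= 1000
# reads outright. Genotypes: HOM_ALT at >= 90% alternative frequency, HET when
# reference and alternative both reach 10%, HOM_REF otherwise. Only
# substitutions are called; gaps count toward the window filter only.

#' Quality-window filter for a single read base
#'
#' @param qual numeric phred qualities along the read.
#' @param mismatch logical vector: gap-or-mismatch flag along the read.
#' @param variant_offset 1-based offset of the candidate base in the read.
#' @param params a \code{caller_params}.
#' @return TRUE when the base survives the window filter. The window is
#'   truncated at read ends.
#' @export
window_filter <- function(qual, mismatch, variant_offset, params = caller_params()) {
  n <- length(qual)
  stopifnot(variant_offset >= 1L, variant_offset <= n,
            length(mismatch) == n)
  h <- (params$window_length - 1L) %/% 2L
  lo <- max(1L, variant_offset - h)
  hi <- min(n, variant_offset + h)
  central_ok <- qual[variant_offset] >= params$min_central_quality
  avg_ok <- mean(qual[lo:hi]) >= params$min_average_quality
  mm_ok <- sum(mismatch[lo:hi]) <= params$max_gap_mismatch
  central_ok && avg_ok && mm_ok
}

#' Call one pileup column
#'
#' @param bases character vector of filtered base calls at the position.
#' @param ref reference base.
#' @param params a \code{caller_params}.
#' @return NULL when coverage is below \code{min_coverage}; otherwise a list
#'   with genotype ("HOM_REF", "HOM_ALT", "HET"), alt (NA_character_ when no
#'   alternative is supported), coverage, and freq (supporting frequency of
#'   the alternative, 0 when none).
#' @export
call_position <- function(bases, ref, params = caller_params()) {
  cov <- length(bases)
  if (cov < params$min_coverage) return(NULL)
  tab <- table(bases)
  alleles <- names(tab)
  counts <- as.integer(tab)
  nonref <- alleles != ref
  supported <- nonref & counts >= params$required_variant_count &
    (counts / cov >= params$min_variant_frequency |
       counts >= params$sufficient_variant_count)
  if (!any(supported)) {
    return(list(genotype = "HOM_REF", alt = NA_character_,
                coverage = cov, freq = 0))
  }
  cand <- which(supported)
  alt_i <- cand[order(-counts[cand], alleles[cand])][1L]
  alt <- alleles[alt_i]
  alt_freq <- counts[alt_i] / cov
  ref_freq <- if (ref %in% alleles) tab[[ref]] / cov else 0
  genotype <- if (alt_freq >= params$hom_frequency) "HOM_ALT"
  else if (alt_freq >= params$min_variant_frequency &&
           ref_freq >= params$min_variant_frequency) "HET"
  else "HOM_REF"
  list(genotype = genotype, alt = alt, coverage = cov, freq = alt_freq)
}

# rowwise truncated-window sums of a reads x offsets matrix
.window_sums <- function(M, h) {
  n <- ncol(M)
  CS <- M
  for (j in 2:n) CS[, j] <- CS[, j - 1L] + M[, j]
  W <- matrix(0, nrow(M), n)
  for (j in seq_len(n)) {
    hi <- min(n, j + h)
    lo <- j - h - 1L
    W[, j] <- CS[, hi] - (if (lo >= 1L) CS[, lo] else 0)
  }
  W
}

#' Call variants from read alignments against a transcript reference
#'
#' Applies the per-base quality-window filter to every aligned base, piles up
#' the survivors, and emits one row per position with coverage at or above
#' \code{min_coverage} -- including homozygous-reference rows, which the
#' multi-variety genotype matrix needs as "sufficient information" cells.
#'
#' @param aln alignment \code{data.table} with columns read_id, gene (or
#'   transcript), pos (0-based), seq, qual (phred+33). Ungapped full-length
#'   alignments are assumed (the simulator's output or the sam-min dialect
#'   restricted to `<len>M` CIGARs).
#' @param reference named character vector of transcript sequences.
#' @param params a \code{caller_params}.
#' @return \code{data.table}: transcript, pos (0-based), ref, alt, genotype,
#'   coverage, freq.
#' @export
call_variants <- function(aln, reference, params = caller_params()) {
  aln <- as.data.table(aln)
  if (!"transcript" %in% names(aln) && "gene" %in% names(aln))
    setnames(aln, "gene", "transcript")
  empty <- data.table(transcript = character(), pos = integer(),
                      ref = character(), alt = character(),
                      genotype = character(), coverage = integer(),
                      freq = numeric())
  if (nrow(aln) == 0L) return(empty)
  if (!all(aln$transcript %in% names(reference)))
    stop("alignment references transcripts absent from the reference",
         call. = FALSE)

  # reference as one int vector with per-transcript offsets
  ref_lens <- nchar(reference)
  ref_off <- setNames(c(0L, cumsum(ref_lens))[seq_along(reference)],
                      names(reference))
  ref_int <- utf8ToInt(paste(reference, collapse = ""))

  h <- (params$window_length - 1L) %/% 2L
  pieces <- list()
  for (len in sort(unique(nchar(aln$seq)))) {
    sub <- aln[nchar(seq) == len]
    nr <- nrow(sub)
    B <- matrix(utf8ToInt(paste(sub$seq, collapse = "")), nr, len,
                byrow = TRUE)
    Q <- matrix(utf8ToInt(paste(sub$qual, collapse = "")) - 33L, nr, len,
                byrow = TRUE)
    gpos <- ref_off[sub$transcript] + sub$pos  # 0-based global
    RP <- outer(gpos, seq_len(len) - 1L, "+")  # 0-based global ref position
    R <- matrix(ref_int[RP + 1L], nr, len)
    MM <- B != R
    avgQ <- .window_sums(Q, h)
    wlen <- outer(rep(1L, nr),
                  pmin(len, seq_len(len) + h) - pmax(1L, seq_len(len) - h) + 1L)
    nmm <- .window_sums(MM + 0L, h)
    acc <- Q >= params$min_central_quality &
      avgQ / wlen >= params$min_average_quality &
      nmm <= params$max_gap_mismatch
    keep <- as.vector(acc)
    pieces[[length(pieces) + 1L]] <- data.table(
      gp = as.vector(RP)[keep], b = as.vector(B)[keep])
  }
  bases <- rbindlist(pieces)
  if (nrow(bases) == 0L) return(empty)

  cnt <- bases[, .N, by = .(gp, b)]
  cnt[, cov := sum(N), by = gp]
  cnt <- cnt[cov >= params$min_coverage]
  if (nrow(cnt) == 0L) return(empty)
  cnt[, refb := ref_int[gp + 1L]]
  # supported alternative alleles
  cnt[, supp := b != refb & N >= params$required_variant_count &
        (N / cov >= params$min_variant_frequency |
           N >= params$sufficient_variant_count)]
  ref_n <- cnt[b == refb, .(gp, ref_n = N)]
  alt <- cnt[supp == TRUE][order(gp, -N, b)][, .SD[1L], by = gp]
  pos_tab <- unique(cnt[, .(gp, cov, refb)])
  pos_tab <- merge(pos_tab, ref_n, by = "gp", all.x = TRUE)
  pos_tab[is.na(ref_n), ref_n := 0L]
  pos_tab <- merge(pos_tab, alt[, .(gp, alt_b = b, alt_n = N)],
                   by = "gp", all.x = TRUE)
  pos_tab[, alt_freq := ifelse(is.na(alt_n), 0, alt_n / cov)]
  pos_tab[, ref_freq := ref_n / cov]
  pos_tab[, genotype := ifelse(
    is.na(alt_n), "HOM_REF",
    ifelse(alt_freq >= params$hom_frequency, "HOM_ALT",
           ifelse(alt_freq >= params$min_variant_frequency &
                    ref_freq >= params$min_variant_frequency,
                  "HET", "HOM_REF")))]

  # map global positions back to transcript coordinates
  tx_idx <- findInterval(pos_tab$gp, c(0L, cumsum(ref_lens)))
  pos_tab[, transcript := names(reference)[tx_idx]]
  pos_tab[, pos := gp - ref_off[transcript]]
  out <- pos_tab[, .(
    transcript, pos = as.integer(pos),
    ref = vapply(refb, intToUtf8, character(1)),
    alt = ifelse(is.na(alt_b), NA_character_,
                 vapply(alt_b, function(x) if (is.na(x)) NA_character_
                        else intToUtf8(x), character(1))),
    genotype, coverage = cov, freq = alt_freq)]
  setorder(out, transcript, pos)
  out[]
}

#' Call variants independently for several varieties
#'
#' @param aln_list named list of per-variety alignment tables.
#' @param reference named character vector of transcript sequences.
#' @param params a \code{caller_params}.
#' @return named list of per-variety call tables (see
#'   \code{\link{call_variants}}).
#' @export
call_varieties <- function(aln_list, reference, params = caller_params()) {
  lapply(aln_list, call_variants, reference = reference, params = params)
}
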