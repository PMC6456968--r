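# Multi-variety genotype matrix and the five-way SNP taxonomy.
#
# With inbred varieties a heterozygous-looking call reflects a mixture of the
# two homoeolog copies, not true heterozygosity; the decision table over the
# non-missing genotype calls of a position is therefore:
#   all HOM_ALT                          -> misassembly (reference artefact)
#   all HET                              -> inter_homoeolog (constitutive)
#   homozygous only, both REF and ALT    -> simple (diploid behaviour)
#   HET plus one homozygous class        -> hemi
#   HET plus both homozygous classes     -> multi_genotype

.SNP_CLASSES <- c("simple", "hemi", "inter_homoeolog", "multi_genotype",
                  "misassembly")

#' Classify one genotype-matrix row
#'
#' @param calls character vector of per-variety calls among "HOM_REF",
#'   "HOM_ALT", "HET", "MISSING".
#' @return one of "simple", "hemi", "inter_homoeolog", "multi_genotype",
#'   "misassembly".
#' @export
classify_position <- function(calls) {
  calls <- calls[calls != "MISSING" & !is.na(calls)]
  n_ref <- sum(calls == "HOM_REF")
  n_alt <- sum(calls == "HOM_ALT")
  n_het <- sum(calls == "HET")
  if (n_ref + n_alt + n_het == 0L)
    stop("no informative calls at this position", call. = FALSE)
  if (n_alt + n_het == 0L)
    stop("all calls homozygous-reference: not a SNP", call. = FALSE)
  if (n_het == 0L && n_ref == 0L) return("misassembly")
  if (n_ref == 0L && n_alt == 0L) return("inter_homoeolog")
  if (n_het == 0L) return("simple")
  if (xor(n_ref > 0L, n_alt > 0L)) return("hemi")
  "multi_genotype"
}

#' SNP frequency and histogram bin of a genotype-matrix row
#'
#' Frequency is the fraction of informative (non-missing) varieties calling a
#' non-reference nucleotide (HET or HOM_ALT). The bin is the half-open
#' interval \code{[origin + k*width, origin + (k+1)*width)} containing the
#' frequency; frequencies beyond the last edge fall in the top bin.
#'
#' @param calls character vector of per-variety calls.
#' @param params a \code{taxonomy_params}.
#' @return list with \code{frequency}, \code{bin} (1-based index) and
#'   \code{bin_label} ("lo-hi").
#' @export
snp_frequency <- function(calls, params = taxonomy_params()) {
  calls <- calls[calls != "MISSING" & !is.na(calls)]
  n_inf <- length(calls)
  if (n_inf == 0L) stop("no informative calls", call. = FALSE)
  f <- sum(calls %in% c("HET", "HOM_ALT")) / n_inf
  k <- floor((f - params$bin_origin) / params$bin_width)
  k <- min(max(k, 0), params$n_bins - 1L)
  lo <- params$bin_origin + k * params$bin_width
  list(frequency = f, bin = as.integer(k + 1L),
       bin_label = sprintf("%.2f-%.2f", lo, lo + params$bin_width))
}

#' Is a genotype-matrix row a rare SNP?
#'
#' Rare means the non-reference allele is carried by at most
#' \code{rare_max_carriers} varieties (default: exactly one; non-rare SNPs
#' show allelic presence in two or more genotypes).
#'
#' @param calls character vector of per-variety calls.
#' @param params a \code{taxonomy_params}.
#' @return logical.
#' @export
is_rare <- function(calls, params = taxonomy_params()) {
  calls <- calls[calls != "MISSING" & !is.na(calls)]
  carriers <- sum(calls %in% c("HET", "HOM_ALT"))
  if (carriers == 0L) stop("no carriers: not a SNP", call. = FALSE)
  carriers <= params$rare_max_carriers
}

#' Build the multi-variety genotype matrix
#'
#' Combines per-variety call tables (which include homozygous-reference rows
#' as "sufficient information") into one row per candidate position: positions
#' where at least one variety calls a non-reference genotype, at least
#' \code{min_informative_varieties} varieties are informative, retained.
#' Cells of varieties lacking coverage are "MISSING".
#'
#' @param calls_list named list of per-variety call tables from
#'   \code{\link{call_variants}}.
#' @param params a \code{taxonomy_params}.
#' @return \code{data.table} with transcript, pos, ref, one column per
#'   variety, and n_informative.
#' @export
build_genotype_matrix <- function(calls_list, params = taxonomy_params()) {
  stopifnot(length(calls_list) >= 2L, !is.null(names(calls_list)))
  varieties <- names(calls_list)
  long <- rbindlist(lapply(varieties, function(v) {
    dt <- as.data.table(calls_list[[v]])[, .(transcript, pos, ref, genotype)]
    dt[, variety := v]
    dt
  }))
  cand <- unique(long[genotype != "HOM_REF", .(transcript, pos)])
  if (nrow(cand) == 0L)
    return(data.table(transcript = character(), pos = integer(),
                      ref = character()))
  long <- long[cand, on = c("transcript", "pos")]
  refs <- long[!is.na(ref), .(ref = ref[1L]), by = .(transcript, pos)]
  wide <- data.table::dcast(long, transcript + pos ~ variety,
                            value.var = "genotype")
  for (v in varieties) {
    col <- wide[[v]]
    col[is.na(col)] <- "MISSING"
    wide[[v]] <- col
  }
  wide <- merge(wide, refs, by = c("transcript", "pos"))
  gm <- as.matrix(wide[, varieties, with = FALSE])
  wide[, n_informative := rowSums(gm != "MISSING")]
  wide <- wide[n_informative >= params$min_informative_varieties]
  setcolorder(wide, c("transcript", "pos", "ref", varieties, "n_informative"))
  setorder(wide, transcript, pos)
  wide[]
}

#' Classify every row of a genotype matrix
#'
#' Adds the SNP class, carrier count, non-reference frequency, histogram bin
#' and rarity flag to each retained row.
#'
#' @param gm genotype matrix from \code{\link{build_genotype_matrix}}.
#' @param params a \code{taxonomy_params}.
#' @return the matrix with class, carriers, frequency, bin, bin_label and
#'   rare columns appended.
#' @export
classify_genotype_matrix <- function(gm, params = taxonomy_params()) {
  gm <- as.data.table(gm)
  varieties <- setdiff(names(gm), c("transcript", "pos", "ref",
                                    "n_informative", "class", "carriers",
                                    "frequency", "bin", "bin_label", "rare"))
  M <- as.matrix(gm[, varieties, with = FALSE])
  n_ref <- rowSums(M == "HOM_REF")
  n_alt <- rowSums(M == "HOM_ALT")
  n_het <- rowSums(M == "HET")
  n_inf <- n_ref + n_alt + n_het
  if (any(n_alt + n_het == 0L))
    stop("genotype matrix contains all-reference rows", call. = FALSE)
  cls <- rep("multi_genotype", nrow(gm))
  cls[n_het == 0L & n_ref == 0L] <- "misassembly"
  cls[n_het > 0L & n_ref == 0L & n_alt == 0L] <- "inter_homoeolog"
  cls[n_het == 0L & n_ref > 0L & n_alt > 0L] <- "simple"
  cls[n_het > 0L & xor(n_ref > 0L, n_alt > 0L)] <- "hemi"
  f <- (n_het + n_alt) / n_inf
  k <- pmin(pmax(floor((f - params$bin_origin) / params$bin_width), 0),
            params$n_bins - 1L)
  lo <- params$bin_origin + k * params$bin_width
  gm[, `:=`(class = cls,
            carriers = as.integer(n_het + n_alt),
            frequency = f,
            bin = as.integer(k + 1L),
            bin_label = sprintf("%.2f-%.2f", lo, lo + params$bin_width),
            rare = (n_het + n_alt) <= params$rare_max_carriers)]
  gm[]
}

#' Partition summary of classified SNPs
#'
#' @param classes character vector (or classified matrix) of SNP classes.
#' @return list with \code{partition} (class, count, percent -- percentages of
#'   the total, rounded to 2 decimals), \code{total}, and
#'   \code{varietal_snps} (simple + hemi + multi_genotype count).
#' @export
summarize_partition <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$class
  stopifnot(all(classes %in% .SNP_CLASSES))
  counts <- vapply(.SNP_CLASSES, function(cl) sum(classes == cl), integer(1))
  total <- length(classes)
  partition <- data.table(
    class = .SNP_CLASSES,
    count = as.integer(counts),
    percent = round(counts / total * 100, 2)
  )
  list(partition = partition, total = total,
       varietal_snps = as.integer(counts[["simple"]] + counts[["hemi"]] +
                                    counts[["multi_genotype"]]))
}

#' Select array candidate SNPs
#'
#' Candidates for assay design are varietal simple and hemi SNPs confirmed in
#' at least \code{selection_min_carriers} varieties; inter-homoeolog and
#' misassembly positions are excluded as non-varietal.
#'
#' @param classified classified genotype matrix
#'   (\code{\link{classify_genotype_matrix}}).
#' @param params a \code{taxonomy_params}.
#' @return the selected rows.
#' @export
select_array_candidates <- function(classified, params = taxonomy_params()) {
  classified <- as.data.table(classified)
  classified[class %in% c("simple", "hemi") &
               carriers >= params$selection_min_carriers]
}
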