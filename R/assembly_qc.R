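# Assembly-completeness metrics from BLAST-style alignment hits.
#
# A hit against a benchmark gene is accepted when any of three length
# conditions holds (>= 60% of the contig, > 80% of the gene, >= 200 bp);
# accepted hits give the fraction of the gene span covered, the minimal
# number of contigs needed to achieve that span, and -- using the identity
# pattern of a known homoeolog gene pair -- an estimate of how many of the
# two homoeolog copies the assembly reconstructed.

#' Hit acceptance rule
#'
#' @param hit_length alignment length in bp.
#' @param contig_length length of the matching contig.
#' @param gene_length length of the benchmark gene.
#' @param identity percent identity of the hit.
#' @param params a \code{qc_params}.
#' @return TRUE when the hit passes the identity pre-filter and any of the
#'   three length conditions.
#' @export
accept_hit <- function(hit_length, contig_length, gene_length, identity = 100,
                       params = qc_params()) {
  identity >= params$min_identity &
    (hit_length >= params$hit_contig_fraction * contig_length |
       hit_length > params$hit_gene_fraction * gene_length |
       hit_length >= params$hit_min_length)
}

# minimal contig subset achieving the union span: greedy cover, picking the
# contig adding the most uncovered bases; ties broken by longer total hit
.greedy_contig_cover <- function(hits, target) {
  chosen <- character(0)
  covered <- IRanges::IRanges()
  remaining <- unique(hits$contig)
  target_len <- sum(IRanges::width(target))
  while (sum(IRanges::width(covered)) < target_len && length(remaining)) {
    gain <- vapply(remaining, function(ctg) {
      h <- hits[hits$contig == ctg, ]
      r <- IRanges::reduce(IRanges::IRanges(h$gstart + 1L, h$gend))
      sum(IRanges::width(IRanges::setdiff(r, covered)))
    }, numeric(1))
    tot <- vapply(remaining, function(ctg)
      sum(hits$gend[hits$contig == ctg] - hits$gstart[hits$contig == ctg]),
      numeric(1))
    best <- remaining[order(-gain, -tot, remaining)][1L]
    if (gain[match(best, remaining)] <= 0) break
    h <- hits[hits$contig == best, ]
    covered <- IRanges::reduce(c(covered,
                                 IRanges::IRanges(h$gstart + 1L, h$gend)))
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, best)
  }
  chosen
}

#' Gene-reconstruction accounting for one benchmark gene
#'
#' @param hits \code{data.table} of this gene's accepted hits with columns
#'   contig, gstart, gend (0-based half-open gene coordinates), identity.
#'   Hits extending beyond the gene are clipped with a warning.
#' @param gene_length gene length in bp.
#' @param params a \code{qc_params}.
#' @return list with \code{span_fraction} (union of hit intervals over gene
#'   length), \code{contigs_needed} (size of a minimal contig subset
#'   achieving that union, greedy), \code{reconstructed}
#'   (span >= \code{reconstructed_span}) and \code{contigs} (the subset).
#' @export
gene_reconstruction <- function(hits, gene_length, params = qc_params()) {
  hits <- as.data.table(hits)
  if (nrow(hits) == 0L)
    return(list(span_fraction = 0, contigs_needed = 0L,
                reconstructed = FALSE, contigs = character(0)))
  if (any(hits$gstart < 0L | hits$gend > gene_length)) {
    warning("hit outside gene bounds clipped")
    hits[, `:=`(gstart = pmax(gstart, 0L),
                gend = pmin(gend, gene_length))]
    hits <- hits[gend > gstart]
  }
  union_ <- IRanges::reduce(IRanges::IRanges(hits$gstart + 1L, hits$gend))
  span <- sum(IRanges::width(union_)) / gene_length
  chosen <- .greedy_contig_cover(hits, union_)
  list(span_fraction = span, contigs_needed = length(chosen),
       reconstructed = span >= params$reconstructed_span,
       contigs = chosen)
}

# non-overlapping cumulative coverage of a set of hits: overlaps keep the
# higher-identity hit and trim the other
.nonoverlap_coverage <- function(hits, gene_length) {
  if (nrow(hits) == 0L) return(0)
  hits <- hits[order(-hits$identity, hits$gstart), ]
  covered <- IRanges::IRanges()
  total <- 0L
  for (i in seq_len(nrow(hits))) {
    r <- IRanges::IRanges(hits$gstart[i] + 1L, hits$gend[i])
    add <- IRanges::setdiff(r, covered)
    total <- total + sum(IRanges::width(add))
    covered <- IRanges::reduce(c(covered, r))
  }
  total / gene_length
}

#' Homoeolog copy-number estimate for one gene pair
#'
#' Accepted hits are assigned to the A subgenome when their identity reaches
#' \code{a_identity_floor} ("close to 100\%") and to the B subgenome when
#' their identity deviates at most \code{b_identity_band} percent from the
#' known paired identity of the homoeolog gene pair; other hits stay
#' unassigned (putative paralogs). Per-subgenome coverage uses
#' non-overlapping hit spans. Categories: \code{both} when both coverages
#' reach \code{copy_coverage_full}; \code{one} when exactly one does and the
#' other is below \code{copy_presence_floor}; \code{one_to_two} when one does
#' and the other sits between floor and full; \code{less_than_one} when
#' neither does but one reaches the floor; \code{none} otherwise.
#'
#' @param hits accepted-hit \code{data.table} (contig, gstart, gend,
#'   identity).
#' @param gene_length gene length in bp.
#' @param paired_identity percent identity between the known A/B gene pair.
#' @param params a \code{qc_params}.
#' @return list with coverage_A, coverage_B, category, indeterminate (TRUE
#'   when the A and B identity bands overlap).
#' @export
homoeolog_copy_estimate <- function(hits, gene_length, paired_identity,
                                    params = qc_params()) {
  indeterminate <- paired_identity >= params$a_identity_floor
  hits <- as.data.table(hits)
  asg <- if (nrow(hits)) ifelse(
    hits$identity >= params$a_identity_floor, "A",
    ifelse(abs(hits$identity - paired_identity) <= params$b_identity_band,
           "B", "unassigned")) else character(0)
  cov_a <- .nonoverlap_coverage(hits[asg == "A"], gene_length)
  cov_b <- .nonoverlap_coverage(hits[asg == "B"], gene_length)
  full <- params$copy_coverage_full
  floor_ <- params$copy_presence_floor
  hi <- max(cov_a, cov_b); lo <- min(cov_a, cov_b)
  category <- if (hi >= full && lo >= full) "both"
  else if (hi >= full && lo < floor_) "one"
  else if (hi >= full) "one_to_two"
  else if (hi >= floor_) "less_than_one"
  else "none"
  list(coverage_A = cov_a, coverage_B = cov_b, category = category,
       indeterminate = indeterminate)
}

#' Assembly-QC report over a benchmark gene set
#'
#' Applies the acceptance rule to a BLAST tabular hit set and computes
#' per-gene reconstruction metrics (and copy estimates where a paired
#' identity is supplied).
#'
#' @param hits BLAST hits from \code{\link{read_alignment_table}} (dialect
#'   blast-tab-12) where queries are benchmark genes and subjects contigs;
#'   query coordinates are used as gene coordinates.
#' @param gene_lengths named vector of benchmark gene lengths.
#' @param contig_lengths named vector of contig lengths.
#' @param paired_identity optional named vector (per gene) of homoeolog-pair
#'   identities enabling copy estimation.
#' @param params a \code{qc_params}.
#' @return \code{data.table} with one row per gene: n_hits, n_accepted,
#'   span_fraction, contigs_needed, reconstructed, and (when applicable)
#'   coverage_A, coverage_B, category.
#' @export
assembly_qc_report <- function(hits, gene_lengths, contig_lengths,
                               paired_identity = NULL, params = qc_params()) {
  hits <- as.data.table(hits)
  out <- vector("list", length(gene_lengths))
  for (gi in seq_along(gene_lengths)) {
    g <- names(gene_lengths)[gi]
    gl <- gene_lengths[[g]]
    h <- hits[query_id == g]
    acc_rows <- h[accept_hit(length, contig_lengths[subject_id], gl,
                             identity, params) %in% TRUE]
    gh <- data.table(contig = acc_rows$subject_id,
                     gstart = acc_rows$qstart, gend = acc_rows$qend,
                     identity = acc_rows$identity)
    rec <- gene_reconstruction(gh, gl, params)
    row <- data.table(gene = g, n_hits = nrow(h), n_accepted = nrow(gh),
                      span_fraction = rec$span_fraction,
                      contigs_needed = rec$contigs_needed,
                      reconstructed = rec$reconstructed)
    if (!is.null(paired_identity) && g %in% names(paired_identity)) {
      ce <- homoeolog_copy_estimate(gh, gl, paired_identity[[g]], params)
      row[, `:=`(coverage_A = ce$coverage_A, coverage_B = ce$coverage_B,
                 category = ce$category)]
    }
    out[[gi]] <- row
  }
  rbindlist(out, fill = TRUE)
}
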