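#' @importFrom data.table data.table := as.data.table setorder rbindlist setnames fread fwrite setkey dcast setcolorder .N .SD
#' @importFrom stats rnorm rpois rbinom rnbinom runif median p.adjust pnorm dnbinom glm coef var setNames Gamma
#' @importFrom utils head tail
NULL

# -- internal: check a scalar numeric lies in a closed range ------------------
.check_range <- function(x, lo, hi, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("parameter '%s' must be a single number in [%s, %s]",
                 name, format(lo), format(hi)), call. = FALSE)
  invisible(x)
}

#' Variant-caller parameters
#'
#' Thresholds for the quality-window read filter and the per-position calling
#' rules. Defaults follow CLC-style transcriptome SNP-calling settings:
#' an 11-base quality window around the variant
#' base with at most 6 gaps+mismatches, central base quality >= 20, window
#' average quality >= 15; calls require coverage >= 8 filtered reads and an
#' alternative allele is supported when its read count is >= 4 and either its
#' frequency is >= 10% or its absolute count reaches 1000.
#'
#' @param window_length odd window length in bp centred on the variant base.
#' @param max_gap_mismatch maximum gaps plus mismatches tolerated in the window.
#' @param min_central_quality minimum phred quality of the variant base.
#' @param min_average_quality minimum mean phred quality across the window.
#' @param min_coverage minimum filtered read depth for any call.
#' @param min_variant_frequency minimum allele frequency supporting an allele.
#' @param sufficient_variant_count absolute read support that waives the
#'   frequency requirement.
#' @param required_variant_count absolute minimum read support for any
#'   alternative allele.
#' @param hom_frequency allele frequency at or above which a supported
#'   alternative is called homozygous.
#' @return an object of class \code{caller_params}.
#' @export
caller_params <- function(window_length = 11L,
                          max_gap_mismatch = 6L,
                          min_central_quality = 20,
                          min_average_quality = 15,
                          min_coverage = 8L,
                          min_variant_frequency = 0.10,
                          sufficient_variant_count = 1000L,
                          required_variant_count = 4L,
                          hom_frequency = 0.90) {
  if (window_length %% 2L != 1L)
    stop("window_length must be odd", call. = FALSE)
  .check_range(max_gap_mismatch, 0, window_length, "max_gap_mismatch")
  .check_range(min_central_quality, 0, 93, "min_central_quality")
  .check_range(min_average_quality, 0, 93, "min_average_quality")
  .check_range(min_coverage, 1, Inf, "min_coverage")
  .check_range(min_variant_frequency, 0, 1, "min_variant_frequency")
  .check_range(hom_frequency, 0, 1, "hom_frequency")
  if (!(min_variant_frequency > 0 && min_variant_frequency < hom_frequency))
    stop("need 0 < min_variant_frequency < hom_frequency <= 1", call. = FALSE)
  structure(list(
    window_length = as.integer(window_length),
    max_gap_mismatch = as.integer(max_gap_mismatch),
    min_central_quality = min_central_quality,
    min_average_quality = min_average_quality,
    min_coverage = as.integer(min_coverage),
    min_variant_frequency = min_variant_frequency,
    sufficient_variant_count = as.integer(sufficient_variant_count),
    required_variant_count = as.integer(required_variant_count),
    hom_frequency = hom_frequency
  ), class = "caller_params")
}

#' SNP taxonomy parameters
#'
#' @param min_coverage reads needed for a genotype cell to be informative.
#' @param min_informative_varieties minimum non-missing varieties for a row to
#'   be retained (5 for the SNP table; frequency-distribution reports use 7).
#' @param rare_max_carriers carrier count at or below which a SNP is rare.
#' @param selection_min_carriers minimum carriers for array-candidate selection.
#' @param n_bins,bin_origin,bin_width frequency histogram binning scheme; the
#'   defaults give seven bins 0.05-0.18, 0.18-0.31, ..., 0.83-0.96.
#' @return an object of class \code{taxonomy_params}.
#' @export
taxonomy_params <- function(min_coverage = 8L,
                            min_informative_varieties = 5L,
                            rare_max_carriers = 1L,
                            selection_min_carriers = 3L,
                            n_bins = 7L,
                            bin_origin = 0.05,
                            bin_width = 0.13) {
  .check_range(min_coverage, 1, Inf, "min_coverage")
  .check_range(min_informative_varieties, 1, Inf, "min_informative_varieties")
  .check_range(rare_max_carriers, 0, Inf, "rare_max_carriers")
  .check_range(selection_min_carriers, 0, Inf, "selection_min_carriers")
  .check_range(n_bins, 1, Inf, "n_bins")
  .check_range(bin_origin, 0, 1, "bin_origin")
  .check_range(bin_width, 0, 1, "bin_width")
  if (bin_origin + n_bins * bin_width > 1 + bin_width)
    stop("binning scheme extends beyond frequency 1", call. = FALSE)
  structure(list(
    min_coverage = as.integer(min_coverage),
    min_informative_varieties = as.integer(min_informative_varieties),
    rare_max_carriers = as.integer(rare_max_carriers),
    selection_min_carriers = as.integer(selection_min_carriers),
    n_bins = as.integer(n_bins),
    bin_origin = bin_origin,
    bin_width = bin_width
  ), class = "taxonomy_params")
}

#' Phasing parameters
#'
#' Phase blocks are retained when their Minimum Error Correction score is at
#' most \code{max_mec} and the better haplotype matches the reference pattern
#' at \code{min_reference_concordance} of phased sites or more; that haplotype
#' is labelled A-subgenome when the match reaches \code{min_subgenome_match}.
#'
#' @param max_mec maximum MEC score for a retained block.
#' @param min_reference_concordance minimum fraction of sites phased as the
#'   reference haplotype expects, in (0.5, 1].
#' @param min_subgenome_match minimum reference match for the A-genome label,
#'   in (0.5, 1].
#' @param exhaustive_site_limit use exhaustive bipartition search up to this
#'   many heterozygous sites; larger blocks use greedy extension plus
#'   single-site flip refinement.
#' @return an object of class \code{phasing_params}.
#' @export
phasing_params <- function(max_mec = 10,
                           min_reference_concordance = 0.90,
                           min_subgenome_match = 0.90,
                           exhaustive_site_limit = 15L) {
  .check_range(max_mec, 0, Inf, "max_mec")
  if (min_reference_concordance <= 0.5 || min_reference_concordance > 1)
    stop("min_reference_concordance must be in (0.5, 1]", call. = FALSE)
  if (min_subgenome_match <= 0.5 || min_subgenome_match > 1)
    stop("min_subgenome_match must be in (0.5, 1]", call. = FALSE)
  .check_range(exhaustive_site_limit, 1, 24, "exhaustive_site_limit")
  structure(list(
    max_mec = max_mec,
    min_reference_concordance = min_reference_concordance,
    min_subgenome_match = min_subgenome_match,
    exhaustive_site_limit = as.integer(exhaustive_site_limit)
  ), class = "phasing_params")
}

#' Default pseudo-replicate scheme for the 13-variety panel
#'
#' The thirteen inbred varieties are merged into five artificial replicate
#' groups before differential-expression testing, compensating the scarcity of
#' homoeolog-specific reads in lowly expressed genes.
#'
#' @return named list of character vectors; names are group labels.
#' @export
default_replicate_scheme <- function() {
  list(
    g1 = c("Altar84", "Capeiti8", "Claudio"),
    g2 = c("Creso", "Edmore", "Kofa"),
    g3 = c("Meridiano", "Neodur", "Saragolla"),
    g4 = c("Strongfield", "Svevo"),
    g5 = c("Valnova", "Yavaros79")
  )
}

#' Differential-expression parameters
#'
#' @param glm_alpha BH-adjusted p-value threshold for the GLM Wald test.
#' @param tissue_alpha Bonferroni-corrected threshold for per-tissue tests.
#' @param lfc_cap absolute log2 fold-change above which results are excluded.
#' @param pseudo_replicate_scheme named list mapping group labels to variety
#'   name vectors; must partition the variety set.
#' @return an object of class \code{de_params}.
#' @export
de_params <- function(glm_alpha = 0.001,
                      tissue_alpha = 0.01,
                      lfc_cap = 7,
                      pseudo_replicate_scheme = default_replicate_scheme()) {
  .check_range(glm_alpha, 0, 1, "glm_alpha")
  .check_range(tissue_alpha, 0, 1, "tissue_alpha")
  .check_range(lfc_cap, 0, Inf, "lfc_cap")
  vs <- unlist(pseudo_replicate_scheme, use.names = FALSE)
  if (anyDuplicated(vs))
    stop("pseudo_replicate_scheme assigns a variety to more than one group",
         call. = FALSE)
  structure(list(
    glm_alpha = glm_alpha,
    tissue_alpha = tissue_alpha,
    lfc_cap = lfc_cap,
    pseudo_replicate_scheme = pseudo_replicate_scheme
  ), class = "de_params")
}

#' Assembly-QC parameters
#'
#' @param min_identity minimum percent identity pre-filter for hits.
#' @param hit_contig_fraction accept a hit when hit length >= this fraction of
#'   the contig length.
#' @param hit_gene_fraction accept a hit when hit length > this fraction of the
#'   gene length.
#' @param hit_min_length accept a hit when hit length >= this many bp.
#' @param reconstructed_span gene counts as reconstructed when this fraction of
#'   its span is covered.
#' @param a_identity_floor percent identity at or above which a hit is assigned
#'   to the A subgenome.
#' @param b_identity_band maximum percent deviation from the paired identity
#'   for a B-subgenome assignment.
#' @param copy_coverage_full per-subgenome coverage counting as a full copy.
#' @param copy_presence_floor coverage below which a subgenome counts as absent.
#' @return an object of class \code{qc_params}.
#' @export
qc_params <- function(min_identity = 80,
                      hit_contig_fraction = 0.60,
                      hit_gene_fraction = 0.80,
                      hit_min_length = 200L,
                      reconstructed_span = 0.80,
                      a_identity_floor = 99.0,
                      b_identity_band = 1.0,
                      copy_coverage_full = 0.80,
                      copy_presence_floor = 0.20) {
  .check_range(min_identity, 0, 100, "min_identity")
  .check_range(hit_contig_fraction, 0, 1, "hit_contig_fraction")
  .check_range(hit_gene_fraction, 0, 1, "hit_gene_fraction")
  .check_range(hit_min_length, 0, Inf, "hit_min_length")
  .check_range(reconstructed_span, 0, 1, "reconstructed_span")
  .check_range(a_identity_floor, 0, 100, "a_identity_floor")
  .check_range(b_identity_band, 0, 100, "b_identity_band")
  .check_range(copy_coverage_full, 0, 1, "copy_coverage_full")
  .check_range(copy_presence_floor, 0, 1, "copy_presence_floor")
  if (copy_presence_floor >= copy_coverage_full)
    stop("copy_presence_floor must be below copy_coverage_full", call. = FALSE)
  structure(list(
    min_identity = min_identity,
    hit_contig_fraction = hit_contig_fraction,
    hit_gene_fraction = hit_gene_fraction,
    hit_min_length = as.integer(hit_min_length),
    reconstructed_span = reconstructed_span,
    a_identity_floor = a_identity_floor,
    b_identity_band = b_identity_band,
    copy_coverage_full = copy_coverage_full,
    copy_presence_floor = copy_presence_floor
  ), class = "qc_params")
}

#' Whole-pipeline configuration
#'
#' Bundles every stage's parameter block plus the RNG seed and log level, and
#' serialises losslessly to a flat key=value text file (see
#' \code{\link{write_config}}).
#'
#' @param caller,taxonomy,phasing,de,qc per-stage parameter objects.
#' @param rng_seed integer seed used by every stochastic stage.
#' @param log_level one of "quiet", "info", "debug".
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(caller = caller_params(),
                            taxonomy = taxonomy_params(),
                            phasing = phasing_params(),
                            de = de_params(),
                            qc = qc_params(),
                            rng_seed = 1L,
                            log_level = c("info", "quiet", "debug")) {
  stopifnot(inherits(caller, "caller_params"),
            inherits(taxonomy, "taxonomy_params"),
            inherits(phasing, "phasing_params"),
            inherits(de, "de_params"),
            inherits(qc, "qc_params"))
  structure(list(
    caller = caller, taxonomy = taxonomy, phasing = phasing,
    de = de, qc = qc,
    rng_seed = as.integer(rng_seed),
    log_level = match.arg(log_level)
  ), class = "pipeline_config")
}

# flatten one parameter block to "prefix.key=value" lines
.flatten_block <- function(block, prefix) {
  keys <- setdiff(names(block), "pseudo_replicate_scheme")
  lines <- vapply(keys, function(k) {
    sprintf("%s.%s=%s", prefix, k, format(block[[k]], digits = 15))
  }, character(1))
  if (!is.null(block$pseudo_replicate_scheme)) {
    sch <- block$pseudo_replicate_scheme
    enc <- paste(vapply(names(sch), function(g)
      paste0(g, ":", paste(sch[[g]], collapse = "+")), character(1)),
      collapse = ";")
    lines <- c(lines, sprintf("%s.pseudo_replicate_scheme=%s", prefix, enc))
  }
  lines
}

#' Write a pipeline configuration to a flat key=value file
#'
#' @param config a \code{pipeline_config}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lines <- c(
    .flatten_block(config$caller, "caller"),
    .flatten_block(config$taxonomy, "taxonomy"),
    .flatten_block(config$phasing, "phasing"),
    .flatten_block(config$de, "de"),
    .flatten_block(config$qc, "qc"),
    sprintf("rng_seed=%d", config$rng_seed),
    sprintf("log_level=%s", config$log_level)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a pipeline configuration from a flat key=value file
#'
#' @param path file written by \code{\link{write_config}}.
#' @return a \code{pipeline_config}.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) stop("malformed config line: ", lines[which(eq < 0)[1]],
                        call. = FALSE)
  keys <- substr(lines, 1L, eq - 1L)
  vals <- substr(lines, eq + 1L, nchar(lines))
  kv <- setNames(as.list(vals), keys)

  take <- function(prefix, defaults) {
    out <- defaults
    for (k in names(defaults)) {
      v <- kv[[paste0(prefix, ".", k)]]
      if (is.null(v)) next
      out[[k]] <- if (k == "pseudo_replicate_scheme") {
        groups <- strsplit(v, ";", fixed = TRUE)[[1]]
        parts <- strsplit(groups, ":", fixed = TRUE)
        setNames(lapply(parts, function(p)
          strsplit(p[2], "+", fixed = TRUE)[[1]]),
          vapply(parts, `[`, character(1), 1L))
      } else if (is.numeric(defaults[[k]])) {
        as.numeric(v)
      } else v
    }
    out
  }

  pipeline_config(
    caller  = do.call(caller_params,  take("caller",  unclass(caller_params()))),
    taxonomy = do.call(taxonomy_params, take("taxonomy", unclass(taxonomy_params()))),
    phasing = do.call(phasing_params, take("phasing", unclass(phasing_params()))),
    de      = do.call(de_params,      take("de",      unclass(de_params()))),
    qc      = do.call(qc_params,      take("qc",      unclass(qc_params()))),
    rng_seed = as.integer(kv[["rng_seed"]] %||% 1L),
    log_level = kv[["log_level"]] %||% "info"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# line-oriented stage logging; honours the configured level
.log <- function(level, config_level, fmt, ...) {
  ranks <- c(quiet = 0L, info = 1L, debug = 2L)
  if (ranks[[level]] <= ranks[[config_level %||% "info"]] &&
      config_level != "quiet")
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  invisible(NULL)
}
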