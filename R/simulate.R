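# Synthetic allotetraploid (AABB) ground-truth generator.
#
# Each gene is a homoeolog pair: an A-subgenome sequence and a B-subgenome
# sequence diverging at a per-bp substitution rate (the inter-homoeolog
# sites). A panel of inbred varieties then carries varietal SNPs of each
# mechanistic class:
#   - hemi: a substitution on one subgenome in a carrier subset (heterozygous
#     look in carriers, homozygous-reference elsewhere);
#   - simple: loss of the B homoeolog transcript shared by all varieties plus
#     varietal substitutions on the retained A copy (diploid behaviour);
#   - multi_genotype: a hemi mechanism plus additional carriers homozygous for
#     the alternative allele on both subgenomes;
#   - misassembly: the reference itself mutated, so every variety is
#     homozygous-alternative against it.
# The reference transcript equals the A-subgenome sequence except at
# misassembly sites, mirroring an A-genome-like phasing reference.

.BASES <- c("A", "C", "G", "T")

.mutate_base <- function(base) {
  vapply(base, function(b) sample(setdiff(.BASES, b), 1L), character(1),
         USE.NAMES = FALSE)
}

.rand_seq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

#' Simulation parameters for the synthetic allotetraploid generator
#'
#' @param n_genes number of homoeolog gene pairs.
#' @param gene_length length range (min, max) in bp; minimum 300 bp, the
#'   assembly's minimum contig length.
#' @param homoeolog_divergence substitution rate per bp between the A and B
#'   copies; the default 0.02 gives ~98\% identity, inside the observed
#'   95-100\% band for homoeolog gene pairs.
#' @param n_varieties number of inbred varieties in the panel.
#' @param variety_names optional character vector of variety names.
#' @param class_rates per-bp injection rates for the varietal and artefact
#'   site classes (simple, hemi, multi_genotype, misassembly). Inter-homoeolog
#'   sites are the divergent sites themselves and follow
#'   \code{homoeolog_divergence}.
#' @param carriers_distribution how many varieties carry a varietal allele:
#'   \code{"uniform"} draws uniformly from 1..(n_varieties-1).
#' @param read_length read length in bp (paired 2 x 100 bp by default).
#' @param fragment_mean,fragment_sd fragment size distribution in bp; the
#'   default 200 +/- 20 makes the two 100 bp mates tile the fragment, so
#'   per-position coverage stays near-uniform even on minimum-length
#'   transcripts.
#' @param depth mean read coverage per homoeolog.
#' @param base_error_rate i.i.d. per-base sequencing error rate.
#' @param tissues tissue labels.
#' @param expr_mean negative-binomial mean expression per homoeolog unit.
#' @param expr_dispersion negative-binomial dispersion (alpha; variance =
#'   mu + alpha mu^2).
#' @param bias_fraction fraction of genes with a homoeolog expression bias.
#' @param bias_log2fc signed log2 A/B ratio for biased genes (default 1, a
#'   two-fold homoeolog bias).
#' @param site_margin polymorphic sites are confined to the uniformly covered
#'   transcript core, at least this many bp from transcript ends and from
#'   deletion junctions (default: one read length); the per-bp divergence
#'   rate is rescaled over the eligible core so the expected number of
#'   divergent sites per gene stays \code{homoeolog_divergence * length}.
#' @param seed RNG seed.
#' @return an object of class \code{sim_params}.
#' @export
sim_params <- function(n_genes = 50L,
                       gene_length = c(300L, 1500L),
                       homoeolog_divergence = 0.02,
                       n_varieties = 13L,
                       variety_names = NULL,
                       class_rates = c(simple = 0.001, hemi = 0.004,
                                       multi_genotype = 0.001,
                                       misassembly = 0.0005),
                       carriers_distribution = "uniform",
                       read_length = 100L,
                       fragment_mean = 200,
                       fragment_sd = 20,
                       depth = 30,
                       base_error_rate = 0.001,
                       tissues = c("grain", "leaf", "root"),
                       expr_mean = 200,
                       expr_dispersion = 0.05,
                       bias_fraction = 0.2,
                       bias_log2fc = 1,
                       site_margin = NULL,
                       seed = 1L) {
  if (n_varieties < 2L) stop("n_varieties must be >= 2", call. = FALSE)
  if (gene_length[1] < 300L)
    stop("gene_length minimum is 300 bp", call. = FALSE)
  if (homoeolog_divergence < 0 || homoeolog_divergence > 0.05)
    warning("homoeolog_divergence outside [0, 0.05] leaves the 95-100% ",
            "homoeolog identity band")
  for (r in class_rates) .check_range(r, 0, 1, "class_rates")
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  if (expr_dispersion <= 0) stop("expr_dispersion must be > 0", call. = FALSE)
  if (fragment_mean < read_length)
    stop("fragment size below read length", call. = FALSE)
  .check_range(bias_fraction, 0, 1, "bias_fraction")
  .check_range(base_error_rate, 0, 1, "base_error_rate")
  if (is.null(variety_names))
    variety_names <- if (n_varieties == 13L)
      unlist(default_replicate_scheme(), use.names = FALSE)
    else sprintf("v%02d", seq_len(n_varieties))
  stopifnot(length(variety_names) == n_varieties)
  structure(list(
    n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    homoeolog_divergence = homoeolog_divergence,
    n_varieties = as.integer(n_varieties),
    variety_names = variety_names,
    class_rates = class_rates,
    carriers_distribution = carriers_distribution,
    read_length = as.integer(read_length),
    fragment_mean = fragment_mean,
    fragment_sd = fragment_sd,
    depth = depth,
    base_error_rate = base_error_rate,
    tissues = tissues,
    expr_mean = expr_mean,
    expr_dispersion = expr_dispersion,
    bias_fraction = bias_fraction,
    bias_log2fc = bias_log2fc,
    site_margin = as.integer(if (is.null(site_margin)) read_length
                             else site_margin),
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Simulate one homoeolog transcript pair
#'
#' Draws a random A-subgenome sequence and substitutes bases at a per-bp rate
#' to obtain the diverged B copy. Uses the current RNG state.
#'
#' @param params a \code{sim_params}.
#' @param gene_index integer index used for the gene identifier.
#' @return list with \code{gene}, \code{length}, \code{seq_a}, \code{seq_b}
#'   and \code{divergent_sites} (data.table: pos 0-based, a_allele, b_allele).
#' @export
simulate_homoeolog_pair <- function(params, gene_index = 1L) {
  L <- sample(params$gene_length[1]:params$gene_length[2], 1L)
  seq_a <- .rand_seq(L)
  m <- params$site_margin
  core <- if (L > 2L * m) (m + 1L):(L - m) else seq_len(L)
  rate <- min(1, params$homoeolog_divergence * L / length(core))
  div <- core[runif(length(core)) < rate]
  seq_b <- seq_a
  if (length(div)) {
    a_all <- substring(seq_a, div, div)
    b_all <- .mutate_base(a_all)
    for (i in seq_along(div)) substr(seq_b, div[i], div[i]) <- b_all[i]
  } else {
    a_all <- character(0); b_all <- character(0)
  }
  list(gene = sprintf("g%04d", gene_index), length = L,
       seq_a = seq_a, seq_b = seq_b,
       divergent_sites = data.table(pos = div - 1L, a_allele = a_all,
                                    b_allele = b_all))
}

# draw number of carriers for a varietal site
.draw_carriers <- function(params, min_c = 1L, max_c = params$n_varieties - 1L) {
  if (max_c < min_c) stop("carrier count exceeds n_varieties", call. = FALSE)
  if (min_c == max_c) return(min_c)
  sample(min_c:max_c, 1L)
}

#' Simulate the full allotetraploid truth set
#'
#' Generates homoeolog pairs, injects varietal SNP sites of each class into a
#' variety panel, assigns per-gene expression bias, and derives the collapsed
#' reference (A sequence with misassembly mutations). Deterministic given
#' \code{params$seed}.
#'
#' @param params a \code{sim_params}.
#' @return an object of class \code{tetra_sim}: list with params, genes,
#'   seq_a, seq_b, reference, sites, deletions, bias.
#' @export
simulate_tetraploid <- function(params = sim_params()) {
  set.seed(params$seed)
  nv <- params$n_varieties
  genes <- vector("list", params$n_genes)
  sites_l <- vector("list", params$n_genes)
  dels_l <- vector("list", params$n_genes)
  seq_a <- character(params$n_genes)
  seq_b <- character(params$n_genes)
  refs <- character(params$n_genes)
  rates <- params$class_rates

  for (gi in seq_len(params$n_genes)) {
    pair <- simulate_homoeolog_pair(params, gi)
    L <- pair$length
    div_pos1 <- pair$divergent_sites$pos + 1L  # 1-based working coords
    taken <- rep(FALSE, L)
    taken[div_pos1] <- TRUE
    # confine injected sites to the uniformly covered transcript core
    m <- min(params$site_margin, L %/% 2L)
    if (m > 0L) taken[c(seq_len(m), (L - m + 1L):L)] <- TRUE

    ref <- pair$seq_a
    sa <- pair$seq_a
    sb <- pair$seq_b

    rows <- list()
    if (nrow(pair$divergent_sites)) {
      rows[[length(rows) + 1L]] <- data.table(
        gene = pair$gene, pos = pair$divergent_sites$pos,
        class = "inter_homoeolog",
        ref = pair$divergent_sites$a_allele,
        alt = pair$divergent_sites$b_allele,
        subgenome = "B", carriers = "", hom_carriers = "")
    }

    # simple sites: loss of the whole B homoeolog transcript shared by all
    # varieties, plus varietal substitutions on the retained A copy -- the
    # single-subgenome allelic complement of the simple-SNP mechanism.
    # Divergent sites of such genes are invisible (only the reference-like A
    # copy is expressed) and carry no inter-homoeolog label.
    dels <- data.table(gene = character(), subgenome = character(),
                       start = integer(), end = integer())
    n_simple <- rbinom(1L, L, rates[["simple"]])
    single_copy <- n_simple > 0L
    if (single_copy) {
      rows <- list()  # no inter-homoeolog labels on single-copy genes
      dels <- data.table(gene = pair$gene, subgenome = "B",
                         start = 0L, end = L)
    }

    place <- function(n) {
      out <- integer(0); t2 <- 0L
      while (n > 0L && t2 < 50L * (n + 1L)) {
        t2 <- t2 + 1L
        p <- sample.int(L, 1L)
        if (taken[p]) next
        taken[p] <<- TRUE
        out <- c(out, p); n <- n - 1L
      }
      out
    }

    if (single_copy) {
      for (p in place(n_simple)) {
        refb <- substring(ref, p, p)
        rows[[length(rows) + 1L]] <- data.table(
          gene = pair$gene, pos = p - 1L, class = "simple",
          ref = refb, alt = .mutate_base(refb), subgenome = "A",
          carriers = paste(sort(sample.int(nv, .draw_carriers(params))),
                           collapse = ","),
          hom_carriers = "")
      }
    }

    for (p in if (single_copy) integer(0)
         else place(rbinom(1L, L, rates[["hemi"]]))) {
      refb <- substring(ref, p, p)
      rows[[length(rows) + 1L]] <- data.table(
        gene = pair$gene, pos = p - 1L, class = "hemi",
        ref = refb, alt = .mutate_base(refb),
        subgenome = sample(c("A", "B"), 1L),
        carriers = paste(sort(sample.int(nv, .draw_carriers(params))),
                         collapse = ","),
        hom_carriers = "")
    }

    for (p in if (single_copy) integer(0)
         else place(rbinom(1L, L, rates[["multi_genotype"]]))) {
      refb <- substring(ref, p, p)
      total <- .draw_carriers(params, min_c = 2L)
      n_hom <- sample.int(total - 1L, 1L)
      cs <- sample.int(nv, total)
      rows[[length(rows) + 1L]] <- data.table(
        gene = pair$gene, pos = p - 1L, class = "multi_genotype",
        ref = refb, alt = .mutate_base(refb),
        subgenome = sample(c("A", "B"), 1L),
        carriers = paste(sort(cs[seq_len(total - n_hom)]), collapse = ","),
        hom_carriers = paste(sort(cs[(total - n_hom + 1L):total]),
                             collapse = ","))
    }

    for (p in place(rbinom(1L, L, rates[["misassembly"]]))) {
      truthb <- substring(sa, p, p)
      refb <- .mutate_base(truthb)  # reference differs from every variety
      substr(ref, p, p) <- refb
      rows[[length(rows) + 1L]] <- data.table(
        gene = pair$gene, pos = p - 1L, class = "misassembly",
        ref = refb, alt = truthb, subgenome = "both",
        carriers = paste(seq_len(nv), collapse = ","), hom_carriers = "")
    }

    genes[[gi]] <- data.table(gene = pair$gene, length = L)
    sites_l[[gi]] <- if (length(rows)) rbindlist(rows) else NULL
    dels_l[[gi]] <- dels
    seq_a[gi] <- sa; seq_b[gi] <- sb; refs[gi] <- ref
  }

  genes <- rbindlist(genes)
  names(seq_a) <- names(seq_b) <- names(refs) <- genes$gene
  sites <- rbindlist(sites_l[!vapply(sites_l, is.null, logical(1))])
  if (nrow(sites)) setorder(sites, gene, pos)
  dels <- rbindlist(dels_l)

  # per-gene expression bias, constant across tissues
  biased <- runif(params$n_genes) < params$bias_fraction
  sign_ <- sample(c(-1, 1), params$n_genes, replace = TRUE)
  bias <- data.table(
    gene = rep(genes$gene, each = length(params$tissues)),
    tissue = rep(params$tissues, params$n_genes),
    log2_ratio = rep(ifelse(biased, sign_ * abs(params$bias_log2fc), 0),
                     each = length(params$tissues)),
    biased = rep(biased, each = length(params$tissues))
  )

  structure(list(params = params, genes = genes, seq_a = seq_a, seq_b = seq_b,
                 reference = refs, sites = sites, deletions = dels,
                 bias = bias),
            class = "tetra_sim")
}

#' Expected genotype calls implied by the simulation truth
#'
#' The decision each site's mechanism implies for every variety, before any
#' sequencing: the substrate for classifier recovery tests.
#'
#' @param sim a \code{tetra_sim}.
#' @return \code{data.table} with gene, pos, class and one column per variety
#'   holding "HOM_REF", "HET" or "HOM_ALT".
#' @export
truth_genotypes <- function(sim) {
  nv <- sim$params$n_varieties
  s <- sim$sites
  if (nrow(s) == 0L) return(data.table())
  g <- matrix("HOM_REF", nrow = nrow(s), ncol = nv)
  for (i in seq_len(nrow(s))) {
    cls <- s$class[i]
    cs <- if (nzchar(s$carriers[i]))
      as.integer(strsplit(s$carriers[i], ",")[[1]]) else integer(0)
    hs <- if (nzchar(s$hom_carriers[i]))
      as.integer(strsplit(s$hom_carriers[i], ",")[[1]]) else integer(0)
    if (cls == "inter_homoeolog") g[i, ] <- "HET"
    else if (cls == "hemi") g[i, cs] <- "HET"
    else if (cls == "simple") g[i, cs] <- "HOM_ALT"
    else if (cls == "multi_genotype") { g[i, cs] <- "HET"; g[i, hs] <- "HOM_ALT" }
    else if (cls == "misassembly") g[i, ] <- "HOM_ALT"
  }
  out <- data.table(gene = s$gene, pos = s$pos, class = s$class)
  for (v in seq_len(nv)) out[[sim$params$variety_names[v]]] <- g[, v]
  out
}

#' Materialise the two subgenome sequences of one variety
#'
#' @param sim a \code{tetra_sim}.
#' @param variety variety index (1-based) or name.
#' @return list with named character vectors \code{A} and \code{B}.
#' @export
variety_sequences <- function(sim, variety) {
  if (is.character(variety))
    variety <- match(variety, sim$params$variety_names)
  sa <- sim$seq_a
  sb <- sim$seq_b
  s <- sim$sites
  if (nrow(s)) {
    for (i in which(s$class %in% c("hemi", "simple", "multi_genotype"))) {
      cs <- as.integer(strsplit(s$carriers[i], ",")[[1]])
      hs <- if (nzchar(s$hom_carriers[i]))
        as.integer(strsplit(s$hom_carriers[i], ",")[[1]]) else integer(0)
      p <- s$pos[i] + 1L
      gene <- s$gene[i]
      if (variety %in% hs) {  # multi-genotype homozygous carrier: both copies
        substr(sa[gene], p, p) <- s$alt[i]
        substr(sb[gene], p, p) <- s$alt[i]
      } else if (variety %in% cs) {
        if (s$subgenome[i] == "A") substr(sa[gene], p, p) <- s$alt[i]
        else substr(sb[gene], p, p) <- s$alt[i]
      }
    }
  }
  list(A = sa, B = sb)
}

#' Simulate paired-end reads for one variety and tissue
#'
#' Fragment counts per gene follow a Poisson law with total mean
#' \code{2 * depth * L / (2 * read_length)} split between subgenomes by the
#' tissue's true expression ratio, so each homoeolog's expected coverage is
#' \code{depth} in the unbiased case. Fragments overlapping a deleted
#' homoeolog segment on their subgenome are not produced. Base errors are
#' i.i.d.; qualities are Q30 except Q10 at error positions. Reads are
#' reported in reference (forward) orientation with their true 0-based
#' alignment positions, i.e. as a perfect aligner would place them.
#'
#' @param sim a \code{tetra_sim}.
#' @param variety variety index or name.
#' @param tissue tissue label.
#' @return \code{data.table}: read_id, variety, tissue, gene, subgenome
#'   (truth), mate, pos, seq, qual.
#' @export
simulate_reads <- function(sim, variety, tissue) {
  params <- sim$params
  if (is.numeric(variety)) variety <- params$variety_names[variety]
  stopifnot(tissue %in% params$tissues)
  if (params$fragment_mean < params$read_length)
    stop("fragment size below read length", call. = FALSE)
  rl <- params$read_length
  vseq <- variety_sequences(sim, variety)
  out <- vector("list", nrow(sim$genes) * 2L)
  k <- 0L
  for (gi in seq_len(nrow(sim$genes))) {
    gid <- sim$genes$gene[gi]
    L <- sim$genes$length[gi]
    lfc <- sim$bias$log2_ratio[sim$bias$gene == gid &
                                 sim$bias$tissue == tissue][1]
    p_a <- 2^lfc / (1 + 2^lfc)
    for (sub in c("A", "B")) {
      # kept reference segments after any homoeolog-segment deletions: the
      # subgenome's transcript is their concatenation, so fragments are
      # sampled on the shortened sequence; a pair may straddle a deletion
      # junction but a single read must map within one segment
      # plain-vector subset: bare column names would shadow locals here
      keep_del <- sim$deletions$gene == gid & sim$deletions$subgenome == sub
      del <- as.data.frame(sim$deletions)[keep_del, ]
      if (nrow(del)) {
        del <- del[order(del$start), ]
        seg_start <- c(0L, del$end)
        seg_end <- c(del$start, L)
        keep_seg <- seg_end > seg_start
        seg_start <- seg_start[keep_seg]; seg_end <- seg_end[keep_seg]
      } else {
        seg_start <- 0L; seg_end <- L
      }
      seg_len <- seg_end - seg_start
      Ls <- sum(seg_len)                      # shortened transcript length
      seg_off <- cumsum(c(0L, seg_len))[seq_along(seg_len)]
      w <- if (sub == "A") p_a else 1 - p_a
      n <- rpois(1L, params$depth * Ls / rl * w)
      if (n == 0L || Ls < rl) next
      flen <- pmin(Ls, pmax(rl, round(rnorm(n, params$fragment_mean,
                                            params$fragment_sd))))
      start <- floor(runif(n, 0, Ls - flen + 1))  # 0-based, shortened coords
      p2s <- start + flen - rl
      seg1 <- findInterval(start, seg_off)
      seg2 <- findInterval(p2s, seg_off)
      ok <- start + rl <= seg_off[seg1] + seg_len[seg1] &
        p2s + rl <= seg_off[seg2] + seg_len[seg2]
      start <- start[ok]; p2s <- p2s[ok]
      seg1 <- seg1[ok]; seg2 <- seg2[ok]
      n <- length(start)
      if (n == 0L) next
      # map shortened coordinates back to reference coordinates
      start_ref <- seg_start[seg1] + (start - seg_off[seg1])
      p2_ref <- seg_start[seg2] + (p2s - seg_off[seg2])
      gseq <- vseq[[sub]][[gid]]
      s1 <- substring(gseq, start_ref + 1L, start_ref + rl)
      s2 <- substring(gseq, p2_ref + 1L, p2_ref + rl)
      start <- start_ref
      p2 <- p2_ref
      ids <- sprintf("%s_%s_%s_%s_%05d", variety, tissue, gid, sub,
                     seq_len(n))
      reads <- data.table(
        read_id = rep(ids, 2L),
        variety = variety, tissue = tissue, gene = gid, subgenome = sub,
        mate = rep(1:2, each = n),
        pos = c(start, p2),
        seq = c(s1, s2)
      )
      k <- k + 1L
      out[[k]] <- reads
    }
  }
  reads <- rbindlist(out[seq_len(k)])
  if (nrow(reads) == 0L) {
    reads[, qual := character(0)]
    return(reads)
  }
  q30 <- strrep("?", rl)  # phred 30
  reads[, qual := q30]
  if (params$base_error_rate > 0) {
    nerr <- rbinom(nrow(reads), rl, params$base_error_rate)
    idx <- which(nerr > 0L)
    for (i in idx) {
      ep <- sample.int(rl, nerr[i])
      sq <- reads$seq[i]; ql <- reads$qual[i]
      for (p in ep) {
        substr(sq, p, p) <- .mutate_base(substring(sq, p, p))
        substr(ql, p, p) <- "+"  # phred 10
      }
      reads[i, `:=`(seq = sq, qual = ql)]
    }
  }
  reads[]
}

#' Simulate a homoeolog-specific count matrix over tissues and replicates
#'
#' Draws negative-binomial counts for each gene's A and B unit across
#' pseudo-replicate groups within tissues. Biased genes have an A/B mean
#' ratio of \code{2^bias_log2fc}; per-gene and per-gene-by-tissue lognormal
#' variation makes the tissue factor informative.
#'
#' @param sim a \code{tetra_sim} (supplies bias truth and parameters).
#' @param n_groups number of pseudo-replicate columns per tissue.
#' @param column_depths optional per-column depth multipliers (length
#'   \code{n_groups * length(tissues)}); defaults to 1.
#' @return list with \code{counts} (integer matrix, rows "gene.A"/"gene.B"),
#'   \code{units} (data.table gene, subgenome), \code{col_data} (tissue,
#'   group), and \code{truth} (the per-gene bias table).
#' @export
simulate_counts <- function(sim, n_groups = 5L, column_depths = NULL) {
  params <- sim$params
  tissues <- params$tissues
  nc <- n_groups * length(tissues)
  if (is.null(column_depths)) column_depths <- rep(1, nc)
  stopifnot(length(column_depths) == nc)
  genes <- sim$genes$gene
  ng <- length(genes)
  base_mean <- params$expr_mean * 2^rnorm(ng, 0, 0.5)
  tissue_eff <- matrix(2^rnorm(ng * length(tissues), 0, 0.5), ng)
  # bias table is gene-major with tissues nested; one lfc per gene
  lfc <- sim$bias$log2_ratio[seq(1, nrow(sim$bias), by = length(tissues))]
  units <- data.table(gene = rep(genes, each = 2L),
                      subgenome = rep(c("A", "B"), ng))
  col_data <- data.table(tissue = rep(tissues, each = n_groups),
                         group = rep(sprintf("g%d", seq_len(n_groups)),
                                     length(tissues)))
  counts <- matrix(0L, nrow = 2L * ng, ncol = nc,
                   dimnames = list(paste(units$gene, units$subgenome,
                                         sep = "."),
                                   paste(col_data$tissue, col_data$group,
                                         sep = ".")))
  size <- 1 / params$expr_dispersion
  for (j in seq_len(nc)) {
    ti <- match(col_data$tissue[j], tissues)
    mu_a <- base_mean * tissue_eff[, ti] * 2^(lfc / 2) * column_depths[j]
    mu_b <- base_mean * tissue_eff[, ti] * 2^(-lfc / 2) * column_depths[j]
    mu <- as.vector(rbind(mu_a, mu_b))
    counts[, j] <- rnbinom(2L * ng, mu = mu, size = size)
  }
  list(counts = counts, units = units, col_data = col_data,
       truth = data.table(gene = genes, log2_ratio = lfc,
                          biased = lfc != 0))
}
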