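# Double-reference homoeolog-specific counting and differential expression.
#
# Reads are scored against the A and B variants of each reconstructed block;
# a pair counts for the variant it matches strictly better (matching bases
# minus mismatching bases over the block region) and is dropped as ambiguous
# on ties -- which is exactly the set of pairs covering no divergent site.
# Counts from the inbred varieties are merged into five pseudo-replicate
# groups per tissue, normalised by median-of-ratios size factors, given
# pooled method-of-moments dispersions with an a0 + a1/mu trend, and tested
# with (i) a negative-binomial GLM Wald test on the subgenome factor across
# tissues and (ii) a per-tissue conditioned exact negative-binomial test.

#' Assign reads to homoeolog-specific block sequences
#'
#' Score difference between the A and B variants is twice the difference in
#' divergent sites matched, so only the sites where the reconstructed A and B
#' sequences differ are inspected; pairs covering no divergent site tie and
#' are removed as ambiguous. A proper pair increments its unit by exactly 1.
#'
#' @param aln alignment table (read_id, transcript/gene, pos, seq) for one
#'   sample, aligned to the original transcript coordinates.
#' @param sequences reconstructed sequence set from
#'   \code{\link{reconstruct_homoeologs}}.
#' @return list with \code{counts} (data.table: transcript, block, subgenome,
#'   count) and \code{assignments} (data.table: read_id, transcript, block,
#'   subgenome).
#' @export
assign_reads <- function(aln, sequences) {
  aln <- as.data.table(aln)
  if (!"transcript" %in% names(aln) && "gene" %in% names(aln))
    setnames(aln, "gene", "transcript")
  sequences <- as.data.table(sequences)
  # divergent positions (transcript coords) between each piece's A and B
  sites_l <- vector("list", nrow(sequences))
  for (i in seq_len(nrow(sequences))) {
    a <- utf8ToInt(sequences$seq_a[i])
    b <- utf8ToInt(sequences$seq_b[i])
    d <- which(a != b)
    if (!length(d)) next
    sites_l[[i]] <- data.table(
      transcript = sequences$transcript[i], block = sequences$block[i],
      spos = sequences$start[i] + d - 1L,
      a_allele = vapply(a[d], intToUtf8, character(1)),
      b_allele = vapply(b[d], intToUtf8, character(1)))
  }
  sites <- rbindlist(sites_l[!vapply(sites_l, is.null, logical(1))])
  empty <- list(counts = data.table(transcript = character(),
                                    block = integer(),
                                    subgenome = character(),
                                    count = integer()),
                assignments = data.table(read_id = character(),
                                         transcript = character(),
                                         block = integer(),
                                         subgenome = character()))
  if (nrow(sites) == 0L || nrow(aln) == 0L) return(empty)

  reads <- aln[, .(read_id, transcript, pos, seq, len = nchar(seq))]
  reads[, end := pos + len]
  setkey(sites, transcript, spos)
  ov <- sites[reads,
              on = .(transcript, spos >= pos, spos < end),
              .(read_id, transcript, block,
                spos = x.spos, a_allele, b_allele,
                rpos = x.spos - i.pos + 1L, seq = i.seq),
              nomatch = NULL]
  if (nrow(ov) == 0L) return(empty)
  ov[, base := substring(seq, rpos, rpos)]
  ov[, score := (base == a_allele) - (base == b_allele)]
  pair_block <- ov[, .(score = sum(score)), by = .(read_id, block)]
  # a pair spanning a split boundary goes to the block with stronger evidence
  best <- pair_block[order(read_id, -abs(score), block)][, .SD[1L],
                                                         by = read_id]
  best <- best[score != 0L]
  if (nrow(best) == 0L) return(empty)
  tx_of <- unique(ov[, .(read_id, transcript)])
  best <- merge(best, tx_of, by = "read_id")
  best[, subgenome := ifelse(score > 0L, "A", "B")]
  assignments <- best[, .(read_id, transcript, block, subgenome)]
  counts <- assignments[, .(count = .N), by = .(transcript, block, subgenome)]
  setorder(counts, transcript, block, subgenome)
  list(counts = counts[], assignments = assignments[])
}

#' Merge per-variety counts into pseudo-replicate groups
#'
#' @param counts \code{data.table} with variety, tissue, transcript, block,
#'   subgenome, count.
#' @param scheme named list of variety groups
#'   (\code{\link{default_replicate_scheme}}); must cover every variety in
#'   \code{counts}.
#' @param tissues tissue order for the (tissue-major, group-minor) columns.
#' @return list with \code{counts} (integer matrix, rows
#'   "transcript.blockN.A/B"), \code{units} (transcript, block, subgenome) and
#'   \code{col_data} (tissue, group).
#' @export
merge_pseudo_replicates <- function(counts, scheme = default_replicate_scheme(),
                                    tissues = NULL) {
  counts <- as.data.table(counts)
  vmap <- rep(names(scheme), lengths(scheme))
  names(vmap) <- unlist(scheme, use.names = FALSE)
  unknown <- setdiff(unique(counts$variety), names(vmap))
  if (length(unknown))
    stop("varieties absent from the pseudo-replicate scheme: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(tissues)) tissues <- sort(unique(counts$tissue))
  counts[, group := vmap[variety]]
  agg <- counts[, .(count = sum(count)),
                by = .(transcript, block, subgenome, tissue, group)]
  units <- unique(agg[, .(transcript, block, subgenome)])
  setorder(units, transcript, block, subgenome)
  col_data <- data.table(tissue = rep(tissues, each = length(scheme)),
                         group = rep(names(scheme), length(tissues)))
  M <- matrix(0L, nrow(units), nrow(col_data),
              dimnames = list(
                sprintf("%s.block%d.%s", units$transcript, units$block,
                        units$subgenome),
                paste(col_data$tissue, col_data$group, sep = ".")))
  ri <- match(sprintf("%s.block%d.%s", agg$transcript, agg$block,
                      agg$subgenome), rownames(M))
  ci <- match(paste(agg$tissue, agg$group, sep = "."), colnames(M))
  ok <- !is.na(ci)
  M[cbind(ri[ok], ci[ok])] <- agg$count[ok]
  list(counts = M, units = units, col_data = col_data)
}

#' Median-of-ratios size factors
#'
#' Each column's factor is the median across all-positive rows of the ratio
#' between the column's count and the row's geometric mean, normalised so the
#' factors have geometric mean 1.
#'
#' @param counts integer count matrix (units x samples).
#' @return numeric vector of positive per-column factors.
#' @export
size_factors <- function(counts) {
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use)) {
    warning("no row with all-positive counts; ",
            "falling back to per-column positive-subset medians")
    raw <- apply(counts, 2L, function(k) {
      pos <- k > 0
      median(exp(log(k[pos]) - rowMeans(log(counts + 1))[pos]))
    })
  } else {
    raw <- apply(counts, 2L, function(k)
      exp(median(log(k[use]) - log_gm[use])))
  }
  raw / exp(mean(log(raw)))
}

#' Pooled method-of-moments dispersion estimation
#'
#' Per unit, a method-of-moments dispersion is computed within each tissue's
#' replicate columns on normalised counts and pooled across tissues weighted
#' by degrees of freedom; a mean-dispersion trend
#' \code{alpha(mu) = a0 + a1/mu} is then fitted across units and each unit
#' takes the larger of its empirical and fitted value (conservative choice).
#'
#' @param counts count matrix.
#' @param sf size factors.
#' @param col_data \code{data.table} with a tissue column matching the matrix
#'   columns.
#' @return \code{data.table}: unit (rowname), mu, disp_emp, disp_fit,
#'   dispersion (NA for all-zero units), plus the trend coefficients as
#'   attribute \code{"trend"}.
#' @export
estimate_dispersion <- function(counts, sf, col_data) {
  q <- sweep(counts, 2L, sf, "/")
  tissues <- unique(col_data$tissue)
  num <- rep(0, nrow(counts)); den <- rep(0, nrow(counts))
  for (t in tissues) {
    j <- which(col_data$tissue == t)
    if (length(j) < 2L) next
    mu_t <- rowMeans(q[, j, drop = FALSE])
    v_t <- apply(q[, j, drop = FALSE], 1L, var)
    z_t <- mu_t * mean(1 / sf[j])
    d_t <- ifelse(mu_t > 0, (v_t - z_t) / mu_t^2, NA_real_)
    w <- length(j) - 1L
    ok <- !is.na(d_t)
    num[ok] <- num[ok] + w * d_t[ok]
    den[ok] <- den[ok] + w
  }
  disp_emp <- ifelse(den > 0, num / den, NA_real_)
  mu <- rowMeans(q)
  fit_ok <- !is.na(disp_emp) & disp_emp > 1e-8 & mu > 0
  trend <- c(a0 = 1e-8, a1 = 0)
  if (sum(fit_ok) >= 10L) {
    fit <- tryCatch(suppressWarnings(
      glm(disp_emp[fit_ok] ~ I(1 / mu[fit_ok]),
          family = Gamma(link = "identity"),
          start = c(0.1, 1))),
      error = function(e) NULL)
    cf <- if (!is.null(fit) && fit$converged) coef(fit)
    else coef(stats::lm(disp_emp[fit_ok] ~ I(1 / mu[fit_ok])))
    trend <- c(a0 = max(cf[[1]], 1e-8), a1 = max(cf[[2]], 0))
  }
  disp_fit <- ifelse(mu > 0, trend[["a0"]] + trend[["a1"]] / mu, NA_real_)
  dispersion <- ifelse(mu > 0, pmax(disp_emp, disp_fit, 1e-8, na.rm = TRUE),
                       NA_real_)
  out <- data.table(unit = rownames(counts), mu = mu, disp_emp = disp_emp,
                    disp_fit = disp_fit, dispersion = dispersion)
  attr(out, "trend") <- trend
  out
}

# split "tx.blockN.A" rownames back into unit keys
.unit_keys <- function(units) {
  sprintf("%s.block%d", units$transcript, units$block)
}

.pair_units <- function(counts, units) {
  units <- as.data.table(units)
  if (!"transcript" %in% names(units) && "gene" %in% names(units))
    setnames(units, "gene", "transcript")
  if (!"block" %in% names(units)) units[, block := 1L]
  uk <- .unit_keys(units)
  a_row <- which(units$subgenome == "A")
  b_row <- match(uk[a_row], uk[units$subgenome == "B"])
  b_idx <- which(units$subgenome == "B")[b_row]
  ok <- !is.na(b_idx)
  data.table(unit_key = uk[a_row][ok],
             transcript = units$transcript[a_row][ok],
             block = units$block[a_row][ok],
             a = a_row[ok], b = b_idx[ok])
}

#' GLM Wald test for homoeolog differential expression
#'
#' For each gene-block, counts of the A and B units across all samples are
#' modelled with a log-link negative-binomial regression on tissue plus
#' subgenome (size factors as offset, fixed per-unit dispersion); the Wald
#' statistic on the subgenome coefficient gives the p-value, BH-adjusted over
#' all tested blocks. log2 fold-changes (A over B) come from normalised means
#' with a 0.5 pseudocount; blocks beyond the \code{lfc_cap} are never flagged
#' significant.
#'
#' @param counts count matrix.
#' @param units unit table (transcript/gene, block, subgenome per row).
#' @param col_data tissue/group table for the columns.
#' @param params a \code{de_params}.
#' @param sf,disp optional precomputed size factors and dispersion table.
#' @return \code{data.table}: transcript, block, lfc, p, padj, significant,
#'   direction, converged.
#' @export
glm_wald_test <- function(counts, units, col_data, params = de_params(),
                          sf = NULL, disp = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(disp)) disp <- estimate_dispersion(counts, sf, col_data)
  pairs <- .pair_units(counts, units)
  tissue <- factor(col_data$tissue)
  multi_tissue <- nlevels(tissue) > 1L
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ka <- counts[pairs$a[i], ]
    kb <- counts[pairs$b[i], ]
    if (sum(ka) + sum(kb) == 0) next
    alpha <- max(disp$dispersion[pairs$a[i]], disp$dispersion[pairs$b[i]],
                 1e-8, na.rm = TRUE)
    y <- c(ka, kb)
    sub <- factor(rep(c("A", "B"), each = length(ka)), levels = c("B", "A"))
    tis <- rep(tissue, 2L)
    off <- rep(log(sf), 2L)
    fit <- tryCatch(suppressWarnings(
      if (multi_tissue)
        glm(y ~ tis + sub + offset(off),
            family = MASS::negative.binomial(theta = 1 / alpha),
            control = stats::glm.control(maxit = 100))
      else
        glm(y ~ sub + offset(off),
            family = MASS::negative.binomial(theta = 1 / alpha),
            control = stats::glm.control(maxit = 100))),
      error = function(e) NULL)
    ma <- mean(ka / sf); mb <- mean(kb / sf)
    lfc <- log2((ma + 0.5) / (mb + 0.5))
    if (is.null(fit) || !fit$converged) {
      res[[i]] <- data.table(transcript = pairs$transcript[i],
                             block = pairs$block[i], lfc = lfc,
                             p = NA_real_, converged = FALSE)
      next
    }
    # dispersion fixed at 1: the NB variance is already in the family
    sm <- summary(fit, dispersion = 1)$coefficients
    row <- grep("^subA$", rownames(sm))
    z <- sm[row, "z value"]
    res[[i]] <- data.table(transcript = pairs$transcript[i],
                           block = pairs$block[i], lfc = lfc,
                           p = 2 * pnorm(-abs(z)), converged = TRUE)
  }
  out <- rbindlist(res[!vapply(res, is.null, logical(1))])
  if (nrow(out) == 0L) return(out)
  out[, padj := p.adjust(p, method = "BH")]
  out[, significant := !is.na(padj) & padj <= params$glm_alpha &
        abs(lfc) <= params$lfc_cap]
  out[, direction := ifelse(lfc > 0, "A-up", "B-up")]
  out[]
}

# conditioned exact negative-binomial test on summed counts
.nb_exact_p <- function(ka, kb, mu_a, mu_b, size_a, size_b) {
  ks <- ka + kb
  if (ks == 0L) return(NA_real_)
  if (ks <= 10000L) {
    a <- 0:ks
    pr <- dnbinom(a, size = size_a, mu = mu_a) *
      dnbinom(ks - a, size = size_b, mu = mu_b)
    tot <- sum(pr)
    if (tot == 0) return(1)
    min(1, sum(pr[pr <= pr[ka + 1L] * (1 + 1e-7)]) / tot)
  } else {
    # asymptotic fallback for very deep units
    va <- mu_a + mu_a^2 / size_a
    vb <- mu_b + mu_b^2 / size_b
    z <- (ka - kb) / sqrt(va + vb)
    2 * pnorm(-abs(z))
  }
}

#' Per-tissue exact negative-binomial homoeolog test
#'
#' Within one tissue, the A and B counts of each gene-block are summed over
#' the replicate columns and compared with a conditioned exact
#' negative-binomial test under the pooled dispersion (asymptotic fallback
#' above 10,000 total reads). P-values are Bonferroni-corrected over the
#' units tested in the tissue.
#'
#' @param counts count matrix.
#' @param units unit table.
#' @param col_data tissue/group table.
#' @param tissue tissue label to test.
#' @param params a \code{de_params}.
#' @param sf,disp optional precomputed size factors and dispersion table.
#' @return \code{data.table}: transcript, block, tissue, lfc, p, p_corrected,
#'   significant, direction.
#' @export
tissue_nb_test <- function(counts, units, col_data, tissue,
                           params = de_params(), sf = NULL, disp = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(disp)) disp <- estimate_dispersion(counts, sf, col_data)
  j <- which(col_data$tissue == tissue)
  if (!length(j)) stop("unknown tissue: ", tissue, call. = FALSE)
  pairs <- .pair_units(counts, units)
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ka_v <- counts[pairs$a[i], j]
    kb_v <- counts[pairs$b[i], j]
    ka <- sum(ka_v); kb <- sum(kb_v)
    if (ka + kb == 0L) next
    alpha <- max(disp$dispersion[pairs$a[i]], disp$dispersion[pairs$b[i]],
                 1e-8, na.rm = TRUE)
    s <- sum(sf[j])
    mu0 <- (ka + kb) / (2 * s)          # pooled per-unit base mean
    mu_sum <- mu0 * s
    v_sum <- sum(mu0 * sf[j] + alpha * (mu0 * sf[j])^2)
    size_sum <- if (v_sum > mu_sum) mu_sum^2 / (v_sum - mu_sum) else 1e8
    p <- .nb_exact_p(ka, kb, mu_sum, mu_sum, size_sum, size_sum)
    lfc <- log2((ka / s + 0.5) / (kb / s + 0.5))
    res[[i]] <- data.table(transcript = pairs$transcript[i],
                           block = pairs$block[i], tissue = tissue,
                           lfc = lfc, p = p)
  }
  out <- rbindlist(res[!vapply(res, is.null, logical(1))])
  if (nrow(out) == 0L) return(out)
  out[, p_corrected := pmin(1, p * .N)]
  out[, significant := !is.na(p_corrected) &
        p_corrected <= params$tissue_alpha & abs(lfc) <= params$lfc_cap]
  out[, direction := ifelse(lfc > 0, "A-up", "B-up")]
  out[]
}

#' Fold-change concordance across phase blocks of a gene
#'
#' Genes reconstructed in two or more phased blocks should show the same
#' homoeolog fold-change direction in every block; discordance flags phasing
#' or assignment errors.
#'
#' @param results GLM result table (\code{\link{glm_wald_test}}).
#' @return list with \code{genes} (transcript, n_blocks, concordant) and
#'   \code{summary} (n_genes, n_concordant, fraction).
#' @export
block_concordance <- function(results) {
  results <- as.data.table(results)
  multi <- results[, .N, by = transcript][N >= 2L, transcript]
  genes <- results[transcript %in% multi,
                   .(n_blocks = .N,
                     concordant = all(lfc > 0) || all(lfc < 0)),
                   by = transcript]
  list(genes = genes,
       summary = data.table(n_genes = nrow(genes),
                            n_concordant = sum(genes$concordant),
                            fraction = if (nrow(genes)) mean(genes$concordant)
                            else NA_real_))
}
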