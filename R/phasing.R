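# Read-backed phase reconstruction of heterozygous (inter-homoeolog) sites.
#
# Each read pair becomes a fragment: its observed allele (0 = reference,
# 1 = alternative, NA = gap/other) at every heterozygous site it covers.
# Sites co-covered by a fragment are connected; each connectivity component
# is a candidate phase block, resolved into two complementary haplotypes by
# minimising the MEC score: the total number of fragment-allele corrections
# needed for every fragment to be consistent with one of the two haplotypes.
# Because the reference is A-genome-like, the haplotype matching the
# all-reference pattern is labelled A and its complement B.

#' Build read-backed fragments over heterozygous sites
#'
#' Mates sharing a read identifier are merged into one fragment; a site where
#' the mates disagree is set to gap. Alleles matching neither the reference
#' nor the alternative are gaps. Fragments informative for phasing cover at
#' least two sites; sites never co-covered end up in different connectivity
#' components.
#'
#' @param aln alignment table for one transcript (read_id, pos 0-based, seq).
#' @param het_sites \code{data.table} with pos (0-based), ref, alt for the
#'   transcript's heterozygous sites, sorted by pos.
#' @return list with \code{fragments} (matrix: fragments x sites, values
#'   0/1/NA, rownames read ids) and \code{components} (integer vector:
#'   component id per site).
#' @export
build_fragments <- function(aln, het_sites) {
  het_sites <- as.data.table(het_sites)
  setorder(het_sites, pos)
  ns <- nrow(het_sites)
  if (ns == 0L)
    return(list(fragments = matrix(integer(0), 0, 0), components = integer(0)))
  aln <- as.data.table(aln)
  # which reads cover which sites
  len <- nchar(aln$seq)
  pieces <- lapply(seq_len(ns), function(i) {
    p <- het_sites$pos[i]
    hit <- which(aln$pos <= p & aln$pos + len > p)
    if (!length(hit)) return(NULL)
    base <- substring(aln$seq[hit], p - aln$pos[hit] + 1L,
                      p - aln$pos[hit] + 1L)
    allele <- ifelse(base == het_sites$ref[i], 0L,
                     ifelse(base == het_sites$alt[i], 1L, NA_integer_))
    data.table(read_id = aln$read_id[hit], site = i, allele = allele)
  })
  obs <- rbindlist(pieces[!vapply(pieces, is.null, logical(1))])
  if (nrow(obs) == 0L)
    return(list(fragments = matrix(integer(0), 0, ns),
                components = seq_len(ns)))
  # merge mates: conflicting alleles at a shared site -> gap
  obs <- obs[, .(allele = if (length(unique(allele[!is.na(allele)])) == 1L)
    unique(allele[!is.na(allele)]) else NA_integer_),
    by = .(read_id, site)]
  obs <- obs[!is.na(allele)]
  cov_n <- obs[, .N, by = read_id]
  obs <- obs[read_id %in% cov_n[N >= 2L, read_id]]
  frag_ids <- unique(obs$read_id)
  F <- matrix(NA_integer_, length(frag_ids), ns,
              dimnames = list(frag_ids, NULL))
  if (nrow(obs)) F[cbind(match(obs$read_id, frag_ids), obs$site)] <- obs$allele

  # connectivity components via union-find over sites
  parent <- seq_len(ns)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(F)) {
    for (r in seq_len(nrow(F))) {
      s <- which(!is.na(F[r, ]))
      if (length(s) > 1L)
        for (j in s[-1L]) {
          a <- find(s[1L]); b <- find(j)
          if (a != b) parent[b] <- a
        }
    }
  }
  comp <- vapply(seq_len(ns), find, integer(1))
  comp <- match(comp, unique(comp))
  list(fragments = F, components = comp)
}

# MEC score of a haplotype assignment h (0/1 vector over sites) for a
# fragment matrix F: each fragment counts its smaller mismatch count against
# h or its complement.
.mec_score <- function(F, h) {
  mism <- sweep(F, 2L, h, function(a, b) (a != b) + 0L)
  m1 <- rowSums(mism, na.rm = TRUE)
  cov <- rowSums(!is.na(F))
  sum(pmin(m1, cov - m1))
}

# greedy left-to-right extension + single-site flip refinement, multi-start
.phase_heuristic <- function(F) {
  ns <- ncol(F)
  refine <- function(h) {
    best <- .mec_score(F, h)
    repeat {
      improved <- FALSE
      # single-site flips
      for (j in seq_len(ns)) {
        h2 <- h; h2[j] <- 1L - h2[j]
        sc <- .mec_score(F, h2)
        if (sc < best) { h <- h2; best <- sc; improved <- TRUE }
      }
      # suffix flips repair chain-break errors single flips cannot reach
      for (j in seq_len(ns)) {
        h2 <- h; h2[j:ns] <- 1L - h2[j:ns]
        sc <- .mec_score(F, h2)
        if (sc < best) { h <- h2; best <- sc; improved <- TRUE }
      }
      if (!improved) break
    }
    list(h = h, mec = best)
  }
  greedy <- function() {
    h <- integer(ns)
    for (j in seq_len(ns)) {
      if (j == 1L) { h[1L] <- 0L; next }
      sub <- F[, seq_len(j), drop = FALSE]
      h[j] <- 0L
      s0 <- .mec_score(sub, h[seq_len(j)])
      h[j] <- 1L
      s1 <- .mec_score(sub, h[seq_len(j)])
      h[j] <- if (s0 <= s1) 0L else 1L
    }
    h
  }
  starts <- list(greedy(), integer(ns))
  # seed from the highest-coverage fragments, gaps filled with 0
  cov <- rowSums(!is.na(F))
  for (r in order(-cov)[seq_len(min(8L, nrow(F)))]) {
    h <- F[r, ]
    h[is.na(h)] <- 0L
    if (h[1L] == 1L) h <- 1L - h
    starts[[length(starts) + 1L]] <- h
  }
  best <- NULL
  for (h in unique(starts)) {
    cand <- refine(h)
    if (is.null(best) || cand$mec < best$mec) best <- cand
  }
  best
}

#' Phase one connectivity component by MEC minimisation
#'
#' Finds the haplotype bipartition minimising the MEC score: exhaustive search
#' over all \code{2^(n-1)} phasings when the component has at most
#' \code{exhaustive_site_limit} sites, otherwise greedy extension with
#' single-site flip refinement from multiple deterministic starts.
#'
#' @param fragments matrix (fragments x sites, 0/1/NA) restricted to one
#'   component's sites.
#' @param params a \code{phasing_params}.
#' @return NULL when fewer than 2 sites; otherwise list with \code{haplotype}
#'   (0/1 vector, first site fixed to 0), \code{mec}, and \code{n_fragments}.
#' @export
phase_block <- function(fragments, params = phasing_params()) {
  ns <- ncol(fragments)
  if (ns < 2L) return(NULL)
  F <- fragments[rowSums(!is.na(fragments)) >= 2L, , drop = FALSE]
  if (nrow(F) == 0L) return(NULL)
  if (ns <= params$exhaustive_site_limit) {
    K <- 2L^(ns - 1L)
    X <- ifelse(is.na(F), 0L, F)
    M <- (!is.na(F)) + 0L
    codes <- 0:(K - 1L)
    H <- vapply(seq_len(ns), function(j)
      if (j == 1L) rep(0L, K) else bitwAnd(bitwShiftR(codes, j - 2L), 1L),
      integer(K))           # K x ns, first site always 0
    # mismatches of each fragment against each candidate haplotype
    mism <- X %*% t(1L - H) + (M - X) %*% t(H)   # frags x K
    cov <- rowSums(M)
    mec_all <- colSums(pmin(mism, cov - mism))
    best <- which.min(mec_all)
    list(haplotype = H[best, ], mec = as.integer(mec_all[best]),
         n_fragments = nrow(F))
  } else {
    res <- .phase_heuristic(F)
    h <- res$h
    if (h[1L] == 1L) h <- 1L - h
    list(haplotype = as.integer(h), mec = as.integer(res$mec),
         n_fragments = nrow(F))
  }
}

#' Filter a phase block and assign subgenome labels
#'
#' A block is rejected when its MEC score exceeds \code{max_mec} or when
#' neither haplotype matches the all-reference pattern at
#' \code{min_reference_concordance} of sites. The better-matching haplotype is
#' labelled A-subgenome (and its complement B) when its match reaches
#' \code{min_subgenome_match}; at an exact tie both labels stay unassigned.
#'
#' @param block result of \code{\link{phase_block}}.
#' @param params a \code{phasing_params}.
#' @return NULL when rejected; otherwise the block with
#'   \code{reference_concordance}, \code{label_h1}, \code{label_h2} added,
#'   where h1 is the block haplotype and h2 its complement.
#' @export
filter_and_label <- function(block, params = phasing_params()) {
  if (is.null(block)) return(NULL)
  if (block$mec > params$max_mec) return(NULL)
  match1 <- mean(block$haplotype == 0L)
  match2 <- 1 - match1
  best <- max(match1, match2)
  if (best < params$min_reference_concordance) return(NULL)
  block$reference_concordance <- best
  if (match1 == match2) {
    block$label_h1 <- "unassigned"
    block$label_h2 <- "unassigned"
  } else if (best >= params$min_subgenome_match) {
    if (match1 > match2) { block$label_h1 <- "A"; block$label_h2 <- "B" }
    else { block$label_h1 <- "B"; block$label_h2 <- "A" }
  } else {
    block$label_h1 <- "unassigned"
    block$label_h2 <- "unassigned"
  }
  block
}

#' Phase one transcript end to end
#'
#' Builds fragments over the transcript's heterozygous sites, phases each
#' connectivity component, and filters/labels the resulting blocks.
#'
#' @param aln alignment table for the transcript.
#' @param het_sites heterozygous site table (pos, ref, alt).
#' @param params a \code{phasing_params}.
#' @return \code{data.table} of retained blocks: block id, site positions
#'   (list), ref/alt alleles (list), haplotype (list, alleles of h1), mec,
#'   reference_concordance, label_h1, label_h2, n_sites, n_fragments.
#' @export
phase_transcript <- function(aln, het_sites, params = phasing_params()) {
  het_sites <- as.data.table(het_sites)
  setorder(het_sites, pos)
  fb <- build_fragments(aln, het_sites)
  out <- list()
  for (cid in unique(fb$components)) {
    sites <- which(fb$components == cid)
    if (length(sites) < 2L) next
    sub <- fb$fragments[, sites, drop = FALSE]
    blk <- phase_block(sub, params)
    blk <- filter_and_label(blk, params)
    if (is.null(blk)) next
    out[[length(out) + 1L]] <- data.table(
      block = length(out) + 1L,
      sites = list(het_sites$pos[sites]),
      ref = list(het_sites$ref[sites]),
      alt = list(het_sites$alt[sites]),
      haplotype = list(blk$haplotype),
      mec = blk$mec,
      reference_concordance = blk$reference_concordance,
      label_h1 = blk$label_h1, label_h2 = blk$label_h2,
      n_sites = length(sites), n_fragments = blk$n_fragments)
  }
  if (!length(out))
    return(data.table(block = integer(), sites = list(), ref = list(),
                      alt = list(), haplotype = list(), mec = integer(),
                      reference_concordance = numeric(),
                      label_h1 = character(), label_h2 = character(),
                      n_sites = integer(), n_fragments = integer()))
  rbindlist(out)
}

#' Edit homoeolog-specific sequences from retained phase blocks
#'
#' The A sequence carries the A-labelled haplotype's allele at every phased
#' site and the B sequence its complement; homozygous-alternative (fixed)
#' variants are substituted into both. A transcript whose phasing produced two
#' or more discontinuous blocks is emitted as split records, one per block,
#' with split boundaries at the midpoints between neighbouring blocks so the
#' pieces tile the transcript without overlap.
#'
#' @param ref_seq reference transcript sequence (character scalar).
#' @param blocks retained block table from \code{\link{phase_transcript}};
#'   blocks without an A/B assignment are skipped.
#' @param fixed_sites optional \code{data.table} (pos, alt) of
#'   homozygous-alternative sites to edit into both sequences.
#' @return \code{data.table}: block, start, end (0-based half-open piece
#'   coordinates), seq_a, seq_b, n_phased (phased sites applied in the piece),
#'   n_fixed (fixed sites applied in the piece).
#' @export
edit_homoeolog_sequences <- function(ref_seq, blocks, fixed_sites = NULL) {
  L <- nchar(ref_seq)
  seq_a <- ref_seq
  seq_b <- ref_seq
  if (!is.null(fixed_sites) && nrow(fixed_sites)) {
    for (i in seq_len(nrow(fixed_sites))) {
      p <- fixed_sites$pos[i] + 1L
      substr(seq_a, p, p) <- fixed_sites$alt[i]
      substr(seq_b, p, p) <- fixed_sites$alt[i]
    }
  }
  blocks <- as.data.table(blocks)
  if (nrow(blocks)) blocks <- blocks[label_h1 %in% c("A", "B")]
  if (nrow(blocks) == 0L) {
    return(data.table(block = 0L, start = 0L, end = L,
                      seq_a = seq_a, seq_b = seq_b, n_phased = 0L,
                      n_fixed = if (is.null(fixed_sites)) 0L
                      else nrow(fixed_sites)))
  }
  first_pos <- vapply(blocks$sites, min, integer(1))
  blocks <- blocks[order(first_pos)]
  spans <- t(vapply(blocks$sites, range, integer(2)))
  if (nrow(blocks) > 1L &&
      any(spans[-1L, 1L] <= spans[-nrow(spans), 2L]))
    stop("overlapping phase blocks", call. = FALSE)

  nb <- nrow(blocks)
  cuts <- if (nb > 1L)
    floor((spans[-nb, 2L] + spans[-1L, 1L]) / 2) + 1L else integer(0)
  starts <- c(0L, cuts)
  ends <- c(cuts, L)

  out <- vector("list", nb)
  for (i in seq_len(nb)) {
    sa <- seq_a; sb <- seq_b
    sites <- blocks$sites[[i]]
    refs <- blocks$ref[[i]]
    alts <- blocks$alt[[i]]
    hap <- blocks$haplotype[[i]]
    a_is_h1 <- blocks$label_h1[i] == "A"
    for (j in seq_along(sites)) {
      p <- sites[j] + 1L
      h1_allele <- if (hap[j] == 0L) refs[j] else alts[j]
      h2_allele <- if (hap[j] == 0L) alts[j] else refs[j]
      if (a_is_h1) {
        substr(sa, p, p) <- h1_allele
        substr(sb, p, p) <- h2_allele
      } else {
        substr(sa, p, p) <- h2_allele
        substr(sb, p, p) <- h1_allele
      }
    }
    nf <- if (is.null(fixed_sites) || !nrow(fixed_sites)) 0L
    else sum(fixed_sites$pos >= starts[i] & fixed_sites$pos < ends[i])
    out[[i]] <- data.table(
      block = blocks$block[i], start = starts[i], end = ends[i],
      seq_a = substring(sa, starts[i] + 1L, ends[i]),
      seq_b = substring(sb, starts[i] + 1L, ends[i]),
      n_phased = length(sites), n_fixed = nf)
  }
  rbindlist(out)
}

#' Reconstruct homoeolog-specific sequences for a whole gene set
#'
#' Runs \code{\link{phase_transcript}} and
#' \code{\link{edit_homoeolog_sequences}} per transcript, using the HET calls
#' of the supplied call table as phasing sites and its HOM_ALT calls as fixed
#' variants.
#'
#' @param aln alignment table (all transcripts).
#' @param calls call table from \code{\link{call_variants}} for the sample
#'   driving the phasing.
#' @param reference named character vector of transcript sequences.
#' @param params a \code{phasing_params}.
#' @return list with \code{blocks} (per-transcript block table) and
#'   \code{sequences} (data.table: transcript, block, start, end, id_a, id_b,
#'   seq_a, seq_b), where ids follow the \code{gene.blockN.A} convention.
#' @export
reconstruct_homoeologs <- function(aln, calls, reference,
                                   params = phasing_params()) {
  aln <- as.data.table(aln)
  if (!"transcript" %in% names(aln) && "gene" %in% names(aln))
    setnames(aln, "gene", "transcript")
  calls <- as.data.table(calls)
  blocks_l <- list()
  seqs_l <- list()
  for (tx in intersect(unique(calls[genotype != "HOM_REF", transcript]),
                       names(reference))) {
    tx_calls <- calls[transcript == tx]
    het <- tx_calls[genotype == "HET", .(pos, ref, alt)]
    fixed <- tx_calls[genotype == "HOM_ALT", .(pos, alt)]
    if (nrow(het) < 2L) next
    blks <- phase_transcript(aln[transcript == tx], het, params)
    if (nrow(blks) == 0L) next
    pieces <- edit_homoeolog_sequences(reference[[tx]], blks, fixed)
    pieces[, transcript := tx]
    blks[, transcript := tx]
    blocks_l[[tx]] <- blks
    seqs_l[[tx]] <- pieces
  }
  if (!length(seqs_l))
    return(list(blocks = data.table(), sequences = data.table()))
  sequences <- rbindlist(seqs_l)
  sequences[, `:=`(id_a = sprintf("%s.block%d.A", transcript, block),
                   id_b = sprintf("%s.block%d.B", transcript, block))]
  setcolorder(sequences, c("transcript", "block", "start", "end",
                           "id_a", "id_b"))
  list(blocks = rbindlist(blocks_l), sequences = sequences[])
}
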