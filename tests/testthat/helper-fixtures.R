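# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

.memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small error-free panel: 12 genes, 13 varieties, one tissue of reads,
# per-variety calls -- enough to exercise calling/taxonomy/phasing
small_sim <- function() .memo("small_sim", function() {
  sim_params(n_genes = 12L, gene_length = c(300L, 700L),
             base_error_rate = 0, depth = 30, seed = 42L) |>
    simulate_tetraploid()
})

small_reads <- function() .memo("small_reads", function() {
  sim <- small_sim()
  set.seed(4242)
  aln <- lapply(sim$params$variety_names,
                function(v) simulate_reads(sim, v, "leaf"))
  names(aln) <- sim$params$variety_names
  aln
})

small_calls <- function() .memo("small_calls", function() {
  call_varieties(small_reads(), small_sim()$reference)
})

# independent brute-force oracle for the genotype-calling rule table
oracle_call <- function(bases, ref, params = caller_params()) {
  cov <- length(bases)
  if (cov < params$min_coverage) return(NULL)
  best_alt <- NA_character_
  best_n <- -1L
  for (a in sort(unique(bases[bases != ref]))) {
    n <- sum(bases == a)
    supported <- n >= params$required_variant_count &&
      (n / cov >= params$min_variant_frequency ||
         n >= params$sufficient_variant_count)
    if (supported && n > best_n) {
      best_alt <- a
      best_n <- n
    }
  }
  if (is.na(best_alt))
    return(list(genotype = "HOM_REF", alt = NA_character_))
  af <- best_n / cov
  rf <- sum(bases == ref) / cov
  g <- if (af >= params$hom_frequency) "HOM_ALT"
  else if (af >= params$min_variant_frequency &&
           rf >= params$min_variant_frequency) "HET"
  else "HOM_REF"
  list(genotype = g, alt = best_alt)
}

# independent rule-table oracle for the five-way SNP taxonomy
oracle_classify <- function(calls) {
  calls <- calls[calls != "MISSING"]
  r <- sum(calls == "HOM_REF")
  a <- sum(calls == "HOM_ALT")
  h <- sum(calls == "HET")
  if (h == 0 && r == 0 && a > 0) return("misassembly")
  if (h > 0 && r == 0 && a == 0) return("inter_homoeolog")
  if (h == 0 && r > 0 && a > 0) return("simple")
  if (h > 0 && r > 0 && a > 0) return("multi_genotype")
  if (h > 0) return("hemi")
  stop("not a SNP")
}

# exhaustive MEC oracle: scan every bipartition (first site fixed to 0)
oracle_mec <- function(F) {
  ns <- ncol(F)
  best <- Inf
  for (code in 0:(2^(ns - 1L) - 1L)) {
    h <- c(0L, as.integer(intToBits(code))[seq_len(ns - 1L)])
    mec <- 0L
    for (r in seq_len(nrow(F))) {
      obs <- F[r, ]
      m1 <- sum(obs != h, na.rm = TRUE)
      m0 <- sum(obs != (1L - h), na.rm = TRUE)
      mec <- mec + min(m1, m0)
    }
    if (mec < best) best <- mec
  }
  best
}

# random phasing instance: true haplotype, fragments with flip noise
random_fragments <- function(n_sites, n_frags, flip = 0.05) {
  truth <- sample(0:1, n_sites, replace = TRUE)
  F <- matrix(NA_integer_, n_frags, n_sites)
  for (r in seq_len(n_frags)) {
    a <- sample.int(n_sites - 1L, 1L)
    b <- min(n_sites, a + sample.int(4L, 1L))
    obs <- if (runif(1) < 0.5) truth[a:b] else 1L - truth[a:b]
    err <- runif(length(obs)) < flip
    obs[err] <- 1L - obs[err]
    F[r, a:b] <- obs
  }
  F[rowSums(!is.na(F)) >= 2L, , drop = FALSE]
}

# genotype-matrix row as a character vector
gt_row <- function(hom_ref = 0, hom_alt = 0, het = 0, missing = 0) {
  c(rep("HOM_REF", hom_ref), rep("HOM_ALT", hom_alt),
    rep("HET", het), rep("MISSING", missing))
}
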