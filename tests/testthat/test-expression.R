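test_that("read assignment follows the strict-better score rule", {
  pieces <- data.table::data.table(
    transcript = "g1", block = 1L, start = 0L, end = 40L,
    seq_a = paste0(strrep("A", 10), "T", strrep("A", 29)),
    seq_b = paste0(strrep("A", 10), "G", strrep("A", 29)))
  aln <- data.table::data.table(
    read_id = c("pA", "pB", "pN"),
    transcript = "g1",
    pos = c(5L, 5L, 20L),
    seq = c(paste0("AAAAA", "T", "AAAA"),   # matches A at the divergent site
            paste0("AAAAA", "G", "AAAA"),   # matches B
            strrep("A", 10)))               # covers no divergent site
  res <- assign_reads(aln, pieces)
  expect_equal(nrow(res$assignments), 2L)
  expect_equal(res$assignments$subgenome[res$assignments$read_id == "pA"], "A")
  expect_equal(res$assignments$subgenome[res$assignments$read_id == "pB"], "B")
  expect_false("pN" %in% res$assignments$read_id)  # ambiguous, dropped
  expect_equal(res$counts$count, c(1L, 1L))
})

test_that("error-free assignment never contradicts the subgenome of origin", {
  sim <- small_sim()
  aln1 <- small_reads()[[1]]
  rec <- reconstruct_homoeologs(aln1, small_calls()[[1]], sim$reference)
  res <- assign_reads(aln1, rec$sequences)
  truth <- unique(aln1[, c("read_id", "subgenome")])
  m <- merge(res$assignments, truth, by = "read_id",
             suffixes = c("", "_true"))
  expect_equal(sum(m$subgenome != m$subgenome_true), 0L)
})

test_that("pseudo-replicate merging conserves counts with ordered columns", {
  set.seed(21)
  vn <- unlist(default_replicate_scheme(), use.names = FALSE)
  counts <- data.table::CJ(variety = vn, tissue = c("grain", "leaf", "root"),
                           transcript = c("g1", "g2"), block = 1L,
                           subgenome = c("A", "B"))
  counts$count <- rpois(nrow(counts), 50)
  merged <- merge_pseudo_replicates(counts)
  expect_equal(ncol(merged$counts), 15L)
  expect_equal(colnames(merged$counts)[1:5],
               paste("grain", c("g1", "g2", "g3", "g4", "g5"), sep = "."))
  expect_equal(sum(merged$counts), sum(counts$count))
  # identity scheme leaves counts untouched
  ident <- setNames(as.list(vn), vn)
  m1 <- merge_pseudo_replicates(counts, scheme = ident)
  expect_equal(sum(m1$counts), sum(counts$count))
  expect_equal(ncol(m1$counts), 39L)
  expect_error(merge_pseudo_replicates(
    data.table::data.table(variety = "NotAVariety", tissue = "leaf",
                           transcript = "g1", block = 1L, subgenome = "A",
                           count = 1L)), "absent")
})

test_that("size factors recover scaling and match the DESeq2 oracle", {
  set.seed(22)
  base <- matrix(rnbinom(2000 * 6, mu = 100, size = 10), ncol = 6)
  scaled <- sweep(base, 2, c(1, 2, 1, 1, 1, 1), "*")
  sf <- size_factors(scaled)
  expect_equal(sf[2] / sf[1], 2, tolerance = 0.05)
  # single column normalises to 1
  expect_equal(size_factors(base[, 1, drop = FALSE]), 1)
  # depth-multiplier recovery on simulator output
  sim <- simulate_tetraploid(sim_params(n_genes = 1000L, bias_fraction = 0,
                                        expr_mean = 200, seed = 23L))
  set.seed(23)
  depths <- exp(rnorm(15, 0, 0.3))
  cc <- simulate_counts(sim, column_depths = depths)
  sf2 <- size_factors(cc$counts)
  target <- depths / exp(mean(log(depths)))
  expect_true(all(abs(sf2 / target - 1) < 0.05))

  skip_if_not_installed("DESeq2")
  ref <- DESeq2::estimateSizeFactorsForMatrix(scaled)
  expect_equal(sf / sf[1], unname(ref / ref[1]), tolerance = 1e-6)
})

test_that("dispersion estimation recovers the simulated parameter", {
  col_data <- data.table::data.table(
    tissue = rep(c("grain", "leaf", "root"), each = 5),
    group = rep(paste0("g", 1:5), 3))
  set.seed(24)
  mu <- rep(exp(runif(2000, log(50), log(2000))), each = 15)
  counts <- matrix(rnbinom(2000 * 15, mu = mu, size = 1 / 0.2),
                   ncol = 15, byrow = TRUE)
  rownames(counts) <- sprintf("u%04d", 1:2000)
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, sf, col_data)
  mid <- disp$mu >= 50
  expect_lt(abs(median(disp$disp_emp[mid], na.rm = TRUE) - 0.2), 0.04)
  # constant counts: empirical dispersion collapses, fitted floor applies
  const <- matrix(100L, 20, 15,
                  dimnames = list(sprintf("c%d", 1:20), NULL))
  d2 <- estimate_dispersion(const, rep(1, 15), col_data)
  expect_true(all(d2$disp_emp <= 0))
  expect_true(all(d2$dispersion > 0))
  # Poisson counts: fitted trend stays small at high means
  set.seed(25)
  pois <- matrix(rpois(2000 * 15, lambda = mu), ncol = 15, byrow = TRUE)
  rownames(pois) <- sprintf("p%04d", 1:2000)
  dp <- estimate_dispersion(pois, size_factors(pois), col_data)
  trend <- attr(dp, "trend")
  expect_lt(trend[["a0"]] + trend[["a1"]] / 100, 0.05)
})

test_that("GLM Wald results are antisymmetric under A/B exchange", {
  sim <- simulate_tetraploid(sim_params(n_genes = 40L, bias_fraction = 0.5,
                                        expr_mean = 500, seed = 26L))
  set.seed(26)
  cc <- simulate_counts(sim)
  res <- glm_wald_test(cc$counts, cc$units, cc$col_data)
  swapped <- cc$counts
  a_rows <- which(cc$units$subgenome == "A")
  b_rows <- which(cc$units$subgenome == "B")
  swapped[a_rows, ] <- cc$counts[b_rows, ]
  swapped[b_rows, ] <- cc$counts[a_rows, ]
  res2 <- glm_wald_test(swapped, cc$units, cc$col_data)
  expect_equal(res2$lfc, -res$lfc, tolerance = 1e-8)
  expect_equal(res2$p, res$p, tolerance = 1e-6)
})

test_that("tissue test is exact on identical counts and directional", {
  counts <- matrix(rep(c(50L, 50L), each = 15), nrow = 2, byrow = TRUE,
                   dimnames = list(c("g1.block1.A", "g1.block1.B"), NULL))
  units <- data.table::data.table(transcript = "g1", block = 1L,
                                  subgenome = c("A", "B"))
  col_data <- data.table::data.table(
    tissue = rep(c("grain", "leaf", "root"), each = 5),
    group = rep(paste0("g", 1:5), 3))
  r <- tissue_nb_test(counts, units, col_data, "leaf")
  expect_equal(r$lfc, 0)
  expect_equal(r$p, 1)
  up <- counts
  up["g1.block1.A", ] <- 400L
  r2 <- tissue_nb_test(up, units, col_data, "leaf")
  expect_equal(r2$direction, "A-up")
  expect_true(r2$significant)
})

test_that("block concordance flags sign disagreements", {
  res <- data.table::data.table(
    transcript = c("g1", "g1", "g2", "g2", "g3"),
    block = c(1L, 2L, 1L, 2L, 1L),
    lfc = c(1.2, 0.3, 1.2, -0.4, 2))
  bc <- block_concordance(res)
  expect_equal(nrow(bc$genes), 2L)  # single-block g3 not considered
  expect_true(bc$genes$concordant[bc$genes$transcript == "g1"])
  expect_false(bc$genes$concordant[bc$genes$transcript == "g2"])
  expect_equal(bc$summary$fraction, 0.5)
})

test_that("per-tissue testing controls family-wise error under the null", {
  sim <- simulate_tetraploid(sim_params(n_genes = 1000L, bias_fraction = 0,
                                        expr_mean = 200, seed = 27L))
  set.seed(27)
  cc <- simulate_counts(sim)
  r <- tissue_nb_test(cc$counts, cc$units, cc$col_data, "grain")
  expect_equal(sum(r$significant), 0L)
})
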