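test_that("zero divergence gives identical homoeolog copies", {
  p <- sim_params(homoeolog_divergence = 0, seed = 1L)
  set.seed(1)
  pair <- simulate_homoeolog_pair(p, 1L)
  expect_identical(pair$seq_a, pair$seq_b)
  expect_equal(nrow(pair$divergent_sites), 0L)
})

test_that("divergent sites are exactly the A/B differences", {
  p <- sim_params(seed = 2L)
  set.seed(2)
  for (i in 1:5) {
    pair <- simulate_homoeolog_pair(p, i)
    a <- utf8ToInt(pair$seq_a)
    b <- utf8ToInt(pair$seq_b)
    expect_identical(which(a != b) - 1L, pair$divergent_sites$pos)
    expect_false(is.unsorted(pair$divergent_sites$pos, strictly = TRUE))
  }
})

test_that("mean homoeolog identity matches the divergence rate", {
  p <- sim_params(gene_length = c(300L, 300L), homoeolog_divergence = 0.02,
                  seed = 3L)
  set.seed(3)
  ident <- vapply(1:2000, function(i) {
    pair <- simulate_homoeolog_pair(p, i)
    1 - nrow(pair$divergent_sites) / pair$length
  }, numeric(1))
  expect_lt(abs(mean(ident) - 0.98), 0.001)
  # identity band of the full generator at defaults
  sim <- small_sim()
  idm <- mapply(function(a, b) mean(utf8ToInt(a) == utf8ToInt(b)),
                sim$seq_a, sim$seq_b)
  expect_true(all(idm >= 0.95 & idm <= 1))
})

test_that("truth and reads are deterministic given the seed", {
  s1 <- simulate_tetraploid(sim_params(n_genes = 4L, seed = 9L))
  s2 <- simulate_tetraploid(sim_params(n_genes = 4L, seed = 9L))
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$reference, s2$reference)
  set.seed(5); r1 <- simulate_reads(s1, 1, "leaf")
  set.seed(5); r2 <- simulate_reads(s2, 1, "leaf")
  expect_identical(r1, r2)
})

test_that("zero class rates leave the panel identical to the reference", {
  p <- sim_params(n_genes = 3L,
                  class_rates = c(simple = 0, hemi = 0,
                                  multi_genotype = 0, misassembly = 0),
                  seed = 4L)
  sim <- simulate_tetraploid(p)
  expect_true(all(sim$sites$class == "inter_homoeolog"))
  vs <- variety_sequences(sim, 2)
  expect_identical(vs$A, sim$seq_a)
  expect_identical(vs$B, sim$seq_b)
})

test_that("class mechanisms imply the expected genotype patterns", {
  sim <- small_sim()
  tg <- truth_genotypes(sim)
  vn <- sim$params$variety_names
  gmat <- as.matrix(tg[, vn, with = FALSE])
  for (i in seq_len(nrow(tg))) {
    calls <- gmat[i, ]
    switch(tg$class[i],
      inter_homoeolog = expect_true(all(calls == "HET")),
      misassembly = expect_true(all(calls == "HOM_ALT")),
      simple = expect_true(all(calls %in% c("HOM_REF", "HOM_ALT")) &&
                             any(calls == "HOM_ALT") &&
                             any(calls == "HOM_REF")),
      hemi = expect_true(all(calls %in% c("HOM_REF", "HET")) &&
                           any(calls == "HET") && any(calls == "HOM_REF")),
      multi_genotype = expect_true(any(calls == "HET") &&
                                     any(calls == "HOM_ALT") &&
                                     any(calls == "HOM_REF")))
  }
})

test_that("per-homoeolog read depth follows the Poisson coverage law", {
  p <- sim_params(n_genes = 1L, gene_length = c(1000L, 1000L), depth = 50,
                  bias_fraction = 0, base_error_rate = 0,
                  class_rates = c(simple = 0, hemi = 0.004,
                                  multi_genotype = 0.001,
                                  misassembly = 0.0005),
                  seed = 6L)
  sim <- simulate_tetraploid(p)
  set.seed(6)
  reads <- simulate_reads(sim, 1, "leaf")
  pairs_per_sub <- reads[, .N / 2, by = subgenome]$V1
  lambda <- 50 * 1000 / (2 * 100)  # depth * L / (2 * read_length)
  expect_true(all(abs(pairs_per_sub - lambda) <= 3 * sqrt(lambda)))
  # unbiased origin split is symmetric
  n_a <- sum(reads$subgenome == "A") / 2
  n <- nrow(reads) / 2
  expect_lt(abs(n_a / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("base errors appear at the configured rate with Q10 qualities", {
  p <- sim_params(n_genes = 2L, gene_length = c(500L, 500L),
                  base_error_rate = 0.01, depth = 30, seed = 7L)
  sim <- simulate_tetraploid(p)
  set.seed(7)
  reads <- simulate_reads(sim, 1, "leaf")
  qn <- unlist(lapply(reads$qual, function(q) utf8ToInt(q) - 33L))
  err_frac <- mean(qn == 10L)
  expect_lt(abs(err_frac - 0.01), 0.005)
  expect_true(all(qn %in% c(10L, 30L)))
})

test_that("simulated counts reflect the configured bias and dispersion", {
  p0 <- sim_params(n_genes = 300L, bias_fraction = 0, expr_mean = 1000,
                   expr_dispersion = 0.05, seed = 8L)
  sim0 <- simulate_tetraploid(p0)
  set.seed(8)
  c0 <- simulate_counts(sim0)
  a <- c0$counts[c0$units$subgenome == "A", ]
  b <- c0$counts[c0$units$subgenome == "B", ]
  lr <- log2(rowSums(a) / rowSums(b))
  expect_lt(abs(mean(lr)), 0.05)

  p2 <- sim_params(n_genes = 300L, bias_fraction = 1, bias_log2fc = 2,
                   expr_mean = 2000, expr_dispersion = 0.05, seed = 9L)
  sim2 <- simulate_tetraploid(p2)
  set.seed(9)
  c2 <- simulate_counts(sim2)
  a <- c2$counts[c2$units$subgenome == "A", ]
  b <- c2$counts[c2$units$subgenome == "B", ]
  ratio <- rowSums(a) / rowSums(b)
  signs <- sign(c2$truth$log2_ratio)
  expect_lt(abs(mean(log2(ratio) * signs) - 2), 0.1)

  # near-zero dispersion approaches Poisson: variance ~ mean
  pp <- sim_params(n_genes = 500L, bias_fraction = 0, expr_mean = 100,
                   expr_dispersion = 1e-6, seed = 10L)
  simp <- simulate_tetraploid(pp)
  set.seed(10)
  cp <- simulate_counts(simp)
  m <- rowMeans(cp$counts[, 1:5])     # one tissue's replicates
  v <- apply(cp$counts[, 1:5], 1, var)
  big <- m >= 50
  expect_lt(abs(mean(v[big] / m[big]) - 1), 0.15)
})

test_that("carrier draws never exceed the panel size", {
  p <- sim_params(n_varieties = 3L, seed = 11L)
  set.seed(11)
  for (i in 1:200) expect_lte(tetrasnp:::.draw_carriers(p), 2L)
  expect_error(tetrasnp:::.draw_carriers(p, min_c = 5L), "carrier count")
})
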